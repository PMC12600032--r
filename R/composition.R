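# Old-growth vs secondary forest composition per cluster / ecosystem.

composition_from <- function(tbl, group_col, type_col = "forest_type") {
  typed <- dplyr::filter(tbl, .data[[type_col]] %in% c("OGF", "SF"))
  n_untyped <- nrow(tbl) - nrow(typed)
  if (n_untyped > 0) {
    rlang::inform(sprintf("%d record(s) without a valid forest type excluded",
                          n_untyped))
  }
  out <- typed |>
    dplyr::group_by(ecosystem = as.character(.data[[group_col]])) |>
    dplyr::summarise(
      n_OGF = sum(.data[[type_col]] == "OGF"),
      n_SF = sum(.data[[type_col]] == "SF"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      proportion_OGF = .data$n_OGF / (.data$n_OGF + .data$n_SF),
      proportion_SF = .data$n_SF / (.data$n_OGF + .data$n_SF)
    )
  out
}

#' Forest-type composition of the in situ clusters
#'
#' Per cluster, the share of plots typed as old-growth (OGF) versus
#' secondary (SF) forest. Plots without a valid type are excluded from the
#' denominators; clusters with no typed plot are omitted with a warning.
#'
#' @param plot_metadata Plot table with `plot_id` and `forest_type`
#'   (`"OGF"` or `"SF"`).
#' @param labels Site-to-cluster labels (a `bioregion_clustering`, tibble,
#'   or named vector).
#' @return A tibble with `ecosystem`, `n_OGF`, `n_SF`, `proportion_OGF`,
#'   `proportion_SF`.
#' @export
composition_by_cluster <- function(plot_metadata, labels) {
  lab_tbl <- if (inherits(labels, "bioregion_clustering")) labels$labels
    else if (is.data.frame(labels)) as_tibble(labels)
    else tibble(site_id = names(labels), cluster_id = unname(labels))
  joined <- plot_metadata |>
    dplyr::mutate(plot_id = as.character(.data$plot_id)) |>
    dplyr::inner_join(
      dplyr::mutate(lab_tbl, site_id = as.character(.data$site_id)),
      by = c("plot_id" = "site_id")
    )
  empty <- setdiff(unique(as.character(lab_tbl$cluster_id)),
                   unique(as.character(joined$cluster_id[
                     joined$forest_type %in% c("OGF", "SF")])))
  if (length(empty) > 0) {
    warn(paste0("cluster(s) without typed plots omitted: ",
                paste(empty, collapse = ", ")))
  }
  composition_from(joined, "cluster_id")
}

#' Forest-type composition of predicted ecosystems from pixel counts
#'
#' @param pixel_table Pixel table with `ecosystem` and `forest_type`
#'   columns (one row per pixel).
#' @return A tibble with `ecosystem`, `n_OGF`, `n_SF`, `proportion_OGF`,
#'   `proportion_SF`.
#' @export
composition_by_ecosystem <- function(pixel_table) {
  if (!all(c("ecosystem", "forest_type") %in% names(pixel_table))) {
    abort("pixel table needs `ecosystem` and `forest_type` columns")
  }
  composition_from(pixel_table, "ecosystem")
}

#' Compare two forest-type compositions of the same ecosystems
#'
#' Per shared ecosystem, the absolute difference in old-growth share
#' between two composition tables (e.g. in situ clusters vs
#' model-predicted ecosystems), with a flag for rows where the dominant
#' forest type inverts between the two sources; plus the mean and SD of
#' the differences. Symmetric in its arguments.
#'
#' @param a,b Composition tables from [composition_by_cluster()] /
#'   [composition_by_ecosystem()] (or any tibble with `ecosystem` and
#'   `proportion_OGF`).
#' @return A list of class `composition_comparison`: `by_ecosystem`
#'   (tibble `ecosystem`, `ogf_a`, `ogf_b`, `abs_diff`, `inverted`),
#'   `mean_abs_diff`, `sd_abs_diff`.
#' @export
compare_compositions <- function(a, b) {
  shared <- intersect(a$ecosystem, b$ecosystem)
  if (length(shared) == 0) abort("the two tables share no ecosystem ids")
  tbl <- dplyr::inner_join(
    dplyr::select(a, "ecosystem", ogf_a = "proportion_OGF"),
    dplyr::select(b, "ecosystem", ogf_b = "proportion_OGF"),
    by = "ecosystem"
  ) |>
    dplyr::mutate(
      abs_diff = abs(.data$ogf_a - .data$ogf_b),
      inverted = (.data$ogf_a - 0.5) * (.data$ogf_b - 0.5) < 0
    )
  structure(
    list(
      by_ecosystem = tbl,
      mean_abs_diff = mean(tbl$abs_diff),
      sd_abs_diff = stats::sd(tbl$abs_diff)
    ),
    class = "composition_comparison"
  )
}

#' @export
print.composition_comparison <- function(x, ...) {
  cat(sprintf(
    "Forest-type composition: mean |dOGF| = %.0f%% +/- %.0f%% over %d ecosystems",
    100 * x$mean_abs_diff, 100 * x$sd_abs_diff, nrow(x$by_ecosystem)
  ), "\n")
  inv <- x$by_ecosystem$ecosystem[x$by_ecosystem$inverted]
  if (length(inv) > 0) {
    cat("  dominant type inverts for:", paste(inv, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.composition_comparison <- function(x, ...) x$by_ecosystem

#' @export
glance.composition_comparison <- function(x, ...) {
  tibble(
    mean_abs_diff = x$mean_abs_diff, sd_abs_diff = x$sd_abs_diff,
    n_ecosystems = nrow(x$by_ecosystem),
    n_inverted = sum(x$by_ecosystem$inverted)
  )
}
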