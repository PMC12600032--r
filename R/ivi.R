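# Dominant-species selection by the Importance Value Index (IVI).

#' Read and validate a tree inventory table
#'
#' Loads a tree record table from a CSV file (or validates an in-memory data
#' frame) with columns `plot_id`, `subplot_id`, `species` and `dbh_cm`.
#' Records with diameter at breast height below 10 cm are censused differently
#' in most national inventories and are rejected here: the analysis targets
#' the canopy community.
#'
#' @param x Path to a CSV file, or a data frame with the four columns above.
#' @param min_dbh Minimum DBH in cm; records below it are dropped with a
#'   warning (default 10).
#' @return A tibble with columns `plot_id`, `subplot_id`, `species`,
#'   `dbh_cm`.
#' @export
read_tree_records <- function(x, min_dbh = 10) {
  rec <- if (is.character(x)) readr::read_csv(x, show_col_types = FALSE) else as_tibble(x)
  need <- c("plot_id", "subplot_id", "species", "dbh_cm")
  miss <- setdiff(need, names(rec))
  if (length(miss) > 0) {
    abort(paste0("tree record table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (any(!nzchar(as.character(rec$species)))) abort("empty species names found")
  below <- rec$dbh_cm < min_dbh
  if (any(below)) {
    warn(sprintf("dropping %d record(s) with DBH < %g cm", sum(below), min_dbh))
    rec <- rec[!below, , drop = FALSE]
  }
  if (nrow(rec) == 0) abort("no tree records left after DBH filtering")
  dplyr::mutate(rec,
    plot_id = as.character(.data$plot_id),
    subplot_id = as.character(.data$subplot_id),
    species = as.character(.data$species)
  )
}

#' Basal area of a stem from its DBH
#'
#' @param dbh_cm Diameter at breast height in cm.
#' @return Basal area in m^2 (`pi * (dbh/200)^2`).
#' @export
basal_area <- function(dbh_cm) pi * (dbh_cm / 200)^2

#' Importance Value Index per species and plot
#'
#' For every (plot, species) pair computes the three classical components of
#' Curtis & McIntosh's importance value: relative density (share of stems),
#' relative dominance (share of basal area) and relative frequency (share of
#' subplot-presence counts), each expressed in percent so that every
#' component sums to 100 within a plot. The IVI is the mean of the three
#' components, so per-plot IVI totals are also 100: a species with
#' IVI >= 5 holds at least 5% of the plot's importance.
#'
#' @param records Tree record table as returned by [read_tree_records()].
#' @return A tibble with columns `plot_id`, `species`, `n_stems`,
#'   `basal_area_m2`, `n_subplots`, `rel_density`, `rel_dominance`,
#'   `rel_frequency`, `ivi`.
#' @examples
#' rec <- tibble::tibble(
#'   plot_id = "p1",
#'   subplot_id = c("s1", "s1", "s2", "s2"),
#'   species = c("A", "A", "A", "B"),
#'   dbh_cm = c(20, 25, 30, 25)
#' )
#' compute_ivi(rec)
#' @export
compute_ivi <- function(records) {
  records <- read_tree_records(records)
  per_sp <- records |>
    dplyr::group_by(.data$plot_id, .data$species) |>
    dplyr::summarise(
      n_stems = dplyr::n(),
      basal_area_m2 = sum(basal_area(.data$dbh_cm)),
      n_subplots = dplyr::n_distinct(.data$subplot_id),
      .groups = "drop"
    )
  out <- per_sp |>
    dplyr::group_by(.data$plot_id) |>
    dplyr::mutate(
      rel_density = 100 * .data$n_stems / sum(.data$n_stems),
      rel_dominance = 100 * .data$basal_area_m2 / sum(.data$basal_area_m2),
      rel_frequency = 100 * .data$n_subplots / sum(.data$n_subplots),
      ivi = (.data$rel_density + .data$rel_dominance + .data$rel_frequency) / 3
    ) |>
    dplyr::ungroup()
  if (any(!is.finite(out$rel_dominance))) {
    abort("plot with zero total basal area")
  }
  out
}

#' Select dominant species and build the site-by-species abundance table
#'
#' Keeps, in every plot, the species whose IVI is at least `threshold_pct`
#' (inclusive), and returns a wide site-by-species table of stem counts for
#' the union of species kept anywhere. Plots where no species reaches the
#' threshold carry no dominance signal and are dropped with a warning.
#'
#' @param ivi IVI table from [compute_ivi()].
#' @param threshold_pct IVI threshold in percent (default 5, the value used
#'   for national-scale dominance screening).
#' @return A wide tibble: `plot_id` plus one integer column per dominant
#'   species (stem counts; 0 where the species was not retained for a plot).
#' @export
select_dominant <- function(ivi, threshold_pct = 5) {
  stopifnot(threshold_pct >= 0, threshold_pct <= 100)
  kept <- dplyr::filter(ivi, .data$ivi >= threshold_pct)
  lost <- setdiff(unique(ivi$plot_id), unique(kept$plot_id))
  if (length(lost) > 0) {
    warn(sprintf(
      "dropping %d plot(s) with no species at IVI >= %g%%: %s",
      length(lost), threshold_pct, paste(head(lost, 5), collapse = ", ")
    ))
  }
  if (nrow(kept) == 0) abort("no species passes the IVI threshold in any plot")
  kept |>
    dplyr::select("plot_id", "species", "n_stems") |>
    tidyr::pivot_wider(
      names_from = "species", values_from = "n_stems", values_fill = 0L,
      names_sort = TRUE
    ) |>
    dplyr::arrange(.data$plot_id)
}

#' Cumulative IVI retained by a dominance threshold
#'
#' For each threshold, sums per plot the IVI of the retained species and
#' averages over plots (plot-weighted mean). Because the per-plot IVI total
#' is 100, the result reads directly as the mean percentage of plot
#' importance captured by the dominant set; it is non-increasing in the
#' threshold.
#'
#' @param ivi IVI table from [compute_ivi()].
#' @param thresholds Numeric vector of thresholds in percent.
#' @return A tibble with columns `threshold` and `mean_retained_ivi`.
#' @export
ivi_retention <- function(ivi, thresholds) {
  stopifnot(all(thresholds >= 0), all(thresholds <= 100))
  purrr::map_dfr(thresholds, function(t) {
    per_plot <- ivi |>
      dplyr::group_by(.data$plot_id) |>
      dplyr::summarise(retained = sum(.data$ivi[.data$ivi >= t]), .groups = "drop")
    tibble(threshold = t, mean_retained_ivi = mean(per_plot$retained))
  })
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same sites,
#' computed from the contingency table under the permutation model. Equals 1
#' for identical partitions (up to label renaming) and is 0 in expectation
#' for independent partitions.
#'
#' @param labels_a,labels_b Vectors of cluster labels over the same sites
#'   (values are compared as factors; names, if present on both, are used to
#'   align the sites).
#' @return A single number in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    if (!setequal(names(labels_a), names(labels_b))) {
      abort("partitions are over different site sets")
    }
    labels_b <- labels_b[names(labels_a)]
  }
  if (length(labels_a) != length(labels_b)) {
    abort("partitions must cover the same sites")
  }
  n <- length(labels_a)
  if (n < 2) abort("need at least 2 sites")
  tab <- table(labels_a, labels_b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(n)
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Sensitivity of the clustering to the IVI threshold
#'
#' Re-runs dominant-species selection and the full turnover clustering at
#' each threshold, then compares every pair of resulting partitions with the
#' Adjusted Rand Index on the plots retained by both runs.
#'
#' @param records Tree record table.
#' @param thresholds Numeric vector of IVI thresholds (>= 2 values).
#' @param k Number of clusters to cut at; `NULL` (default) selects k by the
#'   elbow rule independently per threshold.
#' @param n_randomizations,seed,k_range Passed to the clustering stage (see
#'   [cluster_sites()]).
#' @return A symmetric matrix of ARI values with unit diagonal, one
#'   row/column per threshold.
#' @export
threshold_sensitivity <- function(records, thresholds, k = NULL,
                                  n_randomizations = 100, seed = 1,
                                  k_range = NULL) {
  stopifnot(length(thresholds) >= 2)
  ivi <- compute_ivi(records)
  runs <- purrr::map(thresholds, function(t) {
    mat <- suppressWarnings(select_dominant(ivi, threshold_pct = t))
    res <- cluster_sites(mat,
      n_randomizations = n_randomizations, seed = seed,
      k = k, k_range = k_range
    )
    setNames(res$labels$cluster_id, res$labels$site_id)
  })
  m <- length(thresholds)
  out <- matrix(1, m, m, dimnames = list(thresholds, thresholds))
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      common <- intersect(names(runs[[i]]), names(runs[[j]]))
      out[i, j] <- out[j, i] <-
        adjusted_rand_index(runs[[i]][common], runs[[j]][common])
    }
  }
  out
}
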