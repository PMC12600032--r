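# Species test values, contributive sets and the cluster-interaction matrix.

#' Species test values per cluster
#'
#' For species i and cluster j, the test value is the standardised
#' difference between the species' mean abundance in the cluster and its
#' global mean:
#' \deqn{\rho_{ij} = \frac{\mu_{ij} - \mu}
#'   {\sqrt{\frac{n - n_j}{n - 1} \cdot \frac{\sigma^2}{n_j}}}}
#' where \eqn{n} is the total number of sites, \eqn{n_j} the cluster size,
#' and \eqn{\mu}, \eqn{\sigma^2} the mean and population variance of the
#' species' abundances over all sites. The denominator is exactly the
#' standard deviation of the mean of \eqn{n_j} sites drawn without
#' replacement from the full site pool, so \eqn{\rho} reads as a z-score of
#' over/under-representation. Species with zero variance carry no signal and
#' get \eqn{\rho = 0} everywhere.
#'
#' @param matrix Site-by-species abundance table (wide tibble or matrix).
#' @param labels Cluster labels covering all sites (named vector or tibble
#'   with `site_id`, `cluster_id`).
#' @return An object of class `species_test_values`: list with `rho`
#'   (species x cluster matrix), `mu`, `sigma2`, `n`, `n_j`, `mu_ij`.
#' @export
test_values <- function(matrix, labels) {
  m <- as_species_matrix(matrix)
  lab <- align_labels(labels, rownames(m))
  n <- nrow(m)
  if (n < 2) abort("need at least 2 sites")
  clusters <- sort(unique(as.character(lab)))
  n_j <- purrr::map_int(clusters, ~ sum(lab == .x))
  names(n_j) <- clusters
  if (any(n_j == n)) abort("a cluster equal to the full site set has an undefined test value")
  mu <- colMeans(m)
  sigma2 <- colMeans(m^2) - mu^2           # population variance (divisor n)
  mu_ij <- vapply(clusters, function(cl) colMeans(m[lab == cl, , drop = FALSE]),
                  numeric(ncol(m)))
  if (!is.matrix(mu_ij)) mu_ij <- matrix(mu_ij, nrow = 1)
  denom <- sqrt(outer(sigma2, ((n - n_j) / (n - 1)) / n_j))
  rho <- (mu_ij - mu) / denom
  rho[sigma2 == 0, ] <- 0
  dimnames(rho) <- list(colnames(m), clusters)
  dimnames(mu_ij) <- dimnames(rho)
  structure(
    list(rho = rho, mu = mu, sigma2 = sigma2, n = n, n_j = n_j, mu_ij = mu_ij),
    class = "species_test_values"
  )
}

#' @export
print.species_test_values <- function(x, ...) {
  cat("Species test values:", nrow(x$rho), "species x", ncol(x$rho),
      "clusters (n =", x$n, "sites)\n")
  invisible(x)
}

#' Tidy species test values into a long tibble
#'
#' @param x A `species_test_values` object.
#' @param ... Unused.
#' @return A tibble with columns `species`, `cluster`, `rho`,
#'   `mean_in_cluster`, `mean_overall`.
#' @export
tidy.species_test_values <- function(x, ...) {
  as_tibble(x$rho, rownames = "species") |>
    tidyr::pivot_longer(-"species", names_to = "cluster", values_to = "rho") |>
    dplyr::left_join(
      as_tibble(x$mu_ij, rownames = "species") |>
        tidyr::pivot_longer(-"species", names_to = "cluster",
                            values_to = "mean_in_cluster"),
      by = c("species", "cluster")
    ) |>
    dplyr::mutate(mean_overall = x$mu[.data$species])
}

#' Significantly contributive species per cluster
#'
#' Flags the species whose test value reaches the one-tailed Gaussian
#' significance threshold `delta` (default 1.96, the upper 2.5% quantile):
#' the assemblage A_j that characterises cluster j. The boundary is
#' inclusive (`rho >= delta`).
#'
#' @param tv A `species_test_values` object.
#' @param delta Significance threshold on rho (default 1.96).
#' @return An object of class `contributive_sets`: list with `sets` (named
#'   list of species vectors per cluster), `delta`, and `species_counts`
#'   (tibble `species`, `n_clusters` — how many clusters each species
#'   contributes to).
#' @export
contributive_species <- function(tv, delta = 1.96) {
  stopifnot(inherits(tv, "species_test_values"), delta > 0)
  sets <- apply(tv$rho >= delta, 2, function(col) rownames(tv$rho)[col],
                simplify = FALSE)
  counts <- tibble(
    species = rownames(tv$rho),
    n_clusters = unname(rowSums(tv$rho >= delta))
  )
  structure(list(sets = sets, delta = delta, species_counts = counts),
            class = "contributive_sets")
}

#' @export
print.contributive_sets <- function(x, ...) {
  cat("Contributive species at delta =", x$delta, "\n")
  for (cl in names(x$sets)) {
    cat(sprintf("  %s: %d species\n", cl, length(x$sets[[cl]])))
  }
  invisible(x)
}

#' Normalised positive contributions per species
#'
#' Clips negative test values at zero (`clip = "zero"`, the default) or
#' zeroes everything below the significance threshold
#' (`clip = "significant"`), then divides each species row by its sum so
#' that retained rows sum to 1: the relative contribution of each species
#' across clusters. Species with no positive entry carry no positive signal
#' and are dropped with a message.
#'
#' @param tv A `species_test_values` object.
#' @param clip `"zero"` (positive part) or `"significant"` (keep only
#'   entries at or above `delta`).
#' @param delta Threshold used when `clip = "significant"`.
#' @return A species x cluster matrix whose rows sum to 1, with attribute
#'   `dropped` (species excluded).
#' @export
normalize_contributions <- function(tv, clip = c("zero", "significant"),
                                    delta = 1.96) {
  stopifnot(inherits(tv, "species_test_values"))
  clip <- match.arg(clip)
  rho_plus <- pmax(tv$rho, 0)
  if (clip == "significant") rho_plus[tv$rho < delta] <- 0
  rs <- rowSums(rho_plus)
  dropped <- rownames(rho_plus)[rs == 0]
  if (length(dropped) > 0) {
    rlang::inform(sprintf(
      "%d species with no positive contribution dropped from the normalised table",
      length(dropped)
    ))
  }
  keep <- rs > 0
  out <- rho_plus[keep, , drop = FALSE] / rs[keep]
  attr(out, "dropped") <- dropped
  out
}

#' Cluster-interaction matrix from contributive species
#'
#' For clusters j, j' the interaction value is the mean, over the species
#' contributive to j (the set A_j), of their normalised contribution to j':
#' \deqn{\lambda_{jj'} = \frac{1}{|A_j|} \sum_{i \in A_j} \hat\rho^+_{ij'}}
#' Each row of lambda sums to 1; the diagonal is the specificity of the
#' cluster (how much of its characteristic assemblage's contribution it
#' keeps to itself), off-diagonal entries measure sharing of contributive
#' species. Clusters with an empty A_j cannot be scored and are dropped with
#' a warning.
#'
#' @param rho_hat Normalised contribution matrix from
#'   [normalize_contributions()].
#' @param sets A `contributive_sets` object.
#' @return An object of class `cluster_interaction`: list with `lambda`
#'   (cluster x cluster matrix), `rho_hat`, `sets`.
#' @export
interaction_matrix <- function(rho_hat, sets) {
  stopifnot(inherits(sets, "contributive_sets"))
  clusters <- colnames(rho_hat)
  usable <- purrr::keep(clusters, function(cl) {
    length(intersect(sets$sets[[cl]], rownames(rho_hat))) > 0
  })
  dropped <- setdiff(clusters, usable)
  if (length(dropped) > 0) {
    warn(paste0("cluster(s) with no contributive species dropped from the network: ",
                paste(dropped, collapse = ", ")))
  }
  if (length(usable) == 0) abort("no cluster has contributive species")
  lambda <- t(vapply(usable, function(cl) {
    members <- intersect(sets$sets[[cl]], rownames(rho_hat))
    colMeans(rho_hat[members, , drop = FALSE])
  }, numeric(ncol(rho_hat))))
  dimnames(lambda) <- list(usable, colnames(rho_hat))
  structure(list(lambda = lambda, rho_hat = rho_hat, sets = sets),
            class = "cluster_interaction")
}

#' @export
print.cluster_interaction <- function(x, ...) {
  spec <- diag(x$lambda[, rownames(x$lambda), drop = FALSE])
  cat("Cluster-interaction matrix over", nrow(x$lambda), "clusters\n")
  cat(sprintf("  mean specificity: %.1f%% (range %.0f%%-%.0f%%)\n",
              100 * mean(spec), 100 * min(spec), 100 * max(spec)))
  invisible(x)
}

#' Tidy a cluster-interaction matrix into a long tibble
#'
#' @param x A `cluster_interaction` object.
#' @param ... Unused.
#' @return A tibble with columns `from`, `to`, `lambda`, `specificity`
#'   (logical: diagonal entry).
#' @export
tidy.cluster_interaction <- function(x, ...) {
  as_tibble(x$lambda, rownames = "from") |>
    tidyr::pivot_longer(-"from", names_to = "to", values_to = "lambda") |>
    dplyr::mutate(specificity = .data$from == .data$to)
}

#' Edge list of the cluster-interaction network
#'
#' Off-diagonal interactions strictly greater than `min_edge` become
#' directed edges; diagonal entries are reported separately as specificity.
#'
#' @param x A `cluster_interaction` object (or a bare lambda matrix).
#' @param min_edge Minimum off-diagonal interaction to keep an edge
#'   (default 0.05; strictly greater-than).
#' @return A list with `edges` (tibble `from`, `to`, `weight`) and
#'   `specificity` (tibble `cluster`, `specificity`).
#' @export
network_edges <- function(x, min_edge = 0.05) {
  lambda <- if (inherits(x, "cluster_interaction")) x$lambda else x
  long <- as_tibble(lambda, rownames = "from") |>
    tidyr::pivot_longer(-"from", names_to = "to", values_to = "weight")
  list(
    edges = dplyr::filter(long, .data$from != .data$to, .data$weight > min_edge),
    specificity = long |>
      dplyr::filter(.data$from == .data$to) |>
      dplyr::transmute(cluster = .data$from, specificity = .data$weight)
  )
}

#' Convert the interaction network to an igraph object
#'
#' @param x A `cluster_interaction` object.
#' @param min_edge Passed to [network_edges()].
#' @return A directed, weighted [igraph::graph] with a `specificity` vertex
#'   attribute.
#' @export
as_igraph <- function(x, min_edge = 0.05) {
  net <- network_edges(x, min_edge = min_edge)
  g <- igraph::graph_from_data_frame(
    net$edges, directed = TRUE,
    vertices = data.frame(name = net$specificity$cluster)
  )
  igraph::V(g)$specificity <- net$specificity$specificity
  g
}

#' Project the cluster network onto two environmental gradients
#'
#' Places each cluster at the per-cluster median of two plot-level
#' environmental variables (e.g. elevation and annual precipitation), the
#' coordinates used to draw the interaction network in environmental space.
#'
#' @param x A `cluster_interaction` object (or lambda matrix) — only the
#'   cluster names are used.
#' @param plot_env Plot-level table with `plot_id` and the two variables.
#' @param labels Site-to-cluster labels (named vector or tibble).
#' @param x_var,y_var Names of the environmental variables to use.
#' @return A tibble with columns `cluster`, `x`, `y` (medians), plus
#'   `x_var`/`y_var` attributes.
#' @export
project_network <- function(x, plot_env, labels, x_var, y_var) {
  lambda <- if (inherits(x, "cluster_interaction")) x$lambda else x
  for (v in c(x_var, y_var)) {
    if (!v %in% names(plot_env)) {
      abort(paste0("environmental variable `", v, "` not found in plot table"))
    }
  }
  lab_tbl <- if (is.data.frame(labels)) labels else
    tibble(site_id = names(labels), cluster_id = unname(labels))
  env <- plot_env |>
    dplyr::mutate(plot_id = as.character(.data$plot_id)) |>
    dplyr::inner_join(
      dplyr::mutate(lab_tbl, site_id = as.character(.data$site_id)),
      by = c("plot_id" = "site_id")
    )
  out <- env |>
    dplyr::filter(as.character(.data$cluster_id) %in% rownames(lambda)) |>
    dplyr::group_by(cluster = as.character(.data$cluster_id)) |>
    dplyr::summarise(
      x = median(.data[[x_var]]), y = median(.data[[y_var]]), .groups = "drop"
    )
  attr(out, "x_var") <- x_var
  attr(out, "y_var") <- y_var
  out
}
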