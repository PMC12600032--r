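# Cluster-number selection and singleton resolution for bioregionalisation.

#' Between-cluster share of total dissimilarity
#'
#' The ratio of the sum of dissimilarities over between-cluster site pairs
#' to the sum over all site pairs. It is 0 when all sites share one cluster,
#' 1 when every site is its own cluster, and non-decreasing along any
#' refinement of a partition; read as the fraction of compositional
#' variation explained by the partition.
#'
#' @param D Symmetric dissimilarity matrix.
#' @param labels Cluster labels covering the sites of `D` (named vector or
#'   tibble with `site_id`/`cluster_id`).
#' @return A number in `[0, 1]`.
#' @export
pc_distance <- function(D, labels) {
  D <- check_dissim(D)
  if (nrow(D) < 2) abort("pc_distance is undefined for a single site")
  lab <- align_labels(labels, rownames(D))
  lt <- lower.tri(D)
  between <- outer(lab, lab, `!=`)
  tot <- sum(D[lt])
  if (tot == 0) return(0)
  sum(D[lt & between]) / tot
}

# Elbow of a curve: index maximising perpendicular distance to the chord
# joining the first and last points.
elbow_index <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 2)
  x0 <- x[1]; y0 <- y[1]; x1 <- x[n]; y1 <- y[n]
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  if (len == 0) return(1L)
  d <- abs((y1 - y0) * x - (x1 - x0) * y + x1 * y0 - y1 * x0) / len
  if (max(d) <= 1e-12) return(NA_integer_)  # flat / strictly linear curve
  which.max(d)
}

#' Select the number of clusters with an elbow rule
#'
#' Cuts the tree at every k in `k_range`, computes [pc_distance()] for each
#' cut, and picks the k whose point on the (k, pc) curve lies farthest from
#' the chord joining the curve's endpoints. A curve with no elbow (strictly
#' linear) falls back to the smallest k with a warning.
#'
#' @param tree An `upgma_tree` or `hclust` object.
#' @param D The dissimilarity matrix the tree was built from.
#' @param k_range Integer vector of candidate k; default
#'   `2:min(20, n_sites - 1)`.
#' @return A list of class `k_selection`: `k` (chosen), `pc_curve` (tibble
#'   with `k`, `pc_distance`).
#' @export
select_k_elbow <- function(tree, D, k_range = NULL) {
  D <- check_dissim(D)
  hc <- if (inherits(tree, "upgma_tree")) tree$tree else tree
  n <- nrow(D)
  if (is.null(k_range)) k_range <- 2:max(2, min(20, n - 1))
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2) || any(k_range > n)) {
    abort("k_range must lie within [2, n_sites]")
  }
  pc <- purrr::map_dbl(k_range, function(k) {
    lab <- cutree(hc, k = k)[rownames(D)]
    pc_distance(D, lab)
  })
  idx <- elbow_index(k_range, pc)
  if (is.na(idx)) {
    warn("pc_distance curve has no elbow; falling back to the smallest k")
    idx <- 1L
  }
  structure(
    list(k = k_range[idx], pc_curve = tibble(k = k_range, pc_distance = pc)),
    class = "k_selection"
  )
}

#' @export
print.k_selection <- function(x, ...) {
  cat("Elbow-selected number of clusters: k =", x$k, "\n")
  cat(sprintf("  pc_distance at k: %.4f\n",
              x$pc_curve$pc_distance[x$pc_curve$k == x$k]))
  invisible(x)
}

#' Resolve single-site clusters by floristic similarity
#'
#' Isolated sites may reflect genuine floristic specificity or merely a high
#' rate of unique species from sampling noise. Each singleton is compared to
#' the pooled species set of every multi-site cluster with Simpson
#' similarity (`1 -` [simpson_dissimilarity()]); if the best similarity
#' reaches the threshold the site is merged into that cluster, otherwise it
#' is excluded from further analysis. With `n_comparisons_correction` the
#' required similarity is tightened to `1 - (1 - threshold) / m` over the
#' `m` candidate clusters, a Bonferroni-style guard against merging by
#' chance when many clusters are screened.
#'
#' @param labels Cluster labels from a tree cut (named vector or tibble).
#' @param matrix Site-by-species abundance table covering all labelled
#'   sites.
#' @param similarity_threshold Minimum Simpson similarity to merge
#'   (default 0.5).
#' @param n_comparisons_correction Tighten the threshold over the number of
#'   candidate clusters (default `TRUE`).
#' @return An object of class `bioregion_clustering`: `labels` (tibble
#'   `site_id`, `cluster_id` with contiguous ids over retained sites), `k`,
#'   and `singleton_log` (tibble `site_id`, `best_cluster`, `similarity`,
#'   `threshold_used`, `disposition`).
#' @export
resolve_singletons <- function(labels, matrix, similarity_threshold = 0.5,
                               n_comparisons_correction = TRUE) {
  m <- as_species_matrix(matrix)
  lab <- align_labels(labels, rownames(m))
  sizes <- table(lab)
  multi <- names(sizes)[sizes > 1]
  singles <- names(sizes)[sizes == 1]
  if (length(multi) == 0 && length(singles) > 0) {
    abort("all clusters are singletons; no reference clusters to compare to")
  }
  thr <- similarity_threshold
  if (n_comparisons_correction && length(multi) > 0) {
    thr <- 1 - (1 - similarity_threshold) / length(multi)
  }
  pooled <- purrr::map(multi, function(cl) {
    sites <- names(lab)[lab == cl]
    colnames(m)[colSums(m[sites, , drop = FALSE]) > 0]
  })
  names(pooled) <- multi
  log <- list()
  out <- lab
  single_sites <- names(lab)[lab %in% singles]
  for (s in single_sites) {
    sp <- colnames(m)[m[s, ] > 0]
    sims <- purrr::map_dbl(pooled, function(ps) 1 - simpson_dissimilarity(sp, ps))
    best <- which.max(sims)
    if (sims[best] >= thr) {
      out[s] <- multi[best]
      disp <- "merged"
    } else {
      out <- out[names(out) != s]
      disp <- "excluded"
    }
    log[[s]] <- tibble(
      site_id = s, best_cluster = as.character(multi[best]),
      similarity = unname(sims[best]), threshold_used = thr,
      disposition = disp
    )
  }
  relab <- as.integer(factor(out, levels = unique(out)))  # contiguous 1..k
  structure(
    list(
      labels = tibble(site_id = names(out), cluster_id = relab),
      k = length(unique(relab)),
      singleton_log = if (length(log) > 0) dplyr::bind_rows(log) else
        tibble(site_id = character(), best_cluster = character(),
               similarity = double(), threshold_used = double(),
               disposition = character())
    ),
    class = "bioregion_clustering"
  )
}

#' Full turnover-based bioregionalisation of sites
#'
#' Convenience wrapper chaining [bray_turnover()], [upgma_best_tree()],
#' [select_k_elbow()] (unless `k` is given) and [resolve_singletons()].
#'
#' @param matrix Site-by-species abundance table (wide tibble or matrix).
#' @param n_randomizations,seed Passed to [upgma_best_tree()].
#' @param k Fixed number of clusters; `NULL` selects k by the elbow rule.
#' @param k_range Candidate k for the elbow rule.
#' @param similarity_threshold,n_comparisons_correction Passed to
#'   [resolve_singletons()].
#' @return A `bioregion_clustering` object with additional elements `tree`
#'   (`upgma_tree`), `selection` (`k_selection` or `NULL`), `D`
#'   (dissimilarity matrix).
#' @export
cluster_sites <- function(matrix, n_randomizations = 100, seed = 1, k = NULL,
                          k_range = NULL, similarity_threshold = 0.5,
                          n_comparisons_correction = TRUE) {
  m <- as_species_matrix(matrix)
  D <- bray_turnover(m)
  tree <- upgma_best_tree(D, n_randomizations = n_randomizations, seed = seed)
  sel <- NULL
  if (is.null(k)) {
    sel <- select_k_elbow(tree, D, k_range = k_range)
    k <- sel$k
  }
  lab <- cutree(tree$tree, k = k)[rownames(D)]
  res <- resolve_singletons(lab, m,
    similarity_threshold = similarity_threshold,
    n_comparisons_correction = n_comparisons_correction
  )
  res$tree <- tree
  res$selection <- sel
  res$D <- D
  res
}

#' @export
print.bioregion_clustering <- function(x, ...) {
  cat("Bioregionalisation:", x$k, "clusters over", nrow(x$labels), "sites\n")
  if (nrow(x$singleton_log) > 0) {
    cat("  singleton dispositions:",
        paste(sprintf("%s (%s)", x$singleton_log$site_id,
                      x$singleton_log$disposition), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname tidy.bioregion_clustering
#' @export
tidy.bioregion_clustering <- function(x, ...) x$labels

#' Tidy and summarise a bioregionalisation
#'
#' `tidy()` returns the site-to-cluster assignment; `glance()` a one-row
#' summary (k, sites retained, cophenetic correlation and the pc_distance of
#' the chosen cut, when available).
#'
#' @param x A `bioregion_clustering` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
glance.bioregion_clustering <- function(x, ...) {
  tibble(
    k = x$k,
    n_sites = nrow(x$labels),
    n_merged = sum(x$singleton_log$disposition == "merged"),
    n_excluded = sum(x$singleton_log$disposition == "excluded"),
    cophenetic_corr = if (!is.null(x$tree)) x$tree$cophenetic_corr else NA_real_,
    pc_distance = if (!is.null(x$D)) {
      pc_distance(x$D[x$labels$site_id, x$labels$site_id],
                  setNames(x$labels$cluster_id, x$labels$site_id))
    } else NA_real_
  )
}
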