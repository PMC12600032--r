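# Abundance-based turnover dissimilarity between sites.

#' Balanced-variation (turnover) component of Bray-Curtis dissimilarity
#'
#' For a pair of sites with abundance vectors x1, x2, let
#' `A = sum_s min(x1_s, x2_s)` (shared abundance), `B = sum(x1) - A` and
#' `C = sum(x2) - A` (abundance exclusive to each site). The turnover
#' component is `min(B, C) / (A + min(B, C))`: the balanced fraction of
#' individuals replaced between the sites. Unlike the full Bray-Curtis
#' index it ignores the nestedness (abundance-gradient) part, so nested
#' assemblages score 0 and fully disjoint ones score 1, regardless of site
#' size.
#'
#' @param matrix Wide site-by-species table (`plot_id` + species columns) as
#'   produced by [select_dominant()], or a numeric matrix with site
#'   rownames.
#' @return A symmetric site-by-site matrix of dissimilarities in `[0, 1]`
#'   with zero diagonal.
#' @examples
#' m <- rbind(s1 = c(a = 5, b = 3, c = 0), s2 = c(a = 2, b = 0, c = 4))
#' bray_turnover(m)  # 4 / (2 + 4) = 0.6667
#' @export
bray_turnover <- function(matrix) {
  m <- as_species_matrix(matrix)
  if (nrow(m) < 2) abort("need at least 2 sites")
  if (any(m < 0)) abort("abundances must be non-negative")
  tot <- rowSums(m)
  if (any(tot == 0)) {
    abort(paste0("site(s) with zero total abundance: ",
                 paste(head(rownames(m)[tot == 0], 5), collapse = ", ")))
  }
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    xi <- m[i, ]
    for (j in (i + 1):n) {
      A <- sum(pmin(xi, m[j, ]))
      mbc <- min(tot[i], tot[j]) - A
      d <- if (mbc <= 0) 0 else mbc / (A + mbc)
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Simpson (presence-based turnover) dissimilarity of two species sets
#'
#' `min(b, c) / (a + min(b, c))` where `a` is the number of shared species
#' and `b`, `c` the numbers exclusive to each set. The presence-absence
#' analogue of [bray_turnover()]; used to assess whether an isolated site is
#' floristically close to an existing cluster.
#'
#' @param pa1,pa2 Character vectors of species names (non-empty).
#' @return A number in `[0, 1]`.
#' @export
simpson_dissimilarity <- function(pa1, pa2) {
  pa1 <- unique(pa1); pa2 <- unique(pa2)
  if (length(pa1) == 0 || length(pa2) == 0) abort("species sets must be non-empty")
  a <- length(intersect(pa1, pa2))
  b <- length(setdiff(pa1, pa2))
  c_ <- length(setdiff(pa2, pa1))
  mbc <- min(b, c_)
  if (mbc == 0) 0 else mbc / (a + mbc)
}
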