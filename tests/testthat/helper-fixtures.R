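# Shared fixtures and independent oracles, built in code.

# Two-species toy plot used across IVI tests: spA 3 stems / BA 0.6 m2 in
# both subplots, spB 1 stem / BA 0.2 m2 in one subplot. Basal areas are
# realised through DBH choices: BA = pi (dbh/200)^2.
dbh_for_ba <- function(ba_m2) 200 * sqrt(ba_m2 / pi)

toy_two_species_plot <- function() {
  tibble::tibble(
    plot_id = "p1",
    subplot_id = c("s1", "s1", "s2", "s2"),
    species = c("spA", "spA", "spA", "spB"),
    dbh_cm = c(
      dbh_for_ba(0.2), dbh_for_ba(0.2), dbh_for_ba(0.2), dbh_for_ba(0.2)
    )
  )
}

# Random small abundance matrix (integer counts, no empty sites).
random_abundance <- function(n_sites, n_species, max_count = 9) {
  m <- matrix(sample(0:max_count, n_sites * n_species, replace = TRUE),
              n_sites, n_species,
              dimnames = list(paste0("s", seq_len(n_sites)),
                              paste0("sp", seq_len(n_species))))
  empty <- rowSums(m) == 0
  m[empty, 1] <- 1L
  m
}

# Independent brute-force turnover oracle: walks species one by one and
# accumulates shared/exclusive abundance from first principles.
brute_turnover_pair <- function(x1, x2) {
  A <- 0; B <- 0; C <- 0
  for (s in seq_along(x1)) {
    shared <- min(x1[s], x2[s])
    A <- A + shared
    B <- B + (x1[s] - shared)
    C <- C + (x2[s] - shared)
  }
  if (min(B, C) == 0) 0 else min(B, C) / (A + min(B, C))
}

brute_turnover_matrix <- function(m) {
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) D[i, j] <- brute_turnover_pair(m[i, ], m[j, ])
    }
  }
  D
}

# Brute-force ARI from the 2x2 pair-counting table.
brute_ari <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]; sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (!sa && !sb) n00 <- n00 + 1
      else if (sa) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  tot <- n11 + n00 + n10 + n01
  expected <- (n11 + n10) * (n11 + n01) / tot
  maxi <- ((n11 + n10) + (n11 + n01)) / 2
  if (maxi == expected) return(1)
  (n11 - expected) / (maxi - expected)
}

# All set partitions of 1..n as a list of label vectors (restricted growth
# strings).
all_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, next_max) {
    i <- length(labels) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- labels
      return(invisible())
    }
    for (v in seq_len(next_max + 1)) {
      recurse(c(labels, v), max(next_max, v))
    }
  }
  recurse(integer(0), 0L)
  out
}

# Small well-separated segment training table: `n_per_class` segments per
# cluster, one informative feature separating the classes plus `n_noise`
# standard-normal distractors.
separable_training <- function(n_per_class = 20, n_classes = 2, n_noise = 3,
                               gap = 10) {
  n <- n_per_class * n_classes
  cl <- rep(seq_len(n_classes), each = n_per_class)
  tbl <- tibble::tibble(
    segment_id = sprintf("seg%03d", seq_len(n)),
    informative = gap * cl + rnorm(n),
    cluster = factor(cl)
  )
  for (k in seq_len(n_noise)) tbl[[paste0("noise", k)]] <- rnorm(n)
  tbl
}

# Tiny default simulation config for fast tests; any argument can be
# overridden through `...`.
test_sim_config <- function(...) {
  args <- list(
    n_clusters = 3,
    sites_per_cluster = c(8, 6, 5),
    species_per_cluster_pool = 6,
    n_shared_species = 4,
    trees_per_plot_mean = 40,
    n_feature_variables = 8,
    pixels_per_segment = 20
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}
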