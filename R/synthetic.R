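# Synthetic inventory, segment and landscape generator with known truth.
#
# Emulates the structure of a national forest inventory: K site clusters,
# each planted with its own pool of dominant canopy species over a shared
# background pool, heavy-tailed abundances (Dirichlet-multinomial),
# lognormal DBH truncated at the 10 cm census threshold, subplot occupancy,
# cluster-correlated environmental variables with pure-noise distractors,
# and cluster-dependent old-growth/secondary forest mixing.

#' Configuration for the synthetic forest-inventory generator
#'
#' Defaults describe a desk-scale landscape with 5 unbalanced site clusters
#' (84 plots), 8 planted dominant species per cluster over 10 shared
#' background species, ~60 stems per plot with oligarchy-like dominance
#' (Dirichlet concentration 0.6), lognormal DBH (meanlog 3.1, sdlog 0.45,
#' truncated at 10 cm), two informative environmental gradients (elevation
#' 300–2300 m, annual precipitation 1800–3800 mm/yr) among 34 candidate
#' variables, and secondary-forest probabilities spread over \[0.1, 0.9\].
#'
#' @param n_clusters Number of planted clusters K (>= 2).
#' @param sites_per_cluster Integer vector of plots per cluster (length K;
#'   imbalance allowed).
#' @param species_per_cluster_pool Dominant species per cluster pool.
#' @param n_shared_species Background species present everywhere (0 for a
#'   zero-noise landscape).
#' @param trees_per_plot_mean Mean stems per plot (Poisson).
#' @param abundance_dispersion Dirichlet concentration per pool species;
#'   smaller values give stronger single-species oligarchies.
#' @param dbh_lognormal_params Named vector `c(mu, sigma)` of log DBH (cm),
#'   truncated at 10 cm.
#' @param n_subplots Subplots per plot (uniform tree assignment).
#' @param env_cluster_means Named list: per environmental variable, a
#'   length-K vector of cluster means.
#' @param env_sd Named vector of within-cluster SDs, one per variable in
#'   `env_cluster_means`.
#' @param n_feature_variables Total candidate segment variables, informative
#'   environmental variables included; the rest are pure-noise distractors.
#' @param sf_probability_per_cluster Length-K vector of probabilities that a
#'   plot/pixel of the cluster is secondary forest.
#' @param pixels_per_segment Pixel samples per segment.
#' @param n_segments Total segments; default `3 *` number of plots (each
#'   plot sits in its own segment, the rest are unsampled).
#' @param seed Integer RNG seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_clusters = 5,
                       sites_per_cluster = c(30, 22, 16, 10, 6),
                       species_per_cluster_pool = 8,
                       n_shared_species = 10,
                       trees_per_plot_mean = 60,
                       abundance_dispersion = 0.6,
                       dbh_lognormal_params = c(mu = 3.1, sigma = 0.45),
                       n_subplots = 4,
                       env_cluster_means = NULL,
                       env_sd = c(elevation = 150, precipitation = 250),
                       n_feature_variables = 34,
                       sf_probability_per_cluster = NULL,
                       pixels_per_segment = 40,
                       n_segments = NULL,
                       seed = 1) {
  if (is.null(env_cluster_means)) {
    env_cluster_means <- list(
      elevation = seq(300, 2300, length.out = n_clusters),
      precipitation = seq(1800, 3800, length.out = n_clusters)
    )
  }
  if (is.null(sf_probability_per_cluster)) {
    sf_probability_per_cluster <- seq(0.1, 0.9, length.out = n_clusters)
  }
  cfg <- list(
    n_clusters = as.integer(n_clusters),
    sites_per_cluster = as.integer(sites_per_cluster),
    species_per_cluster_pool = as.integer(species_per_cluster_pool),
    n_shared_species = as.integer(n_shared_species),
    trees_per_plot_mean = trees_per_plot_mean,
    abundance_dispersion = abundance_dispersion,
    dbh_lognormal_params = dbh_lognormal_params,
    n_subplots = as.integer(n_subplots),
    env_cluster_means = env_cluster_means,
    env_sd = env_sd,
    n_feature_variables = as.integer(n_feature_variables),
    sf_probability_per_cluster = sf_probability_per_cluster,
    pixels_per_segment = as.integer(pixels_per_segment),
    n_segments = if (is.null(n_segments)) 3L * sum(as.integer(sites_per_cluster))
      else as.integer(n_segments),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fail <- function(field, why) {
    abort(paste0("invalid `", field, "`: ", why), class = "sim_config_error")
  }
  if (cfg$n_clusters < 2) fail("n_clusters", "need at least 2 clusters")
  if (length(cfg$sites_per_cluster) != cfg$n_clusters ||
      any(cfg$sites_per_cluster < 1)) {
    fail("sites_per_cluster", "must be positive and of length n_clusters")
  }
  if (cfg$species_per_cluster_pool < 1) fail("species_per_cluster_pool", "must be positive")
  if (cfg$n_shared_species < 0) fail("n_shared_species", "must be non-negative")
  if (cfg$trees_per_plot_mean <= 0) fail("trees_per_plot_mean", "must be positive")
  if (cfg$abundance_dispersion <= 0) fail("abundance_dispersion", "must be positive")
  if (length(cfg$dbh_lognormal_params) != 2 || cfg$dbh_lognormal_params[2] < 0) {
    fail("dbh_lognormal_params", "need (mu, sigma) with sigma >= 0")
  }
  if (cfg$n_subplots < 1) fail("n_subplots", "must be positive")
  vars <- names(cfg$env_cluster_means)
  if (is.null(vars) || any(!nzchar(vars))) {
    fail("env_cluster_means", "variables must be named")
  }
  for (v in vars) {
    if (length(cfg$env_cluster_means[[v]]) != cfg$n_clusters) {
      fail("env_cluster_means", paste0("`", v, "` needs a mean for every cluster"))
    }
  }
  if (!setequal(names(cfg$env_sd), vars) || any(cfg$env_sd < 0)) {
    fail("env_sd", "need a non-negative SD for every environmental variable")
  }
  if (cfg$n_feature_variables < length(vars)) {
    fail("n_feature_variables", "must be at least the number of informative variables")
  }
  if (length(cfg$sf_probability_per_cluster) != cfg$n_clusters ||
      any(cfg$sf_probability_per_cluster < 0) ||
      any(cfg$sf_probability_per_cluster > 1)) {
    fail("sf_probability_per_cluster", "need probabilities in [0,1] for every cluster")
  }
  if (cfg$pixels_per_segment < 1) fail("pixels_per_segment", "must be positive")
  if (cfg$n_segments < sum(cfg$sites_per_cluster)) {
    fail("n_segments", "need at least one segment per plot")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic inventory config:", x$n_clusters, "clusters,",
      sum(x$sites_per_cluster), "plots,",
      x$n_clusters * x$species_per_cluster_pool, "pool +",
      x$n_shared_species, "shared species; seed", x$seed, "\n")
  invisible(x)
}

truncated_lognormal <- function(n, mu, sigma, lower = 10) {
  if (sigma == 0) return(rep(max(exp(mu), lower), n))
  out <- rlnorm(n, mu, sigma)
  bad <- out < lower
  while (any(bad)) {
    out[bad] <- rlnorm(sum(bad), mu, sigma)
    bad <- out < lower
  }
  out
}

#' Generate a synthetic tree inventory with known cluster structure
#'
#' Every plot belongs to one planted cluster; its stems are a
#' Dirichlet-multinomial draw over the cluster's dominant pool plus the
#' shared background pool, with the shared pool collectively given half the
#' concentration mass of the cluster pool so planted dominants dominate both
#' stems and basal area in expectation. DBH is lognormal truncated at 10 cm;
#' trees fall uniformly into subplots. Plot metadata carries coordinates,
#' cluster-correlated environmental variables and an OGF/SF type drawn with
#' the cluster's secondary-forest probability.
#'
#' @param config A [sim_config()] object.
#' @return A list with `records` (tree table: `plot_id`, `subplot_id`,
#'   `species`, `dbh_cm`), `plots` (metadata: `plot_id`, `area_ha`,
#'   `forest_type`, `x`, `y`, one column per environmental variable) and
#'   `truth` (class `sim_truth`: `plot_cluster`, `planted_dominants`,
#'   `segment_cluster`, `informative_variables`, `config_hash`).
#' @export
generate_inventory <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  K <- config$n_clusters
  n_plots <- sum(config$sites_per_cluster)
  pools <- purrr::map(seq_len(K), function(k) {
    sprintf("sp_c%d_%02d", k, seq_len(config$species_per_cluster_pool))
  })
  shared <- if (config$n_shared_species > 0) {
    sprintf("sp_shared_%02d", seq_len(config$n_shared_species))
  } else character(0)
  plot_ids <- sprintf("p%03d", seq_len(n_plots))
  plot_cluster <- rep(seq_len(K), config$sites_per_cluster)
  names(plot_cluster) <- plot_ids

  env_vars <- names(config$env_cluster_means)
  mu_dbh <- config$dbh_lognormal_params[[1]]
  sd_dbh <- config$dbh_lognormal_params[[2]]

  out <- with_seed(derive_seed(config$seed, "inventory"), {
    records <- purrr::map(seq_len(n_plots), function(p) {
      k <- plot_cluster[p]
      sp <- c(pools[[k]], shared)
      alpha <- c(
        rep(config$abundance_dispersion, length(pools[[k]])),
        if (length(shared) > 0) {
          rep(config$abundance_dispersion * 0.5 * length(pools[[k]]) /
                length(shared), length(shared))
        }
      )
      n_trees <- max(1L, rpois(1, config$trees_per_plot_mean))
      g <- rgamma(length(alpha), shape = alpha)
      while (sum(g) == 0) g <- rgamma(length(alpha), shape = alpha)
      counts <- as.vector(stats::rmultinom(1, n_trees, g / sum(g)))
      keep <- counts > 0
      tibble(
        plot_id = plot_ids[p],
        species = rep(sp[keep], counts[keep]),
        subplot_id = sprintf("s%02d", sample.int(config$n_subplots,
                                                 sum(counts), replace = TRUE)),
        dbh_cm = truncated_lognormal(sum(counts), mu_dbh, sd_dbh)
      )
    }) |> dplyr::bind_rows() |>
      dplyr::select("plot_id", "subplot_id", "species", "dbh_cm")

    centers_x <- runif(K, 0, 100)
    centers_y <- runif(K, 0, 100)
    plots <- tibble(
      plot_id = plot_ids,
      area_ha = 0.1,
      forest_type = ifelse(
        runif(n_plots) < config$sf_probability_per_cluster[plot_cluster],
        "SF", "OGF"
      ),
      x = centers_x[plot_cluster] + rnorm(n_plots, 0, 3),
      y = centers_y[plot_cluster] + rnorm(n_plots, 0, 3)
    )
    for (v in env_vars) {
      plots[[v]] <- rnorm(
        n_plots,
        mean = config$env_cluster_means[[v]][plot_cluster],
        sd = config$env_sd[[v]]
      )
    }

    seg_ids <- sprintf("seg%04d", seq_len(config$n_segments))
    extra <- config$n_segments - n_plots
    seg_cluster <- c(
      plot_cluster,
      if (extra > 0) sample(seq_len(K), extra, replace = TRUE,
                            prob = config$sites_per_cluster)
    )
    segment_cluster <- tibble(
      segment_id = seg_ids,
      plot_id = c(plot_ids, rep(NA_character_, extra)),
      cluster = as.integer(seg_cluster)
    )
    list(records = records, plots = plots, segment_cluster = segment_cluster)
  })

  truth <- structure(
    list(
      plot_cluster = tibble(plot_id = plot_ids,
                            cluster = as.integer(plot_cluster)),
      planted_dominants = setNames(pools, seq_len(K)),
      segment_cluster = out$segment_cluster,
      informative_variables = env_vars,
      config_hash = rlang::hash(unclass(config))
    ),
    class = "sim_truth"
  )
  list(records = out$records, plots = out$plots, truth = truth)
}

check_truth <- function(config, truth) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!identical(truth$config_hash, rlang::hash(unclass(config)))) {
    abort("truth object was generated under a different config",
          class = "sim_consistency_error")
  }
}

#' Generate segment quantile features from the planted clusters
#'
#' One row per segment. Informative variables draw `pixels_per_segment`
#' pixel values from the segment cluster's Gaussian; distractor variables
#' (`noise_*`, filling up to `n_feature_variables`) draw from a standard
#' normal independent of cluster. Features are the q25/q50/q75 of the pixel
#' samples. Segments containing a plot carry that plot's id.
#'
#' @param config The [sim_config()] used for [generate_inventory()].
#' @param truth The matching `sim_truth`.
#' @return A tibble: `segment_id`, `plot_id`, then `<var>_q25/_q50/_q75`
#'   columns for every variable.
#' @export
generate_segments <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  check_truth(config, truth)
  seg <- truth$segment_cluster
  env_vars <- truth$informative_variables
  n_noise <- config$n_feature_variables - length(env_vars)
  noise_vars <- if (n_noise > 0) sprintf("noise_%02d", seq_len(n_noise)) else character(0)
  n_seg <- nrow(seg)
  px <- config$pixels_per_segment

  with_seed(derive_seed(config$seed, "segments"), {
    out <- tibble(segment_id = seg$segment_id, plot_id = seg$plot_id)
    qs <- c(0.25, 0.5, 0.75)
    for (v in c(env_vars, noise_vars)) {
      if (v %in% env_vars) {
        mu <- config$env_cluster_means[[v]][seg$cluster]
        sd_v <- config$env_sd[[v]]
      } else {
        mu <- rep(0, n_seg)
        sd_v <- 1
      }
      pix <- matrix(rnorm(n_seg * px, mean = rep(mu, each = px), sd = sd_v),
                    nrow = px)
      qmat <- apply(pix, 2, quantile, probs = qs, names = FALSE, type = 7)
      out[[paste0(v, "_q25")]] <- qmat[1, ]
      out[[paste0(v, "_q50")]] <- qmat[2, ]
      out[[paste0(v, "_q75")]] <- qmat[3, ]
    }
    out
  })
}

#' Generate a forest-type pixel landscape from the planted clusters
#'
#' Expands every segment into `pixels_per_segment` pixels labelled with the
#' segment's cluster as ecosystem; each pixel is secondary forest with the
#' cluster's configured probability, old-growth otherwise.
#'
#' @param config The [sim_config()] used for [generate_inventory()].
#' @param truth The matching `sim_truth`.
#' @param pixels_per_segment Override for the number of pixels per segment.
#' @return A tibble: `segment_id`, `ecosystem`, `forest_type`.
#' @export
generate_landscape <- function(config, truth,
                               pixels_per_segment = config$pixels_per_segment) {
  stopifnot(inherits(config, "sim_config"))
  check_truth(config, truth)
  seg <- truth$segment_cluster
  n_pix <- nrow(seg) * pixels_per_segment
  cluster <- rep(seg$cluster, each = pixels_per_segment)
  with_seed(derive_seed(config$seed, "landscape"), {
    tibble(
      segment_id = rep(seg$segment_id, each = pixels_per_segment),
      ecosystem = as.integer(cluster),
      forest_type = ifelse(
        runif(n_pix) < config$sf_probability_per_cluster[cluster], "SF", "OGF"
      )
    )
  })
}
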