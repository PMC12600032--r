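# End-to-end orchestration: simulate -> IVI -> clustering -> contributions
# -> network -> ecosystem model -> forest-type composition.

#' Pipeline configuration with field-standard defaults
#'
#' Collects every stage parameter with its default: IVI threshold 5%,
#' 1000 UPGMA order randomisations, significance threshold delta = 1.96,
#' minimum network edge 5%, minimum 15 labelled segments per modelled
#' cluster, 10-fold CV, RFE subset sizes 5–30, collinearity threshold
#' |r| > 0.7, 100 importance permutations. One global seed fans out to
#' deterministic per-stage seeds.
#'
#' @param sim A [sim_config()] for the simulation stage (its seed is
#'   overridden by `seed`).
#' @param ivi_threshold,n_randomizations,delta,min_edge,min_cluster_size,folds,rfe_sizes,r_threshold,n_permutations
#'   Stage parameters (defaults above).
#' @param k Fixed cluster count; `NULL` selects k by the elbow rule.
#' @param env_x,env_y Environmental variables for the network projection.
#' @param num_trees Trees per random forest (default 500).
#' @param seed Global seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            ivi_threshold = 5,
                            n_randomizations = 1000,
                            delta = 1.96,
                            min_edge = 0.05,
                            min_cluster_size = 15,
                            folds = 10,
                            rfe_sizes = 5:30,
                            r_threshold = 0.7,
                            n_permutations = 100,
                            k = NULL,
                            env_x = "precipitation",
                            env_y = "elevation",
                            num_trees = 500,
                            seed = 1) {
  sim$seed <- as.integer(seed)
  structure(
    list(
      sim = sim, ivi_threshold = ivi_threshold,
      n_randomizations = n_randomizations, delta = delta,
      min_edge = min_edge, min_cluster_size = min_cluster_size,
      folds = folds, rfe_sizes = rfe_sizes, r_threshold = r_threshold,
      n_permutations = n_permutations, k = k, env_x = env_x, env_y = env_y,
      num_trees = num_trees, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

write_stage_csv <- function(x, dir, name) {
  path <- file.path(dir, paste0(name, ".csv"))
  readr::write_csv(as_tibble(x), path)
  path
}

#' Run the full delineation pipeline on a synthetic landscape
#'
#' Executes every stage in order — inventory simulation, IVI dominance
#' screening, turnover clustering, species contributions and the
#' interaction network, the segment random-forest model (RFE, collinearity
#' pruning, CV, importance) and forest-type composition — writing each
#' stage's artifacts to `out_dir` (CSV; Newick and GraphML when `ape` /
#' `igraph` support them) together with a JSON provenance manifest of
#' parameters, seed and output digests. Reruns with the same config produce
#' identical manifests.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips all
#'   file output.
#' @return A list of class `pipeline_result` with each stage's objects
#'   (`inventory`, `ivi`, `abundance`, `clustering`, `test_values`,
#'   `interaction`, `network`, `coords`, `rfe`, `kept_features`, `fit`,
#'   `importance`, `predictions`, `composition_clusters`,
#'   `composition_ecosystems`, `comparison`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  files <- character(0)
  emit <- function(x, name) {
    if (!is.null(out_dir)) files[[name]] <<- write_stage_csv(x, out_dir, name)
    invisible(x)
  }
  stage <- "simulate"
  res <- tryCatch({
    inv <- generate_inventory(config$sim)
    segments <- generate_segments(config$sim, inv$truth)
    landscape <- generate_landscape(config$sim, inv$truth)
    emit(inv$records, "tree_records"); emit(inv$plots, "plot_metadata")
    emit(segments, "segment_features")

    stage <- "ivi"
    ivi <- compute_ivi(inv$records)
    abundance <- select_dominant(ivi, threshold_pct = config$ivi_threshold)
    emit(ivi, "ivi"); emit(abundance, "abundance_matrix")

    stage <- "cluster"
    clustering <- cluster_sites(
      abundance,
      n_randomizations = config$n_randomizations,
      seed = derive_seed(config$seed, "clustering"),
      k = config$k
    )
    emit(clustering$labels, "cluster_labels")
    if (!is.null(out_dir)) {
      D <- clustering$D
      emit(as_tibble(D, rownames = "site_id"), "dissimilarity")
      if (requireNamespace("ape", quietly = TRUE)) {
        files[["dendrogram"]] <- write_newick(
          clustering$tree, file.path(out_dir, "dendrogram.nwk")
        )
      }
    }

    stage <- "contributions"
    tv <- test_values(abundance, clustering$labels)
    sets <- contributive_species(tv, delta = config$delta)
    rho_hat <- suppressMessages(normalize_contributions(tv))
    inter <- interaction_matrix(rho_hat, sets)
    emit(tidy(tv), "test_values")
    emit(as_tibble(inter$lambda, rownames = "cluster"), "lambda")

    stage <- "network"
    net <- network_edges(inter, min_edge = config$min_edge)
    coords <- project_network(inter, inv$plots, clustering$labels,
                              x_var = config$env_x, y_var = config$env_y)
    emit(net$edges, "network_edges"); emit(coords, "network_coords")
    if (!is.null(out_dir)) {
      g <- as_igraph(inter, min_edge = config$min_edge)
      gml <- file.path(out_dir, "network.graphml")
      igraph::write_graph(g, gml, format = "graphml")
      files[["network_graphml"]] <- gml
    }

    stage <- "model"
    lab <- label_segments(segments, clustering,
                          min_cluster_size = config$min_cluster_size)
    rfe <- select_features_rfe(
      lab$train, subset_sizes = config$rfe_sizes, folds = min(5, config$folds),
      seed = derive_seed(config$seed, "rfe"), num_trees = config$num_trees
    )
    pruned <- prune_collinear(lab$train, rfe$best_subset,
                              r_threshold = config$r_threshold)
    fit <- fit_evaluate(lab$train, features = pruned$kept,
                        folds = config$folds,
                        seed = derive_seed(config$seed, "model"),
                        num_trees = config$num_trees)
    imp <- permutation_importance(fit, n_permutations = config$n_permutations,
                                  seed = derive_seed(config$seed, "importance"))
    preds <- predict_segments(fit, lab$predict)
    emit(rfe$scores, "rfe_scores")
    emit(as_tibble(fit$confusion_pct, rownames = "truth"), "confusion")
    emit(tidy(fit), "per_class_f1")
    emit(as_tibble(imp), "importance")
    emit(preds, "segment_predictions")

    stage <- "composition"
    comp_cl <- suppressWarnings(
      composition_by_cluster(inv$plots, clustering)
    )
    predicted_pixels <- landscape |>
      dplyr::inner_join(
        dplyr::select(preds, "segment_id", "ecosystem"),
        by = "segment_id", suffix = c("_true", "")
      )
    comp_eco <- composition_by_ecosystem(predicted_pixels)
    comparison <- compare_compositions(comp_cl, comp_eco)
    emit(comp_cl, "composition_clusters")
    emit(comp_eco, "composition_ecosystems")
    emit(comparison$by_ecosystem, "composition_comparison")

    list(
      inventory = inv, segments = segments, landscape = landscape,
      ivi = ivi, abundance = abundance, clustering = clustering,
      test_values = tv, sets = sets, interaction = inter, network = net,
      coords = coords, rfe = rfe, kept_features = pruned$kept, fit = fit,
      importance = imp, predictions = preds,
      composition_clusters = comp_cl, composition_ecosystems = comp_eco,
      comparison = comparison
    )
  }, error = function(e) {
    abort(paste0("pipeline failed at stage `", stage, "`: ",
                 conditionMessage(e)), parent = e)
  })

  manifest <- list(
    seed = config$seed,
    parameters = config[setdiff(names(config), "sim")],
    sim = unclass(config$sim),
    outputs = if (!is.null(out_dir)) {
      sums <- tools::md5sum(unlist(files))
      names(sums) <- basename(names(sums))
      as.list(sums)
    } else list()
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res$manifest <- manifest
  class(res) <- "pipeline_result"
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result\n")
  print(x$clustering)
  print(x$interaction)
  print(x$fit)
  print(x$comparison)
  invisible(x)
}
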