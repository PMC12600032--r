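# Object-oriented ecosystem classification on segment quantile features.

#' Summarise per-segment pixel samples into quantile features
#'
#' Statistical zoning: each segment is summarised, per variable, by its
#' 25th, 50th and 75th percentiles (linear-interpolation quantiles,
#' `type = 7`), which damps local pixel variability while keeping the
#' segment's environmental trend.
#'
#' @param pixels Long tibble with columns `segment_id`, `variable`, `value`
#'   (one row per pixel sample per variable).
#' @return A wide tibble: `segment_id` plus `<variable>_q25`,
#'   `<variable>_q50`, `<variable>_q75` columns.
#' @export
compute_segment_quantiles <- function(pixels) {
  need <- c("segment_id", "variable", "value")
  miss <- setdiff(need, names(pixels))
  if (length(miss) > 0) {
    abort(paste0("pixel table missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(pixels) == 0) abort("empty pixel table")
  pixels |>
    dplyr::group_by(.data$segment_id, .data$variable) |>
    dplyr::summarise(
      q25 = quantile(.data$value, 0.25, names = FALSE, type = 7),
      q50 = quantile(.data$value, 0.50, names = FALSE, type = 7),
      q75 = quantile(.data$value, 0.75, names = FALSE, type = 7),
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(
      names_from = "variable", values_from = c("q25", "q50", "q75"),
      names_glue = "{variable}_{.value}", names_sort = TRUE
    ) |>
    dplyr::arrange(.data$segment_id)
}

#' Label segments from plot clusters and split training/prediction sets
#'
#' A segment containing an inventory plot adopts that plot's cluster on the
#' assumption that the plot represents the whole segment. Clusters with
#' fewer than `min_cluster_size` labelled segments are too thin to model
#' and are excluded entirely; segments without a plot form the prediction
#' set. Segments linked to plots from conflicting clusters are excluded
#' with a warning.
#'
#' @param segments Segment feature table with `segment_id`, optional
#'   `plot_id`, and feature columns.
#' @param plot_labels A `bioregion_clustering` object, or a tibble with
#'   `site_id` and `cluster_id`.
#' @param min_cluster_size Minimum labelled segments per retained cluster
#'   (default 15).
#' @return A list with `train` (labelled tibble with a `cluster` factor
#'   column), `predict` (unlabelled segments), `excluded` (tibble with
#'   `segment_id`, `reason`).
#' @export
label_segments <- function(segments, plot_labels, min_cluster_size = 15) {
  lab_tbl <- if (inherits(plot_labels, "bioregion_clustering")) {
    plot_labels$labels
  } else {
    as_tibble(plot_labels)
  }
  if (!all(c("site_id", "cluster_id") %in% names(lab_tbl))) {
    abort("plot labels need `site_id` and `cluster_id` columns")
  }
  if (!"plot_id" %in% names(segments)) {
    abort("segment table needs a `plot_id` column (NA for unsampled segments)")
  }
  seg <- dplyr::mutate(segments, plot_id = as.character(.data$plot_id))
  lab_tbl <- dplyr::mutate(lab_tbl, site_id = as.character(.data$site_id))
  joined <- dplyr::left_join(seg, lab_tbl, by = c("plot_id" = "site_id"))

  conflicts <- joined |>
    dplyr::filter(!is.na(.data$cluster_id)) |>
    dplyr::group_by(.data$segment_id) |>
    dplyr::filter(dplyr::n_distinct(.data$cluster_id) > 1) |>
    dplyr::ungroup()
  if (nrow(conflicts) > 0) {
    warn(sprintf("excluding %d segment(s) linked to plots from different clusters",
                 dplyr::n_distinct(conflicts$segment_id)))
    joined <- dplyr::filter(joined, !.data$segment_id %in% conflicts$segment_id)
  }
  joined <- dplyr::distinct(joined, .data$segment_id, .keep_all = TRUE)

  labelled <- dplyr::filter(joined, !is.na(.data$cluster_id))
  sizes <- dplyr::count(labelled, .data$cluster_id)
  small <- sizes$cluster_id[sizes$n < min_cluster_size]
  excluded <- dplyr::bind_rows(
    if (nrow(conflicts) > 0) {
      tibble(segment_id = unique(conflicts$segment_id),
             reason = "conflicting plot clusters")
    },
    labelled |>
      dplyr::filter(.data$cluster_id %in% small) |>
      dplyr::transmute(.data$segment_id,
                       reason = sprintf("cluster below %d labelled segments",
                                        min_cluster_size))
  )
  train <- labelled |>
    dplyr::filter(!.data$cluster_id %in% small) |>
    dplyr::mutate(cluster = factor(.data$cluster_id)) |>
    dplyr::select(-"cluster_id")
  if (nrow(train) == 0) abort("no cluster reaches the minimum training size")
  list(
    train = train,
    predict = dplyr::filter(joined, is.na(.data$cluster_id)) |>
      dplyr::select(-"cluster_id"),
    excluded = excluded %||% tibble(segment_id = character(), reason = character())
  )
}

feature_columns <- function(train) {
  setdiff(names(train)[vapply(train, is.numeric, logical(1))],
          c("segment_id", "plot_id"))
}

# F1 scores from a confusion-count matrix (rows = truth, cols = prediction).
confusion_f1 <- function(counts) {
  counts <- as.matrix(counts)
  tp <- diag(counts)
  prec <- ifelse(colSums(counts) > 0, tp / colSums(counts), 0)
  rec <- ifelse(rowSums(counts) > 0, tp / rowSums(counts), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  support <- rowSums(counts)
  list(
    per_class = setNames(f1, rownames(counts)),
    macro_f1 = mean(f1),
    f1 = sum(f1 * support) / sum(support)   # support-weighted aggregate
  )
}

# Stratified fold assignment: each class's samples are spread over folds as
# evenly as possible. Returns an integer vector of fold ids.
stratified_folds <- function(y, folds, seed) {
  with_seed(seed, {
    out <- integer(length(y))
    for (cl in levels(y)) {
      idx <- which(y == cl)
      out[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
    }
    out
  })
}

fit_ranger <- function(train, features, seed, num_trees = 500, ...) {
  ranger::ranger(
    dependent.variable.name = "cluster",
    data = as.data.frame(train[c(features, "cluster")]),
    num.trees = num_trees, probability = TRUE, seed = seed, num.threads = 1,
    ...
  )
}

predict_classes <- function(fit, newdata, features) {
  prob <- predict(fit, data = as.data.frame(newdata[features]),
                  num.threads = 1)$predictions
  cls <- colnames(prob)[max.col(prob, ties.method = "first")]
  list(class = cls, prob = prob)
}

# Cross-validated weighted F1 of a feature subset (internal scorer shared by
# RFE and fit_evaluate).
cv_f1 <- function(train, features, folds, seed, num_trees = 500) {
  y <- train$cluster
  fold_id <- stratified_folds(y, folds, derive_seed(seed, "folds"))
  pred <- character(length(y))
  for (f in seq_len(folds)) {
    hold <- fold_id == f
    fit <- fit_ranger(train[!hold, , drop = FALSE], features,
                      seed = seed + f, num_trees = num_trees)
    pred[hold] <- predict_classes(fit, train[hold, , drop = FALSE], features)$class
  }
  counts <- table(factor(y, levels = levels(y)),
                  factor(pred, levels = levels(y)))
  confusion_f1(counts)
}

#' Recursive feature elimination with a random forest
#'
#' Ranks candidate features by recursively refitting a random forest and
#' dropping the least important (impurity importance) variable until one
#' remains, then scores each requested subset size (top-ranked variables)
#' by cross-validated support-weighted F1 and returns the best-scoring
#' subset (smallest size on ties).
#'
#' @param train Labelled training table from [label_segments()].
#' @param subset_sizes Integer vector of subset sizes to score (default
#'   `5:30`, clipped to the number of candidate features with a warning).
#' @param folds Cross-validation folds for scoring (default 5).
#' @param seed Integer seed controlling fold assignment and forest fits.
#' @param num_trees Trees per forest (default 500).
#' @return A list of class `rfe_result`: `ranking` (features, best first),
#'   `best_subset`, `scores` (tibble `size`, `f1`, `macro_f1`).
#' @export
select_features_rfe <- function(train, subset_sizes = 5:30, folds = 5,
                                seed = 1, num_trees = 500) {
  features <- feature_columns(train)
  subset_sizes <- sort(unique(as.integer(subset_sizes)))
  if (any(subset_sizes > length(features))) {
    warn("subset sizes larger than the number of candidate features were clipped")
    subset_sizes <- subset_sizes[subset_sizes <= length(features)]
    if (length(subset_sizes) == 0) subset_sizes <- length(features)
  }
  # backward elimination: refit, drop least important, record elimination order
  current <- features
  elim <- character(0)
  r <- 0L
  while (length(current) > 1) {
    r <- r + 1L
    fit <- fit_ranger(train, current, seed = derive_seed(seed, "rfe") + r,
                      num_trees = num_trees, importance = "impurity")
    imp <- fit$variable.importance
    worst <- names(imp)[which.min(imp)]
    elim <- c(worst, elim)
    current <- setdiff(current, worst)
  }
  ranking <- c(current, elim)  # best first
  scores <- purrr::map_dfr(subset_sizes, function(s) {
    sc <- cv_f1(train, ranking[seq_len(s)], folds = folds, seed = seed,
                num_trees = num_trees)
    tibble(size = s, f1 = sc$f1, macro_f1 = sc$macro_f1)
  })
  best_size <- scores$size[which.max(scores$f1)]
  structure(
    list(ranking = ranking, best_subset = ranking[seq_len(best_size)],
         scores = scores),
    class = "rfe_result"
  )
}

#' @export
print.rfe_result <- function(x, ...) {
  cat("RFE over", length(x$ranking), "candidates; best subset:",
      length(x$best_subset), "features\n")
  cat("  ", paste(head(x$best_subset, 10), collapse = ", "),
      if (length(x$best_subset) > 10) "..." else "", "\n")
  invisible(x)
}

#' Prune collinear features
#'
#' Greedy scan in ranking order: a feature is dropped if its absolute
#' Pearson correlation with any already-kept feature exceeds `r_threshold`
#' — a deterministic stand-in for expert removal of redundant variables.
#'
#' @param train Training table providing the feature values.
#' @param subset Character vector of features in priority (rank) order.
#' @param r_threshold Absolute correlation above which a feature is
#'   redundant (default 0.7; strictly greater-than).
#' @return A list with `kept` (character vector) and `dropped` (tibble
#'   `dropped`, `against`, `r`).
#' @export
prune_collinear <- function(train, subset, r_threshold = 0.7) {
  stopifnot(all(subset %in% names(train)))
  kept <- character(0)
  log <- list()
  for (v in subset) {
    if (length(kept) == 0) {
      kept <- v
      next
    }
    rs <- vapply(kept, function(k) cor(train[[v]], train[[k]]), numeric(1))
    rs[is.na(rs)] <- 0  # constant columns carry no collinearity signal
    if (any(abs(rs) > r_threshold)) {
      worst <- which.max(abs(rs))
      log[[v]] <- tibble(dropped = v, against = kept[worst], r = rs[worst])
    } else {
      kept <- c(kept, v)
    }
  }
  list(
    kept = kept,
    dropped = if (length(log) > 0) dplyr::bind_rows(log) else
      tibble(dropped = character(), against = character(), r = double())
  )
}

#' Fit and cross-validate the ecosystem classifier
#'
#' Fits a probability random forest on the selected features and evaluates
#' it with stratified k-fold cross-validation: out-of-fold predictions are
#' pooled into a confusion matrix (reported as row percentages), per-class
#' F1, a support-weighted aggregate F1 and the macro F1 (unweighted mean
#' over classes, robust to class imbalance). If the smallest class has
#' fewer samples than `folds`, the number of folds is reduced to that size
#' with a warning.
#'
#' @param train Labelled training table from [label_segments()].
#' @param features Feature columns to use; default all numeric columns.
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed.
#' @param num_trees Trees per forest (default 500).
#' @return An object of class `ecosystem_fit`: list with `model` (final
#'   ranger fit on all data), `features`, `classes`, `confusion_counts`,
#'   `confusion_pct` (rows sum to 100), `per_class_f1`, `f1`, `macro_f1`,
#'   `folds`, `seed`, `train`.
#' @export
fit_evaluate <- function(train, features = NULL, folds = 10, seed = 1,
                         num_trees = 500) {
  if (is.null(features)) features <- feature_columns(train)
  y <- droplevels(factor(train$cluster))
  train$cluster <- y
  if (nlevels(y) < 2) abort("need at least two classes to fit a classifier")
  min_class <- min(table(y))
  if (min_class < folds) {
    warn(sprintf("smallest class has %d samples; reducing folds from %d to %d",
                 min_class, folds, min_class))
    folds <- max(2, min_class)
  }
  fold_id <- stratified_folds(y, folds, derive_seed(seed, "folds"))
  pred <- character(length(y))
  for (f in seq_len(folds)) {
    hold <- fold_id == f
    fit <- fit_ranger(train[!hold, , drop = FALSE], features,
                      seed = seed + f, num_trees = num_trees)
    pred[hold] <- predict_classes(fit, train[hold, , drop = FALSE], features)$class
  }
  counts <- table(factor(y, levels = levels(y)), factor(pred, levels = levels(y)))
  scores <- confusion_f1(counts)
  pct <- 100 * counts / pmax(rowSums(counts), 1)
  final <- fit_ranger(train, features, seed = seed, num_trees = num_trees,
                      importance = "permutation")
  structure(
    list(
      model = final, features = features, classes = levels(y),
      confusion_counts = unclass(counts), confusion_pct = unclass(pct),
      per_class_f1 = scores$per_class, f1 = scores$f1,
      macro_f1 = scores$macro_f1, folds = folds, seed = seed,
      num_trees = num_trees, train = train
    ),
    class = "ecosystem_fit"
  )
}

#' @export
print.ecosystem_fit <- function(x, ...) {
  cat("Ecosystem random forest:", length(x$classes), "classes,",
      length(x$features), "features,", x$folds, "-fold CV\n", sep = " ")
  cat(sprintf("  F1 = %.3f, macro F1 = %.3f\n", x$f1, x$macro_f1))
  invisible(x)
}

#' Tidy per-class cross-validation metrics
#'
#' @param x An `ecosystem_fit` object.
#' @param ... Unused.
#' @return `tidy()`: tibble with `class`, `support`, `f1`; `glance()`: a
#'   one-row tibble with `f1`, `macro_f1`, `folds`, `n_features`, `n_train`.
#' @export
tidy.ecosystem_fit <- function(x, ...) {
  tibble(
    class = x$classes,
    support = rowSums(x$confusion_counts),
    f1 = unname(x$per_class_f1)
  )
}

#' @rdname tidy.ecosystem_fit
#' @export
glance.ecosystem_fit <- function(x, ...) {
  tibble(
    f1 = x$f1, macro_f1 = x$macro_f1, folds = x$folds,
    n_features = length(x$features), n_train = nrow(x$train)
  )
}

#' Permutation importance with response-permutation p-values
#'
#' Observed importance is the forest's permutation importance (mean
#' decrease in accuracy) and impurity importance (mean decrease Gini),
#' overall and per class (per-class values aggregate casewise importance
#' over the cases of each class). The null distribution is built by
#' refitting the forest `n_permutations` times on label-permuted data; the
#' p-value of a variable is `(1 + #\{null >= observed\}) /
#' (n_permutations + 1)`, so the smallest attainable p with 100
#' permutations is 1/101.
#'
#' @param fit An `ecosystem_fit` object.
#' @param n_permutations Number of label permutations (default 100).
#' @param seed Integer seed.
#' @return An object of class `ecosystem_importance`: tibble with columns
#'   `variable`, `class` (`"overall"` or a class name), `metric`
#'   (`"mean_decrease_accuracy"` or `"mean_decrease_gini"`), `importance`,
#'   `p_value`; attribute `n_permutations`.
#' @export
permutation_importance <- function(fit, n_permutations = 100, seed = 1) {
  stopifnot(inherits(fit, "ecosystem_fit"))
  train <- fit$train
  features <- fit$features
  obs <- importance_components(train, features, seed = derive_seed(seed, "importance"),
                               num_trees = fit$num_trees)
  null_acc <- array(NA_real_, c(n_permutations, length(features)),
                    dimnames = list(NULL, features))
  null_gini <- null_acc
  null_class <- array(
    NA_real_, c(n_permutations, length(features), length(fit$classes)),
    dimnames = list(NULL, features, fit$classes)
  )
  with_seed(derive_seed(seed, "importance") + 1L, {
    for (r in seq_len(n_permutations)) {
      perm <- train
      perm$cluster <- sample(perm$cluster)
      nl <- importance_components(perm, features,
                                  seed = derive_seed(seed, "importance") + 1L + r,
                                  num_trees = fit$num_trees)
      null_acc[r, ] <- nl$accuracy[features]
      null_gini[r, ] <- nl$gini[features]
      null_class[r, , ] <- nl$per_class[features, , drop = FALSE]
    }
  })
  p_of <- function(nulls, observed) {
    (1 + colSums(sweep(nulls, 2, observed, `>=`), na.rm = TRUE)) /
      (n_permutations + 1)
  }
  rows <- list(
    tibble(
      variable = features, class = "overall",
      metric = "mean_decrease_accuracy",
      importance = unname(obs$accuracy[features]),
      p_value = unname(p_of(null_acc, obs$accuracy[features]))
    ),
    tibble(
      variable = features, class = "overall",
      metric = "mean_decrease_gini",
      importance = unname(obs$gini[features]),
      p_value = unname(p_of(null_gini, obs$gini[features]))
    )
  )
  for (cl in fit$classes) {
    nulls_cl <- null_class[, , cl, drop = FALSE]
    dim(nulls_cl) <- c(n_permutations, length(features))
    rows[[length(rows) + 1]] <- tibble(
      variable = features, class = cl,
      metric = "mean_decrease_accuracy",
      importance = unname(obs$per_class[features, cl]),
      p_value = unname(p_of(nulls_cl, obs$per_class[features, cl]))
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "n_permutations") <- n_permutations
  class(out) <- c("ecosystem_importance", class(out))
  out
}

# Permutation (accuracy) and impurity (Gini) importance of one forest fit,
# plus per-class accuracy importance from casewise contributions.
importance_components <- function(train, features, seed, num_trees = 500) {
  acc_fit <- ranger::ranger(
    dependent.variable.name = "cluster",
    data = as.data.frame(train[c(features, "cluster")]),
    num.trees = num_trees, seed = seed, num.threads = 1,
    importance = "permutation", local.importance = TRUE
  )
  gini_fit <- ranger::ranger(
    dependent.variable.name = "cluster",
    data = as.data.frame(train[c(features, "cluster")]),
    num.trees = num_trees, seed = seed, num.threads = 1,
    importance = "impurity"
  )
  local_imp <- acc_fit$variable.importance.local
  by_class <- split(seq_len(nrow(train)), train$cluster)
  per_class <- matrix(
    NA_real_, length(features), length(by_class),
    dimnames = list(features, names(by_class))
  )
  for (cl in names(by_class)) {
    per_class[, cl] <- colMeans(local_imp[by_class[[cl]], features, drop = FALSE])
  }
  list(
    accuracy = acc_fit$variable.importance,
    gini = gini_fit$variable.importance,
    per_class = per_class
  )
}

#' Partial dependence of class probability on one variable
#'
#' Sweeps the variable over a grid spanning its observed range; at each
#' grid value every training row has the variable set to that value, the
#' forest predicts class probabilities, and the per-class mean probability
#' is reported on both the probability and the log-odds scale (log-odds
#' clamped away from 0/1 by `eps`).
#'
#' @param fit An `ecosystem_fit` object.
#' @param variable Name of a model feature.
#' @param grid_size Number of grid points (default 20).
#' @param eps Probability clamp for the log-odds transform (default 1e-6).
#' @return A tibble of class `ecosystem_pdp` with columns `variable`,
#'   `value`, `class`, `prob`, `log_odds`.
#' @export
partial_dependence <- function(fit, variable, grid_size = 20, eps = 1e-6) {
  stopifnot(inherits(fit, "ecosystem_fit"))
  if (!variable %in% fit$features) {
    abort(paste0("`", variable, "` is not a model feature"))
  }
  v <- fit$train[[variable]]
  grid <- seq(min(v), max(v), length.out = grid_size)
  rows <- purrr::map_dfr(grid, function(g) {
    nd <- fit$train
    nd[[variable]] <- g
    prob <- predict(fit$model, data = as.data.frame(nd[fit$features]),
                    num.threads = 1)$predictions
    p <- colMeans(prob)
    tibble(
      variable = variable, value = g, class = names(p), prob = unname(p),
      log_odds = log(pmin(pmax(unname(p), eps), 1 - eps) /
                       (1 - pmin(pmax(unname(p), eps), 1 - eps)))
    )
  })
  class(rows) <- c("ecosystem_pdp", class(rows))
  rows
}

#' Predict ecosystem labels for unlabelled segments
#'
#' @param fit An `ecosystem_fit` object.
#' @param segments Segment table with the model's feature columns.
#' @return A tibble: `segment_id`, `ecosystem` (hard label), plus one
#'   `prob_<class>` column per class (rows sum to 1).
#' @export
predict_segments <- function(fit, segments) {
  stopifnot(inherits(fit, "ecosystem_fit"))
  miss <- setdiff(fit$features, names(segments))
  if (length(miss) > 0) {
    abort(paste0("missing feature column(s): ", paste(miss, collapse = ", ")))
  }
  pr <- predict_classes(fit$model, segments, fit$features)
  probs <- as_tibble(pr$prob)
  names(probs) <- paste0("prob_", names(probs))
  dplyr::bind_cols(
    tibble(segment_id = segments$segment_id, ecosystem = pr$class),
    probs
  )
}
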