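test_that("segment quantiles follow the linear-interpolation convention", {
  px <- tibble::tibble(
    segment_id = rep(c("g1", "g2", "g3"), times = c(5, 4, 3)),
    variable = "v",
    value = c(1, 2, 3, 4, 5, 1, 2, 3, 4, 7, 7, 7)
  )
  q <- compute_segment_quantiles(px)
  expect_equal(q$v_q50[q$segment_id == "g1"], 3)
  expect_equal(q$v_q25[q$segment_id == "g2"], 1.75)
  expect_equal(unlist(q[q$segment_id == "g3", c("v_q25", "v_q50", "v_q75")]),
               c(v_q25 = 7, v_q50 = 7, v_q75 = 7))
  expect_true(all(q$v_q25 <= q$v_q50 & q$v_q50 <= q$v_q75))
})

test_that("segment labelling applies the minimum-cluster-size rule", {
  segs <- tibble::tibble(
    segment_id = sprintf("g%02d", 1:40),
    plot_id = c(sprintf("p%02d", 1:25), rep(NA, 15)),
    f_q50 = rnorm(40)
  )
  labels <- tibble::tibble(
    site_id = sprintf("p%02d", 1:25),
    cluster_id = rep(c(1, 2), c(18, 7))  # cluster 2 below the threshold
  )
  out <- label_segments(segs, labels, min_cluster_size = 15)
  expect_equal(sort(unique(as.character(out$train$cluster))), "1")
  expect_equal(nrow(out$train), 18)
  expect_equal(nrow(out$predict), 15)
  expect_true(all(grepl("below 15", out$excluded$reason)))
  expect_equal(nrow(out$excluded), 7)
})

test_that("segments linked to conflicting plot clusters are excluded", {
  segs <- tibble::tibble(
    segment_id = c("g1", "g1", "g2"),
    plot_id = c("p1", "p2", "p3"),
    f_q50 = c(0, 0, 1)
  )
  labels <- tibble::tibble(site_id = c("p1", "p2", "p3"), cluster_id = c(1, 2, 1))
  expect_warning(
    out <- label_segments(segs, labels, min_cluster_size = 1),
    "different clusters"
  )
  expect_false("g1" %in% out$train$segment_id)
  expect_true("g2" %in% out$train$segment_id)
})

test_that("confusion-matrix metrics reproduce the toy F1 arithmetic", {
  counts <- rbind(c(2, 0), c(1, 1))
  rownames(counts) <- colnames(counts) <- c("A", "B")
  sc <- ecodelin:::confusion_f1(counts)
  expect_equal(unname(sc$per_class), c(0.8, 2 / 3), tolerance = 1e-12)
  expect_equal(sc$macro_f1, (0.8 + 2 / 3) / 2, tolerance = 1e-12)
  expect_equal(sc$f1, (2 * 0.8 + 2 * 2 / 3) / 4, tolerance = 1e-12)
})

test_that("cross-validation on separable clusters reaches macro F1 = 1", {
  set.seed(2)
  train <- separable_training(n_per_class = 15, n_classes = 3)
  fit <- fit_evaluate(train, folds = 5, seed = 4, num_trees = 100)
  expect_equal(fit$macro_f1, 1)
  expect_equal(fit$f1, 1)
  expect_equal(unname(rowSums(fit$confusion_pct)), rep(100, 3),
               tolerance = 1e-9)
  expect_equal(fit$macro_f1, mean(fit$per_class_f1))
  expect_equal(glance(fit)$macro_f1, 1)
  expect_equal(nrow(tidy(fit)), 3)
})

test_that("shuffled labels score near chance on balanced classes", {
  set.seed(33)
  train <- separable_training(n_per_class = 30, n_classes = 2)
  train$cluster <- sample(train$cluster)
  fit <- fit_evaluate(train, folds = 5, seed = 9, num_trees = 100)
  expect_lt(fit$macro_f1, 0.75)  # chance level is ~0.5 for 2 classes
})

test_that("folds shrink with a warning when the smallest class is tiny", {
  set.seed(3)
  train <- separable_training(n_per_class = 20, n_classes = 2)
  train <- train[c(1:20, 21:25), ]  # class 2 has only 5 samples
  expect_warning(fit <- fit_evaluate(train, folds = 10, seed = 1,
                                     num_trees = 50),
                 "reducing folds")
  expect_equal(fit$folds, 5)
})

test_that("RFE ranks the informative feature first and selects it", {
  set.seed(14)
  results <- sapply(1:5, function(s) {
    train <- separable_training(n_per_class = 15, n_classes = 2, n_noise = 9)
    rfe <- select_features_rfe(train, subset_sizes = c(2, 4), folds = 3,
                               seed = s, num_trees = 100)
    rfe$ranking[1] == "informative" && "informative" %in% rfe$best_subset
  })
  expect_true(all(results))
})

test_that("a leaked label feature is selected with perfect CV score", {
  set.seed(6)
  train <- separable_training(n_per_class = 12, n_classes = 2, n_noise = 4)
  train$leak <- as.numeric(train$cluster)
  rfe <- select_features_rfe(train, subset_sizes = c(1, 3), folds = 3,
                             seed = 2, num_trees = 100)
  expect_true("leak" %in% rfe$best_subset || "informative" %in% rfe$best_subset)
  expect_gte(max(rfe$scores$f1), 0.99)
  # requesting the full feature count is the identity selection
  nfeat <- length(ecodelin:::feature_columns(train))
  rfe_all <- select_features_rfe(train, subset_sizes = nfeat, folds = 3,
                                 seed = 2, num_trees = 50)
  expect_setequal(rfe_all$best_subset, ecodelin:::feature_columns(train))
})

test_that("collinearity pruning follows the greedy rank-order rule", {
  set.seed(5)
  n <- 400
  v1 <- rnorm(n)
  train <- tibble::tibble(
    v1 = v1,
    v2 = v1 + rnorm(n, 0, 0.1),   # r ~ 0.995 with v1
    v3 = rnorm(n),
    dup = v1                       # exact duplicate
  )
  out <- prune_collinear(train, c("v1", "v2", "v3", "dup"), r_threshold = 0.7)
  expect_equal(out$kept, c("v1", "v3"))
  expect_setequal(out$dropped$dropped, c("v2", "dup"))
  # independent features at n = 400 all survive
  ind <- tibble::tibble(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  expect_equal(prune_collinear(ind, c("a", "b", "c"))$kept, c("a", "b", "c"))
})

test_that("pruning a correlation chain keeps the ends", {
  # r(v1,v2) and r(v2,v3) high, r(v1,v3) low -> keep {v1, v3}
  set.seed(91)
  n <- 600
  z1 <- rnorm(n); z3 <- rnorm(n)
  v2 <- (z1 + z3) / sqrt(2) + rnorm(n, 0, 0.25)
  train <- tibble::tibble(v1 = z1, v2 = v2, v3 = z3)
  stopifnot(abs(cor(z1, v2)) > 0.6, abs(cor(z1, z3)) < 0.2)
  out <- prune_collinear(train, c("v1", "v2", "v3"), r_threshold = 0.6)
  expect_equal(out$kept, c("v1", "v3"))
})

test_that("permutation importance flags the separating variable at p = 1/101", {
  set.seed(10)
  train <- separable_training(n_per_class = 25, n_classes = 2, n_noise = 3)
  fit <- fit_evaluate(train, folds = 5, seed = 3, num_trees = 100)
  imp <- permutation_importance(fit, n_permutations = 100, seed = 5)
  overall <- dplyr::filter(imp, class == "overall",
                           metric == "mean_decrease_accuracy")
  inf <- overall[overall$variable == "informative", ]
  expect_equal(inf$p_value, 1 / 101, tolerance = 1e-12)
  expect_gt(inf$importance, max(overall$importance[overall$variable != "informative"]))
  expect_true(all(imp$p_value > 0 & imp$p_value <= 1))
  expect_equal(attr(imp, "n_permutations"), 100)
})

test_that("noise variables are not systematically significant", {
  set.seed(44)
  train <- separable_training(n_per_class = 20, n_classes = 2, n_noise = 4)
  fit <- fit_evaluate(train, folds = 4, seed = 7, num_trees = 60)
  imp <- permutation_importance(fit, n_permutations = 40, seed = 8)
  noise_p <- dplyr::filter(imp, class == "overall",
                           metric == "mean_decrease_accuracy",
                           grepl("^noise", variable))$p_value
  expect_gt(mean(noise_p), 0.2)  # roughly uniform null, not clustered at 0
})

test_that("partial dependence is monotone for a threshold rule and flat for noise", {
  set.seed(19)
  train <- separable_training(n_per_class = 25, n_classes = 2, n_noise = 2)
  fit <- fit_evaluate(train, folds = 5, seed = 6, num_trees = 150)
  pdp <- partial_dependence(fit, "informative", grid_size = 15)
  expect_true(all(pdp$value >= min(train$informative) &
                    pdp$value <= max(train$informative)))
  c2 <- dplyr::filter(pdp, class == "2")
  # high values of the informative feature indicate class 2
  expect_gt(dplyr::last(c2$prob), dplyr::first(c2$prob))
  expect_gt(dplyr::last(c2$log_odds), 0)
  flat <- partial_dependence(fit, "noise1", grid_size = 10)
  spread <- diff(range(dplyr::filter(flat, class == "2")$prob))
  expect_lt(spread, 0.2)
  expect_error(partial_dependence(fit, "absent"), "not a model feature")
})

test_that("segment prediction returns calibrated probability rows", {
  set.seed(27)
  train <- separable_training(n_per_class = 15, n_classes = 3)
  fit <- fit_evaluate(train, folds = 3, seed = 2, num_trees = 100)
  preds <- predict_segments(fit, train)
  expect_equal(nrow(preds), nrow(train))
  probs <- as.matrix(preds[grepl("^prob_", names(preds))])
  expect_equal(unname(rowSums(probs)), rep(1, nrow(train)), tolerance = 1e-9)
  expect_equal(preds$ecosystem, as.character(train$cluster))
  expect_error(predict_segments(fit, train[, c("segment_id", "noise1")]),
               "missing feature")
})
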