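test_that("test value matches the worked example and degenerate cases", {
  # abundances (4,0,0,0) over 4 sites; cluster {s1,s2}:
  # mu = 1, sigma2 = 3, mu_ij = 2, denom = sqrt((2/3) * (3/2)) = 1 -> rho = 1
  m <- matrix(c(4, 0, 0, 0), 4, 1,
              dimnames = list(paste0("s", 1:4), "spA"))
  lab <- setNames(c(1, 1, 2, 2), rownames(m))
  tv <- test_values(m, lab)
  expect_equal(tv$rho["spA", "1"], 1, tolerance = 1e-12)
  # constant species: rho = 0 everywhere
  m2 <- cbind(m, spB = rep(3, 4))
  tv2 <- test_values(m2, lab)
  expect_equal(unname(tv2$rho["spB", ]), c(0, 0))
  # abundance conservation: sum_j n_j mu_ij = n mu
  expect_equal(sum(tv2$n_j * tv2$mu_ij["spA", ]), tv2$n * tv2$mu[["spA"]])
  # two complementary clusters force opposite signs
  expect_lt(prod(tv$rho["spA", ]), 0)
})

test_that("the denominator equals the exhaustive subset-resampling SD for n <= 8", {
  set.seed(8)
  for (n in 3:8) {
    x <- sample(0:6, n, replace = TRUE)
    if (var(x) == 0) x[1] <- x[1] + 1
    mu <- mean(x)
    sigma2 <- mean((x - mu)^2)
    for (nj in 1:(n - 1)) {
      subsets <- combn(n, nj)
      means <- apply(subsets, 2, function(idx) mean(x[idx]))
      pop_sd <- sqrt(mean((means - mean(means))^2))
      expect_equal(mean(means), mu, tolerance = 1e-9)
      expect_equal(pop_sd, sqrt(((n - nj) / (n - 1)) * sigma2 / nj),
                   tolerance = 1e-9)
    }
  }
})

test_that("rho from the package equals a direct formula recomputation", {
  set.seed(12)
  m <- random_abundance(9, 6)
  lab <- setNames(sample(1:3, 9, replace = TRUE), rownames(m))
  lab[1:3] <- 1:3  # ensure every cluster non-empty and not full
  tv <- test_values(m, lab)
  n <- nrow(m)
  for (sp in colnames(m)) {
    x <- m[, sp]
    mu <- mean(x); s2 <- mean((x - mu)^2)
    for (cl in colnames(tv$rho)) {
      nj <- sum(lab == cl)
      expected <- if (s2 == 0) 0 else {
        (mean(x[lab == cl]) - mu) / sqrt(((n - nj) / (n - 1)) * s2 / nj)
      }
      expect_equal(tv$rho[sp, cl], expected, tolerance = 1e-12)
    }
  }
})

test_that("contributive sets use the inclusive delta rule", {
  tv <- structure(
    list(rho = rbind(s1 = c(2.5, -1.0), s2 = c(1.96, 0.3),
                     s3 = c(1.0, 1.5))),
    class = "species_test_values"
  )
  colnames(tv$rho) <- c("1", "2")
  sets <- contributive_species(tv, delta = 1.96)
  expect_setequal(sets$sets[["1"]], c("s1", "s2"))  # boundary included
  expect_equal(sets$sets[["2"]], character(0))
  expect_equal(sets$species_counts$n_clusters, c(1, 1, 0))
  huge <- contributive_species(tv, delta = 1e6)
  expect_true(all(lengths(huge$sets) == 0))
})

test_that("normalised contributions clip at zero and rows sum to 1", {
  rho <- rbind(a = c(3.92, 1.96, -1.0), b = c(0.5, 0, 0),
               c = c(-2, -1, -0.5))
  colnames(rho) <- c("1", "2", "3")
  tv <- structure(list(rho = rho), class = "species_test_values")
  expect_message(rh <- normalize_contributions(tv), "dropped")
  expect_equal(unname(rh["a", ]), c(3.92, 1.96, 0) / 5.88, tolerance = 1e-12)
  expect_equal(unname(rh["b", ]), c(1, 0, 0))
  expect_false("c" %in% rownames(rh))
  expect_equal(attr(rh, "dropped"), "c")
  expect_equal(unname(rowSums(rh)), rep(1, 2), tolerance = 1e-12)
  # significant-only clipping zeroes sub-threshold entries
  rh2 <- suppressMessages(normalize_contributions(tv, clip = "significant"))
  expect_equal(unname(rh2["a", ]), c(3.92, 1.96, 0) / 5.88)
  expect_false("b" %in% rownames(rh2))
})

test_that("interaction matrix is the row mean over contributive species", {
  rho_hat <- rbind(s1 = c(1.0, 0.0), s2 = c(0.8, 0.2))
  colnames(rho_hat) <- c("1", "2")
  sets <- structure(
    list(sets = list(`1` = c("s1", "s2"), `2` = c("s2")), delta = 1.96),
    class = "contributive_sets"
  )
  im <- interaction_matrix(rho_hat, sets)
  expect_equal(unname(im$lambda["1", ]), c(0.9, 0.1), tolerance = 1e-12)
  expect_equal(unname(im$lambda["2", ]), c(0.8, 0.2), tolerance = 1e-12)
  expect_equal(unname(rowSums(im$lambda)), rep(1, 2), tolerance = 1e-12)
})

test_that("lambda rows sum to 1 and permute consistently under relabeling", {
  set.seed(21)
  m <- random_abundance(15, 12)
  lab <- setNames(rep(1:3, each = 5), rownames(m))
  tv <- test_values(m, lab)
  sets <- contributive_species(tv, delta = 1.0)
  rh <- suppressMessages(normalize_contributions(tv))
  im <- suppressWarnings(interaction_matrix(rh, sets))
  expect_equal(unname(rowSums(im$lambda)), rep(1, nrow(im$lambda)),
               tolerance = 1e-9)
  expect_true(all(im$lambda >= 0 & im$lambda <= 1))

  # permute cluster labels: 1->2, 2->3, 3->1
  perm <- c(`1` = "2", `2` = "3", `3` = "1")
  lab2 <- setNames(perm[as.character(lab)], names(lab))
  tv2 <- test_values(m, lab2)
  expect_equal(tv2$rho[, perm[colnames(tv$rho)]], tv$rho,
               ignore_attr = TRUE, tolerance = 1e-12)
  im2 <- suppressWarnings(interaction_matrix(
    suppressMessages(normalize_contributions(tv2)),
    contributive_species(tv2, delta = 1.0)
  ))
  if (setequal(rownames(im$lambda), names(perm))) {
    expect_equal(im2$lambda[perm[rownames(im$lambda)], perm[colnames(im$lambda)]],
                 im$lambda, ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("disjoint planted pools give an identity interaction matrix", {
  # each species positive in exactly one cluster
  m <- rbind(
    a1 = c(5, 6, 0, 0, 0, 0), a2 = c(6, 5, 0, 0, 0, 0),
    b1 = c(0, 0, 5, 6, 0, 0), b2 = c(0, 0, 6, 5, 0, 0),
    c1 = c(0, 0, 0, 0, 5, 6), c2 = c(0, 0, 0, 0, 6, 5)
  )
  colnames(m) <- paste0("sp", 1:6)
  lab <- setNames(rep(1:3, each = 2), rownames(m))
  tv <- test_values(m, lab)
  sets <- contributive_species(tv, delta = 1.0)
  im <- interaction_matrix(suppressMessages(normalize_contributions(tv)), sets)
  expect_equal(unname(im$lambda), diag(3), tolerance = 1e-12)
  edges <- network_edges(im)
  expect_equal(nrow(edges$edges), 0)
  expect_equal(edges$specificity$specificity, rep(1, 3))
})

test_that("network edges use the strict 5% rule and report specificity", {
  lambda <- rbind(`1` = c(0.82, 0.13, 0.05), `2` = c(0.05, 0.93, 0.02),
                  `3` = c(0.04, 0.01, 0.95))
  colnames(lambda) <- c("1", "2", "3")
  net <- network_edges(lambda, min_edge = 0.05)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$from, "1")
  expect_equal(net$edges$to, "2")
  expect_equal(net$edges$weight, 0.13)  # a boundary 0.05 entry is suppressed
  expect_equal(net$specificity$specificity, c(0.82, 0.93, 0.95))
  g <- as_igraph(structure(list(lambda = lambda), class = "cluster_interaction"))
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 1)
})

test_that("network projection places clusters at environmental medians", {
  lambda <- diag(2)
  dimnames(lambda) <- list(c("1", "2"), c("1", "2"))
  env <- tibble::tibble(
    plot_id = paste0("p", 1:7),
    elevation = c(100, 200, 900, 1, 2, 3, 4),
    precipitation = c(5, 6, 7, 10, 20, 30, 40)
  )
  lab <- setNames(c(1, 1, 1, 2, 2, 2, 2), env$plot_id)
  coords <- project_network(lambda, env, lab,
                            x_var = "precipitation", y_var = "elevation")
  expect_equal(coords$y[coords$cluster == "1"], 200)   # odd-sized median
  expect_equal(coords$x[coords$cluster == "2"], 25)    # even: mid of middle two
  expect_error(project_network(lambda, env, lab, x_var = "nope", y_var = "elevation"),
               "not found")
})
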