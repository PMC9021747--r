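test_that("standardize produces exact z-scores and is idempotent", {
  m <- matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "f"))
  std <- standardize(m)
  expect_equal(unname(std$values[, 1]), c(-1, 0, 1), tolerance = 1e-12)
  expect_equal(unname(std$scale["f"]), 1)

  # sample-SD convention on (1,2,3): SD = 1, so z = (-1, 0, 1);
  # against a column with sample SD != 1:
  m2 <- matrix(c(2, 4, 6), 3, 1, dimnames = list(NULL, "f"))
  expect_equal(unname(standardize(m2)$values[, 1]), c(-1, 0, 1), tolerance = 1e-12)

  sim <- simulate_scores(simulation_config(n_biopsies = 50, seed = 3))
  std1 <- standardize(sim$scores)
  std2 <- standardize(std1$values)
  expect_lt(max(abs(std2$values - std1$values)), 1e-9)

  # brute-force accumulation oracle
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  std3 <- standardize(X)
  for (j in 1:3) {
    mu <- sum(X[, j]) / 20
    s2 <- sum((X[, j] - mu)^2) / 19
    expect_equal(unname(std3$values[, j]), (X[, j] - mu) / sqrt(s2), tolerance = 1e-12)
  }

  cst <- cbind(X, k = rep(2, 20))
  expect_warning(stdc <- standardize(cst), "Constant")
  expect_true(all(stdc$values[, "k"] == 0))
})

test_that("exact-fit data is recovered with near-zero RSS", {
  set.seed(1)
  pts <- matrix(c(0, 0, 4, 0, 0, 3), 3, 2, byrow = TRUE,
                dimnames = list(NULL, c("x", "y")))
  X <- pts[rep(1:3, each = 10), ]
  rownames(X) <- sprintf("s%d", 1:30)
  m <- fit_archetypes(X, k = 3, restarts = 5, seed = 2, do_standardize = FALSE)
  expect_lt(m$rss, 1e-10)
  # archetypes equal the generating points up to permutation
  d <- as.matrix(dist(rbind(m$Z, pts)))[1:3, 4:6]
  perm <- unname(apply(d, 1, which.min))
  expect_identical(sort(perm), 1:3)
  expect_lt(max(d[cbind(1:3, perm)]), 1e-6)
})

test_that("a single archetype is the column-mean point", {
  set.seed(4)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(sprintf("s%d", 1:20), c("x", "y")))
  m <- fit_archetypes(X, k = 1, restarts = 3, seed = 1, do_standardize = FALSE)
  expect_equal(as.vector(m$Z), unname(colMeans(X)), tolerance = 1e-6)
  expect_equal(as.vector(m$A), rep(1, 20))
})

test_that("simplex weights satisfy conservation, dominance and monotone-fit contracts", {
  sim <- simulate_scores(simulation_config(n_biopsies = 150, seed = 6))
  m <- fit_archetypes(sim$scores, k = 4, restarts = 3, seed = 5)
  expect_true(all(m$A >= -1e-12))
  expect_true(all(m$B >= -1e-12))
  expect_lt(max(abs(rowSums(m$A) - 1)), 1e-8)
  expect_lt(max(abs(rowSums(m$B) - 1)), 1e-8)

  # Z = B X on the standardized data
  Xs <- standardize(sim$scores, center = m$center, scale = m$scale)$values
  expect_lt(max(abs(m$Z - m$B %*% Xs)), 1e-8)

  # fit dominance: RSS <= one-hot assignment to the nearest archetype
  d2 <- sapply(seq_len(m$k), function(j) rowSums(sweep(Xs, 2, m$Z[j, ])^2))
  expect_lte(m$rss, sum(apply(d2, 1, min)) + 1e-8)
})

test_that("archetype_scores projects known geometry exactly", {
  pts <- matrix(c(0, 0, 2, 0), 2, 2, byrow = TRUE,
                dimnames = list(NULL, c("x", "y")))
  X <- pts[rep(1:2, each = 8), ] + 0 # exact two-point geometry
  rownames(X) <- sprintf("s%d", 1:16)
  m <- fit_archetypes(X, k = 2, restarts = 3, seed = 3, do_standardize = FALSE)

  # an archetype projects to a unit weight vector
  a1 <- archetype_scores(m, matrix(m$Z[1, ], 1, dimnames = list("q", c("x", "y"))))
  expect_equal(as.vector(a1), c(1, 0), tolerance = 1e-6)

  # the midpoint projects to (1/2, 1/2)
  mid <- matrix((m$Z[1, ] + m$Z[2, ]) / 2, 1, dimnames = list("q", c("x", "y")))
  expect_equal(sort(as.vector(archetype_scores(m, mid))), c(0.5, 0.5),
               tolerance = 1e-6)

  expect_error(archetype_scores(m, matrix(0, 1, 3,
    dimnames = list("q", c("x", "y", "z")))), "match")
})

test_that("projection weights beat every vector on a fine simplex grid", {
  set.seed(9)
  k <- 3; p <- 2
  Z <- matrix(rnorm(k * p), k, p, dimnames = list(NULL, c("x", "y")))
  X <- matrix(rnorm(5 * p), 5, p, dimnames = list(sprintf("s%d", 1:5), c("x", "y")))
  A <- injuryarch:::simplex_weights(Z, X)
  # 0.01-step grid over the 3-simplex
  g <- seq(0, 1, by = 0.01)
  grid <- expand.grid(w1 = g, w2 = g)
  grid <- grid[grid$w1 + grid$w2 <= 1 + 1e-12, ]
  W <- cbind(grid$w1, grid$w2, 1 - grid$w1 - grid$w2)
  proj <- W %*% Z
  for (i in 1:5) {
    best_grid <- min(rowSums(sweep(proj, 2, X[i, ])^2))
    mine <- sum((X[i, ] - A[i, ] %*% Z)^2)
    expect_lte(mine, best_grid + 1e-8)
  }
})

test_that("cluster assignment is argmax with lowest-index tie-breaking", {
  A <- rbind(c(0.7, 0.1, 0.2), c(0.5, 0.5, 0.0), c(0.2, 0.3, 0.5))
  rownames(A) <- c("a", "b", "c")
  asg <- assign_clusters(A)
  expect_identical(asg$archetype_index, c(1L, 1L, 3L))
  expect_equal(asg$max_score, c(0.7, 0.5, 0.5))
  expect_true(all(asg$max_score >= 1 / 3))
  lab <- assign_clusters(A, labels = c("L1", "L2", "L3"))
  expect_identical(lab$label, c("L1", "L1", "L3"))
})

test_that("archetype labeling follows profiles, not indices", {
  # noise-free one-hot data at the reference profiles -> labels match truth
  cfg <- simulation_config(n_biopsies = 120, dirichlet_alpha = 0,
                           noise_sd = 0, seed = 13)
  sim <- simulate_scores(cfg)
  m <- fit_archetypes(sim$scores, k = 6, restarts = 4, seed = 2)
  lab <- label_archetypes(m, scores = sim$scores)
  expect_setequal(lab$mapping$label, archetype_labels())
  expect_true(all(lab$mapping$correlation > 0.99))

  # the induced sample labels agree with the planted ones
  fit_lab <- lab$mapping$label[assign_clusters(m)$archetype_index]
  truth_lab <- sim$truth$labels[sim$truth$cluster_true]
  expect_gt(mean(fit_lab == truth_lab), 0.99)

  # AKI2 archetype shows more acute injury than AKI1 in the group means
  pm <- lab$profile_means
  expect_gt(pm$IRRAT[pm$label == "AKI2"], pm$IRRAT[pm$label == "AKI1"])

  # k != 6: indices are returned with a warning
  m3 <- fit_archetypes(sim$scores, k = 3, restarts = 2, seed = 2)
  expect_warning(lab3 <- label_archetypes(m3), "reference")
  expect_identical(lab3$mapping$label, c("1", "2", "3"))
})

test_that("the RSS scree spans the explored k range and collapses on planted structure", {
  set.seed(2)
  pts <- matrix(rnorm(6), 3, 2, dimnames = list(NULL, c("x", "y")))
  X <- pts[rep(1:3, each = 8), ]
  rownames(X) <- sprintf("s%d", 1:24)
  scree <- rss_scree(X, k_range = 2:5, restarts = 4, seed = 1,
                     do_standardize = FALSE)
  expect_identical(nrow(scree), 4L)
  expect_lt(scree$rss[scree$k == 3], 1e-8)
  expect_lt(scree$rss[scree$k == 4], 1e-8)

  # planted k = 6: the largest relative drop happens at or before k = 6
  sim <- simulate_scores(simulation_config(n_biopsies = 250, seed = 17))
  sc6 <- rss_scree(sim$scores, k_range = 2:7, restarts = 3, seed = 4)
  drops <- -diff(sc6$rss) / sc6$rss[-nrow(sc6)]
  expect_lte(sc6$k[which.max(drops) + 1], 6L)
})

test_that("tidy and glance expose the fitted model", {
  sim <- simulate_scores(simulation_config(n_biopsies = 60, seed = 19))
  m <- fit_archetypes(sim$scores, k = 3, restarts = 2, seed = 1)
  td <- tidy(m)
  expect_identical(nrow(td), 3L * 12L)
  expect_true(all(c("archetype", "feature", "value_std", "value") %in% names(td)))
  gl <- glance(m)
  expect_identical(gl$k, 3L)
  expect_identical(gl$n, 60L)
  expect_true(gl$rss >= 0)
})
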