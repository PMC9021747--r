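test_that("low-cortex filtering drops exactly the sub-threshold biopsies", {
  clin <- toy_clinical(20, seed = 2)
  clin$pct_cortex_estimate <- c(rep(5, 4), rep(50, 14), NA, NA)
  expect_message(fl <- filter_low_cortex(clin, 10), "lack a cortex estimate")
  expect_identical(fl$n_removed, 4L)
  expect_identical(nrow(fl$retained), 16L) # missing estimates retained

  all_high <- clin; all_high$pct_cortex_estimate <- rep(60, 20)
  expect_identical(filter_low_cortex(all_high, 10)$n_removed, 0L)
  expect_identical(filter_low_cortex(clin, 0)$n_removed, 0L)
})

test_that("the cohort-scale cortex filter reproduces the published arithmetic", {
  clin <- toy_clinical(1679, seed = 3)
  clin$pct_cortex_estimate <- c(runif(153, 0, 9.99), runif(1526, 10, 100))
  fl <- filter_low_cortex(clin, 10)
  expect_identical(fl$n_removed, 153L)
  expect_identical(nrow(fl$retained), 1526L)
})

test_that("clinical-AKI labeling applies only to histologically normal biopsies", {
  expect_identical(clinical_aki_label("no major abnormalities", 30), "clinical AKI")
  expect_identical(clinical_aki_label("no major abnormalities", 42), "clinical AKI")
  expect_identical(clinical_aki_label("no major abnormalities", 43), "normal")
  expect_identical(clinical_aki_label("no major abnormalities", 50), "normal")
  expect_identical(clinical_aki_label("ABMR", 30), "ABMR")
})

test_that("moving averages slide a stable-sorted window", {
  ma <- moving_average(1:5, 1:5, w = 2)
  expect_equal(ma$y_mean, c(1.5, 2.5, 3.5, 4.5))
  expect_equal(ma$x_mean, c(1.5, 2.5, 3.5, 4.5))

  # constant y -> constant series
  mc <- moving_average(runif(30), rep(7, 30), w = 5)
  expect_true(all(abs(mc$y_mean - 7) < 1e-12))

  # w = 1 returns the sorted data unchanged
  set.seed(5)
  x <- runif(20); y <- rnorm(20)
  m1 <- moving_average(x, y, w = 1)
  expect_equal(m1$y_mean, y[order(x)])

  # ties keep input order
  mt <- moving_average(c(1, 1, 1), c(10, 20, 30), w = 1)
  expect_equal(mt$y_mean, c(10, 20, 30))

  # random n = 50, w = 7 against a nested-loop oracle
  set.seed(11)
  x <- rnorm(50); y <- rnorm(50)
  got <- moving_average(x, y, w = 7)
  ord <- order(x, seq_along(x))
  xs <- x[ord]; ys <- y[ord]
  for (i in seq_len(44)) {
    expect_equal(got$x_mean[i], mean(xs[i:(i + 6)]), tolerance = 1e-12)
    expect_equal(got$y_mean[i], mean(ys[i:(i + 6)]), tolerance = 1e-12)
  }

  expect_error(moving_average(1:3, 1:3, w = 4), "exceeds")
})

test_that("standardized trends are centered and recover the early-AKI peak", {
  set.seed(7)
  A <- matrix(runif(300), 100, 3)
  A <- A / rowSums(A)
  ord <- runif(100)
  tr <- standardized_trend(A, ord, w = 10, labels = c("a", "b", "c"))
  expect_identical(unique(tr$archetype), c("a", "b", "c"))
  for (g in c("a", "b", "c")) {
    expect_lt(abs(mean(tr$y_mean[tr$archetype == g])), 0.2)
  }

  # full-window limit: single point at the overall (zero) mean
  tr_full <- standardized_trend(A, ord, w = 100)
  expect_identical(nrow(tr_full), 3L)
  expect_true(all(abs(tr_full$y_mean) < 1e-9))

  # AKI scores are generated early post-transplant, so their standardized
  # trend peaks in the earliest windows
  cfg <- simulation_config(n_biopsies = 600, seed = 37)
  sim <- simulate_scores(cfg)
  clin <- simulate_clinical(sim$truth, cfg)
  tr2 <- standardized_trend(sim$truth$A_true, clin$days_post_transplant,
                            w = 200, labels = sim$truth$labels)
  for (g in c("AKI1", "AKI2")) {
    s <- tr2$y_mean[tr2$archetype == g]
    expect_lte(which.max(s), ceiling(length(s) * 0.10))
  }
})

test_that("group summaries match hand-computed statistics", {
  clin <- toy_clinical(6, seed = 9)
  clin$days_post_transplant <- c(10L, 30L, 50L, 100L, 200L, 400L)
  clin$egfr <- c(20, 30, 40, 50, 60, 70)
  clin$donor_age <- c(55, 45, 60, 30, 40, 52)
  clin$deceased_donor <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  asg <- tibble::tibble(sample_id = clin$sample_id,
                        label = rep(c("g1", "g2"), each = 3))
  gs <- group_summary(asg, clin)
  g1 <- gs[gs$group == "g1", ]
  expect_identical(g1$n, 3L)
  expect_equal(g1$median_days, 30)
  expect_equal(g1$mean_egfr, 30)
  expect_equal(g1$pct_donor_over_50, 100 * 2 / 3)
  expect_equal(g1$pct_deceased_donor, 100 * 2 / 3)
  expect_equal(sum(gs$n), nrow(clin))

  # single-group degenerate input
  asg1 <- tibble::tibble(sample_id = clin$sample_id, label = "only")
  expect_identical(group_summary(asg1, clin)$n, 6L)

  # rejection filter restricts the denominator
  clin$rejection_group <- c("no-rejection", "TCMR", "no-rejection",
                            "EABMR", "no-rejection", "no-rejection")
  gs_nr <- group_summary(asg, clin, rejection_filter = "no-rejection-only")
  expect_identical(sum(gs_nr$n), 4L)
})

test_that("contingency tables conserve totals and normalize columns", {
  clin <- toy_clinical(8, seed = 13)
  clin$rejection_group <- c("A", "A", "B", "B", "A", "B", "A", "A")
  asg <- tibble::tibble(sample_id = clin$sample_id,
                        label = rep(c("g1", "g2"), 4))
  ct <- contingency(asg, clin, "rejection_group")
  expect_equal(ct$counts[["A", "g1"]], 3)
  expect_equal(ct$counts[["B", "g2"]], 2)
  expect_equal(ct$counts[["Sum", "Sum"]], 8)
  expect_true(all(abs(colSums(ct$column_pct) - 100) < 1e-9))
})

test_that("two-group tests behave at their boundaries and match enumeration", {
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 4)
  tt <- compare_groups(x, y, test = "welch_t")
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p_value, 1)

  wt <- compare_groups(rnorm(10), rnorm(10) + 10, test = "wilcoxon")
  expect_lt(wt$p_value, 0.01)

  # the published early-cohort failure contrast is significant by Fisher
  ft <- compare_groups(matrix(c(12, 3, 34, 36), 2), test = "fisher_exact")
  expect_lt(ft$p_value, 0.05)

  # zero-cell and random tables match full hypergeometric enumeration
  tabs <- list(matrix(c(0, 5, 7, 3), 2), matrix(c(3, 1, 2, 9), 2),
               matrix(c(10, 2, 4, 11), 2), matrix(c(1, 1, 1, 1), 2))
  set.seed(3)
  for (i in 1:6) tabs[[length(tabs) + 1]] <- matrix(rpois(4, 6), 2)
  for (tab in tabs) {
    got <- compare_groups(tab, test = "fisher_exact")$p_value
    expect_equal(got, enum_fisher(tab), tolerance = 1e-9)
  }

  expect_warning(p0 <- compare_groups(matrix(c(0, 0, 3, 4), 2, byrow = TRUE),
                                      test = "fisher_exact"), "Degenerate")
  expect_equal(p0$p_value, 1)
})
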