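test_that("one biopsy per patient is selected uniformly and reproducibly", {
  clin <- toy_clinical(8, seed = 1)
  clin$patient_id <- c("P1", "P2", "P2", "P3", "P3", "P3", "P3", "P3")
  s1 <- select_one_biopsy_per_patient(clin, seed = 4)
  expect_identical(nrow(s1), 3L)
  expect_identical(sort(unique(s1$patient_id)), c("P1", "P2", "P3"))
  expect_identical(s1, select_one_biopsy_per_patient(clin, seed = 4))

  # over many reseeds each of a patient's two biopsies is picked ~50%
  two <- clin[2:3, ]
  picks <- vapply(1:1000, function(s) {
    select_one_biopsy_per_patient(two, seed = s)$sample_id
  }, character(1))
  frac <- mean(picks == two$sample_id[1])
  expect_gt(frac, 0.45)
  expect_lt(frac, 0.55)
})

test_that("the product-limit curve equals hand computation on small fixtures", {
  # times (1, 2+, 3) with events at 1 and 3
  rec <- surv_records(c(1, 2, 3), c(TRUE, FALSE, TRUE))
  cv <- km_curve(rec)
  expect_equal(cv$surv[cv$time == 0], 1)
  expect_equal(cv$surv[cv$time == 1], 2 / 3)
  expect_equal(cv$surv[cv$time == 3], 0)

  # randomized <= 10-record fixtures vs the independent product-limit loop
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(3:10, 1)
    t <- sample(1:500, n)
    e <- runif(n) < 0.6
    cv <- km_curve(surv_records(t, e), horizon_days = 1095)
    hk <- hand_km(pmin(t, 1095), e)
    for (i in seq_len(nrow(hk))) {
      expect_equal(cv$surv[cv$time == hk$time[i]], hk$surv[i],
                   tolerance = 1e-12)
    }
  }

  # no events -> survival identically one
  cv1 <- km_curve(surv_records(c(10, 20, 30), rep(FALSE, 3)))
  expect_true(all(cv1$surv == 1))

  # no censoring -> the empirical survivor function
  t <- c(5, 10, 15, 20)
  cv2 <- km_curve(surv_records(t, rep(TRUE, 4)))
  for (i in seq_along(t)) {
    expect_equal(cv2$surv[cv2$time == t[i]], 1 - i / 4, tolerance = 1e-12)
  }

  expect_error(km_curve(toy_clinical(0)), "No records")
})

test_that("death with function censors and never counts as failure", {
  rec <- surv_records(c(100, 200, 300),
                      failed = c(FALSE, FALSE, TRUE),
                      died = c(TRUE, FALSE, FALSE))
  cv <- km_curve(rec)
  expect_equal(sum(cv$n_event), 1)
  # both earlier records are censorings, so the only event finds 1 at risk
  expect_equal(min(cv$surv), 0)
  expect_false(1 %in% cv$n_event[cv$time %in% c(100, 200)])
})

test_that("failure fractions use the stated evaluability rule", {
  # the published early-AKI1 arithmetic: 12 failures among 46 evaluable
  rec <- surv_records(c(rep(500, 12), rep(1200, 34)),
                      failed = c(rep(TRUE, 12), rep(FALSE, 34)))
  ff <- failure_fraction(rec)
  expect_identical(ff$n_failed, 12L)
  expect_identical(ff$n_evaluable, 46L)
  expect_equal(round(100 * ff$fraction), 26)

  # early censorings leave the denominator
  rec2 <- surv_records(c(100, 2000, 500), c(FALSE, FALSE, TRUE))
  ff2 <- failure_fraction(rec2)
  expect_identical(ff2$n_evaluable, 2L)
  expect_equal(ff2$fraction, 0.5)

  # boundary cases
  expect_equal(failure_fraction(
    surv_records(rep(1200, 5), rep(FALSE, 5)))$fraction, 0)
  expect_equal(failure_fraction(
    surv_records(rep(10, 5), rep(TRUE, 5)))$fraction, 1)
  expect_warning(ff0 <- failure_fraction(
    surv_records(rep(10, 3), rep(FALSE, 3))), "undefined")
  expect_true(is.na(ff0$fraction))
})

test_that("per-group curves reduce to km_curve and flag small groups", {
  clin <- toy_clinical(30, seed = 21)
  clin$followup_days <- as.integer(sample(100:1500, 30))
  clin$graft_failed <- runif(30) < 0.4
  asg <- tibble::tibble(sample_id = clin$sample_id, label = "solo")
  kb <- km_by_group(clin, asg)
  single <- km_curve(clin)
  expect_equal(kb$curves$surv, single$surv)

  # identical survival in two groups -> identical curves
  clin2 <- clin
  asg2 <- tibble::tibble(sample_id = clin$sample_id,
                         label = rep(c("g1", "g2"), 15))
  clin2$followup_days <- rep(as.integer(c(100, 400, 900)), 10)
  clin2$graft_failed <- rep(c(TRUE, FALSE, TRUE), 10)
  kb2 <- km_by_group(clin2, asg2)
  c1 <- kb2$curves[kb2$curves$group == "g1", ]
  c2 <- kb2$curves[kb2$curves$group == "g2", ]
  expect_equal(c1$surv, c2$surv)

  # small groups flagged unreliable
  asg3 <- tibble::tibble(sample_id = clin$sample_id,
                         label = c(rep("big", 27), rep("tiny", 3)))
  expect_warning(kb3 <- km_by_group(clin, asg3), "tiny")
  expect_true(kb3$groups$unreliable[kb3$groups$group == "tiny"])
})

test_that("permutation importance finds a planted signal and survives a noise duplicate", {
  set.seed(31)
  n <- 500
  feats <- tibble::tibble(sample_id = sprintf("S%d", 1:n),
                          signal = rnorm(n),
                          noise1 = rnorm(n), noise2 = rnorm(n))
  out <- tibble::tibble(sample_id = feats$sample_id,
                        label = feats$signal > 0)
  imp <- variable_importance(feats, out, mode = "classification",
                             n_trees = 500, seed = 3)
  expect_identical(imp$feature[1], "signal")
  expect_identical(sort(imp$feature), sort(c("signal", "noise1", "noise2")))
  expect_identical(imp, variable_importance(feats, out, mode = "classification",
                                            n_trees = 500, seed = 3))

  feats$noise3 <- feats$noise1 + rnorm(n, sd = 0.01)
  imp2 <- variable_importance(feats, out, mode = "classification",
                              n_trees = 500, seed = 3)
  expect_identical(imp2$feature[1], "signal")

  expect_error(variable_importance(
    feats, dplyr::mutate(out, label = TRUE), mode = "classification",
    n_trees = 50), "constant")
})

test_that("survival-mode importance ranks a hazard-driving feature first", {
  set.seed(33)
  n <- 400
  risk <- rnorm(n)
  t <- rexp(n, rate = exp(risk)) * 365
  feats <- tibble::tibble(sample_id = sprintf("S%d", 1:n),
                          risk = risk, junk = rnorm(n))
  out <- tibble::tibble(sample_id = feats$sample_id,
                        time = pmin(t, 1095), event = t <= 1095)
  imp <- variable_importance(feats, out, mode = "survival",
                             n_trees = 500, seed = 5)
  expect_identical(imp$feature[1], "risk")
})
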