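# shared fixture builders (all data generated in code at test time)

toy_expr <- function(values = NULL, controls = "N1") {
  if (is.null(values)) {
    values <- matrix(c(4, 10, 8, 20, 2, 5), nrow = 2,
                     dimnames = list(c("p1", "p2"), c("N1", "S1", "S2")))
  }
  expression_matrix(values, control_ids = controls)
}

random_expr <- function(n_probes = 10, n_samples = 5, n_controls = 2,
                        seed = 1) {
  set.seed(seed)
  m <- matrix(exp(rnorm(n_probes * n_samples, log(100), 0.5)),
              n_probes, n_samples,
              dimnames = list(sprintf("p%02d", seq_len(n_probes)),
                              c(sprintf("N%d", seq_len(n_controls)),
                                sprintf("S%d", seq_len(n_samples - n_controls)))))
  expression_matrix(m, control_ids = sprintf("N%d", seq_len(n_controls)))
}

toy_clinical <- function(n = 5, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    sample_id = sprintf("B%03d", seq_len(n)),
    patient_id = sprintf("P%03d", seq_len(n)),
    days_post_transplant = as.integer(sample(1:2000, n)),
    egfr = runif(n, 10, 80),
    proteinuria_positive = sample(c(TRUE, FALSE), n, replace = TRUE),
    donor_age = runif(n, 20, 70),
    deceased_donor = sample(c(TRUE, FALSE), n, replace = TRUE),
    dgf = sample(c(TRUE, FALSE), n, replace = TRUE),
    ci_score = as.integer(sample(0:3, n, replace = TRUE)),
    ct_score = as.integer(sample(0:3, n, replace = TRUE)),
    i_score = as.integer(sample(0:3, n, replace = TRUE)),
    ti_score = as.integer(sample(0:3, n, replace = TRUE)),
    histology_dx = sample(c("no major abnormalities", "ABMR", "TCMR"),
                          n, replace = TRUE),
    rejection_group = sample(c("no-rejection", "EABMR", "TCMR"),
                             n, replace = TRUE),
    pct_cortex_estimate = runif(n, 10, 100),
    followup_days = as.integer(sample(100:2000, n)),
    graft_failed = FALSE,
    died_with_function = FALSE
  )
}

# independent product-limit computation (naive loop over event times)
hand_km <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ev_times <- sort(unique(time[event]))
  s <- 1
  out <- data.frame(time = numeric(0), surv = numeric(0))
  for (t in ev_times) {
    at_risk <- sum(time >= t)
    d <- sum(time == t & event)
    s <- s * (1 - d / at_risk)
    out <- rbind(out, data.frame(time = t, surv = s))
  }
  out
}

# survival record tibble shaped like the clinical columns km_curve needs
surv_records <- function(followup, failed, died = rep(FALSE, length(followup))) {
  tibble::tibble(
    sample_id = sprintf("S%03d", seq_along(followup)),
    followup_days = as.integer(followup),
    graft_failed = failed,
    died_with_function = died
  )
}

# Fisher exact two-sided p by full hypergeometric enumeration
enum_fisher <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - n2); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n2, k)
  p0 <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}
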