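# ---- three-year death-censored graft survival ------------------------------

#' Select one biopsy per patient
#'
#' Survival analyses use one uniformly random biopsy per patient so that
#' patients with many biopsies do not dominate the curves; the selection
#' is reproducible from the seed.
#'
#' @param clinical Clinical tibble with `patient_id`.
#' @param seed Integer seed.
#' @return The subset tibble, exactly one row per patient.
#' @export
select_one_biopsy_per_patient <- function(clinical, seed = 1L) {
  clinical <- as_tibble(clinical)
  set.seed(seed)
  clinical %>%
    dplyr::slice(sample(dplyr::n())) %>% # shuffle, then keep first per patient
    dplyr::distinct(.data$patient_id, .keep_all = TRUE) %>%
    dplyr::arrange(match(.data$sample_id, clinical$sample_id))
}

# death-censored survival records: deaths with function become censorings,
# follow-up truncated at the horizon (alive-at-horizon -> censored there)
.death_censored <- function(clinical, horizon_days) {
  time <- pmin(clinical$followup_days, horizon_days)
  event <- !is.na(clinical$graft_failed) & clinical$graft_failed &
    clinical$followup_days <= horizon_days
  tibble(sample_id = clinical$sample_id, time = time, event = event)
}

#' Death-censored Kaplan-Meier curve
#'
#' Product-limit estimate of graft survival over a horizon (default 3
#' years = 1095 days). Deaths with a functioning graft are treated as
#' censoring events; records alive at the horizon are censored there.
#'
#' @param clinical Clinical tibble (needs `followup_days`, `graft_failed`,
#'   `died_with_function`).
#' @param horizon_days Truncation horizon (default 1095).
#' @param conf_int Include Greenwood log-transformed confidence bands.
#' @return A tibble of class `km_curve` with `time`, `n_risk`, `n_event`,
#'   `surv` (and `lower`/`upper` when requested), starting at
#'   `S(0) = 1`.
#' @export
km_curve <- function(clinical, horizon_days = 1095, conf_int = FALSE) {
  clinical <- as_tibble(clinical)
  if (nrow(clinical) == 0) abort("No records to fit a survival curve on.")
  rec <- .death_censored(clinical, horizon_days)
  fit <- survival::survfit(
    survival::Surv(rec$time, rec$event) ~ 1,
    conf.type = if (conf_int) "log" else "none")
  out <- tibble(
    time = c(0, fit$time),
    n_risk = c(fit$n, fit$n.risk),
    n_event = c(0, fit$n.event),
    surv = c(1, fit$surv)
  )
  if (conf_int) {
    out$lower <- c(1, fit$lower)
    out$upper <- c(1, fit$upper)
  }
  class(out) <- c("km_curve", class(out))
  out
}

#' Crude death-censored failure fraction over a horizon
#'
#' Numerator: graft failures observed within the horizon. Denominator:
#' those failures plus records with follow-up reaching the horizon.
#' Records censored (administratively or by death with function) before
#' the horizon are not evaluable and are excluded from the denominator.
#'
#' @inheritParams km_curve
#' @return Tibble with `n_failed`, `n_evaluable`, `fraction`.
#' @export
failure_fraction <- function(clinical, horizon_days = 1095) {
  clinical <- as_tibble(clinical)
  failed <- !is.na(clinical$graft_failed) & clinical$graft_failed &
    clinical$followup_days <= horizon_days
  evaluable <- failed | clinical$followup_days >= horizon_days
  if (sum(evaluable) == 0) {
    warn("No evaluable records; failure fraction undefined.")
    return(tibble(n_failed = 0L, n_evaluable = 0L, fraction = NA_real_))
  }
  tibble(n_failed = sum(failed), n_evaluable = sum(evaluable),
         fraction = sum(failed) / sum(evaluable))
}

#' Kaplan-Meier curves per injury group
#'
#' Per-group death-censored product-limit curves with group sizes.
#' Optionally restricts to biopsies with no molecular rejection and/or to
#' a time stratum (biopsies at most, or later than, 42 days
#' post-transplant). Groups smaller than `size_floor` are reported but
#' flagged unreliable.
#'
#' @param clinical Clinical tibble.
#' @param assignments Tibble with `sample_id` and `label` (or
#'   `archetype_index`).
#' @param horizon_days Truncation horizon (default 1095).
#' @param rejection_filter `"all"` or `"no-rejection-only"`.
#' @param time_stratum `"all"`, `"early"` (<= 42 days post-transplant) or
#'   `"late"` (> 42 days).
#' @param size_floor Minimum reliable group size (default 10).
#' @param conf_int Include Greenwood bands.
#' @return A list with `curves` (long tibble: `group`, `time`, `n_risk`,
#'   `n_event`, `surv`, ...) and `groups` (tibble: `group`, `n`,
#'   `unreliable`).
#' @export
km_by_group <- function(clinical, assignments, horizon_days = 1095,
                        rejection_filter = c("all", "no-rejection-only"),
                        time_stratum = c("all", "early", "late"),
                        size_floor = 10, conf_int = FALSE) {
  rejection_filter <- match.arg(rejection_filter)
  time_stratum <- match.arg(time_stratum)
  grp <- if ("label" %in% names(assignments)) assignments$label else
    as.character(assignments$archetype_index)
  dat <- dplyr::inner_join(
    tibble(sample_id = assignments$sample_id, group = grp),
    as_tibble(clinical), by = "sample_id")
  if (rejection_filter == "no-rejection-only") {
    dat <- dat[!is.na(dat$rejection_group) &
                 dat$rejection_group == "no-rejection", , drop = FALSE]
  }
  if (time_stratum == "early") dat <- dat[dat$days_post_transplant <= 42, ]
  if (time_stratum == "late") dat <- dat[dat$days_post_transplant > 42, ]
  groups <- dat %>%
    dplyr::count(.data$group, name = "n") %>%
    dplyr::mutate(unreliable = .data$n < size_floor)
  if (any(groups$unreliable)) {
    warn(paste0("Group(s) below the size floor (reported but unreliable): ",
                paste(groups$group[groups$unreliable], collapse = ", ")))
  }
  curves <- purrr::map_dfr(groups$group, function(g) {
    cv <- km_curve(dat[dat$group == g, , drop = FALSE],
                   horizon_days = horizon_days, conf_int = conf_int)
    dplyr::bind_cols(tibble(group = g), as_tibble(cv))
  })
  list(curves = curves, groups = groups)
}

#' Tree-ensemble permutation variable importance
#'
#' Ranks features by permutation importance from a randomized tree
#' ensemble (extremely-randomized splits, one random split point per
#' candidate variable), in classification mode for a binary outcome or in
#' survival mode for a (time, event) outcome. This is the machinery used
#' to ask whether injury or rejection scores better predict low eGFR and
#' graft loss.
#'
#' @param features Tibble with `sample_id` plus numeric feature columns.
#' @param outcome For `mode = "classification"`: tibble with `sample_id`
#'   and logical `label`. For `mode = "survival"`: tibble with
#'   `sample_id`, `time`, `event`.
#' @param mode `"classification"` or `"survival"`.
#' @param n_trees Number of trees (canonical 10000; scale down for quick
#'   runs).
#' @param nsplit Random split points per candidate variable (default 1).
#' @param seed Integer seed; the report is deterministic given it.
#' @return A tibble of class `importance_report` with `feature`,
#'   `importance`, `rank`; attributes `mode`, `n_trees`, `seed`.
#' @export
variable_importance <- function(features, outcome,
                                mode = c("classification", "survival"),
                                n_trees = 10000, nsplit = 1, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot("sample_id" %in% names(features))
  dat <- dplyr::inner_join(as_tibble(features), as_tibble(outcome),
                           by = "sample_id")
  feat_cols <- setdiff(names(features), "sample_id")
  x <- as.data.frame(dat[, feat_cols, drop = FALSE])
  if (mode == "classification") {
    if (length(unique(dat$label)) < 2) abort("Outcome is constant.")
    x$.y <- factor(dat$label, levels = c(FALSE, TRUE))
    fit <- ranger::ranger(.y ~ ., data = x, num.trees = n_trees,
                          probability = TRUE, importance = "permutation",
                          splitrule = "extratrees",
                          num.random.splits = nsplit,
                          num.threads = 1, seed = seed)
  } else {
    if (all(!dat$event) || all(dat$event)) {
      if (all(!dat$event)) abort("Outcome is constant (no events).")
    }
    x$.time <- dat$time
    x$.event <- dat$event
    fit <- ranger::ranger(survival::Surv(.time, .event) ~ ., data = x,
                          num.trees = n_trees, importance = "permutation",
                          splitrule = "extratrees",
                          num.random.splits = nsplit,
                          num.threads = 1, seed = seed)
  }
  imp <- fit$variable.importance[feat_cols]
  out <- tibble(feature = names(imp), importance = unname(imp)) %>%
    dplyr::arrange(dplyr::desc(.data$importance)) %>%
    dplyr::mutate(rank = dplyr::row_number())
  attr(out, "mode") <- mode
  attr(out, "n_trees") <- n_trees
  attr(out, "seed") <- seed
  class(out) <- c("importance_report", class(out))
  out
}
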