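# ---- cohort-level descriptive machinery ------------------------------------

#' Remove biopsies with low estimated cortex content
#'
#' Biopsies estimated to have less than `threshold_pct` percent cortex
#' are dropped before any analysis (high medulla content alters molecular
#' readouts). Rows with a missing estimate are retained and logged.
#'
#' @param clinical Clinical tibble.
#' @param threshold_pct Percent-cortex threshold (default 10).
#' @return A list with `retained` (tibble) and `n_removed`.
#' @export
filter_low_cortex <- function(clinical, threshold_pct = 10) {
  clinical <- as_tibble(clinical)
  est <- clinical$pct_cortex_estimate
  n_missing <- sum(is.na(est))
  if (n_missing > 0) {
    message(sprintf("%d biopsies lack a cortex estimate and are retained.",
                    n_missing))
  }
  drop <- !is.na(est) & est < threshold_pct
  list(retained = clinical[!drop, , drop = FALSE], n_removed = sum(drop))
}

#' Clinical-AKI labeling of histologically normal biopsies
#'
#' Histology defines no "AKI" category, so biopsies with no major
#' abnormalities are relabeled by timing: "clinical AKI" if taken at most
#' 6 weeks (42 days, boundary included) post-transplant, "normal" if
#' later. All other diagnoses pass through unchanged.
#'
#' @param histology_dx Character vector of histology diagnoses.
#' @param days_post_transplant Integer vector.
#' @param normal_dx The diagnosis string the rule applies to.
#' @return Character vector: "clinical AKI", "normal", or the input
#'   diagnosis.
#' @export
clinical_aki_label <- function(histology_dx, days_post_transplant,
                               normal_dx = "no major abnormalities") {
  dplyr::case_when(
    histology_dx == normal_dx & days_post_transplant <= 42 ~ "clinical AKI",
    histology_dx == normal_dx ~ "normal",
    TRUE ~ histology_dx
  )
}

#' Sliding-window moving average of two variables
#'
#' Sorts the pairs by ascending `x` (stable: ties keep input order),
#' then slides a window of `w` consecutive biopsies by one position,
#' recording the mean of both variables per window.
#'
#' @param x Ordering variable (e.g. days post-transplant).
#' @param y Response variable.
#' @param w Window size (default 400).
#' @param x_name Name recorded for the ordering variable.
#' @return A tibble of class `moving_average` with `x_mean`, `y_mean`
#'   (length `n - w + 1`) and attributes `w`, `x_name`.
#' @export
moving_average <- function(x, y, w = 400, x_name = "x") {
  n <- length(x)
  if (length(y) != n) abort("x and y must have equal length.")
  if (w < 1) abort("w must be >= 1.")
  if (w > n) abort("Window w exceeds the number of observations.")
  ord <- order(x, seq_len(n)) # explicit tiebreak: ties keep input order
  xs <- as.numeric(x[ord])
  ys <- as.numeric(y[ord])
  cx <- cumsum(c(0, xs))
  cy <- cumsum(c(0, ys))
  idx <- seq_len(n - w + 1)
  out <- tibble(
    x_mean = (cx[idx + w] - cx[idx]) / w,
    y_mean = (cy[idx + w] - cy[idx]) / w
  )
  attr(out, "w") <- w
  attr(out, "x_name") <- x_name
  class(out) <- c("moving_average", class(out))
  out
}

#' Standardized moving-average trends of archetype scores
#'
#' Each archetype-score column is z-scored across the cohort (mean 0,
#' unit SD) before windowing, so the series are in standard-deviation
#' units and comparable across archetypes despite large differences in
#' mean scores.
#'
#' @param A n x k archetype-score matrix (or `archetype_model`).
#' @param order_var Numeric ordering variable per sample (e.g. days
#'   post-transplant), parallel to the rows of `A`.
#' @param w Window size (default 400).
#' @param labels Optional archetype labels (length k).
#' @return Tibble with `archetype`, `x_mean`, `y_mean` (one series per
#'   archetype, stacked long).
#' @export
standardized_trend <- function(A, order_var, w = 400, labels = NULL) {
  if (inherits(A, "archetype_model")) A <- A$A
  if (length(order_var) != nrow(A)) {
    abort("order_var must have one value per sample.")
  }
  nm <- labels %||% colnames(A) %||% paste0("archetype_", seq_len(ncol(A)))
  purrr::map_dfr(seq_len(ncol(A)), function(j) {
    z <- as.numeric(scale(A[, j]))
    ma <- moving_average(order_var, z, w = w)
    tibble(archetype = nm[j], x_mean = ma$x_mean, y_mean = ma$y_mean)
  })
}

#' Per-group clinical summary
#'
#' The group-summary statistics of the cohort tables: N, median and mean
#' days post-transplant, mean eGFR, mean and median donor age, percent of
#' donors over 50, percent deceased donors — per injury archetype group,
#' optionally restricted to biopsies with no molecular rejection.
#' Missing covariates are excluded per statistic with reported
#' denominators.
#'
#' @param assignments Tibble from [assign_clusters()] (needs `sample_id`
#'   and `label` or `archetype_index`).
#' @param clinical Clinical tibble.
#' @param rejection_filter `"all"` or `"no-rejection-only"`.
#' @return Tibble, one row per group.
#' @export
group_summary <- function(assignments, clinical,
                          rejection_filter = c("all", "no-rejection-only")) {
  rejection_filter <- match.arg(rejection_filter)
  grp <- if ("label" %in% names(assignments)) assignments$label else
    as.character(assignments$archetype_index)
  dat <- dplyr::inner_join(
    tibble(sample_id = assignments$sample_id, group = grp),
    as_tibble(clinical), by = "sample_id")
  if (rejection_filter == "no-rejection-only") {
    dat <- dat[!is.na(dat$rejection_group) &
                 dat$rejection_group == "no-rejection", , drop = FALSE]
  }
  dat %>%
    dplyr::group_by(.data$group) %>%
    dplyr::summarise(
      n = dplyr::n(),
      median_days = median(.data$days_post_transplant, na.rm = TRUE),
      mean_days = mean(.data$days_post_transplant, na.rm = TRUE),
      mean_egfr = mean(.data$egfr, na.rm = TRUE),
      n_egfr = sum(!is.na(.data$egfr)),
      mean_donor_age = mean(.data$donor_age, na.rm = TRUE),
      median_donor_age = median(.data$donor_age, na.rm = TRUE),
      n_donor_age = sum(!is.na(.data$donor_age)),
      pct_donor_over_50 = 100 * mean(.data$donor_age > 50, na.rm = TRUE),
      pct_deceased_donor = 100 * mean(.data$deceased_donor, na.rm = TRUE),
      n_deceased_donor = sum(!is.na(.data$deceased_donor)),
      .groups = "drop"
    )
}

#' Contingency table of a categorical variable across groups
#'
#' Counts per (category, group) with column percentages and margins,
#' in tidy long form.
#'
#' @param assignments Tibble with `sample_id` and `label` (or
#'   `archetype_index`).
#' @param clinical Clinical tibble.
#' @param category_var Name of the categorical clinical column (e.g.
#'   `"rejection_group"`).
#' @return A list with `counts` (category x group matrix with margins)
#'   and `column_pct` (category x group matrix of column percentages).
#' @export
contingency <- function(assignments, clinical, category_var = "rejection_group") {
  grp <- if ("label" %in% names(assignments)) assignments$label else
    as.character(assignments$archetype_index)
  dat <- dplyr::inner_join(
    tibble(sample_id = assignments$sample_id, group = grp),
    as_tibble(clinical), by = "sample_id")
  if (!category_var %in% names(dat)) {
    abort(sprintf("Column '%s' not found in clinical table.", category_var))
  }
  tab <- table(category = dat[[category_var]], group = dat$group)
  pct <- sweep(tab, 2, pmax(colSums(tab), 1), "/") * 100
  counts <- stats::addmargins(tab)
  list(counts = unclass(counts), column_pct = unclass(pct))
}

#' Two-group comparison tests
#'
#' Welch's t-test (unequal variances), the two-sided Wilcoxon rank-sum
#' test, or Fisher's exact test (hypergeometric tail-sum definition) for
#' a 2 x 2 table. Degenerate 2 x 2 tables with an empty margin return
#' p = 1 with a warning.
#'
#' @param g1,g2 Numeric vectors (t / wilcoxon), or for
#'   `test = "fisher_exact"` pass the 2 x 2 integer matrix as `g1`.
#' @param test One of `"welch_t"`, `"wilcoxon"`, `"fisher_exact"`.
#' @return Tibble with `test`, `statistic`, `p_value`.
#' @export
compare_groups <- function(g1, g2 = NULL,
                           test = c("welch_t", "wilcoxon", "fisher_exact")) {
  test <- match.arg(test)
  if (test == "fisher_exact") {
    tab <- as.matrix(g1)
    if (!all(dim(tab) == c(2, 2)) || any(tab < 0) ||
        any(tab != round(tab))) {
      abort("fisher_exact needs a 2 x 2 matrix of non-negative integers.")
    }
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      warn("Degenerate 2 x 2 table (empty margin); p = 1.")
      return(tibble(test = test, statistic = NA_real_, p_value = 1))
    }
    ft <- stats::fisher.test(tab)
    return(tibble(test = test, statistic = unname(ft$estimate),
                  p_value = ft$p.value))
  }
  if (length(g1) < 2 || length(g2) < 2) {
    abort("Need >= 2 observations per group.")
  }
  if (test == "welch_t") {
    if (sd(g1) == 0 && sd(g2) == 0 && mean(g1) == mean(g2)) {
      # identical constant groups: no evidence of difference
      return(tibble(test = test, statistic = 0, p_value = 1))
    }
    tt <- stats::t.test(g1, g2, var.equal = FALSE)
    tibble(test = test, statistic = unname(tt$statistic), p_value = tt$p.value)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(g1, g2, exact = FALSE))
    tibble(test = test, statistic = unname(wt$statistic), p_value = wt$p.value)
  }
}
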