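# ---- out-of-fold median-of-methods classifier probabilities ----------------

#' Derive the four binary classifier endpoints from the clinical table
#'
#' ciProb: Banff ci-lesion score > 1 (i.e. 2 or 3); ctProb: ct > 1;
#' lowGFRProb: eGFR <= 30 (boundary included); ProtProb: proteinuria
#' positive. Missing inputs give missing labels, which are excluded from
#' training downstream.
#'
#' @param clinical A validated clinical tibble.
#' @return Tibble with `sample_id` and logical columns `ciProb`, `ctProb`,
#'   `lowGFRProb`, `ProtProb`.
#' @export
binary_targets <- function(clinical) {
  clinical <- validate_clinical(clinical)
  tibble(
    sample_id = clinical$sample_id,
    ciProb = clinical$ci_score > 1,
    ctProb = clinical$ct_score > 1,
    lowGFRProb = clinical$egfr <= 30,
    ProtProb = clinical$proteinuria_positive
  )
}

#' Cross-validation fold assignment
#'
#' Partitions the labeled samples into `k` folds of sizes differing by at
#' most one, stratified by label when both classes have at least `k`
#' members, deterministic given the seed.
#'
#' @param sample_ids Character vector.
#' @param labels Logical vector parallel to `sample_ids` (NA = unlabeled;
#'   unlabeled samples are not assigned a fold).
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return Tibble with `sample_id` and `fold` (1..k).
#' @export
make_folds <- function(sample_ids, labels, k = 10, seed = 1L) {
  if (k < 2) abort("k must be >= 2.")
  keep <- !is.na(labels)
  ids <- sample_ids[keep]
  lab <- labels[keep]
  if (length(ids) < k) abort("Need at least k labeled samples.")
  set.seed(seed)
  assign_in <- function(idx) {
    # shuffle then deal round-robin: sizes differ by <= 1
    idx <- sample(idx)
    setNames(rep_len(seq_len(k), length(idx)), idx)
  }
  stratify <- sum(lab) >= k && sum(!lab) >= k
  if (stratify) {
    f_pos <- assign_in(ids[lab])
    f_neg <- assign_in(ids[!lab])
    folds <- c(f_pos, f_neg)
  } else {
    folds <- assign_in(ids)
  }
  tibble(sample_id = ids, fold = unname(folds[ids]))
}

#' Default probabilistic learner roster
#'
#' Three diverse binary learners, each a function
#' `f(x_train, y_train, x_test)` returning class-1 probabilities:
#' logistic regression (`glm`), a probability random forest (`ranger`),
#' and naive Bayes (`e1071`). The roster is a plain named list, so the
#' canonical 12-method configuration of the original analysis can be
#' supplied instead.
#'
#' @param num_trees Trees for the random-forest member (default 200).
#' @return Named list of learner functions.
#' @export
default_learners <- function(num_trees = 200) {
  list(
    logistic = function(x_train, y_train, x_test) {
      d <- as.data.frame(x_train)
      d$.y <- as.numeric(y_train)
      fit <- suppressWarnings(stats::glm(.y ~ ., data = d, family = stats::binomial()))
      as.numeric(suppressWarnings(
        stats::predict(fit, newdata = as.data.frame(x_test), type = "response")))
    },
    random_forest = function(x_train, y_train, x_test) {
      d <- as.data.frame(x_train)
      d$.y <- factor(y_train, levels = c(FALSE, TRUE))
      fit <- ranger::ranger(.y ~ ., data = d, probability = TRUE,
                            num.trees = num_trees, num.threads = 1,
                            seed = sample.int(.Machine$integer.max, 1))
      stats::predict(fit, data = as.data.frame(x_test),
                     num.threads = 1)$predictions[, "TRUE"]
    },
    naive_bayes = function(x_train, y_train, x_test) {
      fit <- e1071::naiveBayes(as.data.frame(x_train),
                               factor(y_train, levels = c(FALSE, TRUE)))
      stats::predict(fit, as.data.frame(x_test), type = "raw")[, "TRUE"]
    }
  )
}

#' Strictly out-of-fold ensemble probabilities
#'
#' For each fold, every learner trains on the other folds only and
#' predicts the held-out fold, so no model ever sees the samples it
#' scores. The final per-sample score is the median across learners;
#' per-learner columns are retained for audit. A learner failing on a
#' fold is recorded, warned about, and excluded from the affected
#' samples' medians.
#'
#' @param features Tibble with `sample_id` plus numeric feature columns
#'   (typically gene-set scores).
#' @param labels Tibble with `sample_id` and logical `label`.
#' @param folds Fold assignment from [make_folds()]; computed from
#'   `labels` when `NULL`.
#' @param learners Named list of learner functions
#'   (default [default_learners()]).
#' @param k Folds when `folds` is `NULL` (default 10).
#' @param seed Integer seed (fold assignment and learner RNG).
#' @return Tibble with `sample_id`, one probability column per learner,
#'   and `score` (the median across learners), all in `[0, 1]`.
#' @export
oof_ensemble <- function(features, labels, folds = NULL,
                         learners = default_learners(), k = 10, seed = 1L) {
  if (length(learners) < 1 || is.null(names(learners))) {
    abort("`learners` must be a non-empty named list of functions.")
  }
  stopifnot("sample_id" %in% names(features), "sample_id" %in% names(labels))
  lab <- labels$label[match(features$sample_id, labels$sample_id)]
  if (is.null(folds)) {
    folds <- make_folds(features$sample_id, lab, k = k, seed = seed)
  }
  set.seed(seed)
  x <- as.matrix(features[, setdiff(names(features), "sample_id"), drop = FALSE])
  rownames(x) <- features$sample_id
  fold_of <- folds$fold[match(features$sample_id, folds$sample_id)]
  pred <- matrix(NA_real_, nrow(x), length(learners),
                 dimnames = list(features$sample_id, names(learners)))
  for (f in sort(unique(stats::na.omit(fold_of)))) {
    test_idx <- which(!is.na(fold_of) & fold_of == f)
    train_idx <- which(!is.na(fold_of) & fold_of != f & !is.na(lab))
    for (m in names(learners)) {
      p <- tryCatch(
        learners[[m]](x[train_idx, , drop = FALSE], lab[train_idx],
                      x[test_idx, , drop = FALSE]),
        error = function(e) {
          warn(sprintf("Learner '%s' failed on fold %d: %s", m, f,
                       conditionMessage(e)))
          rep(NA_real_, length(test_idx))
        })
      pred[test_idx, m] <- pmin(pmax(as.numeric(p), 0), 1)
    }
  }
  out <- dplyr::bind_cols(
    tibble(sample_id = features$sample_id),
    as_tibble(pred))
  out$score <- unname(apply(pred, 1, median, na.rm = TRUE))
  out[!is.na(fold_of), , drop = FALSE]
}

#' Assemble the canonical 12-column injury score table
#'
#' Joins the eight PBT scores with the four classifier probabilities into
#' the canonical column ordering ([injury_features()]). Biopsies lacking
#' any classifier score are dropped with a logged count; disjoint sample
#' sets are an error.
#'
#' @param pbt_scores Tibble `sample_id` + PBT columns (see [score_pbts()]).
#' @param classifier_scores Tibble `sample_id` + `ciProb`, `ctProb`,
#'   `lowGFRProb`, `ProtProb`.
#' @return Score tibble with `sample_id` and the 12 canonical columns,
#'   no missing cells.
#' @export
assemble_score_table <- function(pbt_scores, classifier_scores) {
  shared <- intersect(pbt_scores$sample_id, classifier_scores$sample_id)
  if (length(shared) == 0) abort("PBT and classifier tables share no samples.")
  out <- dplyr::inner_join(pbt_scores, classifier_scores, by = "sample_id")
  missing_cols <- setdiff(.injury_features, names(out))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing feature column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- out[, c("sample_id", .injury_features)]
  complete <- stats::complete.cases(out)
  if (any(!complete)) {
    message(sprintf("Dropping %d biopsies with incomplete scores.", sum(!complete)))
  }
  validate_scores(out[complete, , drop = FALSE])
}
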