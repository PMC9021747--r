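# Column schema for the per-biopsy clinical table. Missing values are
# allowed everywhere except sample_id / patient_id / days_post_transplant;
# downstream operations declare their own missing-data policy.
.clinical_schema <- list(
  sample_id = "character", patient_id = "character",
  days_post_transplant = "integer", egfr = "double",
  proteinuria_positive = "logical", donor_age = "double",
  deceased_donor = "logical", dgf = "logical",
  ci_score = "integer", ct_score = "integer",
  i_score = "integer", ti_score = "integer",
  histology_dx = "character", rejection_group = "character",
  pct_cortex_estimate = "double", followup_days = "integer",
  graft_failed = "logical", died_with_function = "logical"
)

#' Validate a per-biopsy clinical table
#'
#' Checks the column set, types and record-level invariants of the
#' clinical table: unique `sample_id`; `days_post_transplant` and
#' `followup_days` non-negative; Banff lesion scores (`ci_score`,
#' `ct_score`, `i_score`, `ti_score`) integers 0-3 or missing;
#' `pct_cortex_estimate` in 0-100 or missing; `graft_failed` and
#' `died_with_function` never both true. Failures name the offending row.
#'
#' @param clinical A data frame with the documented columns.
#' @return The validated table as a tibble (invisibly typed).
#' @export
validate_clinical <- function(clinical) {
  clinical <- as_tibble(clinical)
  missing_cols <- setdiff(names(.clinical_schema), names(clinical))
  if (length(missing_cols) > 0) {
    abort(paste0("Clinical table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  need <- function(col, test, what) {
    bad <- which(!is.na(clinical[[col]]) & !test(clinical[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("Invalid %s in clinical row %d (sample_id '%s'): %s",
                    col, bad[1], clinical$sample_id[bad[1]], what))
    }
  }
  if (anyDuplicated(clinical$sample_id)) {
    dup <- clinical$sample_id[duplicated(clinical$sample_id)][1]
    abort(sprintf("Duplicate sample_id '%s' in clinical table.", dup))
  }
  for (col in c("sample_id", "patient_id", "days_post_transplant")) {
    if (anyNA(clinical[[col]])) {
      abort(sprintf("Missing %s in clinical row %d.",
                    col, which(is.na(clinical[[col]]))[1]))
    }
  }
  need("days_post_transplant", function(v) v >= 0, "must be >= 0")
  need("followup_days", function(v) v >= 0, "must be >= 0")
  need("egfr", function(v) v >= 0, "must be >= 0")
  need("pct_cortex_estimate", function(v) v >= 0 & v <= 100, "must be in [0, 100]")
  for (col in c("ci_score", "ct_score", "i_score", "ti_score")) {
    need(col, function(v) v %in% 0:3, "must be an integer 0-3")
  }
  both <- which(!is.na(clinical$graft_failed) & !is.na(clinical$died_with_function) &
                  clinical$graft_failed & clinical$died_with_function)
  if (length(both) > 0) {
    abort(sprintf(
      "Row %d (sample_id '%s'): graft_failed and died_with_function cannot both be TRUE.",
      both[1], clinical$sample_id[both[1]]))
  }
  clinical
}

#' Read and write the per-biopsy clinical table (CSV)
#'
#' Comma-separated, UTF-8, "." decimal, header mandatory; missing values
#' are empty fields. Reading types and validates every record via
#' [validate_clinical()].
#'
#' @param path File path.
#' @return `read_clinical()` returns a validated tibble;
#'   `write_clinical()` returns `path` invisibly.
#' @export
read_clinical <- function(path) {
  types <- readr::cols(
    sample_id = readr::col_character(), patient_id = readr::col_character(),
    days_post_transplant = readr::col_integer(), egfr = readr::col_double(),
    proteinuria_positive = readr::col_logical(), donor_age = readr::col_double(),
    deceased_donor = readr::col_logical(), dgf = readr::col_logical(),
    ci_score = readr::col_integer(), ct_score = readr::col_integer(),
    i_score = readr::col_integer(), ti_score = readr::col_integer(),
    histology_dx = readr::col_character(), rejection_group = readr::col_character(),
    pct_cortex_estimate = readr::col_double(), followup_days = readr::col_integer(),
    graft_failed = readr::col_logical(), died_with_function = readr::col_logical()
  )
  tbl <- readr::read_csv(path, col_types = types, progress = FALSE)
  prob <- readr::problems(tbl)
  if (nrow(prob) > 0) {
    abort(sprintf("Unparseable value at clinical file row %d, column %d (expected %s).",
                  prob$row[1], prob$col[1], prob$expected[1]))
  }
  validate_clinical(tbl)
}

#' @rdname read_clinical
#' @param clinical A clinical tibble.
#' @export
write_clinical <- function(clinical, path) {
  readr::write_csv(validate_clinical(clinical), path, progress = FALSE)
  invisible(path)
}

#' Read and write injury score tables (CSV)
#'
#' A score table has one row per biopsy: `sample_id` plus numeric feature
#' columns (canonically the 12 of [injury_features()]). Classifier
#' probability columns must lie in `[0, 1]` and PBT columns must be
#' positive.
#'
#' @param path File path.
#' @param scores A score tibble.
#' @return `read_scores()` returns a tibble; `write_scores()` returns
#'   `path` invisibly.
#' @export
read_scores <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  prob <- readr::problems(tbl)
  if (nrow(prob) > 0) {
    abort(sprintf("Unparseable value at scores file row %d, column %d.",
                  prob$row[1], prob$col[1]))
  }
  validate_scores(tbl)
}

#' @rdname read_scores
#' @export
write_scores <- function(scores, path) {
  readr::write_csv(validate_scores(scores), path, progress = FALSE)
  invisible(path)
}

#' @rdname read_scores
#' @export
validate_scores <- function(scores) {
  scores <- as_tibble(scores)
  if (!"sample_id" %in% names(scores)) abort("Score table needs a sample_id column.")
  if (anyDuplicated(scores$sample_id)) {
    abort(sprintf("Duplicate sample_id '%s' in score table.",
                  scores$sample_id[duplicated(scores$sample_id)][1]))
  }
  feat <- setdiff(names(scores), "sample_id")
  for (col in intersect(feat, .prob_features)) {
    bad <- which(!is.na(scores[[col]]) &
                   (scores[[col]] < 0 | scores[[col]] > 1))
    if (length(bad) > 0) {
      abort(sprintf("Probability column %s out of [0, 1] at sample_id '%s'.",
                    col, scores$sample_id[bad[1]]))
    }
  }
  for (col in intersect(feat, .pbt_features)) {
    bad <- which(!is.na(scores[[col]]) & scores[[col]] <= 0)
    if (length(bad) > 0) {
      abort(sprintf("PBT column %s must be positive; offending sample_id '%s'.",
                    col, scores$sample_id[bad[1]]))
    }
  }
  scores
}

#' Serialise an archetype model to JSON and back
#'
#' Models are written as JSON with a `schema_version` field; the round
#' trip is lossless to better than 1e-9 in every weight entry.
#'
#' @param model An `archetype_model` (see [fit_archetypes()]).
#' @param path File path.
#' @return `read_archetype_model()` returns an `archetype_model`;
#'   `write_archetype_model()` returns `path` invisibly.
#' @export
write_archetype_model <- function(model, path) {
  stopifnot(inherits(model, "archetype_model"))
  payload <- list(
    schema_version = 1L,
    k = model$k,
    features = colnames(model$Z),
    sample_ids = rownames(model$A),
    Z = unname(model$Z), A = unname(model$A), B = unname(model$B),
    rss = model$rss, n_iter = model$n_iter, converged = model$converged,
    seed = model$seed, restarts = model$restarts,
    center = model$center, scale = model$scale
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_archetype_model
#' @export
read_archetype_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$schema_version)) abort("Model file lacks schema_version.")
  Z <- matrix(p$Z, nrow = p$k, dimnames = list(NULL, p$features))
  A <- matrix(p$A, ncol = p$k, dimnames = list(p$sample_ids, NULL))
  B <- matrix(p$B, nrow = p$k, dimnames = list(NULL, p$sample_ids))
  new_archetype_model(
    k = as.integer(p$k), Z = Z, A = A, B = B, rss = p$rss,
    n_iter = as.integer(p$n_iter), converged = isTRUE(p$converged),
    seed = p$seed, restarts = as.integer(p$restarts),
    center = setNames(as.numeric(p$center), p$features),
    scale = setNames(as.numeric(p$scale), p$features)
  )
}
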