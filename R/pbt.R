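# ---- pathogenesis-based transcript set (PBT) scoring -----------------------

#' Per-probe control baseline
#'
#' The arithmetic mean of linear-scale intensities across the control
#' (nephrectomy) samples, per probe. This is the denominator of the PBT
#' fold change.
#'
#' @param expr An `injury_expr` with at least one control sample.
#' @param probes Character vector of probe ids.
#' @return Named numeric vector of positive baselines, one per probe.
#' @export
control_baseline <- function(expr, probes) {
  stopifnot(inherits(expr, "injury_expr"))
  if (length(expr$control_sample_ids) == 0) {
    abort("No control samples designated; a baseline needs >= 1 control.")
  }
  missing <- setdiff(probes, probe_ids(expr))
  if (length(missing) > 0) {
    abort(paste0("Probe id(s) absent from expression matrix: ",
                 paste(missing, collapse = ", ")))
  }
  block <- expr$values[probes, expr$control_sample_ids, drop = FALSE]
  rowMeans(block)
}

#' PBT score of one biopsy for one gene set
#'
#' The geometric mean, over the set's member probes, of the biopsy's fold
#' change versus the control baseline:
#' `exp(mean(log(intensity / baseline)))`. A score of 1.0 means
#' control-like expression. Computed in log space; ties exactly with the
#' product-root definition.
#'
#' @param expr An `injury_expr`.
#' @param gene_set Character vector of member probe ids (or a one-row
#'   slice of a `gene_set_collection`).
#' @param sample_id Sample to score.
#' @param na_policy `"error"` (default) fails on probes missing from the
#'   matrix; `"drop"` excludes them (real arrays have absent probes).
#' @return The positive scalar score.
#' @export
pbt_score <- function(expr, gene_set, sample_id,
                      na_policy = c("error", "drop")) {
  na_policy <- match.arg(na_policy)
  if (is.list(gene_set) && !is.null(gene_set$probes)) {
    gene_set <- gene_set$probes[[1]]
  }
  probes <- as.character(gene_set)
  if (!sample_id %in% sample_ids(expr)) {
    abort(sprintf("Sample '%s' not in expression matrix.", sample_id))
  }
  if (na_policy == "drop") {
    probes <- intersect(probes, probe_ids(expr))
  }
  if (length(probes) == 0) {
    abort("Effective probe list is empty after applying the missing-probe policy.")
  }
  baseline <- control_baseline(expr, probes)
  fc_log <- log(expr$values[probes, sample_id]) - log(baseline)
  exp(mean(fc_log))
}

#' Score every biopsy against a gene-set collection
#'
#' One geometric-mean fold-change score per (biopsy, set); control
#' samples are excluded from the output rows.
#'
#' @param expr An `injury_expr`.
#' @param collection A `gene_set_collection`.
#' @param na_policy Passed to [pbt_score()].
#' @return Tibble with `sample_id` and one numeric column per set.
#' @export
score_pbts <- function(expr, collection, na_policy = c("error", "drop")) {
  na_policy <- match.arg(na_policy)
  stopifnot(inherits(expr, "injury_expr"))
  biopsies <- setdiff(sample_ids(expr), expr$control_sample_ids)
  out <- tibble(sample_id = biopsies)
  for (i in seq_len(nrow(collection))) {
    probes <- collection$probes[[i]]
    if (na_policy == "drop") probes <- intersect(probes, probe_ids(expr))
    if (length(probes) == 0) {
      abort(sprintf("Gene set '%s': no member probes present.",
                    collection$name[i]))
    }
    baseline <- control_baseline(expr, probes)
    lfc <- log(expr$values[probes, biopsies, drop = FALSE]) - log(baseline)
    out[[collection$name[i]]] <- unname(exp(colMeans(lfc)))
  }
  out
}
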