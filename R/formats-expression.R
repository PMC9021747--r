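#' Expression matrix container
#'
#' Holds a probes-by-samples matrix of positive linear-scale intensities
#' together with the designation of control (nephrectomy) samples that
#' serve as the fold-change baseline for PBT scoring.
#'
#' @param values Numeric matrix, probes in rows, samples in columns, with
#'   unique row and column names. All values must be strictly positive:
#'   intensities are kept on the linear scale and log transforms happen
#'   inside scoring only.
#' @param control_ids Character vector of sample ids designating the
#'   control population (may be empty when scoring is not intended).
#'
#' @return An object of class `injury_expr`: a list with elements
#'   `values` and `control_sample_ids`.
#' @export
#'
#' @examples
#' m <- matrix(c(4, 10, 5, 12), nrow = 2,
#'             dimnames = list(c("p1", "p2"), c("N1", "S1")))
#' expression_matrix(m, control_ids = "N1")
expression_matrix <- function(values, control_ids = character()) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (probes x samples).")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must have probe row names and sample column names.")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    abort(paste0("Duplicate probe ids: ", paste(dup, collapse = ", ")))
  }
  if (anyDuplicated(colnames(values))) {
    dup <- unique(colnames(values)[duplicated(colnames(values))])
    abort(paste0("Duplicate sample ids: ", paste(dup, collapse = ", ")))
  }
  bad <- which(!is.finite(values) | values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(paste0(
      "Expression values must be positive and finite; offending cell(s): ",
      paste(utils::head(sprintf("[%s, %s]",
                                rownames(values)[bad[, 1]],
                                colnames(values)[bad[, 2]]), 5),
            collapse = ", ")))
  }
  control_ids <- as.character(control_ids)
  missing_ctl <- setdiff(control_ids, colnames(values))
  if (length(missing_ctl) > 0) {
    abort(paste0("Control sample id(s) not in matrix: ",
                 paste(missing_ctl, collapse = ", ")))
  }
  structure(list(values = values, control_sample_ids = control_ids),
            class = "injury_expr")
}

#' @export
print.injury_expr <- function(x, ...) {
  cat(sprintf("<injury_expr> %d probes x %d samples (%d controls)\n",
              nrow(x$values), ncol(x$values), length(x$control_sample_ids)))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x An `injury_expr` object.
#' @export
probe_ids <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

#' Read / write an expression matrix as tab-separated text
#'
#' The on-disk format is plain TSV: first column the probe id, header row
#' of sample ids, linear-scale intensities in the body. Reading validates
#' the [expression_matrix()] invariants (uniqueness, strict positivity)
#' and that every requested control id is present.
#'
#' @param path File path.
#' @param control_ids Character vector of control sample ids expected in
#'   the file.
#'
#' @return `read_expression()` returns an `injury_expr`;
#'   `write_expression()` returns `path` invisibly.
#' @export
read_expression <- function(path, control_ids = character()) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  if (ncol(tbl) < 2) abort("Expression file needs a probe column and >=1 sample column.")
  probes <- as.character(tbl[[1]])
  body <- tbl[, -1, drop = FALSE]
  m <- matrix(NA_real_, nrow(body), ncol(body),
              dimnames = list(probes, names(body)))
  for (j in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v) & !is.na(body[[j]]))
    if (length(bad) > 0) {
      abort(sprintf("Unparseable intensity at probe '%s', sample '%s'.",
                    probes[bad[1]], names(body)[j]))
    }
    m[, j] <- v
  }
  expression_matrix(m, control_ids = control_ids)
}

#' @rdname read_expression
#' @param expr An `injury_expr` object.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "injury_expr"))
  out <- tibble::as_tibble(expr$values, rownames = "probe_id")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
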