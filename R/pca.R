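# ---- PCA co-embedding of the injury score matrix ---------------------------

#' PCA of the standardized injury score matrix
#'
#' Principal components of the same n x 12 matrix used for archetypal
#' analysis, with deterministic sign conventions so the axes carry their
#' conventional meaning: PC1 is oriented so the IRRAT loading is positive
#' (PC1 = global injury), PC2 so the IRRAT loading is negative (AKI =
#' negative PC2, CKD = positive PC2), and PC3 so the IGT loading is
#' negative (inflamed injury = negative PC3). The anchors applied are
#' recorded in the model.
#'
#' @param scores Score tibble, matrix, or `injury_std`.
#' @param do_standardize Z-score columns first (default TRUE).
#' @return An `injury_pca`: `loadings` (p x p orthonormal), `scores`
#'   (tibble `sample_id` + PC columns), `explained` (variance fractions,
#'   non-increasing), `center`, `scale`, `anchors`.
#' @export
fit_pca <- function(scores, do_standardize = TRUE) {
  std <- if (inherits(scores, "injury_std")) {
    scores
  } else if (do_standardize) {
    standardize(scores)
  } else {
    .identity_std(scores)
  }
  X <- std$values
  if (nrow(X) <= ncol(X)) abort("PCA needs more samples than features.")
  sv <- svd(X)
  loadings <- sv$v
  dimnames(loadings) <- list(colnames(X), paste0("PC", seq_len(ncol(X))))
  anchors <- c(PC1 = "IRRAT+", PC2 = "IRRAT-", PC3 = "IGT-")
  flip <- rep(1, ncol(loadings))
  if ("IRRAT" %in% rownames(loadings)) {
    if (loadings["IRRAT", 1] < 0) flip[1] <- -1
    if (ncol(loadings) >= 2 && loadings["IRRAT", 2] > 0) flip[2] <- -1
  }
  if ("IGT" %in% rownames(loadings) && ncol(loadings) >= 3 &&
      loadings["IGT", 3] > 0) {
    flip[3] <- -1
  }
  loadings <- sweep(loadings, 2, flip, "*")
  sc <- X %*% loadings
  ev <- sv$d^2
  out <- structure(list(
    loadings = loadings,
    scores = dplyr::bind_cols(tibble(sample_id = rownames(X)),
                              as_tibble(sc)),
    explained = ev / sum(ev),
    center = std$center, scale = std$scale,
    anchors = anchors[seq_len(min(3, ncol(loadings)))]
  ), class = "injury_pca")
  out
}

#' @export
print.injury_pca <- function(x, ...) {
  cat(sprintf("<injury_pca> %d samples x %d components; PC1-3 explain %.1f%%\n",
              nrow(x$scores), ncol(x$loadings),
              100 * sum(x$explained[seq_len(min(3, length(x$explained)))])))
  invisible(x)
}

#' Probes most correlated with a principal component
#'
#' Ranks probes by descending Spearman correlation between their
#' expression and the chosen PC score over the shared samples; ties break
#' by probe id.
#'
#' @param expr An `injury_expr`.
#' @param pca An `injury_pca` (or a tibble with `sample_id` and PC
#'   columns).
#' @param pc Component name (default `"PC3"`).
#' @param n_top Number of probes to return (default 20).
#' @return Tibble with `probe_id`, `rho`, `rank`.
#' @export
top_correlated_genes <- function(expr, pca, pc = "PC3", n_top = 20) {
  stopifnot(inherits(expr, "injury_expr"))
  sc <- if (inherits(pca, "injury_pca")) pca$scores else as_tibble(pca)
  if (!pc %in% names(sc)) abort(sprintf("Component '%s' not found.", pc))
  shared <- intersect(sample_ids(expr), sc$sample_id)
  if (length(shared) < 3) abort("Need >= 3 shared samples.")
  v <- sc[[pc]][match(shared, sc$sample_id)]
  rho <- apply(expr$values[, shared, drop = FALSE], 1,
               function(row) suppressWarnings(cor(row, v, method = "spearman")))
  ord <- order(-rho, names(rho))
  out <- tibble(probe_id = names(rho)[ord], rho = unname(rho[ord]))
  out$rank <- seq_len(nrow(out))
  utils::head(out, n_top)
}
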