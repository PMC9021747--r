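# ---- archetypal analysis of the injury score matrix ------------------------
#
# Alternating simplex-constrained least squares: minimise ||X - A B X||^2
# over stochastic matrices A (n x k, rows on the simplex) and B (k x n,
# rows on the simplex). Each alternating block update is an exact
# constrained minimisation, so the RSS is non-increasing across
# iterations. Initialisation is furthest-sum vertex seeding with
# multi-restart.

#' Column-standardize a score table
#'
#' Z-scores every feature column (sample-SD convention). The 12 injury
#' features live on incommensurate scales (fold changes vs probabilities),
#' so both PCA and archetypal analysis operate on the standardized matrix
#' by default. Constant columns become zeros with a warning.
#'
#' @param scores Score tibble (`sample_id` + numeric columns) or a
#'   numeric matrix with rownames.
#' @param center,scale Optional precomputed column means / SDs (used to
#'   map new data into an existing model's space).
#' @return An object of class `injury_std`: list with `values` (n x p
#'   matrix), `center`, `scale`.
#' @export
standardize <- function(scores, center = NULL, scale = NULL) {
  if (inherits(scores, "injury_std")) return(scores)
  m <- .score_matrix(scores)
  if (!all(is.finite(m))) abort("Score matrix contains non-finite values.")
  if (is.null(center)) center <- colMeans(m)
  if (is.null(scale)) {
    scale <- apply(m, 2, sd)
    if (any(scale == 0)) {
      warn(paste0("Constant column(s) standardized to zero: ",
                  paste(colnames(m)[scale == 0], collapse = ", ")))
      scale[scale == 0] <- 1
    }
  }
  v <- sweep(sweep(m, 2, center, "-"), 2, scale, "/")
  structure(list(values = v, center = center, scale = scale),
            class = "injury_std")
}

# extract the numeric matrix (rownames = sample ids) from tabular input
.score_matrix <- function(scores) {
  if (is.data.frame(scores)) {
    ids <- if ("sample_id" %in% names(scores)) scores$sample_id else
      as.character(seq_len(nrow(scores)))
    m <- as.matrix(scores[, setdiff(names(scores), "sample_id"), drop = FALSE])
    rownames(m) <- ids
    m
  } else {
    m <- as.matrix(scores)
    if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
    m
  }
}

# an injury_std wrapping raw values with the identity transform
.identity_std <- function(scores) {
  m <- .score_matrix(scores)
  structure(list(values = m,
                 center = setNames(rep(0, ncol(m)), colnames(m)),
                 scale = setNames(rep(1, ncol(m)), colnames(m))),
            class = "injury_std")
}

# simplex-constrained least squares, rows of the result on the simplex:
# row r of the result minimises ||T[r, ] - w %*% P||^2 s.t. w >= 0, sum 1
simplex_weights <- function(P, T, penalty = 200) {
  W <- simplex_weights_cpp(as.matrix(P), as.matrix(T), penalty, 1e-10)
  W
}

new_archetype_model <- function(k, Z, A, B, rss, n_iter, converged,
                                seed, restarts, center, scale) {
  structure(list(k = k, Z = Z, A = A, B = B, rss = rss, n_iter = n_iter,
                 converged = converged, seed = seed, restarts = restarts,
                 center = center, scale = scale),
            class = "archetype_model")
}

#' @export
print.archetype_model <- function(x, ...) {
  cat(sprintf("<archetype_model> k = %d, n = %d, RSS = %.6g, %s after %d iterations\n",
              x$k, nrow(x$A), x$rss,
              if (x$converged) "converged" else "not converged", x$n_iter))
  invisible(x)
}

# furthest-sum vertex seeding: greedily pick points maximising the total
# distance to the already chosen seeds
.furthest_sum <- function(X, k) {
  n <- nrow(X)
  chosen <- sample.int(n, 1)
  if (k > 1) {
    dsum <- rep(0, n)
    for (j in 2:k) {
      last <- X[chosen[length(chosen)], ]
      dsum <- dsum + sqrt(rowSums(sweep(X, 2, last)^2))
      cand <- setdiff(order(dsum, decreasing = TRUE), chosen)
      chosen <- c(chosen, cand[1])
    }
  }
  chosen
}

.fit_archetypes_once <- function(X, k, max_iter, tol) {
  n <- nrow(X)
  p <- ncol(X)
  B <- matrix(0, k, n)
  B[cbind(seq_len(k), .furthest_sum(X, k))] <- 1
  Z <- B %*% X
  rss_prev <- Inf
  rss <- Inf
  A <- NULL
  for (it in seq_len(max_iter)) {
    A <- simplex_weights(Z, X)                       # exact per-row update
    E <- X - A %*% Z
    rss <- sum(E^2)
    # block-coordinate update of B rows (each an exact minimisation)
    for (j in seq_len(k)) {
      aj <- A[, j]
      a2 <- sum(aj^2)
      Rj <- E + tcrossprod(aj, Z[j, ])
      if (a2 < 1e-12) {
        # unused archetype: reseed at the worst-represented sample
        worst <- which.max(rowSums(E^2))
        B[j, ] <- 0
        B[j, worst] <- 1
      } else {
        vstar <- crossprod(Rj, aj)[, 1] / a2
        B[j, ] <- simplex_weights(X, matrix(vstar, 1))
      }
      Z[j, ] <- B[j, , drop = FALSE] %*% X
      E <- Rj - tcrossprod(aj, Z[j, ])
    }
    rss_b <- sum(E^2)
    if (is.finite(rss_prev) && (rss_prev - rss_b) <= tol * max(rss_prev, 1e-12)) {
      rss_prev <- rss_b
      break
    }
    rss_prev <- rss_b
  }
  A <- simplex_weights(Z, X)                         # leave A optimal for Z
  rss <- sum((X - A %*% Z)^2)
  list(A = A, B = B, Z = Z, rss = rss, n_iter = it,
       converged = it < max_iter)
}

#' Fit an archetypal-analysis model
#'
#' Minimises `||X - A B X||^2` by alternating simplex-constrained least
#' squares with furthest-sum initialisation; the best of `restarts` runs
#' by RSS is returned. Rows of `A` (per-sample archetype scores) and of
#' `B` (archetype composition weights over samples) are non-negative and
#' sum to one; the archetypes are `Z = B X`.
#'
#' @param scores Score tibble, numeric matrix, or an `injury_std`.
#' @param k Number of archetypes (canonical default 6).
#' @param max_iter Maximum alternating iterations per restart (default 500).
#' @param tol Relative RSS-improvement convergence tolerance (default 1e-6).
#' @param restarts Random restarts (default 10).
#' @param seed Integer seed.
#' @param do_standardize Z-score columns before fitting (default TRUE).
#' @return An `archetype_model`: `k`, `Z` (k x p), `A` (n x k), `B`
#'   (k x n), `rss`, `n_iter`, `converged`, `seed`, `restarts`, and the
#'   standardization `center`/`scale`.
#' @export
fit_archetypes <- function(scores, k = 6, max_iter = 500, tol = 1e-6,
                           restarts = 10, seed = 1L, do_standardize = TRUE) {
  std <- if (inherits(scores, "injury_std")) {
    scores
  } else if (do_standardize) {
    standardize(scores)
  } else {
    .identity_std(scores) # fit in original units
  }
  X <- std$values
  if (!all(is.finite(X))) abort("Non-finite values in input.")
  if (k > nrow(X)) abort("k cannot exceed the number of samples.")
  if (k < 1) abort("k must be >= 1.")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- .fit_archetypes_once(X, k, max_iter, tol)
    if (is.null(best) || fit$rss < best$rss) best <- fit
  }
  dimnames(best$A) <- list(rownames(X), NULL)
  dimnames(best$B) <- list(NULL, rownames(X))
  colnames(best$Z) <- colnames(X)
  new_archetype_model(
    k = as.integer(k), Z = best$Z, A = best$A, B = best$B, rss = best$rss,
    n_iter = best$n_iter, converged = best$converged, seed = seed,
    restarts = as.integer(restarts), center = std$center, scale = std$scale)
}

#' RSS scree over a range of k
#'
#' Best-of-restarts residual sum of squares for each candidate number of
#' archetypes (the study explored 2-7). The optimizer is stochastic, so
#' an occasional non-monotone step is logged rather than fatal.
#'
#' @inheritParams fit_archetypes
#' @param k_range Integer vector of candidate k (default 2:7).
#' @return Tibble with `k` and `rss`.
#' @export
rss_scree <- function(scores, k_range = 2:7, restarts = 10, seed = 1L,
                      max_iter = 500, tol = 1e-6, do_standardize = TRUE) {
  rss <- purrr::map_dbl(k_range, function(kk) {
    fit_archetypes(scores, k = kk, max_iter = max_iter, tol = tol,
                   restarts = restarts, seed = seed + kk,
                   do_standardize = do_standardize)$rss
  })
  if (any(diff(rss) > 1e-8)) {
    message("RSS scree is not monotone non-increasing; consider more restarts.")
  }
  tibble(k = as.integer(k_range), rss = rss)
}

#' Archetype scores for new samples
#'
#' Projects new samples onto a fitted model's archetypes: per-sample
#' simplex-constrained least-squares weights against the fixed `Z`.
#' New data are standardized with the model's stored center/scale.
#'
#' @param model An `archetype_model`.
#' @param new_scores Score tibble or matrix in original feature units
#'   (columns must match the model's features).
#' @return An n x k weight matrix with rownames from `sample_id`; rows
#'   are non-negative and sum to one.
#' @export
archetype_scores <- function(model, new_scores) {
  stopifnot(inherits(model, "archetype_model"))
  m <- .score_matrix(new_scores)
  if (!setequal(colnames(m), colnames(model$Z))) {
    abort("Feature columns do not match the fitted model.")
  }
  m <- m[, colnames(model$Z), drop = FALSE]
  std <- standardize(m, center = model$center[colnames(model$Z)],
                     scale = model$scale[colnames(model$Z)])
  A <- simplex_weights(model$Z, std$values)
  rownames(A) <- rownames(std$values)
  A
}

#' Assign each sample to its highest-scoring archetype
#'
#' The biopsy's cluster is the argmax of its archetype-score row; ties
#' break toward the lowest archetype index.
#'
#' @param A An n x k archetype-score matrix (or an `archetype_model`).
#' @param labels Optional archetype-index-to-label mapping (character
#'   vector of length k) used to attach scenario labels.
#' @return Tibble with `sample_id`, `archetype_index`, `max_score` and,
#'   when labels are supplied, `label`.
#' @export
assign_clusters <- function(A, labels = NULL) {
  if (inherits(A, "archetype_model")) A <- A$A
  idx <- max.col(A, ties.method = "first")
  out <- tibble(
    sample_id = rownames(A) %||% as.character(seq_len(nrow(A))),
    archetype_index = idx,
    max_score = A[cbind(seq_len(nrow(A)), idx)]
  )
  if (!is.null(labels)) out$label <- labels[idx]
  out
}

# all permutations of 1..k (k <= 7 here, at most 5040 rows)
.permutations <- function(v) {
  n <- length(v)
  if (n == 1) return(matrix(v, 1, 1))
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(v[i], .permutations(v[-i]))
  }))
}

#' Label fitted archetypes by matching reference profiles
#'
#' Matches each fitted archetype to one reference profile
#' ([reference_profiles()]) under an exact one-to-one assignment
#' maximising the total Pearson correlation (computed on the model's
#' standardized feature scale). For k other than the canonical 6, labels
#' are unavailable and archetype indices are returned instead.
#'
#' @param model An `archetype_model`.
#' @param scores Optional score tibble used to report per-archetype mean
#'   features alongside the mapping.
#' @param reference Reference profile matrix (rows labeled, columns =
#'   model features).
#' @return A list with `mapping` (tibble: `archetype_index`, `label`,
#'   `correlation`) and `profile_means` (tibble of per-archetype mean
#'   features, or `NULL` when `scores` is not given).
#' @export
label_archetypes <- function(model, scores = NULL,
                             reference = reference_profiles()) {
  stopifnot(inherits(model, "archetype_model"))
  k <- model$k
  if (k != nrow(reference)) {
    warn(sprintf("k = %d does not match the %d reference profiles; returning indices.",
                 k, nrow(reference)))
    mapping <- tibble(archetype_index = seq_len(k),
                      label = as.character(seq_len(k)),
                      correlation = NA_real_)
  } else {
    feats <- colnames(model$Z)
    ref <- reference[, feats, drop = FALSE]
    ref_std <- sweep(sweep(ref, 2, model$center[feats], "-"), 2,
                     model$scale[feats], "/")
    cmat <- cor(t(model$Z), t(ref_std)) # k x k: archetype vs reference
    perms <- .permutations(seq_len(k))
    tot <- perms
    score <- apply(perms, 1, function(pm) sum(cmat[cbind(seq_len(k), pm)]))
    best <- perms[which.max(score), ]
    mapping <- tibble(
      archetype_index = seq_len(k),
      label = rownames(reference)[best],
      correlation = cmat[cbind(seq_len(k), best)])
  }
  profile_means <- NULL
  if (!is.null(scores)) {
    asg <- assign_clusters(model)
    joined <- dplyr::inner_join(asg, as_tibble(scores), by = "sample_id")
    profile_means <- joined %>%
      dplyr::group_by(.data$archetype_index) %>%
      dplyr::summarise(dplyr::across(dplyr::where(is.numeric) &
                                       !dplyr::any_of("max_score"), mean),
                       n = dplyr::n(), .groups = "drop") %>%
      dplyr::left_join(mapping[, c("archetype_index", "label")],
                       by = "archetype_index")
  }
  list(mapping = mapping, profile_means = profile_means)
}
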