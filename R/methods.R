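# ---- broom-style accessors --------------------------------------------------

#' Tidy an archetype model
#'
#' One row per (archetype, feature) with the archetype coordinate on the
#' standardized scale and mapped back to original feature units.
#'
#' @param x An `archetype_model`.
#' @param ... Unused.
#' @return A tibble with `archetype`, `feature`, `value_std`, `value`.
#' @method tidy archetype_model
#' @export
tidy.archetype_model <- function(x, ...) {
  Z <- x$Z
  raw <- sweep(sweep(Z, 2, x$scale[colnames(Z)], "*"), 2,
               x$center[colnames(Z)], "+")
  tibble(
    archetype = rep(seq_len(x$k), times = ncol(Z)),
    feature = rep(colnames(Z), each = x$k),
    value_std = as.vector(Z),
    value = as.vector(raw)
  )
}

#' @rdname tidy.archetype_model
#' @return `glance()` returns a one-row tibble with `k`, `n`, `rss`,
#'   `n_iter`, `converged`, `restarts`, `seed`.
#' @method glance archetype_model
#' @export
glance.archetype_model <- function(x, ...) {
  tibble(k = x$k, n = nrow(x$A), rss = x$rss, n_iter = x$n_iter,
         converged = x$converged, restarts = x$restarts, seed = x$seed)
}

#' @rdname tidy.archetype_model
#' @method tidy injury_pca
#' @export
tidy.injury_pca <- function(x, ...) {
  tibble(
    feature = rep(rownames(x$loadings), times = ncol(x$loadings)),
    component = rep(colnames(x$loadings), each = nrow(x$loadings)),
    loading = as.vector(x$loadings)
  )
}

#' @rdname tidy.archetype_model
#' @method glance injury_pca
#' @export
glance.injury_pca <- function(x, ...) {
  tibble(n = nrow(x$scores), p = ncol(x$loadings),
         var_pc1 = x$explained[1], var_pc2 = x$explained[2],
         var_pc3 = x$explained[3])
}

# ---- plotting ----------------------------------------------------------------

#' Plot biopsies in injury PC space colored by archetype cluster
#'
#' @param object An `injury_pca`.
#' @param assignments Optional tibble from [assign_clusters()] used to
#'   color points by group.
#' @param dims Two component names (default `c("PC1", "PC2")`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot injury_pca
#' @export
autoplot.injury_pca <- function(object, assignments = NULL,
                                dims = c("PC1", "PC2"), ...) {
  dat <- object$scores
  if (!is.null(assignments)) {
    key <- if ("label" %in% names(assignments)) "label" else "archetype_index"
    dat <- dplyr::left_join(
      dat, tibble(sample_id = assignments$sample_id,
                  group = as.character(assignments[[key]])),
      by = "sample_id")
  } else {
    dat$group <- "biopsy"
  }
  ggplot2::ggplot(dat, ggplot2::aes(.data[[dims[1]]], .data[[dims[2]]],
                                    colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(colour = "injury group") +
    ggplot2::theme_minimal()
}

#' Plot standardized archetype-score trends
#'
#' @param object Long trend tibble from [standardized_trend()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_trends <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x_mean, .data$y_mean,
                                       colour = .data$archetype)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "ordering variable (window mean)",
                  y = "archetype score (SD units)",
                  colour = "archetype") +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier curves
#'
#' @param object Result of [km_by_group()] (or a single `km_curve`).
#' @param ... Unused.
#' @return A ggplot step plot.
#' @export
plot_km <- function(object, ...) {
  dat <- if (is.list(object) && !is.data.frame(object)) object$curves else {
    dplyr::bind_cols(tibble(group = "all"), as_tibble(object))
  }
  ggplot2::ggplot(dat, ggplot2::aes(.data$time, .data$surv,
                                    colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "days post biopsy",
                  y = "death-censored graft survival") +
    ggplot2::theme_minimal()
}

#' Plot a variable-importance report
#'
#' @param object An `importance_report`.
#' @param ... Unused.
#' @return A ggplot bar chart, features ordered by importance.
#' @export
plot_importance <- function(object, ...) {
  dat <- dplyr::mutate(as_tibble(object),
                       feature = stats::reorder(.data$feature, .data$importance))
  ggplot2::ggplot(dat, ggplot2::aes(.data$importance, .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "permutation importance", y = NULL) +
    ggplot2::theme_minimal()
}
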