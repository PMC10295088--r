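#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a production envelope
#'
#' Shaded feasible region of the y flux against the x flux, with the
#' min/max boundary lines.
#'
#' @param object a `production_envelope`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot production_envelope
#' @export
autoplot.production_envelope <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df[df$feasible, ], ggplot2::aes(x = .data$x)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$y_min, ymax = .data$y_max),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$y_min)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$y_max)) +
    ggplot2::labs(x = attr(object, "x_reaction"), y = attr(object, "y_reaction"),
                  title = "Production envelope") +
    ggplot2::theme_minimal()
}

#' Plot a 2-D sample embedding
#'
#' One marker style per sample set on the shared MDS plane; the visual
#' diversity comparison between constrained and default sampling.
#'
#' @param object a `flux_embedding`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot flux_embedding
#' @export
autoplot.flux_embedding <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$label, shape = .data$label)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "MDS 1", y = "MDS 2", colour = NULL, shape = NULL,
                  title = sprintf("Sample diversity (stress %.3f)",
                                  attr(object, "stress"))) +
    ggplot2::theme_minimal()
}

#' Plot a flux importance ranking
#'
#' Mean hit count per candidate flux on a log scale, ascending; the most
#' informative (fewest hits) fluxes come first.
#'
#' @param object an `importance_ranking`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot importance_ranking
#' @export
autoplot.importance_ranking <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$reaction <- factor(df$reaction, levels = rev(df$reaction))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_hits, y = .data$reaction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "mean matching samples (log scale)", y = NULL,
                  title = "Flux importance (fewer hits = more informative)") +
    ggplot2::theme_minimal()
}

#' Plot a validation comparison against the 13C-MFA reference
#'
#' Grouped bars per reaction: the reference flux next to each of the top-k
#' sampled distributions, all per 100 units of substrate uptake.
#'
#' @param object an `mfa_validation`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot mfa_validation
#' @export
autoplot.mfa_validation <- function(object, ...) {
  df <- object$comparison
  df$source <- factor(df$source, levels = unique(df$source))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reaction, y = .data$flux,
                                   fill = .data$source)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::labs(x = NULL, y = "flux per 100 substrate", fill = NULL,
                  title = "Sampled flux distributions vs 13C-MFA reference") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
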