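# ggplot2 views of the result objects: ranked index bars with CI whiskers,
# the mu*/sigma screening plane, and the depletion-vs-half scatter against
# the bisector.

#' @importFrom ggplot2 ggplot aes geom_col geom_errorbar geom_point
#'   geom_abline facet_wrap labs coord_flip theme_minimal
NULL

#' Plot Sobol indices as ranked bars with confidence whiskers
#'
#' @param object a `sobol_sa` result.
#' @param top_k show only the `top_k` highest-ranked factors (by total
#'   effect).
#' @param ... unused.
#' @return A ggplot object: first-order and total-effect panels, factors
#'   ordered by total-effect rank, whiskers at the bootstrap CI.
#' @export
autoplot.sobol_sa <- function(object, top_k = 30, ...) {
  df <- tidy(object)
  keep <- head(object$ranking_total, top_k)
  df <- df[df$factor %in% keep, ]
  long <- tidyr::pivot_longer(
    df,
    cols = c("s1", "st"),
    names_to = "index", values_to = "value")
  long$conf <- ifelse(long$index == "s1", df$s1_conf[match(long$factor, df$factor)],
                      df$st_conf[match(long$factor, df$factor)])
  long$index <- factor(long$index, c("s1", "st"),
                       c("first order (S1)", "total effect (ST)"))
  long$factor <- factor(long$factor, rev(object$ranking_total))
  ggplot(long, aes(x = .data$factor, y = .data$value)) +
    geom_col(fill = "steelblue") +
    geom_errorbar(aes(ymin = .data$value - .data$conf,
                      ymax = .data$value + .data$conf), width = 0.3) +
    coord_flip() +
    facet_wrap(~index) +
    labs(x = NULL, y = "Sobol index") +
    theme_minimal()
}

#' Plot Morris screening results on the mu*-sigma plane
#'
#' Factors far along mu* are influential; factors above the diagonal have
#' elementary effects that vary strongly with the rest of the input space
#' (nonlinearity/interaction).
#'
#' @param object a `morris_sa` result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.morris_sa <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$mu_star, y = .data$sigma)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey50") +
    geom_point() +
    ggplot2::geom_text(aes(label = .data$factor), vjust = -0.6, size = 3) +
    labs(x = expression(mu * "*"), y = expression(sigma)) +
    theme_minimal()
}

#' Plot the depletion-versus-half-reduction scatter
#'
#' Reproduces the scatter diagnostic of the local comparator: each point is
#' a factor, x = relative growth reduction at 50% intake reduction (scaled
#' by the perturbation size), y = reduction at total depletion. Points on
#' the grey bisector respond region-invariantly; off-bisector points reveal
#' regime changes that a single local perturbation cannot see.
#'
#' @param object a `perturbation_run` (or the tibble from
#'   [depletion_vs_half_pairs()]).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.perturbation_run <- function(object, ...) {
  df <- if (inherits(object, "perturbation_run")) object$table else object
  ggplot(df, aes(x = .data$reduction_50_scaled, y = .data$reduction_100)) +
    geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    geom_point() +
    ggplot2::geom_text(aes(label = .data$factor), vjust = -0.6, size = 3) +
    labs(x = "reduction at 50% (scaled)", y = "reduction at depletion") +
    theme_minimal()
}
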