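# broom-style tidiers and diagnostic plots for the fitted objects.

#' @describeIn fit_elastic_net Tidy per-lag coefficients of a history fit.
#' @param x A `vi_histfit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.vi_histfit <- function(x, ...) {
  x$coef
}

#' @describeIn fit_elastic_net One-row fit summary.
#' @exportS3Method generics::glance
glance.vi_histfit <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda,
    n_lags = x$n_lags,
    n_obs = x$n_obs,
    intercept = x$intercept,
    min_cv_deviance = min(x$cv_deviance$deviance),
    extended = x$extended
  )
}

#' @describeIn anneal_fit Tidy fitted parameters.
#' @param x A `vi_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.vi_fit <- function(x, ...) {
  tibble::tibble(term = names(x$theta_hat),
                 estimate = unname(x$theta_hat))
}

#' @describeIn anneal_fit One-row fit summary.
#' @exportS3Method generics::glance
glance.vi_fit <- function(x, ...) {
  tibble::tibble(model = x$model, logLik = x$logLik, mean_ll = x$mean_ll,
                 n_iterations = nrow(x$trace), converged = x$converged)
}

#' @describeIn optimize_in_env Tidy optimised parameters.
#' @param x A `vi_opt`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.vi_opt <- function(x, ...) {
  tibble::tibble(term = names(x$theta_star),
                 estimate = unname(x$theta_star))
}

#' @describeIn optimize_in_env One-row optimisation summary.
#' @exportS3Method generics::glance
glance.vi_opt <- function(x, ...) {
  tibble::tibble(model = x$model, condition = x$condition,
                 mean_regret = x$mean_regret)
}

#' @describeIn fit_elastic_net Coefficient-by-lag diagnostic plot.
#' @param object A `vi_histfit`.
#' @exportS3Method ggplot2::autoplot
autoplot.vi_histfit <- function(object, ...) {
  ggplot2::ggplot(object$coef,
                  ggplot2::aes(x = .data$lag, y = .data$estimate,
                               colour = .data$block)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "trials back", y = "log-odds coefficient",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn optimize_in_env Implied reward/choice trace curves of an
#'   optimised DT parameter vector.
#' @param object A `vi_opt`.
#' @exportS3Method ggplot2::autoplot
autoplot.vi_opt <- function(object, ...) {
  if (object$model != "dt") abort("trace curves are defined for the DT model")
  d <- tidyr::pivot_longer(trace_shapes(object$theta_star),
                           c("b_reward", "b_choice"),
                           names_to = "trace", values_to = "coefficient")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lag, y = .data$coefficient,
                                  colour = .data$trace)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "trials back", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Quick-look plot of a recorded session
#'
#' Choices (points), rewards (filled points) and, when recorded, the true
#' momentary reward probabilities of both options.
#'
#' @param sessions Session tibble; if several sessions are present the
#'   first is shown.
#' @return A ggplot object.
#' @export
plot_session <- function(sessions) {
  sid <- sessions[["session"]] %||% rep(1L, nrow(sessions))
  d <- sessions[sid == sid[1], ]
  g <- ggplot2::ggplot(d, ggplot2::aes(x = .data$trial))
  if (all(c("p_0", "p_1") %in% names(d))) {
    g <- g +
      ggplot2::geom_line(ggplot2::aes(y = .data$p_0, colour = "left p")) +
      ggplot2::geom_line(ggplot2::aes(y = .data$p_1, colour = "right p"))
  }
  g +
    ggplot2::geom_point(ggplot2::aes(y = .data$choice,
                                     shape = factor(.data$reward)),
                        alpha = 0.6, size = 1) +
    ggplot2::scale_shape_manual(values = c(`0` = 1, `1` = 16),
                                name = "reward") +
    ggplot2::labs(y = "choice (0 = left, 1 = right) / P(reward)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
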