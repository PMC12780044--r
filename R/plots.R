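#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the main result
#' types: the committor-training loss curves, the TPS chain trace of the
#' smoothed pore coordinate with its mechanism classification, the
#' accuracy log-posterior, the logit-logit calibration scatter, and the
#' profile likelihood of the lifetime fit.
#'
#' @param object a fitted object from this package.
#' @param ... unused.
#' @name tpslearn-autoplot
NULL

#' @rdname tpslearn-autoplot
#' @export
autoplot.committor_mlp <- function(object, ...) {
  stopifnot(!is.null(object$history))
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$epoch, y = .data$loss,
                               colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::labs(x = "epoch", y = "mean shooting NLL",
                  title = "Committor training") +
    ggplot2::theme_minimal()
}

#' @rdname tpslearn-autoplot
#' @param threshold,window mechanism threshold and smoothing window.
#' @export
autoplot.tps_chain <- function(object, threshold = 1.0, window = 10, ...) {
  mech <- classify_mechanism(object, threshold = threshold, window = window)
  ggplot2::ggplot(mech, ggplot2::aes(x = .data$mc_index)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$xi_hat), alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$xi_smooth,
                                    colour = .data$mechanism, group = 1)) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::labs(x = "TPS MC step", y = "time-averaged coordinate",
                  colour = "mechanism") +
    ggplot2::theme_minimal()
}

#' @rdname tpslearn-autoplot
#' @export
autoplot.accuracy_fit <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$alpha, y = .data$log_posterior)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$alpha_hat, linetype = 2) +
    ggplot2::labs(x = expression(alpha), y = "log posterior",
                  title = sprintf("accuracy alpha_hat = %.3f",
                                  object$alpha_hat)) +
    ggplot2::theme_minimal()
}

#' @rdname tpslearn-autoplot
#' @export
autoplot.calibration_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$q_pred, y = .data$q_act)) +
    ggplot2::geom_point(alpha = 0.3) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "red") +
    ggplot2::labs(x = "predicted logit", y = "actual logit ln[k/(n-k)]") +
    ggplot2::theme_minimal()
}

#' @rdname tpslearn-autoplot
#' @export
autoplot.lifetime_fit <- function(object, ...) {
  ggplot2::ggplot(object$log_lik,
                  ggplot2::aes(x = .data$rate, y = .data$log_lik)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 1 / object$tau_hat, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "closure rate", y = "log likelihood") +
    ggplot2::theme_minimal()
}

#' Committor profile against the analytic oracle
#'
#' Plots a trained 1D committor model against the closed-form committor
#' of the same potential.
#'
#' @param model a committor model over a single coordinate.
#' @param potential the 1D `tps_potential`.
#' @param beta inverse temperature.
#' @param a,b committor boundaries.
#' @param n_points resolution.
#' @export
plot_committor_profile <- function(model, potential, beta, a, b,
                                   n_points = 200) {
  x <- seq(a, b, length.out = n_points)
  df <- tibble::tibble(
    x = rep(x, 2),
    phi = c(predict_phi(model, matrix(x, ncol = 1)),
            analytic_committor_1d(potential, beta, a, b, x)),
    which = rep(c("model", "analytic"), each = n_points)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$phi,
                                   colour = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = expression(phi(x))) +
    ggplot2::theme_minimal()
}
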