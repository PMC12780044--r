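#' Shooting-point selection controls
#'
#' Shooting points are drawn from the current transition path. Until the
#' logit histogram exists the draw is uniform over eligible (interior)
#' frames; afterwards each frame is reweighted so that the distribution
#' of selected committor logits approaches Cauchy(0, 1):
#' `weight_i ~ Cauchy(q_i; 0, 1) / P_hat(q_i | TP)`, with `P_hat` a
#' histogram of logits over frames of sampled transition paths. The
#' histogram is first built after `build_at` MC steps and refreshed every
#' `refresh_every` steps thereafter.
#'
#' @param build_at MC step at which the histogram is first built.
#' @param refresh_every refresh interval in MC steps.
#' @param bins number of equal-width histogram bins.
#' @param clip logits are clipped to this range before binning, so that
#'   near-state frames with diverging logit cannot dominate.
#' @export
sp_control <- function(build_at = 100, refresh_every = 250, bins = 50,
                       clip = c(-10, 10)) {
  stopifnot(build_at >= 1, refresh_every >= 1, bins >= 2, clip[1] < clip[2])
  structure(list(build_at = build_at, refresh_every = refresh_every,
                 bins = bins, clip = clip), class = "sp_control")
}

#' Histogram estimate of the transition-path logit density
#'
#' @param q logit values of frames of sampled transition paths.
#' @param control an [sp_control()].
#' @return A `logit_histogram`: bin edges and a density normalized to
#'   unit integral over the binned range.
#' @export
build_logit_histogram <- function(q, control = sp_control()) {
  q <- pmin(pmax(q, control$clip[1]), control$clip[2])
  edges <- seq(control$clip[1], control$clip[2], length.out = control$bins + 1)
  counts <- tabulate(findInterval(q, edges, rightmost.closed = TRUE),
                     nbins = control$bins)
  width <- diff(edges)[1]
  dens <- counts / (sum(counts) * width)
  structure(list(edges = edges, density = dens, n = length(q),
                 floor_density = if (any(dens > 0)) min(dens[dens > 0]) else 1),
            class = "logit_histogram")
}

hist_density_at <- function(hist, q) {
  q <- pmin(pmax(q, hist$edges[1]), hist$edges[length(hist$edges)])
  bin <- pmin(pmax(findInterval(q, hist$edges, rightmost.closed = TRUE), 1),
              length(hist$density))
  d <- hist$density[bin]
  # frames falling in empty bins: floor the reweighting denominator at the
  # smallest nonzero bin density
  d[d <= 0] <- hist$floor_density
  d
}

#' Per-frame shooting-point selection weights
#'
#' @param path a `tps_path`.
#' @param model a committor model (used for the logits); may be `NULL`
#'   when `hist` is `NULL`.
#' @param hist a `logit_histogram`, or `NULL` for uniform selection.
#' @return normalized probability per frame (endpoints get 0: they lie
#'   inside states and are ineligible as shooting points).
#' @export
selection_weights <- function(path, model = NULL, hist = NULL) {
  nf <- nrow(path$frames)
  eligible <- rep(TRUE, nf)
  eligible[c(1, nf)] <- FALSE
  w <- numeric(nf)
  if (is.null(hist)) {
    w[eligible] <- 1
  } else {
    q <- committor_logit(model, path$frames[eligible, , drop = FALSE])
    w[eligible] <- stats::dcauchy(q, 0, 1) / hist_density_at(hist, q)
    if (!any(w > 0) || !all(is.finite(w))) {
      warning("degenerate selection weights; falling back to uniform",
              call. = FALSE)
      w <- numeric(nf)
      w[eligible] <- 1
    }
  }
  w / sum(w)
}

#' Draw a shooting point index from selection weights
#'
#' @param path a `tps_path`.
#' @param weights normalized per-frame probabilities.
#' @param seed optional seed (otherwise the ambient RNG stream is used).
#' @return frame index.
#' @export
select_sp <- function(path, weights, seed = NULL) {
  stopifnot(abs(sum(weights) - 1) < 1e-8)
  if (!is.null(seed)) set.seed(seed)
  sample.int(length(weights), 1L, prob = weights)
}

#' Shooting-point selection schedule
#'
#' Uniform selection for MC steps before `build_at`; the histogram is
#' built at `build_at` and refreshed every `refresh_every` steps
#' thereafter; otherwise the existing histogram is reused.
#'
#' @param mc_index MC step index (1-based).
#' @param control an [sp_control()].
#' @return one of `"uniform"`, `"build"`, `"reuse"`, `"refresh"`.
#' @export
update_schedule <- function(mc_index, control = sp_control()) {
  stopifnot(mc_index >= 0)
  if (mc_index < control$build_at) return("uniform")
  if (mc_index == control$build_at) return("build")
  if ((mc_index - control$build_at) %% control$refresh_every == 0) {
    return("refresh")
  }
  "reuse"
}
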