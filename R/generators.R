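#' Synthetic shooting records with controllable accuracy
#'
#' Simulates the generative model behind the beta-binomial accuracy
#' estimator: for each record a model committor `phi` is drawn from
#' `phi_sampler`, the true commitment probability `P` is drawn from a
#' Beta distribution with mean `phi` and variance
#' `(1 - alpha_true) phi (1 - phi)` (shape parameters
#' `a = w phi`, `b = w (1 - phi)` with `w = alpha_true / (1 - alpha_true)`),
#' and `k ~ Binomial(n, P)`. The limits are handled as the continuous
#' limits of the density: `alpha_true = 1` gives `P = phi` exactly
#' (binomial outcomes), `alpha_true = 0` gives the two-point mixture
#' `P = 1` with probability `phi`, `P = 0` otherwise.
#'
#' @param N number of records.
#' @param n shots per record (2 during two-way shooting TPS).
#' @param alpha_true accuracy of the committor model in `[0, 1]`.
#' @param phi_sampler function of a count returning committor draws
#'   (default: uniform on `(0.05, 0.95)`).
#' @param seed integer seed.
#' @param n_chains spread records over this many chain ids (for
#'   cross-validation workflows).
#' @return tibble with columns `id`, `chain_id`, `phi`, `p_true`, `n`, `k`.
#' @examples
#' generate_shot_records(5, n = 2, alpha_true = 0.9, seed = 1)
#' @export
generate_shot_records <- function(N, n = 2, alpha_true,
                                  phi_sampler = function(m) runif(m, 0.05, 0.95),
                                  seed = NULL, n_chains = 1) {
  stopifnot(alpha_true >= 0, alpha_true <= 1, n >= 1, N >= 1)
  if (!is.null(seed)) set.seed(seed)
  phi <- phi_sampler(N)
  if (alpha_true >= 1) {
    p <- phi
  } else if (alpha_true <= 0) {
    p <- as.numeric(runif(N) < phi)
  } else {
    w <- alpha_true / (1 - alpha_true)
    p <- rbeta(N, w * phi, w * (1 - phi))
  }
  k <- rbinom(N, size = n, prob = p)
  tibble::tibble(
    id = seq_len(N),
    chain_id = rep_len(seq_len(n_chains), N),
    phi = phi,
    p_true = p,
    n = as.integer(n),
    k = as.integer(k)
  )
}

#' Randomly censored exponential lifetimes
#'
#' Draws exponential durations with mean `1 / rate`; draws exceeding
#' `t_censor` are reported at the censoring time with `censored = TRUE`
#' (the run ended with the pore still open).
#'
#' @param rate exponential rate (1 / mean lifetime).
#' @param t_censor censoring time (same units); `Inf` disables censoring.
#' @param N number of runs.
#' @param seed integer seed.
#' @return tibble with columns `time`, `censored`.
#' @export
generate_censored_lifetimes <- function(rate, t_censor, N, seed = NULL) {
  stopifnot(rate > 0, t_censor > 0, N >= 1)
  if (!is.null(seed)) set.seed(seed)
  t <- rexp(N, rate = rate)
  censored <- t >= t_censor
  tibble::tibble(time = pmin(t, t_censor), censored = censored)
}
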