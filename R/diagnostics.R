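#' Sampler efficiency from expected vs generated transition paths
#'
#' Compares the number of actually generated transition paths to the
#' number expected under the committor model: `n_exp` is the cumulative
#' sum of `P(TP | x) = 2 phi (1 - phi)` over shooting points, `n_gen`
#' the cumulative count of shots that produced a transition path, and
#' `eta_dn(n) = 1 - (n_exp - n_gen) / n` with `n` the MC step count. An
#' efficiency near 1 means the model committor explains the observed
#' transition-path yield.
#'
#' @param records tibble ordered by MC index with columns `phi` (model
#'   committor at the shooting point) and `generated` (logical: did the
#'   shot produce a transition path?), e.g. a `tps_chain` log.
#' @return tibble with `mc_index`, `n_exp`, `n_gen`, `eta_dn`.
#' @examples
#' r <- tibble::tibble(phi = rep(0.5, 4), generated = c(TRUE, FALSE, TRUE, FALSE))
#' efficiency_dn(r)
#' @export
efficiency_dn <- function(records) {
  stopifnot(all(c("phi", "generated") %in% names(records)))
  n <- nrow(records)
  n_exp <- cumsum(p_tp(records$phi))
  n_gen <- cumsum(as.numeric(records$generated))
  tibble::tibble(
    mc_index = seq_len(n),
    n_exp = n_exp,
    n_gen = n_gen,
    eta_dn = 1 - (n_exp - n_gen) / seq_len(n)
  )
}

#' Sampler efficiency from simulation time
#'
#' `eta_T = T_TP / T_all`: the fraction of total propagated simulation
#' time spent inside newly accepted transition paths.
#'
#' @param chain_log a `tps_chain`, or any list/tibble exposing final
#'   `T_TP` and `T_all`.
#' @return scalar in `[0, 1]`.
#' @export
efficiency_time <- function(chain_log) {
  if (inherits(chain_log, "tps_chain")) {
    T_TP <- chain_log$T_TP; T_all <- chain_log$T_all
  } else if (is.data.frame(chain_log)) {
    T_TP <- chain_log$T_TP[nrow(chain_log)]
    T_all <- chain_log$T_all[nrow(chain_log)]
  } else {
    T_TP <- chain_log$T_TP; T_all <- chain_log$T_all
  }
  if (is.na(T_all) || T_all <= 0) stop("T_all must be positive.", call. = FALSE)
  if (T_TP > T_all) stop("T_TP exceeds T_all.", call. = FALSE)
  T_TP / T_all
}

#' Beta-binomial log-probability of shooting outcomes
#'
#' Convolving the binomial outcome distribution with a Beta distribution
#' of the true commitment probability around the model committor `phi`
#' (mean `phi`, variance `(1 - alpha) phi (1 - phi)`) yields a
#' beta-binomial:
#' `p(k | n, phi, alpha) = C(n, k) B(w phi + k, w (1 - phi) + n - k) / B(w phi, w (1 - phi))`
#' with `w = alpha / (1 - alpha)`. The limits are exact: `alpha -> 1`
#' recovers the binomial, `alpha -> 0` the two-point mixture with mass
#' `phi` at `k = n` and `1 - phi` at `k = 0`.
#'
#' @param k hit counts (0..n).
#' @param n shot counts.
#' @param phi model committor in (0, 1).
#' @param alpha accuracy in `[0, 1]`.
#' @return log probabilities (vectorized over the longest argument).
#' @export
betabinom_logpmf <- function(k, n, phi, alpha) {
  m <- max(length(k), length(n), length(phi), length(alpha))
  k <- rep_len(k, m); n <- rep_len(n, m)
  phi <- rep_len(phi, m); alpha <- rep_len(alpha, m)
  if (any(k < 0 | k > n | k != round(k))) {
    stop("`k` must be an integer in 0..n.", call. = FALSE)
  }
  if (any(phi <= 0 | phi >= 1)) stop("`phi` must lie strictly in (0, 1).",
                                     call. = FALSE)
  if (any(alpha < 0 | alpha > 1)) stop("`alpha` must lie in [0, 1].",
                                       call. = FALSE)
  out <- numeric(m)
  hi <- alpha >= 1 - 1e-12
  lo <- alpha <= 1e-12
  mid <- !hi & !lo
  if (any(hi)) out[hi] <- dbinom(k[hi], n[hi], phi[hi], log = TRUE)
  if (any(lo)) {
    out[lo] <- ifelse(k[lo] == 0, log(1 - phi[lo]),
                      ifelse(k[lo] == n[lo], log(phi[lo]), -Inf))
  }
  if (any(mid)) {
    w <- alpha[mid] / (1 - alpha[mid])
    out[mid] <- lchoose(n[mid], k[mid]) +
      lbeta(w * phi[mid] + k[mid], w * (1 - phi[mid]) + n[mid] - k[mid]) -
      lbeta(w * phi[mid], w * (1 - phi[mid]))
  }
  out
}

betabinom_loglik <- function(alpha, k, n, phi) {
  sum(betabinom_logpmf(k, n, phi, alpha))
}

#' Estimate committor-model accuracy
#'
#' Maximizes the beta-binomial log-posterior
#' `L(alpha) = sum_i ln p(k_i | n_i, phi_i, alpha)` over the accuracy
#' `alpha` on a dense grid (resolution `grid_step`) with local
#' refinement. `alpha = 1` means the model fully explains the shot
#' outcomes (`P_i = phi_i`); `alpha = 0` means the outcomes look fully
#' committed (`P` in {0, 1}), i.e. the model has no predictive power. A
#' flat prior on `[0, 1]` is assumed.
#'
#' @param records tibble with columns `phi`, `n`, `k` (model committor
#'   attached to each shooting record).
#' @param grid_step grid resolution for the posterior curve.
#' @param eps records with `phi` outside `(eps, 1 - eps)` are clamped.
#' @return An `accuracy_fit`: `alpha_hat`, `curve` (tibble of `alpha`,
#'   `log_posterior`), `n_records`.
#' @export
estimate_accuracy <- function(records, grid_step = 1e-3, eps = 1e-6) {
  stopifnot(nrow(records) > 0)
  phi <- pmin(pmax(records$phi, eps), 1 - eps)
  k <- records$k; n <- records$n
  grid <- seq(0, 1, by = grid_step)
  lp <- vapply(grid, betabinom_loglik, numeric(1), k = k, n = n, phi = phi)
  i <- which.max(lp)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(betabinom_loglik, c(lo, hi), maximum = TRUE,
                  k = k, n = n, phi = phi, tol = 1e-8)
  alpha_hat <- if (opt$objective >= lp[i]) opt$maximum else grid[i]
  structure(list(alpha_hat = alpha_hat,
                 curve = tibble::tibble(alpha = grid, log_posterior = lp),
                 n_records = nrow(records)),
            class = "accuracy_fit")
}

#' @export
print.accuracy_fit <- function(x, ...) {
  cat("<accuracy_fit> alpha_hat =", signif(x$alpha_hat, 4),
      " (", x$n_records, "records )\n")
  if (!is.null(x$percentiles)) {
    cat("  bootstrap percentiles:",
        paste(names(x$percentiles), signif(x$percentiles, 3),
              sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
tidy.accuracy_fit <- function(x, ...) x$curve

#' @export
glance.accuracy_fit <- function(x, ...) {
  out <- tibble::tibble(alpha_hat = x$alpha_hat, n_records = x$n_records)
  if (!is.null(x$percentiles)) {
    out <- dplyr::bind_cols(out, tibble::as_tibble(as.list(x$percentiles)))
  }
  out
}

#' Bootstrap / cross-validated accuracy estimate
#'
#' Repeats `n_cv` times: hold out one MC chain as the validation set
#' (optionally refitting the committor model on the remaining chains via
#' `refit_fn`), then estimate the accuracy on `n_boot` bootstrap
#' resamples (with replacement) of the held-out chain. Percentiles
#' (2.5/25/50/75/97.5, the box-and-whisker convention) are pooled over
#' all `n_cv * n_boot` resamples.
#'
#' @param records tibble with `phi`, `n`, `k` and `chain_id`.
#' @param n_cv number of held-out rounds (cycling through the chains).
#' @param n_boot bootstrap resamples per round.
#' @param refit_fn optional `function(train_records)` returning a model
#'   whose `predict_phi()` refreshes `phi` on the held-out chain; `NULL`
#'   keeps the stored `phi` (fixed-model bootstrap).
#' @param min_records chains with fewer records are skipped with a
#'   warning.
#' @param seed integer seed.
#' @return An `accuracy_fit` with `percentiles` and `boot` (all
#'   resampled alpha values) attached.
#' @export
bootstrap_accuracy <- function(records, n_cv = 10, n_boot = 100,
                               refit_fn = NULL, min_records = 10, seed = 1) {
  stopifnot("chain_id" %in% names(records))
  chains <- unique(records$chain_id)
  if (length(chains) < 2) stop("need at least 2 chains.", call. = FALSE)
  set.seed(seed)
  held_out <- rep_len(chains, n_cv)
  boots <- numeric(0)
  for (r in seq_len(n_cv)) {
    val <- records[records$chain_id == held_out[r], ]
    if (nrow(val) < min_records) {
      warning(sprintf("chain %s has fewer than %d records; skipped",
                      held_out[r], min_records), call. = FALSE)
      next
    }
    if (!is.null(refit_fn)) {
      train <- records[records$chain_id != held_out[r], ]
      model <- refit_fn(train)
      val$phi <- predict_phi(model, record_features(val))
    }
    for (b in seq_len(n_boot)) {
      idx <- sample.int(nrow(val), nrow(val), replace = TRUE)
      boots <- c(boots, estimate_accuracy(val[idx, ], grid_step = 0.005)$alpha_hat)
    }
  }
  if (length(boots) == 0) stop("no usable chains.", call. = FALSE)
  fit <- estimate_accuracy(records)
  fit$percentiles <- quantile(boots, c(0.025, 0.25, 0.5, 0.75, 0.975),
                              names = TRUE)
  fit$boot <- boots
  fit
}

#' Logit-logit calibration of a committor model
#'
#' Validation shots with larger `n` (20 in the reference protocol) give
#' direct estimates `k / n` of the true committor. A line is fitted to
#' the actual logit `ln[k / (n - k)]` against the model-predicted logit,
#' `q_lin = c q + d`, by least squares; records with `k = 0` or `k = n`
#' (infinite actual logit) are excluded from the fit. The spread of the
#' data around the line is summarized by
#' `Delta phi_lin(phi) = sqrt(1 - alpha (1 - 1/n)) sqrt(phi (1 - phi))`
#' with `alpha` estimated jointly from the same records.
#'
#' @param validation_records tibble with `phi` (model committor), `n`,
#'   `k`; `n >= 2` required.
#' @param model optional committor model used to (re)compute `phi` from
#'   the record features.
#' @return A `calibration_fit`: `slope`, `intercept`, `alpha`, `n_shots`
#'   (typical `n`), `spread` (function of `phi_lin`), `data` (tibble of
#'   logits used).
#' @export
calibration_fit <- function(validation_records, model = NULL) {
  records <- validation_records
  stopifnot(all(records$n >= 2))
  if (!is.null(model)) {
    records$phi <- predict_phi(model, record_features(records))
  }
  usable <- records$k > 0 & records$k < records$n
  if (sum(usable) < 3) stop("fewer than 3 usable validation records.",
                            call. = FALSE)
  d <- records[usable, ]
  q_pred <- log(d$phi / (1 - d$phi))
  q_act <- log(d$k / (d$n - d$k))
  fit <- lm(q_act ~ q_pred)
  alpha <- estimate_accuracy(records)$alpha_hat
  n_typ <- stats::median(records$n)
  spread <- function(phi_lin) {
    sqrt(1 - alpha * (1 - 1 / n_typ)) * sqrt(phi_lin * (1 - phi_lin))
  }
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 alpha = alpha, n_shots = n_typ, spread = spread,
                 n_used = sum(usable), n_excluded = sum(!usable),
                 data = tibble::tibble(q_pred = q_pred, q_act = q_act)),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("<calibration_fit> q_act =", signif(x$slope, 4), "* q_pred +",
      signif(x$intercept, 4), "\n")
  cat("  alpha =", signif(x$alpha, 4), "; records used:", x$n_used,
      "( excluded k in {0, n}:", x$n_excluded, ")\n")
  invisible(x)
}

#' @export
tidy.calibration_fit <- function(x, ...) {
  tibble::tibble(term = c("slope", "intercept", "alpha"),
                 estimate = c(x$slope, x$intercept, x$alpha))
}

#' @export
glance.calibration_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, alpha = x$alpha,
                 n_used = x$n_used, n_excluded = x$n_excluded,
                 n_shots = x$n_shots)
}
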