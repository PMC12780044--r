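test_that("eta_dn matches hand arithmetic", {
  # alternating generated paths at phi = 0.5: expected and generated counts
  # agree at every even step, so eta_dn = 1 there
  r <- tibble::tibble(phi = rep(0.5, 10),
                      generated = rep(c(FALSE, TRUE), 5))
  eff <- efficiency_dn(r)
  expect_equal(eff$eta_dn[seq(2, 10, 2)], rep(1, 5))
  # no transition path ever at phi = 0.5: eta = 1 - 0.5
  r2 <- tibble::tibble(phi = rep(0.5, 50), generated = FALSE)
  expect_equal(efficiency_dn(r2)$eta_dn, rep(0.5, 50))
})

test_that("eta_dn converges to 1 for Bernoulli-generated transition paths", {
  set.seed(17)
  finals <- replicate(100, {
    phi <- runif(400, 0.05, 0.95)
    gen <- runif(400) < p_tp(phi)
    eff <- efficiency_dn(tibble::tibble(phi = phi, generated = gen))
    eff$eta_dn[400]
  })
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - 1), 3 * se)
})

test_that("eta_T is the stated time ratio", {
  expect_equal(efficiency_time(list(T_TP = 3, T_all = 12)), 0.25)
  expect_equal(efficiency_time(list(T_TP = 7, T_all = 7)), 1)
  expect_equal(efficiency_time(list(T_TP = 0, T_all = 5)), 0)
  expect_error(efficiency_time(list(T_TP = 0, T_all = 0)), "positive")
  expect_error(efficiency_time(list(T_TP = 2, T_all = 1)), "exceeds")
})

test_that("beta-binomial limits recover the binomial and the mixture", {
  expect_equal(betabinom_logpmf(1, 2, 0.5, 1), log(0.5))
  expect_equal(betabinom_logpmf(2, 2, 0.3, 0), log(0.3))
  expect_equal(betabinom_logpmf(0, 2, 0.3, 0), log(0.7))
  expect_identical(betabinom_logpmf(1, 2, 0.3, 0), -Inf)
  expect_error(betabinom_logpmf(3, 2, 0.5, 0.5), "0..n")
  expect_error(betabinom_logpmf(1, 2, 0, 0.5), "strictly")
})

test_that("beta-binomial matches quadrature of the stated convolution", {
  cases <- expand.grid(n = c(2, 5, 20), phi = c(0.1, 0.4, 0.7),
                       alpha = c(0.2, 0.6, 0.95))
  for (i in seq_len(nrow(cases))) {
    n <- cases$n[i]; phi <- cases$phi[i]; alpha <- cases$alpha[i]
    for (k in 0:n) {
      expect_lt(abs(exp(betabinom_logpmf(k, n, phi, alpha)) -
                      betabinom_quadrature(k, n, phi, alpha)), 1e-8)
    }
    p <- exp(betabinom_logpmf(0:n, n, phi, alpha))
    expect_equal(sum(p), 1, tolerance = 1e-10)
    expect_equal(sum((0:n) * p), n * phi, tolerance = 1e-8)
  }
})

test_that("accuracy estimation is invariant under record duplication", {
  r <- generate_shot_records(400, n = 2, alpha_true = 0.7, seed = 5)
  f1 <- estimate_accuracy(r)
  f2 <- estimate_accuracy(dplyr::bind_rows(r, r))
  expect_equal(f1$alpha_hat, f2$alpha_hat, tolerance = 1e-8)
  expect_equal(f1$alpha_hat,
               f1$curve$alpha[which.max(f1$curve$log_posterior)],
               tolerance = 2e-3)
  expect_error(estimate_accuracy(r[0, ]))
})

test_that("accuracy recovers a planted value and its limits", {
  r <- generate_shot_records(10000, n = 2, alpha_true = 0.9, seed = 8)
  expect_lt(abs(estimate_accuracy(r)$alpha_hat - 0.9), 0.05)
  r_bin <- generate_shot_records(5000, n = 2, alpha_true = 1, seed = 9)
  expect_gt(estimate_accuracy(r_bin)$alpha_hat, 0.95)
  r_anti <- generate_shot_records(5000, n = 2, alpha_true = 0, seed = 10,
                                  phi_sampler = function(m) rep(0.5, m))
  expect_lt(estimate_accuracy(r_anti)$alpha_hat, 0.05)
})

test_that("bootstrap percentiles are ordered, reproducible and near 1 for binomial data", {
  r <- generate_shot_records(2000, n = 2, alpha_true = 1, seed = 12,
                             n_chains = 4)
  fit <- bootstrap_accuracy(r, n_cv = 4, n_boot = 30, seed = 2)
  pc <- fit$percentiles
  expect_true(all(diff(pc) >= 0))
  expect_gt(pc[["50%"]], 0.9)
  fit2 <- bootstrap_accuracy(r, n_cv = 4, n_boot = 30, seed = 2)
  expect_identical(fit$boot, fit2$boot)
  expect_error(bootstrap_accuracy(dplyr::mutate(r, chain_id = 1)), "2 chains")
})

test_that("calibration recovers a planted logit offset", {
  set.seed(30)
  n <- 20
  q <- runif(2000, -2, 2)
  p_true <- stats::plogis(q)
  recs <- tibble::tibble(phi = stats::plogis(q + 1),  # model logit shifted +1
                         n = n, k = rbinom(2000, n, p_true))
  fit <- calibration_fit(recs)
  expect_lt(abs(fit$slope - 1), 0.1)
  expect_lt(abs(fit$intercept - (-1)), 0.15)
  expect_equal(fit$n_used + fit$n_excluded, 2000)
})

test_that("the calibration spread vanishes for a perfect model at large n", {
  set.seed(31)
  q <- runif(1500, -2, 2)
  recs <- tibble::tibble(phi = stats::plogis(q), n = 50,
                         k = rbinom(1500, 50, stats::plogis(q)))
  fit <- calibration_fit(recs)
  # alpha near 1 and n large: Delta phi_lin = sqrt(1 - alpha(1 - 1/n)) *
  # sqrt(phi(1-phi)) collapses toward 0
  expect_gt(fit$alpha, 0.9)
  expect_lt(fit$spread(0.5), sqrt(1 - 0.9 * (1 - 1 / 50)) * 0.5 + 0.05)
  # exact formula limit
  alpha1 <- function(n) sqrt(1 - 1 * (1 - 1 / n)) * sqrt(0.25)
  expect_lt(alpha1(1e8), 1e-3)
  expect_error(calibration_fit(recs[1:2, ]), "usable")
})
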