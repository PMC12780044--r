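test_that("the pore center finds a head cluster, wrapped and equivariant", {
  params <- pore_params_preset("martini")
  heads <- tibble::tibble(x = rep(3, 8), y = rep(3, 8),
                          z = 3 + c(rep(0.9, 4), rep(-0.9, 4)),
                          type = rep(c("head_P", "head_N"), 4))
  cfg <- membrane_config(heads, box = c(12, 12, 6), midplane_z = 3)
  expect_equal(pore_center(cfg, params), c(3, 3), tolerance = 1e-9)
  # cluster straddling the periodic boundary near x = 0/12
  set.seed(2)
  xs <- (rnorm(40, 0, 0.3)) %% 12
  heads2 <- tibble::tibble(x = xs, y = rep(5, 40),
                           z = 3 + rnorm(40, 0, 0.3), type = "head_P")
  cfg2 <- membrane_config(heads2, box = c(12, 12, 6), midplane_z = 3)
  ctr <- pore_center(cfg2, params)
  w <- exp(-((heads2$z - 3) %% 6 - 6 * round(((heads2$z - 3) %% 6) / 6))^2 /
             (2 * (params$Z_mem / 2)^2))
  bf <- brute_force_periodic_center(heads2$x, w, 12)
  dd <- abs(ctr[1] - bf); dd <- min(dd, 12 - dd)
  expect_lt(dd, 0.05)
  # equivariance under periodic translation
  cfg3 <- membrane_config(dplyr::mutate(heads2, x = x + 1, y = y + 1),
                          box = c(12, 12, 6), midplane_z = 3)
  ctr3 <- pore_center(cfg3, params)
  expect_equal((ctr3 - ctr) %% 12, c(1, 1), tolerance = 1e-6)
  expect_error(pore_center(membrane_config(heads2[0, ], box = c(12, 12, 6)),
                           params), "head")
})

test_that("slab occupancies give exact chain-coordinate values", {
  params <- pore_params_preset("martini")
  expect_equal(xi_chain(slab_config(integer(0)), c(3, 3), params)$xi_ch, 0)
  expect_equal(xi_chain(slab_config(c(1, 3)), c(3, 3), params)$xi_ch, 0.5)
  expect_equal(xi_chain(slab_config(1:4), c(3, 3), params)$xi_ch, 1)
  occ <- xi_chain(slab_config(c(2, 4)), c(3, 3), params)$occupancy
  expect_identical(occ, c(0L, 1L, 0L, 1L))
  # polar particles outside the cylinder do not count
  cfg_far <- slab_config(1:4)
  expect_equal(xi_chain(cfg_far, c(0.5, 0.5), params)$xi_ch, 0)
})

test_that("the pore radius follows the cylindrical water-count formula", {
  params <- pore_params_preset("martini")
  expect_equal(pore_radius(slab_config(integer(0)), c(3, 3), params), 0)
  n_w <- 40
  mid <- 3
  wat <- tibble::tibble(x = 3 + runif(n_w, -0.1, 0.1),
                        y = 3 + runif(n_w, -0.1, 0.1),
                        z = mid + seq(-0.8, 0.8, length.out = n_w),
                        type = "water_O")
  cfg <- membrane_config(wat, box = c(6, 6, 6))
  R1 <- pore_radius(cfg, c(3, 3), params)
  expect_equal(R1, sqrt(n_w * params$v_w / (pi * params$Z_mem)))
  cfg2 <- membrane_config(dplyr::bind_rows(wat, dplyr::mutate(wat, x = x + 0.05)),
                          box = c(6, 6, 6))
  expect_equal(pore_radius(cfg2, c(3, 3), params), sqrt(2) * R1,
               tolerance = 1e-10)
})

test_that("xi_P combines nucleation and expansion continuously", {
  params <- pore_params_preset("martini")
  # nucleation branch: xi_ch = 0.5 -> xi_P = 0.5 / 0.9
  st <- xi_p(slab_config(c(1, 3)), params)
  expect_equal(st$xi_p, 0.5 / 0.9)
  # boundary consistency: a just-nucleated pore reads xi_P = 1 when R = R0
  n_w0 <- round(params$R0^2 * pi * params$Z_mem / params$v_w)
  mid <- 3
  wat <- tibble::tibble(x = 3, y = 3,
                        z = mid + seq(-0.85, 0.85, length.out = n_w0),
                        type = "water_O")
  heads <- tibble::tibble(x = 3, y = 3, z = c(1.7, 4.3),
                          type = c("head_P", "head_N"))
  cfg <- membrane_config(dplyr::bind_rows(heads, wat), box = c(6, 6, 6))
  st2 <- xi_p(cfg, params)
  expect_equal(st2$xi_ch, 1)
  expect_equal(st2$R, params$R0, tolerance = 0.02)
  expect_equal(st2$xi_p, 1, tolerance = 0.06)
  # expansion branch: R = 2 R0 -> xi_P = 2
  wat2 <- dplyr::bind_rows(lapply(0:3, function(i)
    dplyr::mutate(wat, x = x + 0.03 * i)))
  cfg2 <- membrane_config(dplyr::bind_rows(heads, wat2), box = c(6, 6, 6))
  st3 <- xi_p(cfg2, params)
  expect_equal(st3$R, 2 * params$R0, tolerance = 0.02)
  expect_equal(st3$xi_p, 2, tolerance = 0.06)
})

test_that("xi_P grows monotonically as a spanning water column fills in", {
  params <- pore_params_preset("martini")
  mid <- 3
  heads <- tibble::tibble(x = 3, y = 3, z = c(1.7, 4.3),
                          type = c("head_P", "head_N"))
  vals <- vapply(c(0, 5, 10, 20, 40, 80, 160), function(nw) {
    wat <- if (nw > 0) tibble::tibble(
      x = 3, y = 3, z = mid + seq(-0.85, 0.85, length.out = nw),
      type = "water_O") else NULL
    xi_p(membrane_config(dplyr::bind_rows(heads, wat), box = c(6, 6, 6)),
         params)$xi_p
  }, numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_lt(vals[1], 0.3)
  expect_gt(vals[length(vals)], 1.5)
})

test_that("pore descriptors are invariant under periodic translation", {
  params <- pore_params_preset("martini")
  cfg <- planted_pore_config(0.4, seed = 6)
  ref <- xi_p(cfg, params)
  set.seed(7)
  for (i in 1:3) {
    shift <- runif(3, -4, 4)
    shifted <- dplyr::mutate(as.data.frame(cfg),
                             x = x + shift[1], y = y + shift[2],
                             z = z + 0)
    cfg_s <- membrane_config(shifted, box = attr(cfg, "box"),
                             midplane_z = attr(cfg, "midplane_z"))
    st <- xi_p(cfg_s, params)
    expect_equal(st$xi_ch, ref$xi_ch, tolerance = 1e-9)
    expect_equal(st$R, ref$R, tolerance = 1e-9)
    expect_equal(st$xi_p, ref$xi_p, tolerance = 1e-9)
  }
})

test_that("depletion features equal a brute-force sort-and-average oracle", {
  set.seed(8)
  df <- tibble::tibble(
    x = runif(20, 0, 6), y = runif(20, 0, 6), z = runif(20, 1, 5),
    type = sample(c("head_P", "head_N", "water_O", "tail_C"), 20, TRUE)
  )
  cfg <- membrane_config(df, box = c(6, 6, 6))
  center <- c(2, 2)
  feats <- depletion_features(cfg, center = center)
  mi <- function(d, L) d - L * round(d / L)
  sel <- df[df$type %in% c("head_P", "head_N"), ]
  dx <- mi(sel$x - 2, 6); dy <- mi(sel$y - 2, 6); dz <- mi(sel$z - 3, 6)
  d_lat <- sort(sqrt(dx^2 + dy^2))
  got <- feats$value[feats$group == "NP" & feats$metric == "lateral" &
                       feats$feature == "mean3"]
  expect_equal(got, mean(d_lat[1:3]))
  got_iso <- feats$value[feats$group == "water_O" &
                           feats$metric == "isotropic" & feats$feature == "d1"]
  selw <- df[df$type == "water_O", ]
  dxw <- mi(selw$x - 2, 6); dyw <- mi(selw$y - 2, 6); dzw <- mi(selw$z - 3, 6)
  expect_equal(got_iso, min(sqrt(dxw^2 + dyw^2 + dzw^2)))
  # permutation invariance
  feats2 <- depletion_features(
    membrane_config(df[sample(20), ], box = c(6, 6, 6)), center = center)
  expect_equal(feats$value, feats2$value)
  # missing ranks for a tiny group
  one <- membrane_config(
    tibble::tibble(x = 4, y = 2, z = 3, type = "head_P"), box = c(6, 6, 6))
  f1 <- depletion_features(one, center = c(2, 2))
  expect_equal(f1$value[f1$group == "P" & f1$metric == "lateral" &
                          f1$feature == "d1"], 2)
  expect_true(is.na(f1$value[f1$group == "P" & f1$metric == "lateral" &
                               f1$feature == "d2"]))
})

test_that("the censored-exponential lifetime MLE matches closed forms and survreg", {
  expect_equal(pore_lifetime_mle(c(1, 2, 3))$tau_hat, 2)
  fit <- pore_lifetime_mle(c(2, 3), censored = c(FALSE, TRUE))
  expect_equal(fit$tau_hat, 5)
  expect_error(pore_lifetime_mle(c(1, 2), censored = c(TRUE, TRUE)),
               "lower bound")
  # tau_hat maximizes the stored profile log-likelihood
  d <- generate_censored_lifetimes(2.5, 0.5, 500, seed = 9)
  fit2 <- pore_lifetime_mle(d)
  best_rate <- fit2$log_lik$rate[which.max(fit2$log_lik$log_lik)]
  expect_equal(1 / best_rate, fit2$tau_hat, tolerance = 2e-2)
  opt <- optimize(function(k) fit2$n_closures * log(k) - k * sum(d$time),
                  c(1e-3, 100), maximum = TRUE, tol = 1e-10)
  expect_equal(1 / opt$maximum, fit2$tau_hat, tolerance = 1e-6)
  # independent oracle: exponential AFT fit
  sr <- survival::survreg(survival::Surv(time, !censored) ~ 1, data = d,
                          dist = "exponential")
  expect_equal(unname(exp(coef(sr))), fit2$tau_hat, tolerance = 1e-6)
})
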