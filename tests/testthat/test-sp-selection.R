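make_test_path <- function(n_frames = 200, seed = 1) {
  # synthetic 1D "path": interior frames spread over the barrier region
  set.seed(seed)
  x <- c(-0.95, sort(runif(n_frames - 2, -0.9, 0.9)), 0.95)
  pot <- dw_potential()
  tps_path(matrix(x, ncol = 1), dt = 1e-3,
           state_defs = double_well_states(pot))
}

test_that("selection weights are normalized and exclude the endpoints", {
  path <- make_test_path()
  w <- selection_weights(path, model = NULL, hist = NULL)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(w[1], 0)
  expect_equal(w[length(w)], 0)
  expect_true(all(abs(w[2:(length(w) - 1)] - w[2]) < 1e-15))  # uniform
})

test_that("an exactly Cauchy logit histogram gives uniform weights back", {
  # frames whose logits sit exactly at bin centers, with the histogram
  # density equal to Cauchy(0,1) there: the reweighting must cancel
  ctrl <- sp_control(bins = 50, clip = c(-10, 10))
  edges <- seq(-10, 10, length.out = 51)
  centers <- (edges[-1] + edges[-51]) / 2
  q <- centers[10:40]
  x <- q / 3
  frames <- matrix(c(-99, x, 99), ncol = 1)
  states <- list(state_interval("L", 1, hi = -98),
                 state_interval("U", 1, lo = 98))
  path <- tps_path(frames, dt = 1, state_defs = states, check = FALSE)
  model <- committor_fn(function(X) stats::plogis(3 * X[, 1]))
  hist <- build_logit_histogram(q, ctrl)
  hist$density <- stats::dcauchy(centers)
  hist$floor_density <- min(hist$density)
  w <- selection_weights(path, model, hist)
  inner <- w[2:(length(w) - 1)]
  expect_lt(diff(range(inner)) / mean(inner), 1e-6)
})

test_that("reweighted selection draws logits from Cauchy(0,1)", {
  # frames whose logits cover (-4, 4); P_hat built from the frames
  # themselves, so selected logits should follow the restricted Cauchy
  set.seed(42)
  n <- 4000
  x <- runif(n, -4, 4)
  pot <- dw_potential()
  frames <- matrix(c(-99, x, 99), ncol = 1)
  states <- list(state_interval("L", 1, hi = -98),
                 state_interval("U", 1, lo = 98))
  path <- tps_path(frames, dt = 1, state_defs = states, check = FALSE)
  model <- committor_fn(function(X) stats::plogis(X[, 1]))
  ctrl <- sp_control(bins = 40, clip = c(-4, 4))
  hist <- build_logit_histogram(x, ctrl)
  w <- selection_weights(path, model, hist)
  draws <- sample(seq_along(w), 3e4, replace = TRUE, prob = w)
  q_sel <- x[draws - 1]
  # chi-square against Cauchy mass per histogram bin, restricted to (-4, 4)
  edges <- hist$edges
  mass <- diff(stats::pcauchy(edges))
  mass <- mass / sum(mass)
  obs <- tabulate(findInterval(q_sel, edges, rightmost.closed = TRUE),
                  nbins = 40)
  keep <- mass * length(q_sel) >= 5
  chi <- sum((obs[keep] - length(q_sel) * mass[keep])^2 /
               (length(q_sel) * mass[keep]))
  p <- stats::pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("select_sp draws the stated categorical distribution", {
  path <- make_test_path(12)
  w <- numeric(12); w[7] <- 1
  expect_equal(select_sp(path, w, seed = 1), 7L)
  w_u <- selection_weights(path, NULL, NULL)
  set.seed(2)
  draws <- replicate(20000, select_sp(path, w_u))
  obs <- tabulate(draws, nbins = 12)[2:11]
  expected <- rep(20000 / 10, 10)
  chi <- sum((obs - expected)^2 / expected)
  expect_gt(stats::pchisq(chi, df = 9, lower.tail = FALSE), 0.01)
  expect_identical(select_sp(path, w_u, seed = 5), select_sp(path, w_u, seed = 5))
})

test_that("the histogram schedule is uniform, then built, then refreshed", {
  ctrl <- sp_control(build_at = 100, refresh_every = 250)
  expect_identical(update_schedule(99, ctrl), "uniform")
  expect_identical(update_schedule(100, ctrl), "build")
  expect_identical(update_schedule(101, ctrl), "reuse")
  expect_identical(update_schedule(349, ctrl), "reuse")
  expect_identical(update_schedule(350, ctrl), "refresh")
  expect_identical(update_schedule(600, ctrl), "refresh")
})

test_that("logit histograms integrate to one over the binned range", {
  set.seed(3)
  h <- build_logit_histogram(rnorm(5000), sp_control())
  width <- diff(h$edges)[1]
  expect_equal(sum(h$density) * width, 1, tolerance = 1e-12)
})
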