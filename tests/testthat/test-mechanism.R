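linear_model_10d <- function(v0, b = 0.3) {
  committor_fn(
    function(X) stats::plogis(as.numeric(X %*% v0) + b),
    function(X) {
      p <- stats::plogis(as.numeric(X %*% v0) + b)
      outer(p * (1 - p), v0)
    })
}

test_that("flux direction recovers a planted linear committor", {
  set.seed(14)
  v0 <- rnorm(10); v0 <- v0 / sqrt(sum(v0^2))
  model <- linear_model_10d(v0)
  X <- matrix(rnorm(10000 * 10), ncol = 10)
  fd <- flux_direction(model, X, phi_bins = 10)
  expect_equal(sqrt(sum(fd$v^2)), 1, tolerance = 1e-12)
  expect_gt(sum(fd$v * v0), 0.999)
  expect_gt(fd$linearity, 0.99)
  for (vb in fd$bins$v) expect_equal(sqrt(sum(vb^2)), 1, tolerance = 1e-12)
})

test_that("a radially symmetric committor fails the linearity score", {
  set.seed(15)
  model <- committor_fn(function(X) stats::plogis(sqrt(rowSums(X^2)) - 3))
  X <- matrix(rnorm(6000 * 10), ncol = 10)
  fd <- flux_direction(model, X, phi_bins = 10)
  expect_lt(fd$linearity, 0.5)
})

test_that("feature projection behaves like an inner product", {
  X <- matrix(rnorm(50 * 4), ncol = 4)
  e2 <- c(0, 1, 0, 0)
  expect_equal(project_features(X, e2), X[, 2])
  v <- c(1, 1, 0, 0) / sqrt(2)
  perp <- c(0, 0, 3, -2)  # orthogonal to v
  expect_equal(project_features(sweep(X, 2, perp, "+"), v),
               project_features(X, v))
  expect_error(project_features(X, c(1, 2)), "dimension")
  # monotone map preserves committor order exactly
  v0 <- rnorm(4)
  phi <- stats::plogis(project_features(X, v0))
  expect_equal(cor(project_features(X, v0), phi, method = "spearman"), 1)
})

test_that("a low-dimensional model on x.v reproduces a linear committor", {
  set.seed(16)
  v0 <- c(0.8, -0.6)
  X <- matrix(rnorm(4000 * 2), ncol = 2)
  phi_true <- stats::plogis(2 * as.numeric(X %*% v0))
  k <- rbinom(4000, 2, phi_true)
  recs <- tibble::tibble(x = as.numeric(X %*% v0), n = 2L, k = k,
                         chain_id = rep_len(1:3, 4000))
  m <- fit_lowdim_committor(recs, epochs_max = 200, lr = 5e-3,
                            patience = 40, seed = 2)
  phi_hat <- predict_phi(m, matrix(recs$x, ncol = 1))
  expect_gt(cor(phi_hat, phi_true), 0.99)
  expect_s3_class(m$alpha, "accuracy_fit")
})

test_that("a constant input has no predictive power", {
  set.seed(17)
  recs <- tibble::tibble(x = rep(1, 3000), n = 2L,
                         k = ifelse(runif(3000) < 0.5, 0L, 2L),
                         chain_id = rep_len(1:3, 3000))
  m <- fit_lowdim_committor(recs, epochs_max = 60, lr = 5e-3,
                            patience = 60, seed = 3)
  expect_lt(m$alpha$alpha_hat, 0.2)
})

test_that("k-NN density is uniform on a disc and scales with k", {
  set.seed(18)
  n <- 10000
  r <- sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
  pts <- cbind(r * cos(th), r * sin(th))
  interior <- pts[r < 0.6, ][1:500, ]
  d50 <- knn_density(pts, k = 50, eval_points = interior)
  true_density <- n / pi  # points per unit area
  est <- 50 / pi * d50$density  # r^-2 * k / pi = count / area
  rel_err <- abs(est - true_density) / true_density
  # pointwise k-NN noise is ~ 2/sqrt(k); the estimate must be right on
  # average and within 20% for the bulk of the points
  expect_lt(abs(mean(est) / true_density - 1), 0.1)
  expect_lt(median(rel_err), 0.2)
  d100 <- knn_density(pts, k = 100, eval_points = interior)
  ratio <- mean(d100$r_k / d50$r_k)
  expect_lt(abs(ratio - sqrt(2)), 0.05)
})

test_that("k-NN density is permutation invariant and peaks at a cluster", {
  set.seed(19)
  pts <- rbind(matrix(rnorm(400, sd = 3), ncol = 2),
               matrix(rnorm(100, sd = 0.05), ncol = 2))
  d1 <- knn_density(pts, k = 10)
  perm <- sample(nrow(pts))
  d2 <- knn_density(pts[perm, ], k = 10, eval_points = pts)
  expect_equal(d1$density, d2$density, tolerance = 1e-12)
  expect_gt(max(d1$density[201:250]), max(d1$density[1:200]))
})

test_that("the k-NN committor surface respects its degenerate limits", {
  set.seed(20)
  S <- matrix(runif(800), ncol = 2)
  Fm <- matrix(1, nrow = 400, ncol = 3)  # constant features
  grid <- list(s = seq(0.2, 0.8, by = 0.2), t = seq(0.2, 0.8, by = 0.2))
  v <- c(1, 1, 1)
  surf <- knn_committor_surface(S, Fm, grid, k = 20, v = v,
                                committor_1d = function(p) stats::plogis(p))
  expect_equal(var(surf$phi), 0)
  # k = N: every node sees the global mean
  Fm2 <- matrix(rnorm(1200), ncol = 3)
  surf2 <- knn_committor_surface(S, Fm2, grid, k = 400, v = v,
                                 committor_1d = function(p) p)
  expect_equal(var(surf2$proj), 0, tolerance = 1e-20)
  expect_equal(surf2$proj[1], sum(colMeans(Fm2) * v))
})

test_that("iso-lines of a planted linear committor surface are straight", {
  set.seed(21)
  S <- matrix(runif(10000, -1, 1), ncol = 2)
  Fm <- S  # features are the projection coordinates themselves
  v <- c(1, 0)
  grid <- list(s = seq(-0.6, 0.6, length.out = 7),
               t = seq(-0.6, 0.6, length.out = 7))
  surf <- knn_committor_surface(S, Fm, grid, k = 100, v = v,
                                committor_1d = function(p) stats::plogis(3 * p))
  wide <- tidyr::pivot_wider(surf[, c("s", "t", "phi")],
                             names_from = "t", values_from = "phi")
  m <- as.matrix(wide[, -1])
  # along t (columns) phi is constant; along s it increases
  expect_lt(max(apply(m, 1, sd)), 0.02)
  expect_true(all(diff(rowMeans(m)) > 0))
})

test_that("mechanism classification thresholds the smoothed series", {
  lg <- tibble::tibble(mc_index = 1:50, xi_hat = rep(0.1, 50))
  m <- classify_mechanism(lg)
  expect_true(all(m$mechanism == "Pi_T"))
  lg$xi_hat <- rep(2, 50)
  expect_true(all(classify_mechanism(lg)$mechanism == "Pi_P"))
  lg$xi_hat <- c(rep(0.1, 25), rep(2, 25))
  m3 <- classify_mechanism(lg, window = 1)
  expect_identical(attr(m3, "switches"), 26L)
})
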