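#' Reactive-flux direction in feature space
#'
#' Computes `v(phi) = <grad phi>_phi / |<grad phi>_phi|`, the unit
#' direction of the committor gradient averaged on iso-committor bins,
#' and the pooled global direction `v`. Gradients are taken with respect
#' to standardized features (zero mean, unit variance over the sample
#' set) because the feature vector mixes heterogeneous units. If the
#' per-bin directions hardly change with `phi` (minimum pairwise cosine
#' close to 1) the committor is quasi-linear in `x . v`.
#'
#' @param model a committor model with gradient access.
#' @param samples feature matrix.
#' @param phi_bins number of equal bins on `(phi_min, phi_max)`.
#' @param phi_range extreme-committor samples outside this range are
#'   excluded (near the state boundaries a linear model has to fail).
#' @param standardize standardize features before averaging gradients?
#' @return A `flux_direction`: global unit vector `v`, per-bin tibble
#'   (`bin`, `phi_mid`, `n`, one list-column of unit vectors), pairwise
#'   cosine matrix, `linearity` (minimum pairwise cosine).
#' @export
flux_direction <- function(model, samples, phi_bins = 10,
                           phi_range = c(0.05, 0.95), standardize = TRUE) {
  X <- as.matrix(samples)
  phi <- predict_phi(model, X)
  g <- committor_gradient(model, X)
  scale <- if (standardize) pmax(apply(X, 2, sd), 1e-12) else rep(1, ncol(X))
  g <- sweep(g, 2, scale, "*")  # gradient w.r.t. standardized features
  keep <- phi > phi_range[1] & phi < phi_range[2]
  if (!any(keep)) stop("no samples inside `phi_range`.", call. = FALSE)
  phi_k <- phi[keep]; g_k <- g[keep, , drop = FALSE]
  edges <- seq(phi_range[1], phi_range[2], length.out = phi_bins + 1)
  bin <- pmin(pmax(findInterval(phi_k, edges, rightmost.closed = TRUE), 1),
              phi_bins)
  unitize <- function(v) {
    nv <- sqrt(sum(v^2))
    if (nv == 0) return(rep(NA_real_, length(v)))
    v / nv
  }
  v_global <- unitize(colMeans(g_k))
  bins <- sort(unique(bin))
  if (length(bins) < phi_bins) {
    warning(sprintf("%d of %d committor bins are empty and were omitted",
                    phi_bins - length(bins), phi_bins), call. = FALSE)
  }
  v_bins <- lapply(bins, function(b) unitize(colMeans(g_k[bin == b, , drop = FALSE])))
  vb <- do.call(rbind, v_bins)
  cosmat <- vb %*% t(vb)
  bin_tbl <- tibble::tibble(
    bin = bins,
    phi_mid = (edges[bins] + edges[bins + 1]) / 2,
    n = as.integer(table(factor(bin, levels = bins))),
    v = v_bins
  )
  structure(list(v = v_global, bins = bin_tbl, cosine = cosmat,
                 linearity = min(cosmat),
                 feature_names = colnames(X) %||% paste0("x", seq_len(ncol(X))),
                 scale = scale),
            class = "flux_direction")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.flux_direction <- function(x, ...) {
  cat("<flux_direction>", length(x$v), "features,",
      nrow(x$bins), "committor bins; linearity (min pairwise cosine) =",
      signif(x$linearity, 4), "\n")
  invisible(x)
}

#' @export
tidy.flux_direction <- function(x, ...) {
  tibble::tibble(feature = x$feature_names, v = x$v)
}

#' @export
glance.flux_direction <- function(x, ...) {
  tibble::tibble(n_bins = nrow(x$bins), linearity = x$linearity)
}

#' Project features onto a direction
#'
#' Returns the scalar collective coordinate `x . v` per sample. When the
#' committor is strictly monotone in `x . v` this projection preserves
#' the committor ordering exactly.
#'
#' @param samples feature matrix (or a record tibble with feature
#'   columns).
#' @param v direction vector (need not be normalized).
#' @export
project_features <- function(samples, v) {
  X <- if (is.data.frame(samples)) record_features(samples) else as.matrix(samples)
  if (ncol(X) != length(v)) stop("dimension mismatch.", call. = FALSE)
  as.numeric(X %*% v)
}

#' Train a low-dimensional committor model
#'
#' Retrains a small committor network on a reduced input set (typically
#' a couple of physical coordinates plus the linear projection `x . v`)
#' to test whether the quasi-linear picture reproduces the full model.
#' The held-out accuracy `alpha` is attached for comparison.
#'
#' @param records shooting records whose feature columns are the reduced
#'   inputs.
#' @param spec widths of the small network (input width must match).
#' @param ... passed to [train_committor()].
#' @return trained `committor_mlp` with `$alpha` (held-out accuracy fit)
#'   attached.
#' @export
fit_lowdim_committor <- function(records, spec = NULL, ...) {
  X <- record_features(records)
  if (is.null(spec)) spec <- network_spec(c(ncol(X), 8, 8, 1), dropout = 0)
  if (!inherits(spec, "network_spec")) spec <- network_spec(spec)
  model <- train_committor(records, spec, ...)
  val <- records
  val$phi <- predict_phi(model, X)
  model$alpha <- estimate_accuracy(val)
  model
}

#' k-nearest-neighbour density estimate in 2D
#'
#' For each evaluation point the radius `r` of the smallest circle
#' containing `k` data points is measured and the density estimated as
#' `r^-2` (optionally normalized to unit sum over the evaluation set).
#'
#' @param points_2d data matrix (N x 2).
#' @param k neighbours per circle (>= 2).
#' @param eval_points evaluation points (default: the data).
#' @param normalize normalize the estimate to unit sum?
#' @return tibble with `s`, `t`, `r_k`, `density`.
#' @export
knn_density <- function(points_2d, k, eval_points = NULL, normalize = FALSE) {
  X <- as.matrix(points_2d)
  stopifnot(ncol(X) == 2, k >= 2, nrow(X) >= k)
  Q <- if (is.null(eval_points)) X else as.matrix(eval_points)
  res <- cpp_knn_mean(X, X[, 1, drop = FALSE], Q, as.integer(k))
  r <- res$radius
  if (any(r == 0)) {
    warning("duplicate points give zero k-NN radius; flooring at machine scale",
            call. = FALSE)
    r[r == 0] <- sqrt(.Machine$double.eps)
  }
  dens <- r^-2
  if (normalize) dens <- dens / sum(dens)
  tibble::tibble(s = Q[, 1], t = Q[, 2], r_k = r, density = dens)
}

#' Committor iso-surface field on a 2D projection
#'
#' For each node of a grid over two projection coordinates `(s, t)`, the
#' mean full feature vector of the `k` nearest samples (in the
#' projection plane) is computed, projected onto the flux direction `v`,
#' and passed through a 1D committor model `phi(x . v)` - the
#' quasi-linear committor evaluated on locally averaged features. Nodes
#' whose k-NN circle radius exceeds `max_radius` are flagged as outside
#' the data support rather than extrapolated.
#'
#' @param samples projection coordinates (N x 2).
#' @param features full feature matrix (N x p).
#' @param grid tibble/matrix of grid nodes (M x 2), or a list
#'   `list(s = ..., t = ...)` of axis vectors.
#' @param k neighbours to average.
#' @param v flux direction (length p).
#' @param committor_1d function mapping `x . v` to `phi` (e.g. from a
#'   low-dimensional model), or a committor model taking the projection
#'   as single feature.
#' @param max_radius support flag threshold (default: infinite).
#' @return tibble with `s`, `t`, `proj`, `phi`, `r_k`, `in_support`.
#' @export
knn_committor_surface <- function(samples, features, grid, k, v,
                                  committor_1d, max_radius = Inf) {
  S <- as.matrix(samples)
  Fm <- as.matrix(features)
  stopifnot(nrow(S) == nrow(Fm), k <= nrow(S))
  if (is.list(grid) && !is.data.frame(grid)) {
    grid <- as.matrix(expand.grid(s = grid$s, t = grid$t))
  } else grid <- as.matrix(grid)
  res <- cpp_knn_mean(S, Fm, grid, as.integer(k))
  proj <- as.numeric(res$mean %*% v)
  phi <- if (inherits(committor_1d, "committor_model")) {
    predict_phi(committor_1d, matrix(proj, ncol = 1))
  } else committor_1d(proj)
  tibble::tibble(s = grid[, 1], t = grid[, 2], proj = proj, phi = phi,
                 r_k = res$radius, in_support = res$radius <= max_radius)
}

#' Classify the transition mechanism along a TPS chain
#'
#' Labels each MC step by thresholding the smoothed time-averaged pore
#' coordinate: values `xi_hat >= threshold` (default 1, the
#' membrane-spanning-pore criterion) are labelled the pore mechanism
#' `Pi_P`, others the tunneling mechanism `Pi_T`. Switch indices mark
#' mechanism transitions along the chain.
#'
#' @param chain_log a `tps_chain` or tibble with an `xi_hat` column.
#' @param threshold pore threshold on the smoothed series.
#' @param window smoothing window (MC steps).
#' @return tibble with `mc_index`, `xi_hat`, `xi_smooth`, `mechanism`;
#'   attribute `switches` holds the switch indices.
#' @export
classify_mechanism <- function(chain_log, threshold = 1.0, window = 10) {
  log <- if (inherits(chain_log, "tps_chain")) chain_log$log else chain_log
  stopifnot("xi_hat" %in% names(log))
  xs <- smooth_series(log$xi_hat, window)
  mech <- ifelse(xs >= threshold, "Pi_P", "Pi_T")
  switches <- which(mech[-1] != mech[-length(mech)]) + 1L
  out <- tibble::tibble(
    mc_index = if ("mc_index" %in% names(log)) log$mc_index else seq_along(xs),
    xi_hat = log$xi_hat, xi_smooth = xs, mechanism = mech
  )
  attr(out, "switches") <- switches
  out
}
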