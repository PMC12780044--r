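#' Pore reaction-coordinate parameters
#'
#' Parameters of the pore reaction coordinate `xi_P`, which combines
#' pore nucleation (the fraction `xi_ch` of membrane slabs at the pore
#' nucleus occupied by polar atoms) with pore expansion (a cylindrical
#' pore radius `R` estimated from the water count). The shipped preset
#' `"martini"` carries the coarse-grained parameter set: 4 slabs,
#' membrane region `Z_mem = 1.8` nm, chain cylinder `R_cyl = 1.0` nm,
#' water-counting cutoff `D = 1.2` nm, switch `xi_ch_s = 0.9` at radius
#' `R_0 = 0.38` nm.
#'
#' @param N_slabs number of z-slabs across the membrane region.
#' @param Z_mem membrane-region thickness (nm).
#' @param R_cyl lateral cutoff for the chain coordinate (nm).
#' @param D lateral cutoff for water counting (nm).
#' @param xi_ch_s switch value of the chain coordinate (0 < value <= 1).
#' @param R0 radius of a just fully nucleated pore (nm).
#' @param v_w volume per water (nm^3; bulk density default).
#' @return A `pore_params` list.
#' @export
pore_params <- function(N_slabs = 4, Z_mem = 1.8, R_cyl = 1.0, D = 1.2,
                        xi_ch_s = 0.9, R0 = 0.38, v_w = 0.030) {
  stopifnot(N_slabs >= 1, Z_mem > 0, R_cyl > 0, D > 0, R0 > 0, v_w > 0,
            xi_ch_s > 0, xi_ch_s <= 1)
  structure(list(N_slabs = as.integer(N_slabs), Z_mem = Z_mem, R_cyl = R_cyl,
                 D = D, xi_ch_s = xi_ch_s, R0 = R0, v_w = v_w),
            class = "pore_params")
}

#' @rdname pore_params
#' @param preset preset name (currently `"martini"`).
#' @export
pore_params_preset <- function(preset = "martini") {
  switch(preset,
         martini = pore_params(N_slabs = 4, Z_mem = 1.8, R_cyl = 1.0,
                               D = 1.2, xi_ch_s = 0.9, R0 = 0.38),
         stop(sprintf("unknown preset '%s'", preset), call. = FALSE))
}

# minimal-image displacement on a periodic axis
min_image <- function(d, L) d - L * round(d / L)

polar_types <- c("head_P", "head_N", "water_O")

#' Pore center as a weighted circular mean of headgroups
#'
#' Each lateral axis is mapped to a circle (period = box length) and the
#' circular mean of head-particle positions computed, weighted by a
#' Gaussian in the axial distance to the midplane (width `Z_mem / 2`) so
#' that midplane-proximal headgroups - those lining a pore - dominate.
#' The estimate is equivariant under periodic translation.
#'
#' @param config a `membrane_config`.
#' @param params a [pore_params()].
#' @return numeric `c(x, y)` center (nm).
#' @export
pore_center <- function(config, params = pore_params_preset()) {
  box <- attr(config, "box")
  mid <- attr(config, "midplane_z")
  heads <- config[config$type %in% c("head_P", "head_N"), ]
  if (nrow(heads) == 0) stop("no head particles.", call. = FALSE)
  dz <- min_image(heads$z - mid, box[3])
  w <- exp(-dz^2 / (2 * (params$Z_mem / 2)^2))
  if (sum(w) <= 0) stop("zero total center weight.", call. = FALSE)
  circ_mean <- function(x, L) {
    th <- 2 * pi * x / L
    ang <- atan2(sum(w * sin(th)), sum(w * cos(th)))
    (ang %% (2 * pi)) / (2 * pi) * L
  }
  c(circ_mean(heads$x, box[1]), circ_mean(heads$y, box[2]))
}

#' Chain coordinate: slab occupancy by polar atoms
#'
#' The membrane region `midplane +/- Z_mem / 2` is split into `N_slabs`
#' equal slabs; a slab is occupied (1) if at least one polar particle
#' (`head_P`, `head_N`, `water_O`) lies in it within lateral distance
#' `R_cyl` of the pore center. `xi_ch` is the mean occupancy: the
#' fraction of the membrane already spanned by a polar defect.
#'
#' @param config a `membrane_config`.
#' @param center lateral pore center `c(x, y)`.
#' @param params a [pore_params()].
#' @return list with `xi_ch` and `occupancy` (0/1 per slab).
#' @export
xi_chain <- function(config, center, params = pore_params_preset()) {
  box <- attr(config, "box")
  mid <- attr(config, "midplane_z")
  pol <- config[config$type %in% polar_types, ]
  dx <- min_image(pol$x - center[1], box[1])
  dy <- min_image(pol$y - center[2], box[2])
  dz <- min_image(pol$z - mid, box[3])
  lateral <- sqrt(dx^2 + dy^2)
  half <- params$Z_mem / 2
  inside <- lateral <= params$R_cyl & dz >= -half & dz < half
  edges <- seq(-half, half, length.out = params$N_slabs + 1)
  occ <- integer(params$N_slabs)
  if (any(inside)) {
    slab <- pmin(pmax(findInterval(dz[inside], edges, rightmost.closed = TRUE),
                      1L), params$N_slabs)
    occ[unique(slab)] <- 1L
  }
  list(xi_ch = mean(occ), occupancy = occ)
}

#' Cylindrical pore radius from the water count
#'
#' Counts waters within lateral distance `D` of the center and
#' `|z - midplane| < Z_mem / 2` and converts the count to the radius of
#' a cylinder of bulk water:
#' `R = sqrt(N_w v_w / (pi Z_mem))`.
#'
#' @param config a `membrane_config`.
#' @param center lateral pore center.
#' @param params a [pore_params()].
#' @return radius in nm (0 when no water is present).
#' @export
pore_radius <- function(config, center, params = pore_params_preset()) {
  box <- attr(config, "box")
  mid <- attr(config, "midplane_z")
  wat <- config[config$type == "water_O", ]
  if (nrow(wat) == 0) return(0)
  dx <- min_image(wat$x - center[1], box[1])
  dy <- min_image(wat$y - center[2], box[2])
  dz <- min_image(wat$z - mid, box[3])
  n_w <- sum(dx^2 + dy^2 <= params$D^2 & abs(dz) < params$Z_mem / 2)
  sqrt(n_w * params$v_w / (pi * params$Z_mem))
}

#' The pore reaction coordinate
#'
#' Combines nucleation and expansion: while the chain coordinate is
#' below its switch value, `xi_P = xi_ch / xi_ch_s` (so `xi_P` rises to
#' 1 as the polar defect spans the membrane); once the chain is
#' complete, the pore radius takes over,
#' `xi_P = 1 + max(0, R - R0) / R0`, in units of the radius `R0` of a
#' just fully nucleated pore. The combination is continuous at the
#' switch; a formed pore has `xi_P > 1` and an expanded pore relaxing to
#' twice its nucleated size reads `xi_P ~ 2`.
#'
#' @param config a `membrane_config`.
#' @param params a [pore_params()].
#' @return A `pore_state`: tibble row with `center_x`, `center_y`,
#'   `xi_ch`, `R`, `xi_p` plus attribute `occupancy`.
#' @export
xi_p <- function(config, params = pore_params_preset()) {
  center <- pore_center(config, params)
  ch <- xi_chain(config, center, params)
  R <- pore_radius(config, center, params)
  val <- if (ch$xi_ch < params$xi_ch_s) {
    ch$xi_ch / params$xi_ch_s
  } else {
    1 + max(0, R - params$R0) / params$R0
  }
  out <- tibble::tibble(center_x = center[1], center_y = center[2],
                        xi_ch = ch$xi_ch, R = R, xi_p = val)
  attr(out, "occupancy") <- ch$occupancy
  class(out) <- c("pore_state", class(out))
  out
}

#' Depletion/proximity features of atom groups around the pore center
#'
#' For each atom group (water oxygens, P heads, N+P heads, N+P+water,
#' tail carbons, all carbons) and each distance metric to the nucleation
#' center (isotropic 3D, lateral, axial), the sorted nearest-neighbour
#' distances `d1, d2, d3` and the means over the first 2, 3, 4, 5 and 10
#' are reported. Additionally `dz_max_NP1_4` gives the larger of the two
#' per-leaflet mean axial distances of the 4 axially nearest N/P heads -
#' the maximal headgroup depletion from the center.
#'
#' @param config a `membrane_config`.
#' @param center lateral pore center (default: [pore_center()]).
#' @param params a [pore_params()].
#' @return tibble with columns `group`, `metric`, `feature`, `value`
#'   (`NA` when the group is smaller than the requested rank).
#' @export
depletion_features <- function(config, center = NULL,
                               params = pore_params_preset()) {
  box <- attr(config, "box")
  mid <- attr(config, "midplane_z")
  if (is.null(center)) center <- pore_center(config, params)
  groups <- list(
    water_O = "water_O",
    P = "head_P",
    NP = c("head_P", "head_N"),
    NP_water = c("head_P", "head_N", "water_O"),
    tail_C = "tail_C",
    all_C = "tail_C"
  )
  ranks <- c(d1 = 1, d2 = 2, d3 = 3)
  mean_ks <- c(2, 3, 4, 5, 10)
  rows <- list()
  for (gname in names(groups)) {
    sel <- config[config$type %in% groups[[gname]], ]
    dx <- min_image(sel$x - center[1], box[1])
    dy <- min_image(sel$y - center[2], box[2])
    dz <- min_image(sel$z - mid, box[3])
    metrics <- list(isotropic = sqrt(dx^2 + dy^2 + dz^2),
                    lateral = sqrt(dx^2 + dy^2),
                    axial = abs(dz))
    for (mname in names(metrics)) {
      d <- sort(metrics[[mname]])
      for (r in names(ranks)) {
        rows[[length(rows) + 1L]] <- list(
          group = gname, metric = mname, feature = r,
          value = if (length(d) >= ranks[[r]]) d[ranks[[r]]] else NA_real_)
      }
      for (kk in mean_ks) {
        rows[[length(rows) + 1L]] <- list(
          group = gname, metric = mname, feature = paste0("mean", kk),
          value = if (length(d) >= kk) mean(d[seq_len(kk)]) else NA_real_)
      }
    }
  }
  np <- config[config$type %in% c("head_P", "head_N"), ]
  dznp <- min_image(np$z - mid, box[3])
  leaf_mean <- function(v) {
    v <- sort(abs(v))
    if (length(v) >= 4) mean(v[1:4]) else NA_real_
  }
  leaf_vals <- c(leaf_mean(dznp[dznp > 0]), leaf_mean(dznp[dznp <= 0]))
  dz_max <- if (all(is.na(leaf_vals))) NA_real_ else max(leaf_vals, na.rm = TRUE)
  rows[[length(rows) + 1L]] <- list(group = "NP", metric = "axial",
                                    feature = "dz_max_NP1_4", value = dz_max)
  dplyr::bind_rows(lapply(rows, tibble::as_tibble))
}

#' Censored-exponential pore lifetime estimator
#'
#' Maximum-likelihood estimate of the mean open-pore lifetime for
#' randomly censored data with exponential kinetics:
#' `tau_hat = sum(all durations, censored included) / (number of
#' observed closures)`. The estimator maximizes
#' `L(kappa) = prod p(t_i | kappa) prod S(t_j | kappa)` with survival
#' `S(t | kappa) = exp(-kappa t)` over the closure rate
#' `kappa = 1 / tau`; the profile log-likelihood is returned so the
#' maximizer can be verified.
#'
#' @param durations observed open durations (time the pore stayed open
#'   before closing, or before the run was terminated).
#' @param censored logical: was the run terminated with the pore still
#'   open?
#' @param rate_grid grid of rates for the profile log-likelihood
#'   (default: geometric grid around the estimate).
#' @return A `lifetime_fit`: `tau_hat`, `se` (tau / sqrt(n_closures)),
#'   `n_closures`, `n_censored`, `log_lik` (tibble of `rate`,
#'   `log_lik`).
#' @examples
#' pore_lifetime_mle(c(1, 2, 3), c(FALSE, FALSE, FALSE))$tau_hat  # 2
#' @export
pore_lifetime_mle <- function(durations, censored = NULL, rate_grid = NULL) {
  if (is.data.frame(durations)) {
    censored <- durations$censored
    durations <- durations$time
  }
  if (is.null(censored)) censored <- rep(FALSE, length(durations))
  stopifnot(length(censored) == length(durations), all(durations >= 0))
  n_unc <- sum(!censored)
  if (n_unc == 0) {
    stop("no observed closures; only a lower bound on the lifetime exists.",
         call. = FALSE)
  }
  total <- sum(durations)
  tau_hat <- total / n_unc
  if (is.null(rate_grid)) {
    rate_grid <- exp(seq(log(0.05 / tau_hat), log(20 / tau_hat),
                         length.out = 400))
  }
  ll <- n_unc * log(rate_grid) - rate_grid * total
  structure(list(tau_hat = tau_hat, se = tau_hat / sqrt(n_unc),
                 n_closures = n_unc, n_censored = sum(censored),
                 log_lik = tibble::tibble(rate = rate_grid, log_lik = ll)),
            class = "lifetime_fit")
}

#' @export
print.lifetime_fit <- function(x, ...) {
  cat("<lifetime_fit> tau_hat =", signif(x$tau_hat, 4),
      "+/-", signif(x$se, 3),
      sprintf(" (%d closures, %d censored)\n", x$n_closures, x$n_censored))
  invisible(x)
}

#' @export
tidy.lifetime_fit <- function(x, ...) x$log_lik

#' @export
glance.lifetime_fit <- function(x, ...) {
  tibble::tibble(tau_hat = x$tau_hat, se = x$se,
                 n_closures = x$n_closures, n_censored = x$n_censored)
}
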