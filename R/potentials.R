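#' Toy potentials for path-sampling experiments
#'
#' Analytic model potentials (in units of kT, lengths in nm) used as
#' desk-scale surrogates for the bistable systems studied with transition
#' path sampling: a symmetric quartic double well in one dimension and a
#' two-channel landscape in two dimensions whose upper channel passes
#' through a metastable intermediate (the "pore-like" route) while the
#' lower channel crosses a direct saddle (the "tunneling-like" route).
#'
#' A potential is a list with fields `dim`, `energy(x)`, `gradient(x)` and
#' `params`; the built-in families additionally carry a compiled-code spec
#' so that the Langevin propagator can run its inner loop in C++.
#'
#' @param barrier_kT barrier height at the central maximum, in kT (> 0).
#' @param x_min_sep distance between the two minima (nm); minima sit at
#'   `+/- x_min_sep / 2`.
#' @return An object of class `tps_potential`.
#' @examples
#' pot <- make_double_well_1d(barrier_kT = 5, x_min_sep = 2)
#' pot$energy(0) - pot$energy(1)   # barrier height: 5
#' @export
make_double_well_1d <- function(barrier_kT, x_min_sep = 2) {
  if (!is.numeric(barrier_kT) || barrier_kT <= 0) {
    stop("`barrier_kT` must be a positive number.", call. = FALSE)
  }
  if (x_min_sep <= 0) stop("`x_min_sep` must be positive.", call. = FALSE)
  a <- x_min_sep / 2
  params <- c(h = barrier_kT, a = a)
  cpp <- list(type = 1L, params = unname(params))
  structure(
    list(
      dim = 1L,
      energy = function(x) cpp_pot_energy(1L, cpp$params, as.numeric(x)),
      gradient = function(x) cpp_pot_grad(1L, cpp$params, as.numeric(x)),
      params = as.list(params),
      cpp = cpp
    ),
    class = "tps_potential"
  )
}

#' @rdname make_double_well_1d
#'
#' @details `make_two_channel_2d()` builds a landscape with two wells on the
#' x-axis at `(-1, 0)` and `(1, 0)` connected by two channels: channel T
#' crosses a direct saddle near the origin gated by a Gaussian bump of
#' height `barrier_T_kT`, and channel P detours over elevated y through a
#' metastable intermediate at `(0, y_intermediate)` of depth
#' `intermediate_depth_kT`, flanked by two symmetric Gaussian gates of
#' height `barrier_P_kT`. The landscape is symmetric under x-reflection.
#' Stated barrier heights are the amplitudes of the gating Gaussians on a
#' common base surface, so their ratio (not their absolute value on the
#' full surface) decides which channel dominates.
#'
#' @param barrier_T_kT,barrier_P_kT Gaussian gate heights (kT) for the
#'   direct and the intermediate-routed channel.
#' @param intermediate_depth_kT depth (kT) of the metastable basin on
#'   channel P.
#' @param y_intermediate elevation of the intermediate basin (nm).
#' @export
make_two_channel_2d <- function(barrier_T_kT, barrier_P_kT,
                                intermediate_depth_kT = 2,
                                y_intermediate = 1.4) {
  if (barrier_T_kT <= 0 || barrier_P_kT <= 0) {
    stop("barriers must be positive.", call. = FALSE)
  }
  if (intermediate_depth_kT < 0) {
    stop("`intermediate_depth_kT` must be non-negative.", call. = FALSE)
  }
  yI <- y_intermediate
  well_depth <- 8
  ridge <- max(barrier_T_kT, barrier_P_kT) + 2.5
  mouth <- 0.3  # y-extent^2 of the channel mouths
  big <- 1e4    # effectively y-independent ridge term
  gauss <- rbind(
    # two wells on the x axis
    c(-well_depth, -1, 0, 0.25, 0.25),
    c(-well_depth,  1, 0, 0.25, 0.25),
    # ridge along x = 0 separating the two channels ...
    c(ridge, 0, 0, 0.15, big),
    # ... lowered to barrier_T at the direct channel mouth (y ~ 0)
    c(-(ridge - barrier_T_kT), 0, 0, 0.15, mouth),
    # ... and to barrier_P at the elevated channel mouth (y ~ yI)
    c(-(ridge - barrier_P_kT), 0, yI, 0.15, mouth),
    # metastable intermediate dug into the elevated pass
    c(-intermediate_depth_kT, 0, yI, 0.03, 0.10)
  )
  params <- c(0.7, 1.2, 0.5, nrow(gauss), t(gauss))
  cpp <- list(type = 2L, params = unname(params))
  structure(
    list(
      dim = 2L,
      energy = function(x) cpp_pot_energy(2L, cpp$params, as.numeric(x)),
      gradient = function(x) cpp_pot_grad(2L, cpp$params, as.numeric(x)),
      params = list(barrier_T_kT = barrier_T_kT, barrier_P_kT = barrier_P_kT,
                    intermediate_depth_kT = intermediate_depth_kT,
                    y_intermediate = yI, wells = c(-1, 1)),
      cpp = cpp
    ),
    class = "tps_potential"
  )
}

#' @export
print.tps_potential <- function(x, ...) {
  cat("<tps_potential> dim =", x$dim, "\n")
  cat("  params:", paste(names(x$params), unlist(lapply(x$params, function(p)
    paste(signif(unlist(p), 3), collapse = ","))), sep = "=", collapse = "; "), "\n")
  invisible(x)
}
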