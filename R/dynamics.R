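#' Overdamped Langevin propagation
#'
#' Euler-Maruyama integration of overdamped (velocity-free) Langevin
#' dynamics with unit friction, `dx = -grad U(x) dt + sqrt(2 dt / beta) xi`,
#' on a toy potential. Energies are in kT, so `beta` is dimensionless
#' inverse temperature (1 at the reference temperature). With
#' `stop_on_state = TRUE` the integrator halts at the first frame inside
#' any of the supplied states (first-entrance stopping); a trajectory that
#' exhausts `max_steps` without reaching a state is returned with
#' `resolved = FALSE` rather than silently truncated.
#'
#' @param potential a `tps_potential`.
#' @param x0 numeric start point (must match `potential$dim`).
#' @param dt time step (> 0).
#' @param beta inverse temperature; `beta = Inf` (or `0` noise) gives
#'   deterministic steepest descent.
#' @param max_steps hard cap on integration steps.
#' @param seed integer seed; all randomness in the segment flows from it.
#' @param state_defs list of `tps_state` objects (may be `NULL` when
#'   `stop_on_state = FALSE`).
#' @param stop_on_state halt at first state entrance?
#' @param stride record every `stride`-th frame (the entering frame is
#'   always recorded).
#' @return A `tps_segment`: list with `frames` (matrix, one row per
#'   recorded frame), `dt`, `seed`, `terminal_state` (name or `NA`),
#'   `resolved`, `n_steps`.
#' @examples
#' pot <- make_double_well_1d(5, 2)
#' seg <- simulate_overdamped(pot, x0 = 0.2, dt = 1e-3, beta = 1,
#'                            max_steps = 1e4, seed = 1,
#'                            state_defs = double_well_states(pot),
#'                            stop_on_state = TRUE)
#' seg$terminal_state
#' @export
simulate_overdamped <- function(potential, x0, dt, beta = 1, max_steps = 1e5,
                                seed = NULL, state_defs = NULL,
                                stop_on_state = FALSE, stride = 1L) {
  stopifnot(inherits(potential, "tps_potential"))
  if (dt <= 0) stop("`dt` must be positive.", call. = FALSE)
  if (length(x0) != potential$dim) {
    stop("`x0` does not match the potential dimension.", call. = FALSE)
  }
  if (stop_on_state && is.null(state_defs)) {
    stop("`stop_on_state = TRUE` requires `state_defs`.", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  smat <- if (!is.null(state_defs)) states_to_matrix(state_defs) else NULL
  use_cpp <- !is.null(potential$cpp) && (!stop_on_state || !is.null(smat))
  if (use_cpp) {
    res <- cpp_overdamped(potential$cpp$type, potential$cpp$params,
                          as.numeric(x0), dt,
                          if (is.finite(beta)) beta else 0,
                          as.integer(max_steps),
                          if (is.null(smat)) matrix(0, 0, 4) else smat,
                          stop_on_state, as.integer(stride))
    frames <- res$frames
    entered <- res$entered_state
    n_steps <- res$n_steps
    resolved <- res$resolved
  } else {
    noise <- if (is.finite(beta) && beta > 0) sqrt(2 * dt / beta) else 0
    x <- as.numeric(x0)
    frames_list <- list(x)
    entered <- 0L
    n_steps <- 0L
    lab0 <- if (stop_on_state) classify_state(x, state_defs) else NA_character_
    if (stop_on_state && !is.na(lab0)) {
      entered <- match(lab0, state_names(state_defs))
    } else {
      for (step in seq_len(max_steps)) {
        x <- x - potential$gradient(x) * dt +
          noise * rnorm(length(x))
        if (step %% stride == 0) frames_list[[length(frames_list) + 1L]] <- x
        n_steps <- step
        if (stop_on_state) {
          lab <- classify_state(x, state_defs)
          if (!is.na(lab)) {
            if (step %% stride != 0) frames_list[[length(frames_list) + 1L]] <- x
            entered <- match(lab, state_names(state_defs))
            break
          }
        }
      }
    }
    frames <- do.call(rbind, frames_list)
    resolved <- !stop_on_state || entered > 0L
  }
  terminal <- if (entered > 0L) state_names(state_defs)[entered] else NA_character_
  structure(list(frames = frames, dt = dt, seed = seed,
                 terminal_state = terminal, resolved = resolved,
                 n_steps = n_steps),
            class = "tps_segment")
}

#' Default states for the 1D double well
#'
#' States sit at the two minima: L for `x < -f * a`, U for `x > f * a`
#' where `a` is the minimum position.
#'
#' @param potential a double-well `tps_potential`.
#' @param f fraction of the minimum position at which the state begins.
#' @export
double_well_states <- function(potential, f = 0.9) {
  a <- potential$params$a
  list(state_interval("L", coord = 1, hi = -f * a),
       state_interval("U", coord = 1, lo = f * a))
}

#' Default states for the two-channel landscape
#'
#' Discs of radius `radius` around the two wells at `(-1, 0)` and `(1, 0)`.
#'
#' @param potential a two-channel `tps_potential`.
#' @param radius disc radius (nm); the default keeps the discs clear of
#'   both channels while trimming near-state loitering.
#' @export
two_channel_states <- function(potential, radius = 0.55) {
  list(state_ball("L", c(-1, 0), radius),
       state_ball("U", c(1, 0), radius))
}

#' Exact committor of 1D overdamped dynamics
#'
#' For overdamped Langevin dynamics in a 1D potential the committor to `b`
#' with reactant boundary `a` has the closed form
#' `phi(x) = int_a^x exp(beta U(s)) ds / int_a^b exp(beta U(s)) ds`,
#' evaluated here by trapezoidal quadrature on a fine grid. Serves as the
#' independent oracle for learned committor models.
#'
#' @param potential a 1D `tps_potential`.
#' @param beta inverse temperature.
#' @param a,b boundaries (absorbing at both ends), `a < b`.
#' @param x evaluation points in `[a, b]` (vectorized).
#' @param n_grid quadrature resolution.
#' @return Numeric vector of committor probabilities.
#' @export
analytic_committor_1d <- function(potential, beta, a, b, x, n_grid = 20001) {
  stopifnot(inherits(potential, "tps_potential"), potential$dim == 1L, a < b)
  if (any(x < a | x > b)) {
    stop("`x` must lie inside [a, b].", call. = FALSE)
  }
  s <- seq(a, b, length.out = n_grid)
  u <- vapply(s, potential$energy, numeric(1))
  w <- exp(beta * (u - max(u)))  # stabilized integrand
  h <- s[2] - s[1]
  cum <- c(0, cumsum((w[-1] + w[-length(w)]) / 2 * h))
  total <- cum[length(cum)]
  phi <- stats::approx(s, cum / total, xout = x)$y
  pmin(pmax(phi, 0), 1)
}
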