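#' Propagation engines for transition path sampling
#'
#' An engine bundles a stochastic propagator with its state definitions
#' and time step, giving the TPS driver a uniform surface. `propagate(x0)`
#' runs a first-entrance segment from `x0` using the ambient RNG stream
#' (the chain driver owns the seed) and returns a `tps_segment`.
#'
#' @param potential a `tps_potential`.
#' @param dt integration time step.
#' @param beta inverse temperature.
#' @param max_steps cap on steps per segment; exceeding it yields an
#'   unresolved segment, never a silent truncation.
#' @param state_defs list of `tps_state` objects.
#' @param stride frame recording stride.
#' @return A `tps_engine`.
#' @export
make_langevin_engine <- function(potential, dt, beta = 1, max_steps = 5e4,
                                 state_defs, stride = 1L) {
  force(potential); force(dt); force(beta); force(max_steps)
  force(state_defs); force(stride)
  structure(list(
    kind = "langevin",
    dim = potential$dim,
    dt = dt,
    state_defs = state_defs,
    propagate = function(x0) {
      simulate_overdamped(potential, x0, dt = dt, beta = beta,
                          max_steps = max_steps, seed = NULL,
                          state_defs = state_defs, stop_on_state = TRUE,
                          stride = stride)
    }
  ), class = "tps_engine")
}

#' @rdname make_langevin_engine
#' @param spec a `discrete_chain`.
#' @export
make_discrete_engine <- function(spec, max_steps = 1e4) {
  force(spec); force(max_steps)
  sdefs <- list(
    state_indicator("A", function(frame) frame[1] %in% spec$state_A),
    state_indicator("B", function(frame) frame[1] %in% spec$state_B)
  )
  structure(list(
    kind = "discrete",
    dim = 1L,
    dt = 1,
    state_defs = sdefs,
    spec = spec,
    key_fn = function(frames) path_key(as.integer(frames[, 1]), spec),
    propagate = function(x0) {
      res <- cpp_discrete_walk(spec$P, as.integer(x0[1]), spec$absorbing,
                               as.integer(max_steps))
      structure(list(frames = matrix(as.numeric(res$sites), ncol = 1),
                     dt = 1, seed = NULL,
                     terminal_state = c(NA_character_, "A", "B")[res$entered_state + 1L],
                     resolved = res$resolved,
                     n_steps = length(res$sites) - 1L),
                class = "tps_segment")
    }
  ), class = "tps_engine")
}
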