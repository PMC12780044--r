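#' Metastable state definitions
#'
#' A state definition pairs a name with an indicator on trajectory frames.
#' For the built-in engines the indicator is a simple geometric region
#' (an open interval on one coordinate, or a disc in 2D), which also lets
#' the compiled propagator test state membership in its inner loop.
#' Arbitrary indicator functions are accepted for R-level engines.
#'
#' @param name state label (e.g. `"L"`, `"U"`, `"F"`, `"P"`).
#' @param coord coordinate index the interval applies to.
#' @param lo,hi open interval bounds (`lo < x < hi`).
#' @param center,radius disc geometry for `state_ball()`.
#' @param indicator for `state_indicator()`: a function of a frame
#'   (numeric vector) returning `TRUE`/`FALSE`.
#' @return An object of class `tps_state`.
#' @examples
#' L <- state_interval("L", coord = 1, hi = -1.3)
#' U <- state_interval("U", coord = 1, lo = 1.3)
#' classify_state(c(1.4), list(L, U))
#' @export
state_interval <- function(name, coord = 1, lo = -Inf, hi = Inf) {
  stopifnot(lo < hi)
  structure(list(name = name, kind = "interval", coord = as.integer(coord),
                 lo = lo, hi = hi,
                 indicator = function(frame) {
                   v <- frame[coord]
                   v > lo && v < hi
                 }),
            class = "tps_state")
}

#' @rdname state_interval
#' @export
state_ball <- function(name, center, radius) {
  stopifnot(radius > 0, length(center) == 2)
  structure(list(name = name, kind = "ball", center = center, radius = radius,
                 indicator = function(frame) {
                   sum((frame[1:2] - center)^2) < radius^2
                 }),
            class = "tps_state")
}

#' @rdname state_interval
#' @export
state_indicator <- function(name, indicator) {
  stopifnot(is.function(indicator))
  structure(list(name = name, kind = "custom", indicator = indicator),
            class = "tps_state")
}

#' Lipid flip-flop states on the transversal displacement z
#'
#' The lower- and upper-leaflet states are defined by thresholds on the
#' probe lipid's displacement z from the bilayer midplane: state L for
#' `z < -z_star`, state U for `z > z_star` (default 1.3 nm).
#'
#' @param z_star threshold in nm.
#' @param coord which frame coordinate carries z.
#' @return list of two `tps_state` objects.
#' @export
flipflop_states <- function(z_star = 1.3, coord = 1) {
  list(state_interval("L", coord = coord, hi = -z_star),
       state_interval("U", coord = coord, lo = z_star))
}

#' Pore nucleation states on the pore coordinate
#'
#' Flat-membrane state F for `xi_P < 0.05`, expanded-pore state P for
#' `xi_P > 2.0`.
#'
#' @param xi_flat,xi_pore thresholds on the pore reaction coordinate.
#' @param coord which frame coordinate carries xi_P.
#' @return list of two `tps_state` objects.
#' @export
nucleation_states <- function(xi_flat = 0.05, xi_pore = 2.0, coord = 1) {
  list(state_interval("F", coord = coord, hi = xi_flat),
       state_interval("P", coord = coord, lo = xi_pore))
}

#' Classify a frame into a metastable state
#'
#' @param frame numeric vector of frame coordinates/features.
#' @param state_defs list of `tps_state` objects; indicators must be
#'   disjoint.
#' @return The state name, or `NA_character_` if the frame is in no state.
#' @export
classify_state <- function(frame, state_defs) {
  hits <- vapply(state_defs, function(s) isTRUE(s$indicator(frame)), logical(1))
  if (sum(hits) > 1) {
    stop("frame satisfies more than one state indicator (states must be disjoint)",
         call. = FALSE)
  }
  if (!any(hits)) return(NA_character_)
  state_defs[[which(hits)]]$name
}

state_names <- function(state_defs) {
  vapply(state_defs, function(s) s$name, character(1))
}

# Geometry matrix handed to the compiled propagator; custom indicators
# cannot run in C++ and force the R propagation path.
states_to_matrix <- function(state_defs) {
  rows <- lapply(state_defs, function(s) {
    if (s$kind == "interval") c(1, s$coord, s$lo, s$hi)
    else if (s$kind == "ball") c(2, s$center[1], s$center[2], s$radius)
    else NULL
  })
  if (any(vapply(rows, is.null, logical(1)))) return(NULL)
  do.call(rbind, rows)
}
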