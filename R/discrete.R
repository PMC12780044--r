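#' Finite Markov chains as enumerable path-sampling substrates
#'
#' A small discrete chain (a handful of sites, arbitrary row-stochastic
#' hop matrix) whose transition-path ensemble can be enumerated exactly,
#' providing a brute-force oracle for the TPS Markov chain. Two disjoint
#' site sets define the boundary states A and B.
#'
#' @param P row-stochastic transition matrix (`n_sites <= 12`).
#' @param state_A,state_B site indices (1-based) of the two boundary
#'   states.
#' @return An object of class `discrete_chain`.
#' @export
discrete_chain_spec <- function(P, state_A, state_B) {
  P <- as.matrix(P)
  n <- nrow(P)
  if (n != ncol(P)) stop("`P` must be square.", call. = FALSE)
  if (n > 12) stop("chains are limited to 12 sites.", call. = FALSE)
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-10)) {
    stop("rows of `P` must be probability vectors summing to 1.", call. = FALSE)
  }
  if (length(intersect(state_A, state_B)) > 0) {
    stop("states A and B must be disjoint.", call. = FALSE)
  }
  absorbing <- integer(n)
  absorbing[state_A] <- 1L
  absorbing[state_B] <- 2L
  structure(list(P = P, n_sites = n, state_A = as.integer(state_A),
                 state_B = as.integer(state_B), absorbing = absorbing),
            class = "discrete_chain")
}

#' @rdname discrete_chain_spec
#' @details `birth_death_chain()` builds a reversible nearest-neighbour
#' chain on `n_sites` sites with constant up/down hop probabilities
#' (reflecting walls), states A = site 1 and B = site `n_sites`.
#' Reversibility matters: two-way shooting detailed balance assumes it.
#' @param n_sites number of sites.
#' @param p_up,p_down hop probabilities (remainder is the stay
#'   probability).
#' @export
birth_death_chain <- function(n_sites, p_up = 0.5, p_down = 0.5) {
  stopifnot(p_up + p_down <= 1, p_up > 0, p_down > 0)
  P <- matrix(0, n_sites, n_sites)
  for (i in seq_len(n_sites)) {
    if (i > 1) P[i, i - 1] <- p_down
    if (i < n_sites) P[i, i + 1] <- p_up
    P[i, i] <- 1 - sum(P[i, ])
  }
  discrete_chain_spec(P, state_A = 1L, state_B = n_sites)
}

#' Stationary distribution of a discrete chain
#' @param spec a `discrete_chain`.
#' @return probability vector over sites.
#' @export
stationary_distribution <- function(spec) {
  e <- eigen(t(spec$P))
  i <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, i]))
  v / sum(v)
}

#' Exact committor of a discrete chain
#'
#' Probability of reaching state B before state A from each site, by
#' solving the linear system `h = P h` on interior sites with boundary
#' values 0 on A and 1 on B.
#'
#' @param spec a `discrete_chain`.
#' @return numeric vector of committor values per site.
#' @export
exact_committor_discrete <- function(spec) {
  n <- spec$n_sites
  h <- numeric(n)
  h[spec$state_B] <- 1
  interior <- which(spec$absorbing == 0L)
  if (length(interior) > 0) {
    Pi <- spec$P[interior, interior, drop = FALSE]
    b <- spec$P[interior, spec$state_B, drop = FALSE] %*% rep(1, length(spec$state_B))
    h[interior] <- solve(diag(length(interior)) - Pi, b)
  }
  as.numeric(h)
}

#' Enumerate the transition-path ensemble of a discrete chain
#'
#' Exhaustively enumerates every first-entrance A -> B path up to
#' `max_len` frames, with weight `pi(x0) * prod(P(hops))` (pi the
#' stationary distribution), normalized over the enumerated set. The
#' truncated probability mass (paths longer than `max_len`, accounted
#' exactly through the committor of the frontier site) is reported; a
#' truncated fraction above `1e-6` flags a warning status in the output.
#'
#' @param spec a `discrete_chain`.
#' @param max_len maximum path length in frames.
#' @param prune abandon prefixes with weight below this (accounted in the
#'   truncated mass).
#' @return A list with `paths` (tibble: `key`, `length`, `prob`),
#'   `truncated_mass` (fraction of total TP weight not enumerated) and
#'   `status` (`"ok"` or `"truncated"`).
#' @export
enumerate_tpe_discrete <- function(spec, max_len = 50, prune = 1e-14) {
  stopifnot(inherits(spec, "discrete_chain"))
  pi_stat <- stationary_distribution(spec)
  hB <- exact_committor_discrete(spec)
  res <- cpp_enumerate_paths(spec$P, spec$absorbing, pi_stat, hB,
                             as.integer(max_len), prune)
  total <- sum(res$weight) + res$truncated_weight
  paths <- tibble::tibble(key = res$key, length = res$length,
                          prob = res$weight / sum(res$weight)) |>
    dplyr::arrange(dplyr::desc(.data$prob))
  truncated_mass <- res$truncated_weight / total
  list(paths = paths,
       truncated_mass = truncated_mass,
       status = if (truncated_mass > 1e-6) "truncated" else "ok")
}

#' Simulate a first-entrance segment on a discrete chain
#'
#' Random walk from `start` until entering state A or B (or `max_steps`).
#' Randomness comes from R's RNG stream.
#'
#' @param spec a `discrete_chain`.
#' @param start starting site (interior).
#' @param max_steps cap on hops.
#' @return list with `sites`, `terminal_state` ("A"/"B"/`NA`), `resolved`.
#' @export
simulate_discrete_segment <- function(spec, start, max_steps = 10000) {
  res <- cpp_discrete_walk(spec$P, as.integer(start), spec$absorbing,
                           as.integer(max_steps))
  term <- c(NA_character_, "A", "B")[res$entered_state + 1L]
  list(sites = res$sites, terminal_state = term, resolved = res$resolved)
}

#' Path key of a site sequence
#'
#' Canonical string key (sites joined by `-`) used to compare sampled
#' paths against the enumerated ensemble. Paths are canonicalized to the
#' A -> B orientation.
#'
#' @param sites integer vector of sites.
#' @param spec a `discrete_chain`.
#' @export
path_key <- function(sites, spec) {
  if (sites[1] %in% spec$state_B) sites <- rev(sites)
  paste(sites, collapse = "-")
}
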