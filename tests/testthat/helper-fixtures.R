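# Shared fixtures and independent oracles used across the suite.

dw_potential <- function(barrier = 5, sep = 2) make_double_well_1d(barrier, sep)

dw_engine <- function(pot = dw_potential(), dt = 1e-3, beta = 1) {
  make_langevin_engine(pot, dt = dt, beta = beta, max_steps = 1e5,
                       state_defs = double_well_states(pot))
}

# two-way shot records on the 1D double well, shooting points uniform over
# the barrier region
dw_shot_records <- function(N, engine = dw_engine(), seed = 7,
                            range = c(-0.85, 0.85), n_chains = 5) {
  set.seed(seed)
  xs <- runif(N, range[1], range[2])
  k <- integer(N)
  for (i in seq_len(N)) k[i] <- two_way_shot(engine, xs[i], "U")$k
  tibble::tibble(x = xs, n = 2L, k = k, chain_id = rep_len(seq_len(n_chains), N))
}

# scalar-loop oracle for the mean shooting NLL
nll_loop_oracle <- function(records, phi) {
  tot <- 0
  for (i in seq_len(nrow(records))) {
    p <- min(max(phi[i], 1e-7), 1 - 1e-7)
    tot <- tot - (lchoose(records$n[i], records$k[i]) +
                    records$k[i] * log(p) +
                    (records$n[i] - records$k[i]) * log(1 - p))
  }
  tot / nrow(records)
}

# quadrature oracle for the binomial-beta convolution; substituting
# u = F_beta(P) absorbs the endpoint singularities of the beta density,
# leaving the smooth integrand dbinom(k, n, F^-1(u))
betabinom_quadrature <- function(k, n, phi, alpha) {
  w <- alpha / (1 - alpha)
  a <- w * phi; b <- w * (1 - phi)
  integrand <- function(u) dbinom(k, n, qbeta(u, a, b))
  integrate(integrand, 0, 1, rel.tol = 1e-11, abs.tol = 1e-13,
            subdivisions = 500L)$value
}

# brute-force periodic center: origin shift minimizing weighted spread
brute_force_periodic_center <- function(xs, w, L, n_grid = 4000) {
  cand <- seq(0, L, length.out = n_grid + 1)[-(n_grid + 1)]
  spread <- vapply(cand, function(c0) {
    d <- xs - c0
    d <- d - L * round(d / L)
    sum(w * d^2)
  }, numeric(1))
  c0 <- cand[which.min(spread)]
  d <- xs - c0
  d <- d - L * round(d / L)
  (c0 + sum(w * d) / sum(w)) %% L
}

# total variation between a sampled path table and an enumerated ensemble
tv_distance <- function(sample_keys, enumerated) {
  emp <- table(sample_keys) / length(sample_keys)
  keys <- union(names(emp), enumerated$key)
  p <- stats::setNames(numeric(length(keys)), keys)
  p[enumerated$key] <- enumerated$prob
  q <- stats::setNames(numeric(length(keys)), keys)
  q[names(emp)] <- as.numeric(emp)
  0.5 * sum(abs(p - q))
}

# membrane config with planted pore, shared by pore-geometry tests
planted_pore_config <- function(radius = 0.4, seed = 3) {
  generate_membrane_config(n_lipids_per_leaflet = 100, leaflet_sep = 2.6,
                           box = c(6, 6, 6), pore_radius = radius,
                           seed = seed)
}

# minimal membrane config with exactly the polar particles placed by hand;
# used for exact slab-occupancy arithmetic
slab_config <- function(occupied_slabs, params = pore_params_preset(),
                        box = c(6, 6, 6)) {
  mid <- box[3] / 2
  half <- params$Z_mem / 2
  edges <- seq(-half, half, length.out = params$N_slabs + 1)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  # anchor heads far from the pore axis so the center stays at the box middle
  heads <- tibble::tibble(
    x = c(3, 3, 3, 3), y = c(3, 3, 3, 3),
    z = mid + c(1.3, 1.3, -1.3, -1.3) + c(0, 0.01, 0, 0.01),
    type = c("head_P", "head_N", "head_P", "head_N")
  )
  waters <- if (length(occupied_slabs) > 0) {
    tibble::tibble(x = 3, y = 3, z = mid + centers[occupied_slabs],
                   type = "water_O")
  } else NULL
  membrane_config(dplyr::bind_rows(heads, waters), box = box)
}
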