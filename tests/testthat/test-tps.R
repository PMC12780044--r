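test_that("frames classify into the flip-flop and nucleation states", {
  ff <- flipflop_states(1.3)
  expect_identical(classify_state(1.4, ff), "U")
  expect_identical(classify_state(-1.35, ff), "L")
  expect_true(is.na(classify_state(0, ff)))
  nuc <- nucleation_states()
  expect_identical(classify_state(0.04, nuc), "F")
  expect_identical(classify_state(2.4, nuc), "P")
  expect_true(is.na(classify_state(1.0, nuc)))
  overlapping <- list(state_interval("A", 1, lo = 0),
                      state_interval("B", 1, lo = 1))
  expect_error(classify_state(2, overlapping), "more than one")
})

test_that("paths enforce the first-entrance endpoint invariant", {
  pot <- dw_potential()
  states <- double_well_states(pot)
  good <- matrix(c(-0.95, -0.4, 0.3, 0.95), ncol = 1)
  p <- tps_path(good, dt = 1, state_defs = states)
  expect_identical(p$endpoint_states, c("L", "U"))
  bad_interior <- matrix(c(-0.95, 0.93, 0.2, 0.95), ncol = 1)
  expect_error(tps_path(bad_interior, dt = 1, state_defs = states),
               "interior")
  bad_ends <- matrix(c(-0.95, 0.2, -0.95), ncol = 1)
  expect_error(tps_path(bad_ends, dt = 1, state_defs = states), "different")
})

test_that("two-way shots count k toward the final state and splice paths", {
  spec <- birth_death_chain(4, 0.9, 0.1)  # strongly forward
  eng <- make_discrete_engine(spec)
  set.seed(3)
  res <- replicate(200, {
    s <- two_way_shot(eng, 2, "B")
    c(k = s$k, has_path = !is.null(s$path))
  })
  k <- res[1, ]; has_path <- as.logical(res[2, ])
  expect_true(all(k %in% 0:2))
  expect_identical(has_path, k == 1)
  # an assembled trial path runs A -> B with the shooting point inside
  s <- NULL
  set.seed(11)
  repeat { s <- two_way_shot(eng, 2, "B"); if (!is.null(s$path)) break }
  expect_identical(s$path$endpoint_states, c("A", "B"))
  expect_equal(s$path$frames[s$sp_index, 1], 2)
  expect_error(two_way_shot(eng, 1, "B"), "inside a state")
})

test_that("unresolved shots are reported as failed, not truncated", {
  pot <- dw_potential()
  eng <- make_langevin_engine(pot, dt = 1e-6, beta = 1, max_steps = 20,
                              state_defs = double_well_states(pot))
  set.seed(1)
  s <- two_way_shot(eng, 0, "U")
  expect_false(s$resolved)
  expect_true(is.na(s$k))
  expect_null(s$path)
})

test_that("acceptance follows the selection-probability ratio", {
  pot <- dw_potential()
  states <- double_well_states(pot)
  p1 <- tps_path(matrix(c(-0.95, -0.2, 0.2, 0.95), ncol = 1), 1, states)
  p2 <- tps_path(matrix(c(-0.95, -0.3, 0, 0.3, 0.95), ncol = 1), 1, states)
  unif <- function(p) selection_weights(p, NULL, NULL)
  # equal eligible counts: always accept
  p1b <- tps_path(matrix(c(-0.95, -0.1, 0.15, 0.95), ncol = 1), 1, states)
  expect_true(accept_move(p1b, p1, unif, 2, 2, u = 1 - 1e-12))
  # trial has 3 eligible frames vs 2: ratio 2/3
  set.seed(6)
  acc <- replicate(4000, accept_move(p2, p1, unif, 2, 2))
  p_exp <- 2 / 3
  se <- sqrt(p_exp * (1 - p_exp) / 4000)
  expect_lt(abs(mean(acc) - p_exp), 3 * se)
  expect_error(accept_move(p2, p1, unif, 99, 2), "outside")
})

test_that("the chain driver logs exactly what happened", {
  spec <- birth_death_chain(5, 0.6, 0.4)
  eng <- make_discrete_engine(spec)
  model <- committor_table(exact_committor_discrete(spec))
  set.seed(2)
  repeat { s <- two_way_shot(eng, 3, "B"); if (!is.null(s$path)) break }
  ch <- run_chain(eng, s$path, n_steps = 300, model = model, seed = 7)
  expect_equal(nrow(ch$log), 300)
  expect_equal(ch$acceptance_rate, mean(ch$log$accepted))
  expect_equal(ch$log$generated, !is.na(ch$log$k) & ch$log$k == 1L)
  expect_true(all(ch$log$T_TP <= ch$log$T_all))
  expect_true(all(diff(ch$log$T_all) > 0))
  # reproducibility under the same seed
  ch2 <- run_chain(eng, s$path, n_steps = 300, model = model, seed = 7)
  expect_identical(ch$log, ch2$log)
  # zero steps: empty log, seed retained
  ch0 <- run_chain(eng, s$path, n_steps = 0, model = model, seed = 7)
  expect_equal(nrow(ch0$log), 0)
  expect_identical(ch0$final_path$frames, s$path$frames)
})

test_that("a resumed chain reproduces the unbroken run bit-identically", {
  spec <- birth_death_chain(5, 0.6, 0.4)
  eng <- make_discrete_engine(spec)
  model <- committor_table(exact_committor_discrete(spec))
  set.seed(2)
  repeat { s <- two_way_shot(eng, 3, "B"); if (!is.null(s$path)) break }
  full <- run_chain(eng, s$path, n_steps = 250, model = model, seed = 5)
  part <- run_chain(eng, s$path, n_steps = 130, model = model, seed = 5)
  resumed <- run_chain(eng, n_steps = 120, resume_from = part)
  expect_identical(full$log, resumed$log)
  expect_identical(full$records, resumed$records)
})

test_that("path observables average and smooth as stated", {
  pot <- dw_potential()
  states <- double_well_states(pot)
  p <- tps_path(matrix(c(-0.95, -0.2, 0.2, 0.95), ncol = 1), 1, states)
  expect_equal(time_average_xi(p, function(f) rep(3, nrow(f))), 3)
  expect_equal(time_average_xi(p, function(f) f[, 1]),
               mean(c(-0.95, -0.2, 0.2, 0.95)))
  expect_error(time_average_xi(list(frames = matrix(numeric(0))), identity))
  s <- c(1, 2, 3, 4, 5)
  expect_equal(smooth_series(s, 1), s)
  expect_equal(smooth_series(s, 3)[3], 3)
  expect_equal(smooth_series(s, 3)[1], mean(c(1, 2)))
  expect_equal(smooth_series(rep(2, 30), 10), rep(2, 30))
  # hand-computed centered window-4 value
  expect_equal(smooth_series(s, 4)[3], mean(c(2, 3, 4, 5)))
})
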