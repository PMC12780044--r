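#' Transition path objects
#'
#' A transition path is an ordered set of frames whose first and last
#' frames lie inside (different) metastable states while every interior
#' frame lies in none (first-entrance convention). The constructor
#' asserts this invariant.
#'
#' @param frames matrix of frames (rows).
#' @param dt frame time spacing.
#' @param state_defs list of `tps_state`.
#' @param sp_index index of the shooting point that generated the path.
#' @param mc_index MC step of generation.
#' @param check assert the endpoint invariant?
#' @return A `tps_path`.
#' @export
tps_path <- function(frames, dt, state_defs, sp_index = NA_integer_,
                     mc_index = NA_integer_, check = TRUE) {
  frames <- as.matrix(frames)
  nf <- nrow(frames)
  ends <- c(classify_state(frames[1, ], state_defs),
            classify_state(frames[nf, ], state_defs))
  if (check) {
    if (any(is.na(ends)) || ends[1] == ends[2]) {
      stop("path endpoints must lie in two different states.", call. = FALSE)
    }
    interior <- vapply(seq_len(nf - 2L) + 1L, function(i)
      is.na(classify_state(frames[i, ], state_defs)), logical(1))
    if (nf > 2 && !all(interior)) {
      stop("interior path frames must lie in no state (first-entrance).",
           call. = FALSE)
    }
  }
  structure(list(frames = frames, dt = dt,
                 times = (seq_len(nf) - 1) * dt,
                 endpoint_states = ends, sp_index = sp_index,
                 mc_index = mc_index),
            class = "tps_path")
}

#' @export
print.tps_path <- function(x, ...) {
  cat("<tps_path>", nrow(x$frames), "frames,",
      x$endpoint_states[1], "->", x$endpoint_states[2],
      sprintf(" duration %.4g", x$times[length(x$times)]), "\n")
  invisible(x)
}

#' Two-way shooting move
#'
#' Propagates two independent first-entrance segments from the shooting
#' point and counts `k`, the number of segment endpoints in the
#' designated final state (`k` is always counted toward that state,
#' whatever the resulting path direction). If the two endpoints lie in
#' different states, the segments are spliced into a trial transition
#' path (one segment time-reversed through the shooting point), oriented
#' from the initial to the final state.
#'
#' @param engine a `tps_engine`.
#' @param x_sp shooting-point frame (must lie in no state).
#' @param final_state name of the state `k` counts hits of.
#' @param seed optional seed (otherwise ambient RNG stream).
#' @return list with `path` (a `tps_path` or `NULL`), `k` (`NA` if a
#'   segment was unresolved), `resolved`, `sp_index` (index of the
#'   shooting point inside the trial path), `segment_steps` (propagated
#'   steps of both segments, for wall-time accounting).
#' @export
two_way_shot <- function(engine, x_sp, final_state, seed = NULL) {
  state_defs <- engine$state_defs
  if (!is.na(classify_state(x_sp, state_defs))) {
    stop("shooting point lies inside a state.", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  seg1 <- engine$propagate(x_sp)
  seg2 <- engine$propagate(x_sp)
  steps <- seg1$n_steps + seg2$n_steps
  if (!seg1$resolved || !seg2$resolved) {
    return(list(path = NULL, k = NA_integer_, resolved = FALSE,
                sp_index = NA_integer_, segment_steps = steps))
  }
  ends <- c(seg1$terminal_state, seg2$terminal_state)
  k <- sum(ends == final_state)
  path <- NULL
  sp_index <- NA_integer_
  if (ends[1] != ends[2]) {
    # orient the path toward final_state: the segment ending there goes last
    if (seg1$terminal_state == final_state) { tmp <- seg1; seg1 <- seg2; seg2 <- tmp }
    n1 <- nrow(seg1$frames)
    frames <- rbind(seg1$frames[rev(seq_len(n1)), , drop = FALSE],
                    seg2$frames[-1, , drop = FALSE])
    sp_index <- n1
    path <- tps_path(frames, dt = engine$dt, state_defs = state_defs,
                     sp_index = sp_index)
  }
  list(path = path, k = as.integer(k), resolved = TRUE, sp_index = sp_index,
       segment_steps = steps)
}

#' Metropolis-Hastings acceptance for shooting moves
#'
#' For flexible-length two-way shooting from a reversible propagator the
#' acceptance probability preserving the transition-path ensemble is
#' `min(1, p_sel(x_SP | trial) / p_sel(x_SP | current))`, where `p_sel`
#' is the normalized selection weight of the shooting point within each
#' path. (Under uniform selection this reduces to the classic ratio of
#' eligible frame counts, and equals 1 for equal-length paths.)
#'
#' @param trial,current `tps_path` objects; the shooting point must be a
#'   frame of both.
#' @param selection_fn function mapping a path to normalized per-frame
#'   selection probabilities (see [selection_weights()]).
#' @param sp_index_trial,sp_index_current index of the shooting point in
#'   each path.
#' @param u optional uniform variate (for testing); default drawn from
#'   the ambient stream.
#' @return logical: accept?
#' @export
accept_move <- function(trial, current, selection_fn,
                        sp_index_trial, sp_index_current, u = NULL) {
  w_t <- selection_fn(trial)
  w_c <- selection_fn(current)
  if (sp_index_trial > length(w_t) || sp_index_current > length(w_c)) {
    stop("shooting point index outside path frames.", call. = FALSE)
  }
  p_t <- w_t[sp_index_trial]
  p_c <- w_c[sp_index_current]
  if (p_c <= 0) stop("shooting point has zero selection weight in the current path.",
                     call. = FALSE)
  if (is.null(u)) u <- runif(1)
  u < min(1, p_t / p_c)
}

#' Run a sequential two-way-shooting TPS chain
#'
#' The driver repeats: select a shooting point from the current path
#' (uniformly, or Cauchy-logit reweighted once the logit histogram is
#' built), perform a two-way shot, accept or reject by
#' [accept_move()], and log. On rejection (including unresolved shots,
#' which are logged distinctly) the current path is retained and counts
#' as an MC step. The committor model can be retrained on the
#' accumulated shooting records on a schedule. Wall-clock bookkeeping
#' follows the efficiency conventions: `T_TP` accumulates durations of
#' newly accepted transition paths only, `T_all` all propagated segment
#' time including rejected shots.
#'
#' @param engine a `tps_engine`.
#' @param seed_path a `tps_path` to start from.
#' @param n_steps number of MC steps.
#' @param model committor model used for shooting-point selection (and
#'   logged `phi` at the shooting points); `NULL` disables reweighting.
#' @param final_state state whose hits `k` counts; default: the state
#'   the seed path ends in.
#' @param control an [sp_control()].
#' @param xi_fn optional per-frame observable; its path time-average
#'   `xi_hat` is logged per MC step (e.g. a pore coordinate).
#' @param retrain_every,retrain_fn optional committor retraining:
#'   every `retrain_every` steps, `model <- retrain_fn(records, model)`.
#' @param archive_paths keep all accepted paths in the result?
#' @param seed integer seed for the whole chain.
#' @param resume_from a previous `tps_chain` to continue: the RNG state,
#'   current path, logit pool and histogram are restored so that a
#'   resumed run reproduces an unbroken run bit-identically.
#' @return A `tps_chain`: list with `log` (one tibble row per MC step),
#'   `records` (shooting records with feature columns, `n`, `k`,
#'   `accepted`, `mc_index`), `final_path`, `paths` (if archived),
#'   `model`, `hist`, `acceptance_rate`, `T_TP`, `T_all`.
#' @export
run_chain <- function(engine, seed_path, n_steps, model = NULL,
                      final_state = NULL, control = sp_control(),
                      xi_fn = NULL, retrain_every = NULL, retrain_fn = NULL,
                      archive_paths = FALSE, seed = 1, resume_from = NULL) {
  state_defs <- engine$state_defs
  if (!is.null(resume_from)) {
    stopifnot(inherits(resume_from, "tps_chain"))
    current <- resume_from$final_path
    hist <- resume_from$hist
    qpool <- resume_from$state$qpool
    offset <- nrow(resume_from$log)
    T_TP0 <- resume_from$T_TP; T_all0 <- resume_from$T_all
    n_acc0 <- resume_from$state$n_acc
    model <- resume_from$model
    final_state <- resume_from$final_state
    seed <- resume_from$seed
    assign(".Random.seed", resume_from$state$rng, envir = globalenv())
  } else {
    stopifnot(inherits(seed_path, "tps_path"))
    set.seed(seed)
    if (is.null(final_state)) final_state <- seed_path$endpoint_states[2]
    current <- seed_path
    hist <- NULL
    qpool <- list()  # logits of frames of accepted transition paths
    offset <- 0L
    T_TP0 <- 0; T_all0 <- 0; n_acc0 <- 0L
  }
  pool_q <- function(path) {
    if (is.null(model)) return()
    nf <- nrow(path$frames)
    if (nf > 2) {
      qpool[[length(qpool) + 1L]] <<-
        committor_logit(model, path$frames[2:(nf - 1L), , drop = FALSE])
    }
  }
  if (is.null(resume_from)) pool_q(current)

  n_feat <- ncol(current$frames)
  feat_names <- if (n_feat == 1) "x" else paste0("x", seq_len(n_feat))
  log_rows <- vector("list", n_steps)
  rec_rows <- vector("list", n_steps)
  paths <- if (archive_paths) list() else NULL
  T_TP <- T_TP0; T_all <- T_all0
  n_acc <- n_acc0

  for (i in offset + seq_len(n_steps)) {
    phase <- update_schedule(i, control)
    if (!is.null(model) && phase %in% c("build", "refresh") && length(qpool) > 0) {
      hist <- build_logit_histogram(unlist(qpool), control)
    }
    w <- selection_weights(current, model, hist)
    sp_i <- select_sp(current, w)
    x_sp <- current$frames[sp_i, ]
    phi_sp <- if (!is.null(model)) predict_phi(model, x_sp) else NA_real_

    shot <- two_way_shot(engine, x_sp, final_state)
    T_all <- T_all + shot$segment_steps * engine$dt
    accepted <- FALSE
    if (!is.null(shot$path)) {
      accepted <- accept_move(shot$path, current,
                              function(p) selection_weights(p, model, hist),
                              shot$sp_index, sp_i)
      if (accepted) {
        current <- shot$path
        current$mc_index <- i
        n_acc <- n_acc + 1L
        T_TP <- T_TP + current$times[length(current$times)]
        pool_q(current)
        if (archive_paths) paths[[length(paths) + 1L]] <- current
      }
    }
    xi_hat <- if (!is.null(xi_fn)) time_average_xi(current, xi_fn) else NA_real_
    log_rows[[i - offset]] <- list(
      mc_index = i, accepted = accepted, resolved = shot$resolved,
      k = shot$k, phi_sp = phi_sp,
      generated = isTRUE(shot$k == 1L),
      sp_index = sp_i,
      path_len = nrow(current$frames),
      path_time = current$times[length(current$times)],
      path_mc_index = current$mc_index,
      xi_hat = xi_hat,
      path_key = if (!is.null(engine$key_fn)) engine$key_fn(current$frames)
                 else NA_character_,
      T_TP = T_TP, T_all = T_all
    )
    rec <- as.list(setNames(as.numeric(x_sp), feat_names))
    rec$n <- 2L; rec$k <- shot$k
    rec$accepted <- accepted; rec$resolved <- shot$resolved
    rec$mc_index <- i
    rec$phi <- phi_sp
    rec_rows[[i - offset]] <- rec

    if (!is.null(retrain_every) && !is.null(retrain_fn) &&
        i %% retrain_every == 0) {
      so_far <- dplyr::bind_rows(lapply(rec_rows[seq_len(i - offset)],
                                        tibble::as_tibble))
      if (!is.null(resume_from)) {
        so_far <- dplyr::bind_rows(resume_from$records, so_far)
      }
      model <- retrain_fn(so_far, model)
    }
  }
  log <- dplyr::bind_rows(lapply(log_rows, tibble::as_tibble))
  records <- dplyr::bind_rows(lapply(rec_rows, tibble::as_tibble))
  if (!is.null(resume_from)) {
    log <- dplyr::bind_rows(resume_from$log, log)
    records <- dplyr::bind_rows(resume_from$records, records)
  }
  structure(list(log = log, records = records, final_path = current,
                 paths = paths, model = model, hist = hist,
                 acceptance_rate = n_acc / max(nrow(log), 1),
                 T_TP = T_TP, T_all = T_all,
                 final_state = final_state, seed = seed,
                 state = list(rng = get(".Random.seed", envir = globalenv()),
                              qpool = qpool, n_acc = n_acc)),
            class = "tps_chain")
}

#' @export
print.tps_chain <- function(x, ...) {
  cat("<tps_chain>", nrow(x$log), "MC steps, acceptance",
      sprintf("%.3f", x$acceptance_rate), "\n")
  cat("  T_TP =", signif(x$T_TP, 4), " T_all =", signif(x$T_all, 4), "\n")
  invisible(x)
}

#' @export
glance.tps_chain <- function(x, ...) {
  tibble::tibble(
    n_steps = nrow(x$log),
    acceptance_rate = x$acceptance_rate,
    n_generated = sum(x$log$generated, na.rm = TRUE),
    T_TP = x$T_TP,
    T_all = x$T_all,
    eta_T = if (x$T_all > 0) x$T_TP / x$T_all else NA_real_
  )
}

#' @export
tidy.tps_chain <- function(x, ...) x$log

#' Path time-average of an observable
#'
#' @param path a `tps_path`.
#' @param xi_fn function of a frame matrix returning one value per row
#'   (or of a single frame vector returning a scalar).
#' @return mean of the observable over the path frames.
#' @export
time_average_xi <- function(path, xi_fn) {
  if (is.null(path$frames) || nrow(path$frames) == 0) {
    stop("empty path.", call. = FALSE)
  }
  v <- tryCatch(xi_fn(path$frames), error = function(e) NULL)
  if (is.null(v) || length(v) != nrow(path$frames)) {
    v <- apply(path$frames, 1, xi_fn)
  }
  mean(v)
}

#' Centered moving average
#'
#' Smooths a per-MC-step series with a centered moving average of the
#' given window (default 10 steps), truncated at the series ends.
#'
#' @param series numeric vector.
#' @param window window width in steps; 1 returns the series unchanged.
#' @export
smooth_series <- function(series, window = 10) {
  stopifnot(window >= 1)
  n <- length(series)
  half_lo <- floor((window - 1) / 2)
  half_hi <- ceiling((window - 1) / 2)
  vapply(seq_len(n), function(i) {
    mean(series[max(1, i - half_lo):min(n, i + half_hi)])
  }, numeric(1))
}
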