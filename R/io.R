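#' Read and write shooting records
#'
#' Shooting records travel as plain CSV (columns `id`, `phi`, `n`, `k`,
#' plus any feature columns `x`/`x1`.../`chain_id`) or as JSON lines
#' (one record object per line).
#'
#' @param records tibble of shooting records.
#' @param path file path.
#' @export
write_shot_records_csv <- function(records, path) {
  write.csv(as.data.frame(records), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_shot_records_csv
#' @export
read_shot_records_csv <- function(path) {
  tibble::as_tibble(read.csv(path))
}

#' @rdname write_shot_records_csv
#' @export
write_shot_records_jsonl <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(jsonlite::toJSON(as.list(records[i, ]), auto_unbox = TRUE,
                                digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_shot_records_csv
#' @export
read_shot_records_jsonl <- function(path) {
  lines <- readLines(path)
  dplyr::bind_rows(lapply(lines, function(l)
    tibble::as_tibble(jsonlite::fromJSON(l))))
}

default_run_config <- function() {
  list(
    seed = 1,
    out_dir = "tps_run",
    engine = list(kind = "two_channel", barrier_T_kT = 3, barrier_P_kT = 7,
                  intermediate_depth_kT = 2, barrier_kT = 5, x_min_sep = 2,
                  dt = 1e-3, beta = 1, max_steps = 50000, state_radius = 0.55,
                  stride = 5),
    tps = list(n_steps = 200, seed_channel = "T"),
    sp = list(build_at = 100, refresh_every = 250, bins = 50,
              clip = c(-10, 10)),
    network = list(widths = "auto", resnet_depth = 0, dropout = 0.0,
                   l2 = 1e-4),
    train = list(enabled = TRUE, every = 50, epochs_max = 200, lr = 3e-3,
                 batch_size = 256, patience = 30)
  )
}

merge_config <- function(defaults, user, prefix = "") {
  for (key in names(user)) {
    full <- if (prefix == "") key else paste0(prefix, ".", key)
    if (!key %in% names(defaults)) {
      stop(sprintf("unknown config key '%s'", full), call. = FALSE)
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]])) {
        stop(sprintf("config key '%s' must be a mapping", full), call. = FALSE)
      }
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load a run configuration
#'
#' Reads a YAML configuration, validates every key against the known
#' schema (unknown keys are a hard error, naming the offending key) and
#' fills in explicit defaults. The fully resolved configuration is
#' returned and, when `echo_path` is given, also written back out so
#' the effective settings are on record.
#'
#' @param path YAML file.
#' @param echo_path optional path for the resolved-config echo file.
#' @return A `run_config` list.
#' @export
load_run_config <- function(path, echo_path = NULL) {
  user <- yaml::read_yaml(path)
  cfg <- merge_config(default_run_config(), user %||% list())
  class(cfg) <- "run_config"
  if (!is.null(echo_path)) save_run_config(cfg, echo_path)
  cfg
}

#' @rdname load_run_config
#' @param config a `run_config`.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

channel_of_path <- function(path, y_intermediate) {
  max(path$frames[, 2]) > y_intermediate / 2
}

#' Seed a transition path in a chosen channel of the two-channel toy
#'
#' Shoots repeatedly from a point on the chosen channel's ridge until a
#' valid transition path through that channel is obtained (the analogue
#' of preparing restrained initial pathways for either mechanism).
#'
#' @param engine a two-channel `tps_engine`.
#' @param potential the two-channel `tps_potential`.
#' @param channel `"T"` (direct) or `"P"` (through the intermediate).
#' @param max_tries attempts before giving up.
#' @param seed integer seed.
#' @return a `tps_path`.
#' @export
seed_two_channel_path <- function(engine, potential, channel = c("T", "P"),
                                  max_tries = 200, seed = 1) {
  channel <- match.arg(channel)
  yI <- potential$params$y_intermediate
  start <- if (channel == "P") c(0, yI) else c(0, 0.05)
  set.seed(seed)
  for (i in seq_len(max_tries)) {
    shot <- two_way_shot(engine, start, final_state = "U")
    if (!is.null(shot$path) &&
        channel_of_path(shot$path, yI) == (channel == "P")) {
      return(shot$path)
    }
  }
  stop(sprintf("no %s-channel seed path found in %d tries", channel,
               max_tries), call. = FALSE)
}

#' Run the demo pipeline end to end
#'
#' Orchestrates the stages in their natural order on the two-channel toy
#' system: build the landscape and engine, prepare a seed transition
#' path in the requested channel, run the two-way-shooting TPS chain
#' (with optional on-the-fly committor training), then compute
#' diagnostics (efficiencies, accuracy) and the mechanism
#' classification. Artifacts (chain log, shooting records, diagnostics
#' JSON, resolved config, manifest with content hashes) are written to
#' `config$out_dir`.
#'
#' @param config a `run_config` (see [load_run_config()]).
#' @return invisibly, a list with `chain`, `diagnostics`, `mechanism`
#'   and the artifact `manifest`.
#' @export
pipeline_run <- function(config) {
  cfg <- if (inherits(config, "run_config")) config
         else merge_config(default_run_config(), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  eng_cfg <- cfg$engine
  if (eng_cfg$kind == "two_channel") {
    pot <- make_two_channel_2d(eng_cfg$barrier_T_kT, eng_cfg$barrier_P_kT,
                               eng_cfg$intermediate_depth_kT)
    states <- two_channel_states(pot, radius = eng_cfg$state_radius)
  } else {
    pot <- make_double_well_1d(eng_cfg$barrier_kT, eng_cfg$x_min_sep)
    states <- double_well_states(pot)
  }
  engine <- make_langevin_engine(pot, dt = eng_cfg$dt, beta = eng_cfg$beta,
                                 max_steps = eng_cfg$max_steps,
                                 state_defs = states,
                                 stride = eng_cfg$stride)
  seed_path <- if (eng_cfg$kind == "two_channel") {
    seed_two_channel_path(engine, pot, cfg$tps$seed_channel,
                          seed = cfg$seed)
  } else {
    set.seed(cfg$seed)
    repeat {
      shot <- two_way_shot(engine, c(x = 0), final_state = "U")
      if (!is.null(shot$path)) break
    }
    shot$path
  }
  widths <- cfg$network$widths
  if (is.null(widths) || identical(widths, "auto")) {
    widths <- c(pot$dim, 8, 8, 1)
  }
  model <- build_network(network_spec(widths,
                                      resnet_depth = cfg$network$resnet_depth,
                                      dropout = cfg$network$dropout,
                                      l2 = cfg$network$l2),
                         seed = cfg$seed)
  retrain_fn <- NULL
  if (isTRUE(cfg$train$enabled)) {
    retrain_fn <- function(records, old_model) {
      recs <- records[records$resolved & !is.na(records$k), ]
      recs$chain_id <- rep_len(1:2, nrow(recs))
      train_committor(recs, model$spec, epochs_max = cfg$train$epochs_max,
                      lr = cfg$train$lr, batch_size = cfg$train$batch_size,
                      patience = cfg$train$patience, seed = cfg$seed)
    }
  }
  xi_fn <- if (pot$dim == 2) function(frames) frames[, 2] else NULL
  chain <- run_chain(engine, seed_path, n_steps = cfg$tps$n_steps,
                     model = model,
                     control = sp_control(cfg$sp$build_at,
                                          cfg$sp$refresh_every,
                                          cfg$sp$bins, cfg$sp$clip),
                     xi_fn = xi_fn,
                     retrain_every = if (is.null(retrain_fn)) NULL
                                     else cfg$train$every,
                     retrain_fn = retrain_fn,
                     seed = cfg$seed)
  log_ok <- chain$log[chain$log$resolved & !is.na(chain$log$phi_sp), ]
  eff <- efficiency_dn(dplyr::transmute(log_ok, phi = .data$phi_sp,
                                        generated = .data$generated))
  diag <- list(
    acceptance_rate = chain$acceptance_rate,
    eta_T = efficiency_time(chain),
    eta_dn_final = eff$eta_dn[nrow(eff)],
    n_generated = sum(chain$log$generated, na.rm = TRUE)
  )
  mech <- if (!is.null(xi_fn)) classify_mechanism(chain, threshold = 1.0)
          else NULL

  paths <- list(log = file.path(cfg$out_dir, "chain_log.csv"),
                records = file.path(cfg$out_dir, "shot_records.csv"),
                diagnostics = file.path(cfg$out_dir, "diagnostics.json"),
                config = file.path(cfg$out_dir, "config_echo.yaml"))
  write.csv(as.data.frame(chain$log), paths$log, row.names = FALSE)
  write_shot_records_csv(chain$records, paths$records)
  jsonlite::write_json(diag, paths$diagnostics, auto_unbox = TRUE,
                       digits = NA)
  save_run_config(cfg, paths$config)
  manifest <- tibble::tibble(
    artifact = names(paths),
    file = unlist(paths),
    md5 = unname(tools::md5sum(unlist(paths))),
    seed = cfg$seed
  )
  write.csv(as.data.frame(manifest), file.path(cfg$out_dir, "manifest.csv"),
            row.names = FALSE)
  invisible(list(chain = chain, diagnostics = diag, mechanism = mech,
                 manifest = manifest))
}
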