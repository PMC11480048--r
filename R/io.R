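FERM_LOG_SCHEMA <- "rqtwin-1"

ferm_log_columns <- function() {
  c("t", "n_rpm", "feed_lh", "v_l", "x_gl", "s_gl", "etoh_gl", "ara_gl",
    "suc_gl", "p_kaul", "do_moll", "f_air_lmin", "f_o2_lmin", "y_o2_in_pct",
    "y_co2_in_pct", "y_o2_out_true_pct", "y_co2_out_true_pct", "y_o2_out_pct",
    "y_co2_out_pct", "humidity_pct", "our_true", "cer_true", "rq_true",
    "our", "cer", "rq", "mu_true", "qs_true", "qo2_true", "qco2_true",
    "qetoh_true", "qara_true", "qsuc_true", "qp_true", "cum_glc_g",
    "cum_co2_mol", "cum_o2_mol", "action_delta_rpm", "epsilon", "k_p",
    "action_rule")
}

#' Write / read a fermentation log
#'
#' Plain-CSV persistence of a `ferm_log` with the schema version, seed and
#' controller recorded in commented header lines. The round trip is lossless
#' to full double precision.
#'
#' @param log a `ferm_log` from [simulate_fedbatch()].
#' @param path CSV file path.
#' @return `read_ferm_log()` returns the `ferm_log`; `write_ferm_log()` the
#'   path, invisibly.
#' @export
write_ferm_log <- function(log, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# schema: ", FERM_LOG_SCHEMA),
    paste0("# seed: ", attr(log, "seed")),
    paste0("# controller: ", attr(log, "controller"))
  ), con)
  utils::write.csv(log[ferm_log_columns()], con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ferm_log
#' @export
read_ferm_log <- function(path) {
  hdr <- readLines(path, n = 3)
  schema <- sub("^# schema: ", "", hdr[grepl("^# schema:", hdr)])
  if (!length(schema) || schema != FERM_LOG_SCHEMA)
    stop("log schema mismatch: expected ", FERM_LOG_SCHEMA)
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(ferm_log_columns(), names(d))
  if (length(missing))
    stop("log is missing column(s): ", paste(missing, collapse = ", "))
  if (is.unsorted(d$t, strictly = TRUE))
    stop("log time column must be strictly increasing")
  for (nm in setdiff(ferm_log_columns(), "action_rule"))
    d[[nm]] <- as.numeric(d[[nm]])   # all-NA columns otherwise read as logical
  class(d) <- c("ferm_log", "data.frame")
  seed <- sub("^# seed: ", "", hdr[grepl("^# seed:", hdr)])
  attr(d, "seed") <- suppressWarnings(as.integer(seed))
  attr(d, "schema") <- schema
  attr(d, "controller") <- sub("^# controller: ", "",
                               hdr[grepl("^# controller:", hdr)])
  d
}

#' Default run configuration
#'
#' Nested list mirroring the configurable surface: `twin` ([twin_params()]
#' arguments), `controller` (type, set-point, thresholds, schedules, clocks,
#' initial agitation), `gain_model`, `metrics`, `reconciliation`, plus the
#' run-level `seed`, `horizon` and `disturbances`.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    twin = list(
      mu_set = 0.10, S_feed = 400, X0 = 25, V0 = 2, Y_XS_ox = 0.55,
      Y_XS_ferm = 0.10,
      byproduct_split = list(ethanol = 0.90, arabitol = 0.07,
                             succinate = 0.03),
      Y_PX = 3.8, kla_a = NULL, kla_b = 2, calib_N = 575, calib_rq = 1.4,
      O2_sat = 2.1e-4, gas_lag_tau = 7,
      noise_rsd = list(y_o2 = 0.02, y_co2 = 0.02, humidity = 0.02),
      air_O2_frac = 0.2097, air_CO2_frac = 0.0004,
      biomass_formula = list(h = 1.761, o = 0.636, n = 0.143),
      qS_max = 0.30, our_floor = 0.002, online_avg_min = 5,
      vm = 24.465, F_air = 2.0, F_O2 = 0.0,
      humidity_out = 2.0, yxs_observer = 0.45
    ),
    controller = list(
      type = "blc", set_point = 1.4, init_N = NULL,
      mhc = list(check_interval = 30, threshold = 1.6, step = 50,
                 init_N = 600),
      blc = list(check_interval = 10, up_threshold = 1.4,
                 down_threshold = 1.3, down_step = 10,
                 sched_breaks = c(6, 12), sched_steps = c(10, 15, 25),
                 init_N = 550),
      apc = list(min_action_gap = 7, deadband = 2, kp_max = 5000,
                 init_N = 550)
    ),
    gain_model = list(n_trees = 100, cadence_min = 10,
                      corpus_mu = c(0.08, 0.10, 0.12),
                      corpus_strategies = c("mhc", "blc")),
    metrics = list(set_point = 1.4, band = c(1.2, 1.6), exclude_first_h = 0,
                   recovery_band = c(1.3, 1.5), recovery_dwell_min = 10),
    reconciliation = list(confidence = 0.95,
                          rsd = list(mu = 0.05, qS = 0.02, qO2 = 0.05,
                                     qCO2 = 0.05, qEtOH = 0.02, qAra = 0.02,
                                     qSuc = 0.02)),
    seed = 1, horizon = 20,
    disturbances = list(list(t = 13.3, F_air = 1.8, F_O2 = 0.2))
  )
}

merge_config <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s)", if (nzchar(path)) paste0(" in ", path),
         ": ", paste(unknown, collapse = ", "))
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                     paste0(path, nm, "."))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration, rejects unknown keys and merges it
#' over [default_config()].
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return validated configuration list.
#' @export
load_run_config <- function(path) {
  user <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop("config must be a .yaml/.yml or .json file")
  }
  merge_config(default_config(), user)
}

#' Build twin parameters / a controller from a configuration
#'
#' @param config list from [default_config()] or [load_run_config()].
#' @param model optional [gain_model][train_gain_model()] (needed for
#'   `type = "apc"`).
#' @param type controller type override.
#' @return [twin_params()] or a controller object.
#' @export
config_twin_params <- function(config) {
  tw <- config$twin
  tw$byproduct_split <- unlist(tw$byproduct_split)
  tw$noise_rsd <- unlist(tw$noise_rsd)
  tw$biomass_formula <- unlist(tw$biomass_formula)
  do.call(twin_params, tw)
}

#' @rdname config_twin_params
#' @export
config_controller <- function(config, model = NULL,
                              type = config$controller$type) {
  cc <- config$controller
  switch(type,
    null = null_controller(),
    mhc = mhc_controller(init_N = cc$mhc$init_N,
                         check_interval = cc$mhc$check_interval,
                         threshold = cc$mhc$threshold,
                         sched = step_schedule(numeric(0), cc$mhc$step)),
    blc = blc_controller(init_N = cc$blc$init_N,
                         check_interval = cc$blc$check_interval,
                         up_threshold = cc$blc$up_threshold,
                         down_threshold = cc$blc$down_threshold,
                         down_step = cc$blc$down_step,
                         sched = step_schedule(unlist(cc$blc$sched_breaks),
                                               unlist(cc$blc$sched_steps))),
    apc = {
      if (is.null(model)) stop("an APC controller needs a trained gain model")
      apc_controller(model, init_N = cc$apc$init_N,
                     set_point = cc$set_point,
                     min_action_gap = cc$apc$min_action_gap,
                     deadband = cc$apc$deadband,
                     kp_range = c(0, cc$apc$kp_max))
    },
    stop("unknown controller type: ", type)
  )
}
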