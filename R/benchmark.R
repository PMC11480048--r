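#' Generate the gain-model training corpus
#'
#' Simulates the hypoxic fed-batch under the manual-heuristic and
#' Boolean-logic strategies at several design growth rates (same physical
#' plant: the kLa correlation of `params` is reused, only the feed schedule
#' changes), emulating the historical run archive the gain model learns
#' from.
#'
#' @param params base [twin_params()]; per-run parameter sets differ only in
#'   `mu_set`.
#' @param mu_values design growth rates of the corpus runs (1/h).
#' @param strategies subset of `c("mhc", "blc")`.
#' @param horizon run length (h).
#' @param seed base integer seed; each run derives its own.
#' @return list of `ferm_log`s.
#' @export
generate_training_corpus <- function(params = twin_params(),
                                     mu_values = c(0.08, 0.10, 0.12),
                                     strategies = c("mhc", "blc"),
                                     horizon = 20, seed = 1) {
  logs <- list()
  i <- 0
  for (mu in mu_values) {
    p_mu <- twin_params(mu_set = mu, S_feed = params$S_feed, X0 = params$X0,
                        V0 = params$V0, Y_XS_ox = params$Y_XS_ox,
                        Y_XS_ferm = params$Y_XS_ferm,
                        byproduct_split = params$byproduct_split,
                        Y_PX = params$Y_PX,
                        kla_a = params$kla_a, kla_b = params$kla_b,
                        O2_sat = params$O2_sat,
                        gas_lag_tau = params$gas_lag_tau,
                        noise_rsd = params$noise_rsd,
                        air_O2_frac = params$air_O2_frac,
                        air_CO2_frac = params$air_CO2_frac,
                        biomass_formula = params$biomass_formula,
                        qS_max = params$qS_max, our_floor = params$our_floor,
                        vm = params$vm, F_air = params$F_air,
                        F_O2 = params$F_O2,
                        humidity_out = params$humidity_out,
                        yxs_observer = params$yxs_observer,
                        calib = params$calib)
    for (strat in strategies) {
      i <- i + 1
      ctrl <- switch(strat, mhc = mhc_controller(), blc = blc_controller())
      logs[[paste0(strat, "_mu", mu)]] <-
        simulate_fedbatch(ctrl, p_mu, horizon = horizon,
                          seed = (seed * 131 + i) %% .Machine$integer.max)
    }
  }
  logs
}

#' Train the default gain model from a fresh corpus
#'
#' Convenience wrapper: [generate_training_corpus()] +
#' [build_training_set()] + [train_gain_model()].
#'
#' @inheritParams generate_training_corpus
#' @param n_trees forest size.
#' @param cadence_min training-row cadence (min).
#' @return a [gain_model][train_gain_model()].
#' @export
train_default_gain_model <- function(params = twin_params(), seed = 1,
                                     mu_values = c(0.08, 0.10, 0.12),
                                     horizon = 20, n_trees = 100,
                                     cadence_min = 10) {
  corpus <- generate_training_corpus(params, mu_values = mu_values,
                                     horizon = horizon, seed = seed)
  ts <- build_training_set(corpus, params, cadence_min = cadence_min)
  train_gain_model(ts$features, ts$targets, n_trees = n_trees,
                   seed = (seed * 977 + 1) %% .Machine$integer.max)
}

#' Three-strategy closed-loop benchmark
#'
#' Reproduces the control-strategy comparison on the digital twin: for each
#' seed, a fresh training corpus is generated and the gain model retrained,
#' then one 20-h fed-batch is run per strategy (manual-heuristic,
#' Boolean-logic, AI-adaptive-proportional). The inlet O2-enrichment
#' disturbance (air 2.0 -> 1.8 L/min plus 0.2 L/min pure O2 at 13.3 h) is
#' applied to the AI-APC runs, as in the plant campaign that stress-tested
#' that controller.
#'
#' @param seeds integer seeds, one closed-loop replicate set each.
#' @param params [twin_params()].
#' @param horizon run length (h).
#' @param disturb_apc apply the O2-enrichment disturbance to the APC runs.
#' @param t_dist disturbance time (h).
#' @param keep_logs keep the full logs in the result (memory permitting).
#' @return list with `report` (from [compare_controllers()], evaluation
#'   window excludes undefined-RQ samples), `logs` (per strategy, if kept)
#'   and `models`.
#' @export
rq_benchmark <- function(seeds = 1:5, params = twin_params(), horizon = 20,
                         disturb_apc = TRUE, t_dist = 13.3,
                         keep_logs = TRUE) {
  logs <- list(mhc = list(), blc = list(), apc = list())
  models <- list()
  for (s in seeds) {
    model <- train_default_gain_model(params, seed = s, horizon = horizon)
    models[[as.character(s)]] <- model
    run_seed <- function(k) (s * 7919 + k) %% .Machine$integer.max
    logs$mhc[[length(logs$mhc) + 1]] <-
      simulate_fedbatch(mhc_controller(), params, horizon, seed = run_seed(1))
    logs$blc[[length(logs$blc) + 1]] <-
      simulate_fedbatch(blc_controller(), params, horizon, seed = run_seed(2))
    dist <- if (disturb_apc && horizon > t_dist)
      list(list(t = t_dist, F_air = 1.8, F_O2 = 0.2)) else list()
    logs$apc[[length(logs$apc) + 1]] <-
      simulate_fedbatch(apc_controller(model), params, horizon,
                        seed = run_seed(3), disturbances = dist)
  }
  report <- compare_controllers(logs, set_point = 1.4)
  recovery <- if (disturb_apc && horizon > t_dist) {
    vapply(logs$apc, function(l)
      recovery_time(rq_trace(l), t_dist, band = c(1.3, 1.5),
                    dwell_min = 10), 0)
  } else NULL
  list(report = report, recovery_h = recovery,
       logs = if (keep_logs) logs else NULL,
       models = models, seeds = seeds, t_dist = t_dist)
}
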