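#' Exponential glucose feed profile
#'
#' Pre-programmed open-loop feed `F(t) = F0 * exp(mu_set * t)` that holds the
#' design specific growth rate in a carbon-limited fed-batch. The base rate
#' `F0 = X0 * V0 * mu_set / (Y_XS_ox * S_feed)` delivers exactly the glucose
#' that fully oxidative growth of the starting biomass would consume.
#'
#' @param t time since the start of the feeding phase (h).
#' @param params [twin_params()].
#' @return feed rate (L/h).
#' @export
feed_rate <- function(t, params) {
  if (any(t < 0)) stop("t must be non-negative")
  F0 <- params$X0 * params$V0 * params$mu_set /
    (params$Y_XS_ox * params$S_feed)
  F0 * exp(params$mu_set * t)
}

#' Volumetric mass-transfer coefficient
#'
#' Power-law correlation `kLa = a * N^b` of the gas-liquid oxygen transfer
#' coefficient with agitation; `a` is calibrated at construction (see
#' [twin_params()]).
#'
#' @param N agitation rate (rpm), > 0.
#' @param params [twin_params()].
#' @return kLa (1/h), strictly increasing in `N`.
#' @export
kla <- function(N, params) {
  if (any(N <= 0)) stop("N must be positive")
  params$kla_a * N^params$kla_b
}

#' Oxygen transfer rate
#'
#' `OTR = kLa * (O2_sat - DO)`. Under hypoxia (`DO ~ 0`) the transfer
#' capacity `kLa * O2_sat` caps the oxygen uptake rate.
#'
#' @param kla_val kLa (1/h).
#' @param O2_sat saturation dissolved oxygen (mol/L).
#' @param DO dissolved oxygen (mol/L), `0 <= DO <= O2_sat`.
#' @return OTR (mol O2/L/h).
#' @export
otr <- function(kla_val, O2_sat, DO) {
  if (any(DO < 0) || any(DO > O2_sat))
    stop("DO must lie in [0, O2_sat]")
  kla_val * (O2_sat - DO)
}

#' Inlet gas blend
#'
#' Mixes air with pure oxygen and returns the resulting inlet composition.
#' With the default dry-air O2 fraction 0.2097, blending 1.8 L/min air with
#' 0.2 L/min O2 gives an inlet O2 fraction of 28.87%.
#'
#' @param F_air,F_O2 air and pure-oxygen flows (L/min); their sum must be
#'   positive.
#' @param params [twin_params()].
#' @return list with `F_air`, `F_O2`, `F_total` (L/min), `y_o2_in`,
#'   `y_co2_in` (molar fractions).
#' @export
inlet_blend <- function(F_air, F_O2, params = twin_params()) {
  if (F_air < 0 || F_O2 < 0) stop("flows must be non-negative")
  total <- F_air + F_O2
  if (total <= 0) stop("at least one inlet flow must be positive")
  list(F_air = F_air, F_O2 = F_O2, F_total = total,
       y_o2_in = (F_air * params$air_O2_frac + F_O2) / total,
       y_co2_in = F_air * params$air_CO2_frac / total)
}

#' Oxygen-limited metabolic split
#'
#' Routes the glucose uptake between the oxidative and the fermentative
#' lumped reaction. The oxygen demand of fully oxidative metabolism is
#' compared with the volumetric transfer capacity `otr_cap`; the oxidatively
#' unservable glucose fraction is fermented to ethanol (plus minor arabitol
#' and succinate) and CO2. The returned rate vector closes the carbon and
#' degree-of-reduction balances exactly, and its implied RQ grows from the
#' oxidative RQ as `otr_cap` shrinks.
#'
#' @param qS_in specific glucose uptake (g_S/g_DCW/h), > 0.
#' @param otr_cap volumetric oxygen transfer capacity (mol O2/L/h).
#' @param X biomass concentration (g_DCW/L), > 0.
#' @param params [twin_params()].
#' @return object of class `rate_vector`: named list `mu` (1/h), `qS`,
#'   `qEtOH`, `qAra`, `qSuc` (g/g/h), `qO2`, `qCO2` (mol/g/h), `qP`
#'   (kAU/g/h), with the oxidative glucose fraction in attribute `f_ox`.
#' @export
metabolic_split <- function(qS_in, otr_cap, X, params) {
  if (qS_in <= 0 || X <= 0 || otr_cap < 0) stop("domain error: qS_in and X must be positive, otr_cap non-negative")
  st <- params$stoich
  qs_cmol <- qS_in / CMOL_MASS[["glucose"]]     # C-mol/g/h
  demand <- qs_cmol * st$a_ox                   # mol O2/g/h, fully oxidative
  avail <- otr_cap / X
  if (avail <= 0)
    stop("fully anaerobic state: no oxygen transfer with positive glucose uptake (RQ undefined)")
  f <- min(1, avail / demand)
  qo2 <- f * demand
  qco2 <- qs_cmol * (f * st$c_ox + (1 - f) * st$c_f)
  y_cmol <- qs_cmol * (f * st$y_ox + (1 - f) * st$y_f)
  mu <- y_cmol * st$mw_x
  rv <- list(
    mu = mu,
    qS = qS_in,
    qO2 = qo2,
    qCO2 = qco2,
    qEtOH = qs_cmol * (1 - f) * st$b_eth * CMOL_MASS[["ethanol"]],
    qAra = qs_cmol * (1 - f) * st$b_ara * CMOL_MASS[["arabitol"]],
    qSuc = qs_cmol * (1 - f) * st$b_suc * CMOL_MASS[["succinate"]],
    qP = params$Y_PX * mu
  )
  attr(rv, "f_ox") <- f
  class(rv) <- "rate_vector"
  rv
}

#' Initial process state of the feeding phase
#'
#' @param params [twin_params()].
#' @param init_N initial agitation (rpm).
#' @return list holding the true state: totals (`XV` g, `S_g`, `E_g`, `A_g`,
#'   `Su_g` g, `P_kau` kAU), volume, agitation, dissolved O2, lagged off-gas
#'   fractions and cumulative inventories.
#' @export
init_state <- function(params, init_N = 575) {
  inlet <- inlet_blend(params$F_air, params$F_O2, params)
  list(t = 0, V = params$V0, XV = params$X0 * params$V0,
       S_g = 0, E_g = 0, A_g = 0, Su_g = 0, P_kau = 0,
       N = init_N, DO = 0,
       y_o2_lag = inlet$y_o2_in, y_co2_lag = inlet$y_co2_in,
       inlet = inlet,
       cum_glc_g = 0, cum_co2_mol = 0, cum_o2_mol = 0)
}

# instantaneous true fluxes at the current state; uptake semantics:
# feed-limited unless a residual glucose pool exists, in which case uptake
# saturates at qS_max until the pool is consumed
compute_fluxes <- function(state, params) {
  X <- state$XV / state$V
  Fl <- feed_rate(state$t, params)
  feed_flux <- Fl * params$S_feed / state$XV            # g_S/g_DCW/h
  qS_up <- if (state$S_g > 1e-12) params$qS_max else min(feed_flux, params$qS_max)
  o2_sat_eff <- params$O2_sat * state$inlet$y_o2_in / params$air_O2_frac
  kl <- kla(state$N, params)
  cap <- kl * o2_sat_eff
  rv <- metabolic_split(qS_up, cap, X, params)
  demand_vol <- rv$qO2 * X
  DO <- if (demand_vol < cap) o2_sat_eff - demand_vol / kl else 0
  list(F = Fl, rates = rv, X = X, DO = DO, o2_sat_eff = o2_sat_eff,
       our = rv$qO2 * X, cer = rv$qCO2 * X)
}

# true dry off-gas fractions from the gas-phase molar balance
true_offgas <- function(our, cer, V, inlet, params) {
  n_in <- inlet$F_total * 60 / params$vm              # mol/h
  n_out <- n_in - our * V + cer * V
  list(y_o2 = (n_in * inlet$y_o2_in - our * V) / n_out,
       y_co2 = (n_in * inlet$y_co2_in + cer * V) / n_out)
}

#' Advance the twin by one time step
#'
#' Applies an agitation change (if any), integrates feeding, growth, product
#' and byproduct formation with explicit sub-steps, and relaxes the lagged
#' (analyzer-side) off-gas fractions towards their true values with the
#' first-order time constant `gas_lag_tau`.
#'
#' @param state state list from [init_state()] or a previous call.
#' @param action a `control_action` or `NULL`.
#' @param params [twin_params()].
#' @param dt step length (h); 1/60 h (the control clock) is the intended use.
#' @param n_sub number of explicit Euler sub-steps per call.
#' @return updated state list.
#' @export
twin_step <- function(state, action, params, dt = 1 / 60, n_sub = 4) {
  if (dt <= 0) stop("dt must be positive")
  if (!is.null(action) && action$delta_rpm != 0) {
    state$N <- state$N + action$delta_rpm
    if (state$N <= 0) stop("simulation error: agitation driven non-positive")
  }
  h <- dt / n_sub
  tau_h <- params$gas_lag_tau / 60
  for (i in seq_len(n_sub)) {
    fl <- compute_fluxes(state, params)
    rv <- fl$rates
    fed_g <- fl$F * params$S_feed * h
    # uptake over the sub-step, capped by what feed + pool can supply
    xv <- state$XV
    up_g <- min(rv$qS * xv * h, fed_g + state$S_g)
    scale <- if (rv$qS > 0) up_g / (rv$qS * xv * h) else 0
    state$S_g <- max(0, state$S_g + fed_g - up_g)
    state$XV <- xv + rv$mu * xv * h * scale
    state$E_g <- state$E_g + rv$qEtOH * xv * h * scale
    state$A_g <- state$A_g + rv$qAra * xv * h * scale
    state$Su_g <- state$Su_g + rv$qSuc * xv * h * scale
    state$P_kau <- state$P_kau + rv$qP * xv * h * scale
    state$cum_co2_mol <- state$cum_co2_mol + rv$qCO2 * xv * h * scale
    state$cum_o2_mol <- state$cum_o2_mol + rv$qO2 * xv * h * scale
    state$cum_glc_g <- state$cum_glc_g + fed_g
    state$V <- state$V + fl$F * h
    state$t <- state$t + h
    # analyzer/headspace first-order lag on the dry off-gas fractions
    tg <- true_offgas(fl$our * scale, fl$cer * scale, state$V, state$inlet, params)
    state$y_o2_lag <- state$y_o2_lag + h / tau_h * (tg$y_o2 - state$y_o2_lag)
    state$y_co2_lag <- state$y_co2_lag + h / tau_h * (tg$y_co2 - state$y_co2_lag)
    state$DO <- fl$DO
  }
  if (state$V < 0 || state$XV < 0 || state$y_o2_lag < 0 || state$y_o2_lag > 1)
    stop("simulation error: state invariant violated")
  state
}

# one sensor sample: lagged dry fractions -> span noise around the inlet
# baseline -> wet basis -> inverse calibration, then the soft sensor
sample_sensors <- function(state, params, noise) {
  rsd <- params$noise_rsd
  xi <- if (noise) stats::rnorm(3) else c(0, 0, 0)
  dep_o2 <- state$inlet$y_o2_in - state$y_o2_lag
  y_o2 <- state$inlet$y_o2_in - dep_o2 * (1 + xi[1] * rsd[["y_o2"]])
  y_co2 <- state$inlet$y_co2_in +
    (state$y_co2_lag - state$inlet$y_co2_in) * (1 + xi[2] * rsd[["y_co2"]])
  hum <- params$humidity_out * (1 + xi[3] * rsd[["humidity"]])
  # sensor-side (raw) values: wet basis, then un-apply the calibration the
  # soft sensor will re-apply
  wetf <- 1 - params$humidity_out / 100
  cal <- params$calib
  raw_o2 <- (y_o2 * wetf - cal$o2$offset) / cal$o2$span
  raw_co2 <- (y_co2 * wetf - cal$co2$offset) / cal$co2$span
  gas_reading(t = state$t, y_o2 = raw_o2, y_co2 = raw_co2,
              humidity = hum, blend = state$inlet,
              F_total_in = state$inlet$F_total, calib = cal)
}

#' Closed-loop fed-batch simulation
#'
#' Runs the digital twin against a controller at a 1-min control clock and
#' returns the complete fermentation log (true and measured channels plus
#' every control action). Scheduled inlet-gas disturbances are applied at
#' their times. With the same seed, controller and parameters the log is
#' bit-identical between calls.
#'
#' @param controller a controller object ([mhc_controller()],
#'   [blc_controller()], [apc_controller()], [null_controller()]).
#' @param params [twin_params()].
#' @param horizon length of the feeding phase to simulate (h).
#' @param seed integer seed for the measurement noise; `NULL` leaves the RNG
#'   alone.
#' @param disturbances list of `list(t =, F_air =, F_O2 =)` inlet-blend
#'   changes, applied once each when the clock reaches `t`.
#' @param noise logical; `FALSE` silences the measurement noise (true and
#'   measured channels then differ only by the analyzer lag).
#' @return a `ferm_log` data frame (one row per minute) with attributes
#'   `seed`, `schema` and `params`.
#' @export
simulate_fedbatch <- function(controller, params = twin_params(), horizon = 20,
                              seed = NULL, disturbances = list(),
                              noise = TRUE) {
  if (horizon <= 0) stop("horizon must be positive")
  if (!is.null(seed)) set.seed(seed)
  state <- init_state(params, init_N = controller$init_N)
  mem <- controller_init(controller)
  n_rows <- floor(horizon * 60) + 1
  num_cols <- c("t", "n_rpm", "feed_lh", "v_l", "x_gl", "s_gl", "etoh_gl",
                "ara_gl", "suc_gl", "p_kaul", "do_moll", "f_air_lmin",
                "f_o2_lmin", "y_o2_in_pct", "y_co2_in_pct",
                "y_o2_out_true_pct", "y_co2_out_true_pct", "y_o2_out_pct",
                "y_co2_out_pct", "humidity_pct", "our_true", "cer_true",
                "rq_true", "our", "cer", "rq", "mu_true", "qs_true",
                "qo2_true", "qco2_true", "qetoh_true", "qara_true",
                "qsuc_true", "qp_true", "cum_glc_g", "cum_co2_mol",
                "cum_o2_mol", "action_delta_rpm", "epsilon", "k_p")
  m <- matrix(NA_real_, nrow = n_rows, ncol = length(num_cols),
              dimnames = list(NULL, num_cols))
  rule <- character(n_rows)
  pending <- disturbances[order(vapply(disturbances, `[[`, 0, "t"))]
  # trailing buffers of raw per-minute OUR/CER for the online soft sensor
  w_avg <- max(1L, as.integer(params$online_avg_min))
  our_raw <- cer_raw <- rep(NA_real_, n_rows)
  for (k in seq_len(n_rows)) {
    t_now <- (k - 1) / 60
    while (length(pending) && t_now >= pending[[1]]$t - 1e-9) {
      d <- pending[[1]]
      state$inlet <- inlet_blend(d$F_air, d$F_O2, params)
      pending <- pending[-1]
    }
    fl <- compute_fluxes(state, params)
    reading <- sample_sensors(state, params, noise)
    gr <- off_gas_rates(correct_reading(reading), state$V,
                        our_floor = params$our_floor, vm = params$vm)
    # online soft sensor: trailing mean of the raw per-minute rates
    our_raw[k] <- gr$OUR
    cer_raw[k] <- gr$CER
    win <- max(1L, k - w_avg + 1L):k
    gr$OUR <- mean(our_raw[win])
    gr$CER <- mean(cer_raw[win])
    gr$RQ <- if (gr$OUR <= params$our_floor) NA_real_ else gr$CER / gr$OUR
    tg <- true_offgas(fl$our, fl$cer, state$V, state$inlet, params)
    obs <- list(t = t_now, rq = gr$RQ, our = gr$OUR, cer = gr$CER,
                N = state$N, feed_lh = fl$F, cum_glc = state$cum_glc_g,
                y_o2_in = state$inlet$y_o2_in,
                x_total_est = params$X0 * params$V0 +
                  params$yxs_observer * state$cum_glc_g)
    ctrl_err <- NULL
    dec <- tryCatch(controller_decide(controller, obs, mem),
                    error = function(e) e)
    if (inherits(dec, "error")) {
      ctrl_err <- conditionMessage(dec)
      act <- NULL
    } else {
      mem <- dec$mem
      act <- dec$action
    }
    m[k, ] <- c(t_now, state$N, fl$F, state$V, fl$X, state$S_g / state$V,
                state$E_g / state$V, state$A_g / state$V,
                state$Su_g / state$V, state$P_kau / state$V, fl$DO,
                state$inlet$F_air, state$inlet$F_O2,
                100 * state$inlet$y_o2_in, 100 * state$inlet$y_co2_in,
                100 * tg$y_o2, 100 * tg$y_co2,
                100 * reading$y_o2, 100 * reading$y_co2, reading$humidity,
                fl$our, fl$cer, fl$rates$qCO2 / fl$rates$qO2,
                gr$OUR, gr$CER, gr$RQ,
                fl$rates$mu, fl$rates$qS, fl$rates$qO2, fl$rates$qCO2,
                fl$rates$qEtOH, fl$rates$qAra, fl$rates$qSuc, fl$rates$qP,
                state$cum_glc_g, state$cum_co2_mol, state$cum_o2_mol,
                if (is.null(act)) 0 else act$delta_rpm,
                if (is.null(act) || is.null(act$epsilon)) NA_real_ else act$epsilon,
                if (is.null(act) || is.null(act$k_p)) NA_real_ else act$k_p)
    rule[k] <- if (is.null(act)) "NONE" else act$rule
    if (!is.null(ctrl_err)) {
      # controller failure: return the partial log with an error record
      m <- m[seq_len(k), , drop = FALSE]
      rule <- rule[seq_len(k)]
      break
    }
    if (k < n_rows)
      state <- twin_step(state, act, params, dt = 1 / 60)
  }
  log <- as.data.frame(m)
  log$action_rule <- rule
  if (!is.null(ctrl_err)) attr(log, "error") <- ctrl_err
  class(log) <- c("ferm_log", "data.frame")
  attr(log, "seed") <- if (is.null(seed)) NA_integer_ else seed
  attr(log, "schema") <- "rqtwin-1"
  attr(log, "controller") <- controller$type
  attr(log, "params") <- params
  log
}
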