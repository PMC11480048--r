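#' Digital-twin parameters
#'
#' Builds and validates the parameter set of the fed-batch digital twin. The
#' twin starts at the end of the glycerol batch phase (`t = 0` of the feeding
#' phase) with biomass `X0` in volume `V0`, feeds glucose exponentially so
#' that the oxidative design growth rate is `mu_set`, and splits glucose
#' between an oxidative and a fermentative lumped reaction according to how
#' much oxygen the gas-liquid transfer can supply (see
#' [metabolic_split()]).
#'
#' The stoichiometric coefficients of both reactions are solved from carbon
#' and degree-of-reduction balances at construction, so the simulated rates
#' close both balances exactly. The oxidative respiratory quotient `rq_ox`
#' is therefore a derived quantity (~1.03 with the defaults) and is checked
#' to fall in the physiological 1.0-1.1 window.
#'
#' If `kla_a` is `NULL` the kLa power-law prefactor is calibrated in closed
#' form so that the steady twin at batch-end conditions (`X0`, `V0`, design
#' feed) sits at `calib_rq` when agitated at `calib_N` rpm.
#'
#' @param mu_set design specific growth rate (1/h) of the exponential feed.
#' @param S_feed glucose concentration of the feed (g/L).
#' @param X0,V0 biomass (g_DCW/L) and volume (L) at the start of the feeding
#'   phase.
#' @param Y_XS_ox,Y_XS_ferm oxidative and fermentative biomass yields on
#'   glucose (g_DCW/g_S); `Y_XS_ferm < Y_XS_ox`.
#' @param byproduct_split named fractions of fermentative byproduct carbon
#'   going to ethanol, arabitol and succinate.
#' @param Y_PX growth-associated product yield (kAU/g_DCW); the specific
#'   production rate is modelled as `qP = Y_PX * mu`.
#' @param kla_a,kla_b coefficients of `kLa = a * N^b` (kLa in 1/h, N in rpm);
#'   `kla_a = NULL` triggers calibration.
#' @param calib_N,calib_rq calibration point for `kla_a` (rpm, RQ).
#' @param O2_sat dissolved-oxygen saturation with air at culture conditions
#'   (mol O2/L); scaled linearly with the inlet O2 fraction when the inlet is
#'   enriched.
#' @param gas_lag_tau first-order time constant (min) lumping headspace and
#'   analyzer dynamics; the plant response time is 5-10 min.
#' @param noise_rsd named relative SDs of the measured channels (`y_o2`,
#'   `y_co2`, `humidity`). Gas-fraction noise is a span error applied to the
#'   respiration-driven deviation of each off-gas fraction from its inlet
#'   baseline (the analyzers are zero-calibrated on inlet gas each run), so
#'   the computed OUR/CER inherit roughly this relative SD.
#' @param air_O2_frac,air_CO2_frac dry-air molar fractions.
#' @param biomass_formula biomass elemental indices `c(h=, o=, n=)` of
#'   CH_hO_oN_n.
#' @param qS_max glucose uptake saturation (g_S/g_DCW/h); feed beyond it
#'   accumulates as residual glucose.
#' @param our_floor OUR (mol/L/h) below which the soft-sensed RQ is reported
#'   as undefined (early fed-batch low-signal regime).
#' @param online_avg_min trailing averaging window (min) of the online
#'   OUR/CER soft sensor published to the controllers; damps analyzer noise
#'   so the adaptive-proportional deadband can operate as intended.
#' @param vm molar volume of the gas (L/mol) at the reference conditions used
#'   to convert volumetric flows to molar flows (default 25 degC, 1 atm).
#' @param F_air,F_O2 default inlet air and pure-oxygen flows (L/min).
#' @param humidity_out off-gas humidity (%) after the silica drying column.
#' @param yxs_observer nominal overall yield (g/g) used only by the on-line
#'   total-biomass observer fed to the gain model.
#' @param calib per-channel sensor calibration corrections, see
#'   [calib_record()].
#' @return object of class `twin_params` (a validated list, with the solved
#'   stoichiometry in `$stoich`).
#' @examples
#' p <- twin_params()
#' p$stoich$rq_ox         # derived oxidative RQ, ~1.03
#' kla(575, p) * p$O2_sat # oxygen transfer capacity at the calibration point
#' @export
twin_params <- function(mu_set = 0.10,
                        S_feed = 400,
                        X0 = 25,
                        V0 = 2,
                        Y_XS_ox = 0.55,
                        Y_XS_ferm = 0.10,
                        byproduct_split = c(ethanol = 0.90, arabitol = 0.07,
                                            succinate = 0.03),
                        Y_PX = 3.8,
                        kla_a = NULL,
                        kla_b = 2,
                        calib_N = 575,
                        calib_rq = 1.4,
                        O2_sat = 2.1e-4,
                        gas_lag_tau = 7,
                        noise_rsd = c(y_o2 = 0.02, y_co2 = 0.02,
                                      humidity = 0.02),
                        air_O2_frac = 0.2097,
                        air_CO2_frac = 0.0004,
                        biomass_formula = c(h = 1.761, o = 0.636, n = 0.143),
                        qS_max = 0.30,
                        our_floor = 0.002,
                        online_avg_min = 5,
                        vm = 24.465,
                        F_air = 2.0,
                        F_O2 = 0.0,
                        humidity_out = 2.0,
                        yxs_observer = 0.45,
                        calib = NULL) {
  stopifnot(mu_set > 0, S_feed > 0, X0 > 0, V0 > 0,
            O2_sat > 0, kla_b > 0, vm > 0, qS_max > 0, our_floor >= 0)
  if (air_O2_frac <= 0 || air_O2_frac >= 1)
    stop("air_O2_frac must lie in (0, 1)")
  if (gas_lag_tau < 5 || gas_lag_tau > 10)
    stop("gas_lag_tau must lie in the empirical 5-10 min response window")
  stoich <- solve_stoichiometry(Y_XS_ox, Y_XS_ferm, byproduct_split,
                                biomass_formula)
  if (stoich$rq_ox < 1.0 || stoich$rq_ox > 1.1)
    stop(sprintf("derived oxidative RQ (%.3f) outside the 1.0-1.1 window; adjust Y_XS_ox or the biomass formula",
                 stoich$rq_ox))
  p <- list(
    mu_set = mu_set, S_feed = S_feed, X0 = X0, V0 = V0,
    Y_XS_ox = Y_XS_ox, Y_XS_ferm = Y_XS_ferm,
    byproduct_split = byproduct_split, Y_PX = Y_PX,
    kla_a = kla_a, kla_b = kla_b, calib_N = calib_N, calib_rq = calib_rq,
    O2_sat = O2_sat, gas_lag_tau = gas_lag_tau, noise_rsd = noise_rsd,
    air_O2_frac = air_O2_frac, air_CO2_frac = air_CO2_frac,
    biomass_formula = biomass_formula, qS_max = qS_max,
    our_floor = our_floor, online_avg_min = online_avg_min,
    vm = vm, F_air = F_air, F_O2 = F_O2,
    humidity_out = humidity_out, yxs_observer = yxs_observer,
    calib = if (is.null(calib)) calib_record() else calib,
    stoich = stoich
  )
  class(p) <- "twin_params"
  if (is.null(p$kla_a)) {
    # closed-form calibration: kLa(calib_N) must supply exactly the OTR that
    # puts the batch-end steady state at calib_rq
    qsx0 <- feed_rate(0, p) * S_feed / (V0 * CMOL_MASS[["glucose"]]) # C-mol/L/h
    fstar <- oxidative_fraction_for_rq(calib_rq, stoich)
    otr_needed <- fstar * qsx0 * stoich$a_ox
    p$kla_a <- otr_needed / O2_sat / calib_N^kla_b
  }
  stopifnot(p$kla_a > 0)
  p
}

#' @export
print.twin_params <- function(x, ...) {
  cat("Digital-twin parameters\n")
  cat(sprintf("  mu_set %.3f 1/h, S_feed %g g/L, X0 %g g/L, V0 %g L\n",
              x$mu_set, x$S_feed, x$X0, x$V0))
  cat(sprintf("  yields ox/ferm %.2f/%.2f g/g, derived RQ_ox %.3f\n",
              x$Y_XS_ox, x$Y_XS_ferm, x$stoich$rq_ox))
  cat(sprintf("  kLa = %.3e * N^%.1f 1/h, O2_sat %.2e mol/L, lag tau %g min\n",
              x$kla_a, x$kla_b, x$O2_sat, x$gas_lag_tau))
  invisible(x)
}

# oxidative glucose fraction f that yields a target steady RQ:
# RQ(f) = (f*c_ox + (1-f)*c_f) / (f*a_ox)
oxidative_fraction_for_rq <- function(rq, stoich) {
  if (rq < stoich$rq_ox)
    stop(sprintf("RQ %.3f below the oxidative limit %.3f", rq, stoich$rq_ox))
  f <- stoich$c_f / (stoich$a_ox * rq - (stoich$c_ox - stoich$c_f))
  min(f, 1)
}

#' Steady-state respiratory quotient of the twin
#'
#' Quasi-steady RQ at a given agitation for a fixed volumetric glucose uptake,
#' used for kLa calibration, for the gain-model training targets and as a
#' ground-truth map in tests.
#'
#' @param N agitation rate (rpm).
#' @param qsx volumetric glucose uptake (C-mol/L/h), i.e. `qS * X` converted
#'   to C-mol.
#' @param params [twin_params()].
#' @param y_o2_in inlet O2 molar fraction (defaults to dry air).
#' @return dimensionless RQ; equals the oxidative RQ when transfer exceeds
#'   the fully-oxidative oxygen demand.
#' @export
steady_state_rq <- function(N, qsx, params, y_o2_in = params$air_O2_frac) {
  st <- params$stoich
  otr_cap <- kla(N, params) * params$O2_sat * y_o2_in / params$air_O2_frac
  demand <- qsx * st$a_ox
  if (otr_cap >= demand) return(st$rq_ox)
  f <- otr_cap / demand
  (f * st$c_ox + (1 - f) * st$c_f) / (f * st$a_ox)
}

#' Agitation required to hold a target RQ
#'
#' Inverts the steady-state kLa/OTR map of the twin: the agitation whose
#' oxygen transfer capacity puts the metabolic split exactly at `rq_target`
#' for the given volumetric glucose uptake. This is the ground-truth
#' supervision used to label gain-model training rows.
#'
#' @inheritParams steady_state_rq
#' @param rq_target target RQ (> oxidative RQ).
#' @return agitation rate (rpm).
#' @export
required_agitation <- function(qsx, params, rq_target = 1.4,
                               y_o2_in = params$air_O2_frac) {
  st <- params$stoich
  fstar <- oxidative_fraction_for_rq(rq_target, st)
  otr_needed <- fstar * qsx * st$a_ox
  kla_needed <- otr_needed / (params$O2_sat * y_o2_in / params$air_O2_frac)
  (kla_needed / params$kla_a)^(1 / params$kla_b)
}
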