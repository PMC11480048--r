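# Elemental bookkeeping for the two-reaction black-box metabolic model.
# All organic species are handled on a C-mol basis. Degrees of reduction use
# the convention C = 4, H = 1, O = -2, N = -3 (so NH3, the nitrogen source,
# carries zero electrons and drops out of the electron balance).

ATOMIC_MASS <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007)

# g per C-mol of the fixed species (glucose C6H12O6, ethanol C2H6O,
# arabitol C5H12O5, succinate C4H6O4)
CMOL_MASS <- c(
  glucose   = (6 * 12.011 + 12 * 1.008 + 6 * 15.999) / 6,
  ethanol   = (2 * 12.011 + 6 * 1.008 + 1 * 15.999) / 2,
  arabitol  = (5 * 12.011 + 12 * 1.008 + 5 * 15.999) / 5,
  succinate = (4 * 12.011 + 6 * 1.008 + 4 * 15.999) / 4
)

# electrons per C-mol
GAMMA <- c(glucose = 4, ethanol = 6, arabitol = 4.4, succinate = 3.5)

#' Biomass C-mol mass and degree of reduction
#'
#' @param formula named numeric vector `c(h =, o =, n =)` giving the H, O and
#'   N indices of the CH_hO_oN_n biomass formula.
#' @return g per C-mol (for [biomass_cmol_mass()]) or electrons per C-mol
#'   (for [biomass_gamma()]).
#' @keywords internal
biomass_cmol_mass <- function(formula) {
  unname(ATOMIC_MASS["C"] + formula["h"] * ATOMIC_MASS["H"] +
           formula["o"] * ATOMIC_MASS["O"] + formula["n"] * ATOMIC_MASS["N"])
}

#' @rdname biomass_cmol_mass
#' @keywords internal
biomass_gamma <- function(formula) {
  unname(4 + formula["h"] - 2 * formula["o"] - 3 * formula["n"])
}

#' Solve the two-reaction stoichiometry from yields and elemental balances
#'
#' The twin routes glucose through two lumped reactions: an oxidative one
#' (glucose + O2 + NH3 -> biomass + CO2 + H2O) and a fermentative one
#' (glucose + NH3 -> biomass + ethanol/arabitol/succinate + CO2 + H2O).
#' Given the two biomass yields (g/g), the byproduct carbon split and the
#' biomass elemental formula, all remaining coefficients follow from the
#' carbon and degree-of-reduction balances, so both balances close exactly by
#' construction.
#'
#' @param Y_XS_ox,Y_XS_ferm biomass yields on glucose (g_DCW/g_S) of the
#'   oxidative and fermentative reactions.
#' @param byproduct_split named fractions of fermentative byproduct carbon
#'   routed to ethanol, arabitol and succinate (must sum to 1).
#' @param biomass_formula see [biomass_cmol_mass()].
#' @return list of per-C-mol-glucose coefficients: `y_ox`, `a_ox` (mol O2),
#'   `c_ox` (CO2), `rq_ox`, `y_f`, `b_eth`, `b_ara`, `b_suc`, `c_f`, plus
#'   `mw_x` (g per C-mol biomass) and `gamma_x`.
#' @keywords internal
solve_stoichiometry <- function(Y_XS_ox, Y_XS_ferm, byproduct_split,
                                biomass_formula) {
  if (Y_XS_ferm >= Y_XS_ox)
    stop("Y_XS_ferm must be smaller than Y_XS_ox")
  split <- byproduct_split[c("ethanol", "arabitol", "succinate")]
  if (anyNA(split) || any(split < 0) || abs(sum(split) - 1) > 1e-8)
    stop("byproduct_split must give non-negative ethanol/arabitol/succinate fractions summing to 1")

  mw_x <- biomass_cmol_mass(biomass_formula)
  gamma_x <- biomass_gamma(biomass_formula)

  # oxidative reaction, per C-mol glucose
  y_ox <- Y_XS_ox * CMOL_MASS[["glucose"]] / mw_x
  if (y_ox <= 0 || y_ox >= 1)
    stop("oxidative biomass yield outside (0, 1) C-mol/C-mol")
  a_ox <- (GAMMA[["glucose"]] - y_ox * gamma_x) / 4
  if (a_ox <= 0)
    stop("oxidative stoichiometry needs no oxygen; yields are not physical")
  c_ox <- 1 - y_ox
  rq_ox <- c_ox / a_ox

  # fermentative reaction, per C-mol glucose (no oxygen)
  y_f <- Y_XS_ferm * CMOL_MASS[["glucose"]] / mw_x
  gamma_b <- split[["ethanol"]] * GAMMA[["ethanol"]] +
    split[["arabitol"]] * GAMMA[["arabitol"]] +
    split[["succinate"]] * GAMMA[["succinate"]]
  b_tot <- (GAMMA[["glucose"]] - y_f * gamma_x) / gamma_b
  c_f <- 1 - y_f - b_tot
  if (b_tot <= 0 || c_f < 0)
    stop("fermentative stoichiometry infeasible: check Y_XS_ferm and byproduct_split")

  out <- list(
    y_ox = unname(y_ox), a_ox = unname(a_ox), c_ox = unname(c_ox),
    rq_ox = unname(rq_ox),
    y_f = unname(y_f),
    b_eth = unname(b_tot * split[["ethanol"]]),
    b_ara = unname(b_tot * split[["arabitol"]]),
    b_suc = unname(b_tot * split[["succinate"]]),
    c_f = unname(c_f),
    mw_x = mw_x, gamma_x = gamma_x
  )

  # construction invariants (carbon closes trivially; check electrons)
  e_ox <- y_ox * gamma_x + 4 * a_ox
  e_f <- y_f * gamma_x + out$b_eth * GAMMA[["ethanol"]] +
    out$b_ara * GAMMA[["arabitol"]] + out$b_suc * GAMMA[["succinate"]]
  stopifnot(abs(e_ox - 4) < 1e-10, abs(e_f - 4) < 1e-10)
  out
}
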