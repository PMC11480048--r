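#' Species elemental composition table
#'
#' Elemental composition (atoms per molecule), molar mass per C-mol and
#' degree of reduction of the species entering the carbon and electron
#' balances. The fixed species ship as a CSV resource; the biomass row is
#' built from the configurable elemental formula (per C-mol). The degree of
#' reduction uses C = 4, H = 1, O = -2, N = -3, so NH3 (the nitrogen source)
#' and CO2 carry zero electrons.
#'
#' @param params [twin_params()] supplying the biomass formula.
#' @return data frame with `species`, `c`, `h`, `o`, `n`, `cmol_mass`
#'   (g per C-mol), `gamma` (electrons per C-mol).
#' @export
species_composition <- function(params = twin_params()) {
  path <- system.file("extdata", "species_composition.csv",
                      package = "rqtwin", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$cmol_mass <- with(tab, (c * ATOMIC_MASS[["C"]] + h * ATOMIC_MASS[["H"]] +
                                o * ATOMIC_MASS[["O"]] + n * ATOMIC_MASS[["N"]]) / c)
  tab$gamma <- with(tab, (4 * c + h - 2 * o - 3 * n) / c)
  bf <- params$biomass_formula
  rbind(tab, data.frame(
    species = "biomass", c = 1, h = bf[["h"]], o = bf[["o"]], n = bf[["n"]],
    cmol_mass = biomass_cmol_mass(bf), gamma = biomass_gamma(bf)
  ))
}

RATE_NAMES <- c("qS", "mu", "qO2", "qCO2", "qEtOH", "qAra", "qSuc")

#' Measured specific rates with uncertainties
#'
#' Bundles the seven key specific rates (growth, glucose uptake, O2 uptake,
#' CO2 evolution, ethanol/arabitol/succinate production) with per-rate
#' standard deviations derived from relative SDs of the assays (dry cell
#' weight, off-gas analysis, HPLC). Lipase production is excluded from the
#' balances (negligible carbon).
#'
#' @param rates named list or `rate_vector` with `mu` (1/h), `qS`, `qEtOH`,
#'   `qAra`, `qSuc` (g/g/h), `qO2`, `qCO2` (mol/g/h).
#' @param rsd named relative SDs per rate; defaults: 5% on `mu` (biomass),
#'   5% on the gas rates, 2% on the HPLC species.
#' @param params [twin_params()] for the composition table.
#' @return object of class `measured_rates` with `values`, `sd` (native
#'   units) and the composition table.
#' @export
measured_rates <- function(rates,
                           rsd = c(mu = 0.05, qS = 0.02, qO2 = 0.05,
                                   qCO2 = 0.05, qEtOH = 0.02, qAra = 0.02,
                                   qSuc = 0.02),
                           params = twin_params()) {
  v <- vapply(RATE_NAMES, function(nm) rates[[nm]], 0)
  if (anyNA(v)) stop("rates must contain ", paste(RATE_NAMES, collapse = ", "))
  s <- abs(v) * rsd[RATE_NAMES]
  s[s <= 0] <- 1e-12   # degenerate-but-positive SD for exactly-zero rates
  structure(list(values = v, sd = s, composition = species_composition(params)),
            class = "measured_rates")
}

# convert the 7 native-unit rates to C-mol (organics) / mol (O2) basis
rates_to_cmol <- function(values, comp) {
  cm <- function(sp) comp$cmol_mass[comp$species == sp]
  c(qS = values[["qS"]] / cm("glucose"),
    mu = values[["mu"]] / cm("biomass"),
    qO2 = values[["qO2"]],
    qCO2 = values[["qCO2"]],
    qEtOH = values[["qEtOH"]] / cm("ethanol"),
    qAra = values[["qAra"]] / cm("arabitol"),
    qSuc = values[["qSuc"]] / cm("succinate"))
}

# carbon and degree-of-reduction balance matrix over
# (qS, mu, qO2, qCO2, qEtOH, qAra, qSuc) in C-mol units: E %*% r = 0
balance_matrix <- function(comp) {
  g <- function(sp) comp$gamma[comp$species == sp]
  rbind(
    carbon = c(1, -1, 0, -1, -1, -1, -1),
    electron = c(g("glucose"), -g("biomass"), -4, 0, -g("ethanol"),
                 -g("arabitol"), -g("succinate"))
  )
}

#' Carbon-balance closure gap
#'
#' Relative gap `|C_in - C_out| / C_in` between substrate carbon uptake and
#' the carbon recovered in biomass, CO2 and by-products (lipase excluded).
#'
#' @param m a [measured_rates()] (a plain `rate_vector` is wrapped with the
#'   default RSDs).
#' @param params [twin_params()] used only when wrapping a raw rate vector.
#' @return fractional gap (0 = perfectly closed).
#' @export
carbon_balance_gap <- function(m, params = twin_params()) {
  if (!inherits(m, "measured_rates")) m <- measured_rates(m, params = params)
  if (m$values[["qS"]] <= 0) stop("qS must be positive")
  r <- rates_to_cmol(m$values, m$composition)
  c_out <- r[["mu"]] + r[["qCO2"]] + r[["qEtOH"]] + r[["qAra"]] + r[["qSuc"]]
  abs(r[["qS"]] - c_out) / r[["qS"]]
}

#' Reconcile measured rates under elemental balance constraints
#'
#' Weighted-least-squares projection of the measured rate vector onto the
#' subspace satisfying the carbon and degree-of-reduction balances:
#' `r_hat = r - S E' (E S E')^-1 E r` with `S` the diagonal measurement
#' covariance and `E` the balance matrix. The balance residuals `E r` give
#' the consistency statistic `chi2 = (E r)' (E S E')^-1 (E r)`, compared to
#' the chi-squared quantile with as many degrees of freedom as independent
#' balances; a significant value flags a gross measurement error.
#'
#' @param m a [measured_rates()].
#' @param confidence confidence level of the consistency test.
#' @param params [twin_params()] used only when wrapping a raw rate vector.
#' @return object of class `reconciliation_result`: `reconciled` (native
#'   units), `reconciled_cmol`, `residual` (balance residuals), `chi2`,
#'   `dof`, `consistent`, `p_value`.
#' @export
reconcile <- function(m, confidence = 0.95, params = twin_params()) {
  if (!inherits(m, "measured_rates")) m <- measured_rates(m, params = params)
  comp <- m$composition
  r <- rates_to_cmol(m$values, comp)
  # the C-mol conversion is linear, so SDs transform with the same factors
  conv <- r / ifelse(m$values == 0, 1, m$values)
  conv[m$values == 0] <- 1
  s_cmol <- m$sd * abs(conv)
  E <- balance_matrix(comp)
  S <- diag(s_cmol^2)
  ESE <- E %*% S %*% t(E)
  if (rcond(ESE) < 1e-12) stop("balance constraints are rank-deficient")
  res <- drop(E %*% r)
  W <- solve(ESE)
  r_hat <- r - drop(S %*% t(E) %*% W %*% res)
  chi2 <- drop(res %*% W %*% res)
  dof <- nrow(E)
  crit <- stats::qchisq(confidence, df = dof)
  rec_native <- r_hat / conv
  structure(list(
    reconciled = stats::setNames(rec_native, RATE_NAMES),
    reconciled_cmol = r_hat,
    residual = res, chi2 = chi2, dof = dof,
    p_value = stats::pchisq(chi2, df = dof, lower.tail = FALSE),
    consistent = chi2 <= crit, confidence = confidence,
    sd_cmol = s_cmol, composition = comp
  ), class = "reconciliation_result")
}

#' @export
print.reconciliation_result <- function(x, ...) {
  cat(sprintf("Rate reconciliation: chi2 = %.3f (dof %d), %sconsistent at %.0f%%\n",
              x$chi2, x$dof, if (x$consistent) "" else "NOT ",
              100 * x$confidence))
  print(round(x$reconciled, 6))
  invisible(x)
}
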