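#' Sensor calibration record
#'
#' Offset/span corrections for the O2 and CO2 analyzer channels. The
#' corrected fraction is `y * span + offset`; identity calibration leaves
#' readings unchanged. A deliberately biased record can emulate a run whose
#' analyzer calibration was only verified afterwards.
#'
#' @param o2_span,o2_offset,co2_span,co2_offset per-channel span (> 0) and
#'   offset.
#' @return object of class `calib_record`.
#' @export
calib_record <- function(o2_span = 1, o2_offset = 0,
                         co2_span = 1, co2_offset = 0) {
  if (o2_span <= 0 || co2_span <= 0) stop("spans must be positive")
  structure(list(o2 = list(span = o2_span, offset = o2_offset),
                 co2 = list(span = co2_span, offset = co2_offset)),
            class = "calib_record")
}

#' An off-gas analyzer reading
#'
#' Bundle of one time point of raw sensor values (wet-basis fractions before
#' calibration correction), the inlet blend and the calibration record.
#'
#' @param t time (h).
#' @param y_o2,y_co2 raw off-gas molar fractions (0-1).
#' @param humidity off-gas humidity (%), `< 100`.
#' @param blend inlet blend from [inlet_blend()].
#' @param F_total_in total inlet gas flow (L/min), > 0.
#' @param calib [calib_record()].
#' @param corrected logical, set by [correct_reading()].
#' @return object of class `gas_reading`.
#' @export
gas_reading <- function(t, y_o2, y_co2, humidity = 0, blend,
                        F_total_in = blend$F_total, calib = calib_record(),
                        corrected = FALSE) {
  if (y_o2 < 0 || y_o2 > 1 || y_co2 < 0 || y_co2 > 1)
    stop("fractions must lie in [0, 1]")
  if (F_total_in <= 0) stop("F_total_in must be positive")
  structure(list(t = t, y_o2 = y_o2, y_co2 = y_co2, humidity = humidity,
                 blend = blend, F_total_in = F_total_in, calib = calib,
                 corrected = corrected),
            class = "gas_reading")
}

#' Apply calibration and humidity correction to a reading
#'
#' Applies the offset/span correction of each channel, then converts the
#' wet-basis fractions to a dry basis with the measured humidity:
#' `y_dry = y_wet / (1 - humidity/100)`.
#'
#' @param raw a [gas_reading()].
#' @return the corrected `gas_reading` (dry-basis, `corrected = TRUE`).
#' @export
correct_reading <- function(raw) {
  if (raw$humidity >= 100) stop("humidity must be below 100%")
  dryf <- 1 - raw$humidity / 100
  cal <- raw$calib
  out <- raw
  out$y_o2 <- (raw$y_o2 * cal$o2$span + cal$o2$offset) / dryf
  out$y_co2 <- (raw$y_co2 * cal$co2$span + cal$co2$offset) / dryf
  out$corrected <- TRUE
  out
}

#' OUR, CER and RQ from an off-gas reading
#'
#' Inert-gas (N2) balance over the reactor gas phase: the outlet molar flow
#' follows from conservation of the non-respiratory gas,
#' `n_out = n_in * (1 - y_O2_in - y_CO2_in) / (1 - y_O2_out - y_CO2_out)`,
#' and the uptake/evolution rates from the O2 and CO2 molar flow differences
#' divided by the broth volume. When the oxygen uptake falls below
#' `our_floor` the respiratory quotient is reported as `NA`: in the early
#' fed-batch the gas-composition differences are too small for a meaningful
#' ratio.
#'
#' @param reading a corrected [gas_reading()] (a raw one is corrected on the
#'   fly).
#' @param V broth volume (L), > 0.
#' @param our_floor OUR below which RQ is undefined (mol/L/h).
#' @param vm gas molar volume (L/mol) at reference conditions.
#' @param method `"n2_balance"` (default) or `"ratio"`, the naive
#'   `(y_CO2_out - y_CO2_in) / (y_O2_in - y_O2_out)` quotient that ignores
#'   the flow change.
#' @return list with `OUR`, `CER` (mol/L/h) and `RQ` (`NA` when undefined).
#' @export
off_gas_rates <- function(reading, V, our_floor = 0.002, vm = 24.465,
                          method = c("n2_balance", "ratio")) {
  method <- match.arg(method)
  if (V <= 0) stop("V must be positive")
  if (!isTRUE(reading$corrected)) reading <- correct_reading(reading)
  b <- reading$blend
  n_in <- reading$F_total_in * 60 / vm                     # mol/h
  inert_in <- 1 - b$y_o2_in - b$y_co2_in
  inert_out <- 1 - reading$y_o2 - reading$y_co2
  if (inert_out <= 0) stop("outlet inert fraction must be positive")
  n_out <- n_in * inert_in / inert_out
  our <- (n_in * b$y_o2_in - n_out * reading$y_o2) / V
  cer <- (n_out * reading$y_co2 - n_in * b$y_co2_in) / V
  rq <- if (method == "ratio") {
    dy_o2 <- b$y_o2_in - reading$y_o2
    if (dy_o2 <= 0) NA_real_ else (reading$y_co2 - b$y_co2_in) / dy_o2
  } else {
    cer / our
  }
  if (our <= our_floor) rq <- NA_real_
  list(OUR = our, CER = cer, RQ = rq)
}

#' Specific gas rates
#'
#' Per-biomass oxygen uptake and carbon dioxide evolution rates,
#' `qO2 = OUR / X` and `qCO2 = CER / X`.
#'
#' @param rates list with `OUR` and `CER` (mol/L/h), e.g. from
#'   [off_gas_rates()].
#' @param X biomass concentration (g_DCW/L), > 0.
#' @return list with `qO2`, `qCO2` (mol/g_DCW/h).
#' @export
specific_rates <- function(rates, X) {
  if (X <= 0) stop("X must be positive")
  list(qO2 = rates$OUR / X, qCO2 = rates$CER / X)
}
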