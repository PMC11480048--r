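#' Extract the RQ trace from a fermentation log
#'
#' Per-minute RQ with undefined (early low-signal) points dropped,
#' optionally restricted to a time window. Three channels are available:
#' the raw online soft sensor (`"measured"`), the twin's noise-free
#' instantaneous quotient (`"true"`), and the a-posteriori recalculated
#' trace (`"offline"`, the default for performance reporting): OUR and CER
#' smoothed with a centered moving average (default 15 min) before taking
#' the ratio, as is standard when rates are recalculated from off-gas data
#' after a run.
#'
#' @param log a `ferm_log`, or a data frame with `t` and `rq` columns.
#' @param set_point RQ set-point attached to the trace.
#' @param from,to inclusion window (h).
#' @param channel `"offline"`, `"measured"` or `"true"`.
#' @param window_min moving-average window (min) of the offline channel.
#' @param our_floor OUR below which the offline RQ is undefined (mol/L/h).
#' @return object of class `rq_trace`: list with `t`, `y`, `y_sp`, `n`.
#' @export
rq_trace <- function(log, set_point = 1.4, from = 0, to = Inf,
                     channel = c("offline", "measured", "true"),
                     window_min = 15, our_floor = 0.002) {
  channel <- match.arg(channel)
  y <- switch(channel,
    true = log$rq_true,
    measured = log$rq,
    offline = {
      our_s <- moving_average(log$our, window_min)
      cer_s <- moving_average(log$cer, window_min)
      ifelse(!is.na(our_s) & our_s > our_floor, cer_s / our_s, NA_real_)
    })
  keep <- !is.na(y) & log$t >= from & log$t <= to
  tr <- list(t = log$t[keep], y = y[keep], y_sp = set_point,
             n = sum(keep))
  if (tr$n < 1) stop("empty RQ trace")
  if (is.unsorted(tr$t, strictly = TRUE)) stop("times must be strictly increasing")
  class(tr) <- "rq_trace"
  tr
}

as_rq_trace <- function(x) {
  if (inherits(x, "rq_trace")) return(x)
  rq_trace(x)
}

# centered moving average on the 1-min grid; NA values are carried through
# the window edges but do not poison interior points
moving_average <- function(x, window_min) {
  if (window_min <= 1) return(x)
  half <- floor(window_min / 2)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- x[max(1, i - half):min(n, i + half)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, 0)
}

#' Mean relative error from the set-point
#'
#' `MRE = (1/n) * sum(|y_i - y_sp| / y_sp)`: the controller accuracy
#' statistic, 0 when every sample sits on the set-point.
#'
#' @param trace an [rq_trace()] (a `ferm_log` is converted with defaults).
#' @return dimensionless MRE in `[0, Inf)`.
#' @export
mre <- function(trace) {
  trace <- as_rq_trace(trace)
  if (trace$y_sp <= 0) stop("set-point must be positive")
  mean(abs(trace$y - trace$y_sp)) / trace$y_sp
}

#' Root-mean-square deviation from the trace mean
#'
#' `RMSD = sqrt(sum((y_i - mean(y))^2) / n)`: the controller precision
#' statistic (a population SD of the trace), 0 for a constant trace.
#'
#' @inheritParams mre
#' @return RQ units.
#' @export
rmsd <- function(trace) {
  trace <- as_rq_trace(trace)
  sqrt(mean((trace$y - mean(trace$y))^2))
}

#' Time to recover into an RQ band after a disturbance
#'
#' First time after `t_dist` at which the trace enters `band` and stays
#' inside for at least `dwell_min` minutes (so a single in-band sample during
#' an excursion does not count), minus `t_dist`. Zero if the trace never
#' leaves the band after the disturbance; `Inf` if it never settles.
#'
#' @inheritParams mre
#' @param t_dist disturbance time (h), within the trace span.
#' @param band numeric length-2 RQ interval.
#' @param dwell_min dwell requirement (min).
#' @return recovery time (h).
#' @export
recovery_time <- function(trace, t_dist, band = c(1.3, 1.5), dwell_min = 10) {
  trace <- as_rq_trace(trace)
  if (band[2] <= band[1]) stop("band must be a non-empty interval")
  if (t_dist < min(trace$t) || t_dist > max(trace$t))
    stop("t_dist outside the trace span")
  idx <- which(trace$t >= t_dist)
  tt <- trace$t[idx]
  inb <- trace$y[idx] >= band[1] & trace$y[idx] <= band[2]
  dwell_h <- dwell_min / 60
  for (i in seq_along(idx)) {
    if (!inb[i]) next
    win <- tt >= tt[i] & tt <= tt[i] + dwell_h + 1e-9
    if (all(inb[win])) return(tt[i] - t_dist)
  }
  Inf
}

#' Fraction of time inside an RQ band
#'
#' @inheritParams mre
#' @param band numeric length-2 RQ interval.
#' @return fraction of trace samples inside the band.
#' @export
band_occupancy <- function(trace, band = c(1.2, 1.6)) {
  trace <- as_rq_trace(trace)
  mean(trace$y >= band[1] & trace$y <= band[2])
}

#' Controller comparison report
#'
#' Per-replicate and per-strategy summary of the performance statistics:
#' MRE (accuracy), RMSD (precision), mean absolute deviation from the
#' set-point, band occupancy and, when a disturbance time is given, the
#' recovery time into `recovery_band`.
#'
#' @param logs named list (strategy -> list of `ferm_log`s).
#' @param set_point RQ set-point.
#' @param from start (h) of the evaluation window (undefined-RQ samples are
#'   always excluded).
#' @param band occupancy band.
#' @param t_dist,recovery_band optional disturbance time and recovery band.
#' @param channel RQ channel passed to [rq_trace()]; performance statistics
#'   default to the offline recalculated trace.
#' @return list with `replicates` (one row per log) and `summary` (mean and
#'   SD per strategy) data frames.
#' @export
compare_controllers <- function(logs, set_point = 1.4, from = 0,
                                band = c(1.2, 1.6), t_dist = NULL,
                                recovery_band = c(1.3, 1.5),
                                channel = "offline") {
  if (!length(logs)) stop("no logs supplied")
  rows <- do.call(rbind, lapply(names(logs), function(strategy) {
    ll <- logs[[strategy]]
    do.call(rbind, lapply(seq_along(ll), function(i) {
      tr <- rq_trace(ll[[i]], set_point = set_point, from = from,
                     channel = channel)
      data.frame(
        strategy = strategy, replicate = i, n = tr$n,
        mre = mre(tr), rmsd = rmsd(tr),
        mean_abs_dev = mean(abs(tr$y - set_point)),
        band_occupancy = band_occupancy(tr, band),
        recovery_h = if (is.null(t_dist)) NA_real_ else
          recovery_time(tr, t_dist, recovery_band)
      )
    }))
  }))
  agg <- do.call(rbind, lapply(split(rows, rows$strategy), function(d) {
    data.frame(
      strategy = d$strategy[1], n_replicates = nrow(d),
      mre_mean = mean(d$mre), mre_sd = stats::sd(d$mre),
      rmsd_mean = mean(d$rmsd), rmsd_sd = stats::sd(d$rmsd),
      mean_abs_dev = mean(d$mean_abs_dev),
      band_occupancy = mean(d$band_occupancy),
      recovery_h_max = if (all(is.na(d$recovery_h))) NA_real_ else
        max(d$recovery_h, na.rm = TRUE)
    )
  }))
  rownames(rows) <- rownames(agg) <- NULL
  list(replicates = rows, summary = agg)
}

#' Render a comparison report as text
#'
#' @param report from [compare_controllers()].
#' @return character vector of lines, invisibly; also printed.
#' @export
format_report <- function(report) {
  s <- report$summary
  lines <- c(
    sprintf("%-8s %4s %12s %12s %10s %10s", "strategy", "n", "MRE",
            "RMSD", "|RQ-sp|", "in-band"),
    sprintf("%-8s %4d %6.4f+/-%.4f %6.4f+/-%.4f %10.4f %9.1f%%",
            s$strategy, s$n_replicates, s$mre_mean,
            ifelse(is.na(s$mre_sd), 0, s$mre_sd), s$rmsd_mean,
            ifelse(is.na(s$rmsd_sd), 0, s$rmsd_sd),
            s$mean_abs_dev, 100 * s$band_occupancy)
  )
  cat(lines, sep = "\n")
  invisible(lines)
}
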