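test_that("exponential feed has the closed-form base rate and doubling time", {
  p <- default_params()
  F0 <- p$X0 * p$V0 * p$mu_set / (p$Y_XS_ox * p$S_feed)
  expect_equal(feed_rate(0, p), F0)
  expect_equal(feed_rate(10, p), F0 * exp(1))
  for (t in c(0, 1.7, 8.3, 15)) {
    expect_equal(feed_rate(t + log(2) / p$mu_set, p), 2 * feed_rate(t, p))
  }
  expect_true(all(diff(feed_rate(seq(0, 20, 0.5), p)) > 0))
  expect_error(feed_rate(-1, p), "non-negative")
})

test_that("kLa power law is identity at unit coefficients and monotone", {
  p1 <- twin_params(kla_a = 1, kla_b = 1)
  expect_equal(kla(100, p1), 100)
  p <- default_params()
  expect_gt(kla(600, p), kla(550, p))
  expect_error(kla(0, p), "positive")
})

test_that("OTR is the kLa-weighted driving force", {
  expect_equal(otr(100, 2.1e-4, 0), 0.021)
  expect_equal(otr(73, 2.0e-4, 2.0e-4), 0)
  expect_equal(otr(50, 2.0e-4, 1.0e-4), 5.0e-3)
  expect_error(otr(50, 2.0e-4, 3.0e-4), "DO")
})

test_that("blending 1.8 L/min air with 0.2 L/min O2 gives 28.87% inlet O2", {
  p <- default_params()
  expect_equal(inlet_blend(2.0, 0, p)$y_o2_in, p$air_O2_frac)
  expect_equal(inlet_blend(0, 1.0, p)$y_o2_in, 1.0)
  expect_equal(round(100 * inlet_blend(1.8, 0.2, p)$y_o2_in, 2), 28.87)
  # the alternative dry-air fraction stays distinguishable at 2 decimals
  p2 <- twin_params(air_O2_frac = 0.2095)
  expect_equal(100 * inlet_blend(1.8, 0.2, p2)$y_o2_in, 28.855, tolerance = 1e-6)
  expect_error(inlet_blend(0, 0, p), "positive")
})

test_that("metabolic split closes carbon and electron balances exactly", {
  p <- default_params()
  qs <- 0.20
  demand <- qs / (180.156 / 6) * p$stoich$a_ox * 50   # mol O2/L/h at X = 50
  # unconstrained limit: fully oxidative
  rv <- metabolic_split(qs, 2 * demand, 50, p)
  expect_equal(rv$qEtOH, 0)
  expect_equal(rv$qCO2 / rv$qO2, p$stoich$rq_ox)
  # oxygen-limited at 80% of demand: hypoxic RQ
  rv8 <- metabolic_split(qs, 0.8 * demand, 50, p)
  expect_equal(attr(rv8, "f_ox"), 0.8)
  rq8 <- rv8$qCO2 / rv8$qO2
  expect_gt(rq8, 1.2); expect_lt(rq8, 1.6)
  expect_gt(rq8, p$stoich$rq_ox)
  # independent elemental bookkeeping over a sweep of transfer capacities
  for (frac in c(0.05, 0.3, 0.62, 0.8, 0.97, 1.5)) {
    rvf <- metabolic_split(qs, frac * demand, 50, p)
    bal <- oracle_balances(rvf)
    expect_lt(abs(bal[["carbon"]]), 1e-10)
    expect_lt(abs(bal[["electron"]]), 1e-10)
  }
  # RQ increases as the transfer capacity shrinks
  rqs <- sapply(c(0.9, 0.7, 0.5, 0.3), function(f)
    with(metabolic_split(qs, f * demand, 50, p), qCO2 / qO2))
  expect_true(all(diff(rqs) > 0))
  expect_error(metabolic_split(qs, 0, 50, p), "anaerobic")
  expect_error(metabolic_split(-qs, demand, 50, p), "domain")
})

test_that("kLa calibration puts the batch-end steady state at RQ 1.4 between 550 and 600 rpm", {
  p <- default_params()
  # independent root-finding on the steady-state map
  root <- stats::uniroot(function(N) steady_state_rq(N, qsx0(p), p) - 1.4,
                         c(300, 900), tol = 1e-8)$root
  expect_gt(root, 550); expect_lt(root, 600)
  expect_equal(root, p$calib_N, tolerance = 1e-6)
})

test_that("steady-state RQ is non-increasing in agitation and shows hypoxia onset", {
  p <- default_params()
  q <- qsx0(p)
  rqs <- sapply(seq(350, 1200, 25), function(N) steady_state_rq(N, q, p))
  expect_true(all(diff(rqs) <= 1e-12))
  expect_equal(steady_state_rq(2000, q, p), p$stoich$rq_ox)
  expect_gt(steady_state_rq(500, q, p), 1.2)
})

test_that("twin step preserves state under (near) null dynamics", {
  p0 <- twin_params(mu_set = 1e-8)
  st <- init_state(p0, init_N = 575)
  st2 <- twin_step(st, NULL, p0, dt = 1 / 60)
  expect_equal(st2$XV, st$XV, tolerance = 1e-6)
  expect_equal(st2$V, st$V, tolerance = 1e-6)
})

test_that("lagged off-gas follows a first-order response to an agitation step", {
  p <- default_params()
  st <- init_state(p, init_N = 575)
  for (i in 1:240) st <- twin_step(st, NULL, p, dt = 1 / 60)  # settle 4 h
  y0 <- st$y_o2_lag
  tau_min <- p$gas_lag_tau
  st2 <- st
  act <- control_action(st$t, 50, st$N + 50, "MHC_UP")
  traj <- numeric(5 * tau_min)
  for (i in seq_along(traj)) {
    st2 <- twin_step(st2, if (i == 1) act else NULL, p, dt = 1 / 60)
    traj[i] <- st2$y_o2_lag
  }
  frac_at_tau <- (traj[tau_min] - y0) / (traj[length(traj)] - y0)
  # first-order: 1 - exp(-1) = 0.632 at t = tau (drifting plateau loosens it)
  expect_gt(frac_at_tau, 0.55)
  expect_lt(frac_at_tau, 0.75)
})

test_that("simulate returns a per-minute log and is bit-reproducible", {
  p <- default_params()
  log <- simulate_fedbatch(null_controller(), p, horizon = 0.1, seed = 3)
  expect_s3_class(log, "ferm_log")
  expect_equal(nrow(log), 7)
  expect_equal(log$t, (0:6) / 60)
  expect_true(all(log$n_rpm == 575))
  log2 <- simulate_fedbatch(null_controller(), p, horizon = 0.1, seed = 3)
  expect_identical(log, log2)
})

test_that("a controller failure aborts with a partial log and an error record", {
  broken <- structure(list(type = "boom", init_N = 575),
                      class = "rq_controller")
  log <- simulate_fedbatch(broken, default_params(), horizon = 0.5, seed = 1)
  expect_lt(nrow(log), 31)
  expect_match(attr(log, "error"), "unknown controller type")
})

test_that("carbon and electrons are conserved over a closed-loop run", {
  bm <- get_benchmark()
  p <- default_params()
  el <- oracle_elements()
  for (log in list(bm$logs$blc[[1]], bm$logs$mhc[[1]], bm$logs$apc[[1]])) {
    fin <- log[nrow(log), ]
    c_in <- fin$cum_glc_g / el$mw[["glc"]]
    c_out <- (fin$x_gl * fin$v_l - p$X0 * p$V0) / el$mw[["x"]] +
      fin$etoh_gl * fin$v_l / el$mw[["etoh"]] +
      fin$ara_gl * fin$v_l / el$mw[["ara"]] +
      fin$suc_gl * fin$v_l / el$mw[["suc"]] +
      fin$cum_co2_mol + fin$s_gl * fin$v_l / el$mw[["glc"]]
    expect_lt(abs(c_in - c_out) / c_in, 1e-6)
    cons <- fin$cum_glc_g / el$mw[["glc"]] - fin$s_gl * fin$v_l / el$mw[["glc"]]
    e_in <- 4 * cons
    e_out <- el$g[["x"]] * (fin$x_gl * fin$v_l - p$X0 * p$V0) / el$mw[["x"]] +
      el$g[["etoh"]] * fin$etoh_gl * fin$v_l / el$mw[["etoh"]] +
      el$g[["ara"]] * fin$ara_gl * fin$v_l / el$mw[["ara"]] +
      el$g[["suc"]] * fin$suc_gl * fin$v_l / el$mw[["suc"]] +
      4 * fin$cum_o2_mol
    expect_lt(abs(e_in - e_out) / e_in, 1e-6)
  }
})

test_that("the O2-enrichment disturbance dips RQ below set-point and lowers agitation", {
  bm <- get_benchmark()
  log <- bm$logs$apc[[1]]
  dip <- log[log$t > 13.3 & log$t < 14.0, ]
  expect_lt(min(dip$rq_true), 1.3)
  n_before <- log$n_rpm[which.min(abs(log$t - 13.25))]
  n_after <- log$n_rpm[which.min(abs(log$t - 14.5))]
  expect_lt(n_after, n_before)
  # the inlet composition actually changed
  expect_equal(max(dip$f_o2_lmin), 0.2)
  expect_equal(round(max(dip$y_o2_in_pct), 2), 28.87)
})
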