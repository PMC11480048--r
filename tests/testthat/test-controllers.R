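mhc_sched <- step_schedule(c(5, 10), c(25, 50, 100))
clk30 <- controller_clock(30)
clk10 <- controller_clock(10)

test_that("manual-heuristic rule steps up only above RQ 1.6 at check instants", {
  a <- mhc_decide(1.65, t = 7.5, current_N = 700, mhc_sched, clk30)
  expect_equal(a$rule, "MHC_UP")
  expect_equal(a$delta_rpm, 50)           # mid-schedule step
  expect_equal(a$new_N, 750)
  expect_equal(mhc_decide(1.55, 7.5, 700, mhc_sched, clk30)$rule, "NONE")
  # between check instants nothing happens, however large the error
  expect_equal(mhc_decide(1.9, 7.5 + 7 / 60, 700, mhc_sched, clk30)$rule,
               "NONE")
  expect_equal(mhc_decide(NA, 7.5, 700, mhc_sched, clk30)$rule, "NONE")
  # schedule ends: early and late magnitudes
  expect_equal(mhc_decide(1.7, 2, 700, mhc_sched, clk30)$delta_rpm, 25)
  expect_equal(mhc_decide(1.7, 15, 700, mhc_sched, clk30)$delta_rpm, 100)
  # never a decrease, for any RQ
  for (rq in seq(0.8, 2.2, 0.1)) {
    expect_gte(mhc_decide(rq, 10, 700, mhc_sched, clk30)$delta_rpm, 0)
  }
})

test_that("Boolean rule is up above 1.4, down below 1.3, silent in the deadband", {
  sched <- step_schedule(c(6, 12), c(10, 15, 25))
  up <- blc_decide(1.45, t = 2, current_N = 600, sched, clk10)
  expect_equal(up$rule, "BLC_UP"); expect_equal(up$delta_rpm, 10)
  expect_equal(blc_decide(1.45, 8, 600, sched, clk10)$delta_rpm, 15)
  expect_equal(blc_decide(1.45, 14, 600, sched, clk10)$delta_rpm, 25)
  dn <- blc_decide(1.25, 2, 600, sched, clk10)
  expect_equal(dn$rule, "BLC_DOWN"); expect_equal(dn$delta_rpm, -10)
  expect_equal(blc_decide(1.35, 2, 600, sched, clk10)$rule, "NONE")
  expect_equal(blc_decide(1.45, 2 + 3 / 60, 600, sched, clk10)$rule, "NONE")
})

test_that("adaptive-proportional rule honors the action gap, deadband and sign", {
  model <- get_gain_fixture()$model
  feats <- list(t_h = 10, n_rpm = 800, rq = 1.5, our = 0.08, cer = 0.112,
                feed_lh = 0.06, cum_glc_g = 250, y_o2_in = 0.2097,
                x_total_est = 160)
  clk <- controller_clock(1, min_action_gap = 7, last_action_t = -Inf)
  a <- apc_decide(1.5, t = 10, current_N = 800, model, clk, feats)
  expect_equal(a$rule, "APC")
  expect_equal(a$delta_rpm, a$epsilon * a$k_p)
  expect_gt(a$delta_rpm, 0)
  # a fresh action blocks the next one for 7 minutes
  clk_busy <- controller_clock(1, 7, last_action_t = 10 - 4 / 60)
  expect_equal(apc_decide(1.5, 10, 800, model, clk_busy, feats)$rule, "NONE")
  # negative error lowers the agitation
  feats_lo <- within(feats, rq <- 1.3)
  alo <- apc_decide(1.3, 10, 800, model, clk, feats_lo)
  if (alo$rule == "APC") expect_lt(alo$delta_rpm, 0)
  # undefined RQ and zero error give no action
  expect_equal(apc_decide(NA, 10, 800, model, clk, feats)$rule, "NONE")
  expect_equal(apc_decide(1.4, 10, 800, model, clk,
                          within(feats, rq <- 1.4))$rule, "NONE")
  expect_warning(a0 <- apc_decide(1.5, 10, 800, NULL, clk, feats),
                 "unavailable")
  expect_equal(a0$rule, "NONE")
})

test_that("sub-deadband corrections are suppressed", {
  model <- get_gain_fixture()$model
  clk <- controller_clock(1, 7, last_action_t = -Inf)
  # tiny error: |delta| = |eps| * K_P < 2 rpm for any plausible gain
  feats <- list(t_h = 10, n_rpm = 800, rq = 1.4001, our = 0.08, cer = 0.112,
                feed_lh = 0.06, cum_glc_g = 250, y_o2_in = 0.2097,
                x_total_est = 160)
  expect_equal(apc_decide(1.4001, 10, 800, model, clk, feats)$rule, "NONE")
})

test_that("applied actions respect each policy's clock contract", {
  bm <- get_benchmark()
  gaps_ok <- function(log, min_gap_min) {
    tt <- log$t[log$action_rule != "NONE"]
    length(tt) < 2 || min(diff(tt)) * 60 >= min_gap_min - 1e-6
  }
  for (i in 1:5) {
    expect_true(gaps_ok(bm$logs$mhc[[i]], 30))
    expect_true(gaps_ok(bm$logs$blc[[i]], 10))
    expect_true(gaps_ok(bm$logs$apc[[i]], 7))
    # MHC acts only on its 30-min grid
    tt <- bm$logs$mhc[[i]]$t[bm$logs$mhc[[i]]$action_rule != "NONE"]
    expect_true(all(abs(tt * 60 - round(tt * 60 / 30) * 30) < 1e-6))
  }
})

test_that("only BLC and APC ever reduce agitation; APC deltas respect the deadband", {
  bm <- get_benchmark()
  for (i in 1:5) {
    expect_true(all(bm$logs$mhc[[i]]$action_delta_rpm >= 0))
    apc_d <- bm$logs$apc[[i]]$action_delta_rpm
    apc_d <- apc_d[bm$logs$apc[[i]]$action_rule == "APC"]
    expect_true(all(abs(apc_d) >= 2))
    expect_true(any(apc_d < 0))
  }
  expect_true(any(unlist(lapply(bm$logs$blc, function(l)
    any(l$action_delta_rpm < 0)))))
})

test_that("closed-loop RQ stays in the 1.2-1.6 hypoxic band 95% of the time after 2 h", {
  bm <- get_benchmark()
  for (i in 1:5) {
    expect_gte(band_occupancy(rq_trace(bm$logs$blc[[i]], from = 2)), 0.95)
    expect_gte(band_occupancy(rq_trace(bm$logs$apc[[i]], from = 2)), 0.95)
  }
})

test_that("strategy accuracy orders AI-APC before BLC before MHC on a common protocol", {
  bm <- get_benchmark()
  apc_logs <- get_apc_undisturbed()
  mre_mean <- function(ll) mean(vapply(ll, function(l) mre(rq_trace(l)), 0))
  m_apc <- mre_mean(apc_logs)
  m_blc <- mre_mean(bm$logs$blc)
  m_mhc <- mre_mean(bm$logs$mhc)
  expect_lte(m_apc, m_blc)
  expect_lte(m_blc, m_mhc)
})
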