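# minimal synthetic log with the columns build_training_set() consumes
synth_log <- function(n, N, rq, p, t0 = 0) {
  tt <- t0 + (seq_len(n) - 1) / 6          # one row per 10 min
  feed <- feed_rate(tt, p)
  qsx <- feed * p$S_feed / (p$V0 * 180.156 / 6)   # C-mol/L/h, X = X0, V = V0
  d <- data.frame(
    t = tt, n_rpm = N, rq = rq, our = 0.05, cer = 0.05 * rq,
    feed_lh = feed, cum_glc_g = cumsum(feed * p$S_feed) / 6,
    y_o2_in_pct = 100 * p$air_O2_frac,
    qs_true = qsx * (180.156 / 6) / p$X0, x_gl = p$X0, v_l = p$V0
  )
  class(d) <- c("ferm_log", "data.frame")
  attr(d, "params") <- p
  d
}

test_that("training targets are the fixed point when RQ is already held", {
  p <- default_params()
  # at the calibration point the required agitation IS the calibration rpm
  log <- synth_log(1, N = p$calib_N, rq = 1.4, p)
  ts <- build_training_set(list(log), p)
  expect_equal(ts$targets, p$calib_N, tolerance = 1e-9)
  # an under-agitated row needs more rpm than it has
  log2 <- synth_log(1, N = 520, rq = 1.55, p)
  expect_gt(build_training_set(list(log2), p)$targets, 520)
  expect_error(build_training_set(list(), p), "empty")
})

test_that("steady-state inversion matches a bisection oracle to 0.5 rpm", {
  p <- default_params()
  set.seed(5)
  for (i in 1:15) {
    qsx <- runif(1, 0.1, 0.9)
    y_in <- sample(c(p$air_O2_frac, 0.2887), 1)
    target <- required_agitation(qsx, p, rq_target = 1.4, y_o2_in = y_in)
    lo <- 100; hi <- 4000
    for (j in 1:40) {
      mid <- (lo + hi) / 2
      if (steady_state_rq(mid, qsx, p, y_o2_in = y_in) > 1.4) lo <- mid
      else hi <- mid
    }
    expect_lt(abs(target - (lo + hi) / 2), 0.5)
  }
})

test_that("forest training is deterministic and an ensemble of one is a single tree", {
  fx <- get_gain_fixture()
  m1 <- train_gain_model(fx$ts$features, fx$ts$targets, seed = 7)
  m2 <- train_gain_model(fx$ts$features, fx$ts$targets, seed = 7)
  x <- fx$ts$features[10, ]
  expect_identical(predict_gain(m1, x), predict_gain(m2, x))
  mono <- train_gain_model(fx$ts$features, fx$ts$targets, n_trees = 1,
                           seed = 3)
  pr <- predict_gain(mono, x, all_trees = TRUE)
  expect_equal(length(pr$trees), 1)
  expect_equal(pr$mean, pr$trees[1])
})

test_that("the ensemble prediction is the mean of the tree predictions", {
  fx <- get_gain_fixture()
  set.seed(21)
  idx <- sample(nrow(fx$ts$features), 25)
  for (i in idx) {
    pr <- predict_gain(fx$model, fx$ts$features[i, ], all_trees = TRUE)
    expect_equal(pr$mean, mean(pr$trees), tolerance = 1e-9)
    expect_gte(pr$mean, min(pr$trees))
    expect_lte(pr$mean, max(pr$trees))
    # the implied agitation inherits both properties (affine map)
    pa <- predict_agitation(fx$model, fx$ts$features[i, ], all_trees = TRUE)
    expect_equal(pa$mean, mean(pa$trees), tolerance = 1e-9)
  }
})

test_that("the derived gain reproduces the proportional law exactly", {
  fx <- get_gain_fixture()
  x <- fx$ts$features[40, ]
  g <- derive_kp(fx$model, x, current_N = x$n_rpm, rq = x$rq)
  expect_equal(g$delta_rpm, (x$rq - 1.4) * g$k_p)
  expect_equal(g$n_pred - x$n_rpm, g$delta_rpm)
  expect_gte(g$k_p, 0)
  # negative error: the step is negative whenever the gain is positive
  x_lo <- x; x_lo$rq <- 1.32
  g_lo <- derive_kp(fx$model, x_lo, current_N = x$n_rpm, rq = 1.32)
  expect_lte(g_lo$delta_rpm, 0)
  # clamping shrinks but never flips the step
  g_cl <- derive_kp(fx$model, x, current_N = x$n_rpm, rq = x$rq,
                    kp_range = c(0, 1))
  expect_equal(sign(g_cl$delta_rpm) * sign(g$delta_rpm) >= 0, TRUE)
  expect_error(derive_kp(fx$model, x, x$n_rpm, rq = 1.4), "zero error")
  expect_error(derive_kp(fx$model, x, x$n_rpm, rq = 1.5,
                         kp_range = c(-5, 10)), "non-negative")
})

test_that("schema violations are rejected at train and predict time", {
  fx <- get_gain_fixture()
  expect_error(train_gain_model(fx$ts$features[, -1], fx$ts$targets),
               "schema")
  expect_error(predict_gain(fx$model, list(bogus = 1)), "schema")
  x <- fx$ts$features[1, ]; x$rq <- NA
  expect_error(predict_gain(fx$model, x), "missing")
})

test_that("held-out required-agitation predictions are accurate inside the envelope", {
  p <- default_params()
  corpus <- generate_training_corpus(p, horizon = 20, seed = 7)
  ts <- build_training_set(corpus, p)
  # leave one run out: train on five runs, test on the held-out one
  n_run <- length(corpus)
  run_id <- rep(seq_len(n_run), vapply(corpus, function(l)
    sum((round(l$t * 60) %% 10 == 0) & !is.na(l$rq)), 0L))
  hold <- run_id == 2
  model <- train_gain_model(ts$features[!hold, ], ts$targets[!hold],
                            seed = 13)
  pred <- vapply(which(hold), function(i)
    predict_agitation(model, ts$features[i, ]), 0)
  err <- pred - ts$targets[hold]
  expect_lt(sqrt(mean(err^2)), 0.05 * diff(range(ts$targets)))
  expect_lt(stats::median(abs(err) / ts$targets[hold]), 0.05)
})

test_that("a gain model survives a save/load round trip", {
  fx <- get_gain_fixture()
  path <- tempfile(fileext = ".rds")
  write_gain_model(fx$model, path)
  m2 <- read_gain_model(path)
  x <- fx$ts$features[3, ]
  expect_identical(predict_gain(fx$model, x), predict_gain(m2, x))
  saveRDS(list(1), path)
  expect_error(read_gain_model(path), "compatible")
})
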