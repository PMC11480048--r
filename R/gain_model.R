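GAIN_FEATURES <- c("t_h", "n_rpm", "rq", "our", "cer", "feed_lh",
                   "cum_glc_g", "y_o2_in", "x_total_est")

#' Build a gain-model training set from fermentation logs
#'
#' Samples each log on a control cadence (default every 10 min), assembles
#' the nine default features (fed-batch time, agitation, soft-sensed RQ, OUR
#' and CER, feed rate, cumulative glucose fed, inlet O2 fraction, estimated
#' total biomass) and labels every row with the agitation that would hold the
#' twin at the target RQ — the ground-truth steady-state inversion of the
#' kLa/OTR map at the row's true state ([required_agitation()]). Rows with an
#' undefined RQ are dropped. This simulation-side supervision replaces
#' operator-action labels, which only a physical plant can provide.
#'
#' @param logs list of `ferm_log` data frames from [simulate_fedbatch()];
#'   the corpus should span at least two control strategies and two design
#'   growth rates so the learned map generalizes.
#' @param params [twin_params()] the logs were generated with (feed and kLa
#'   parameters are taken from here; per-log `mu_set` may differ and is read
#'   from each log's own params attribute when present).
#' @param rq_target RQ the labels hold (set-point).
#' @param cadence_min sampling cadence (min).
#' @return list with `features` (data frame) and `targets` (rpm vector).
#' @export
build_training_set <- function(logs, params, rq_target = 1.4,
                               cadence_min = 10) {
  if (length(logs) == 0) stop("empty training corpus")
  rows <- lapply(logs, function(log) {
    p <- attr(log, "params")
    if (is.null(p)) p <- params
    keep <- (round(log$t * 60) %% cadence_min == 0) & !is.na(log$rq)
    d <- log[keep, , drop = FALSE]
    if (nrow(d) == 0) return(NULL)
    qsx <- d$qs_true * d$x_gl / CMOL_MASS[["glucose"]]   # C-mol/L/h
    target <- mapply(function(q, y) {
      required_agitation(q, p, rq_target = rq_target, y_o2_in = y)
    }, qsx, d$y_o2_in_pct / 100)
    feats <- data.frame(
      t_h = d$t, n_rpm = d$n_rpm, rq = d$rq, our = d$our, cer = d$cer,
      feed_lh = d$feed_lh, cum_glc_g = d$cum_glc_g,
      y_o2_in = d$y_o2_in_pct / 100,
      x_total_est = p$X0 * p$V0 + p$yxs_observer * d$cum_glc_g
    )
    cbind(feats, .target = target)
  })
  all <- do.call(rbind, rows)
  if (is.null(all) || nrow(all) == 0) stop("training corpus yielded no usable rows")
  list(features = all[GAIN_FEATURES], targets = all$.target)
}

#' Train the random-forest gain model
#'
#' Fits an ensemble of regression trees (bootstrap resampling with per-split
#' feature subsampling) supplying the adaptive proportional gain of the
#' control law `delta_rpm = epsilon * K_P`. The forest regresses `K_P`
#' itself: each training row is converted to a realized gain
#' `K_P = (N_required - N_current) / (RQ - set_point)` from its
#' required-agitation label and its own `n_rpm`/`rq` features. Regressing
#' the gain rather than the agitation keeps the controller responsive
#' outside the training envelope (the gain scales like `N / RQ-sensitivity`
#' and extrapolates benignly, whereas a direct agitation regression
#' reproduces the corpus agitation and saturates). Rows whose error is
#' inside `eps_floor` (ill-conditioned division) or whose realized gain is
#' negative (transient-corrupted labels) are dropped.
#'
#' Hyperparameters follow standard random-forest practice: unlimited depth,
#' minimum node size 2, `ceiling(sqrt(p))` candidate features per split;
#' only the tree count is a first-class parameter (100 by default). The
#' ensemble prediction is the arithmetic mean of the per-tree predictions.
#'
#' @param features,targets from [build_training_set()]; targets are the
#'   required agitation (rpm). At least 50 usable rows after filtering.
#' @param n_trees number of trees.
#' @param seed integer seed making the fit reproducible.
#' @param set_point RQ set-point the gains refer to.
#' @param eps_floor smallest |RQ - set_point| from which a gain label is
#'   formed.
#' @param kp_max largest admissible gain label (rpm per RQ unit).
#' @return object of class `gain_model` wrapping the forest, the feature
#'   schema and training metadata.
#' @export
train_gain_model <- function(features, targets, n_trees = 100, seed = 1,
                             set_point = 1.4, eps_floor = 0.03,
                             kp_max = 5000) {
  if (!identical(names(features), GAIN_FEATURES))
    stop("feature schema mismatch; expected: ",
         paste(GAIN_FEATURES, collapse = ", "))
  eps <- features$rq - set_point
  kp <- (targets - features$n_rpm) / eps
  keep <- abs(eps) >= eps_floor & kp >= 0 & kp <= kp_max
  if (sum(keep) < 50)
    stop("need at least 50 usable training rows (|RQ - set_point| >= ",
         eps_floor, " with non-negative realized gain)")
  features <- features[keep, , drop = FALSE]
  kp <- kp[keep]
  if (stats::sd(kp) < 1e-9)
    warning("degenerate (constant) targets; the model will predict the constant")
  set.seed(seed)
  forest <- randomForest::randomForest(
    x = features, y = kp, ntree = n_trees,
    mtry = ceiling(sqrt(ncol(features))), nodesize = 2
  )
  structure(list(forest = forest, schema = GAIN_FEATURES, n_trees = n_trees,
                 seed = seed, n_rows = nrow(features),
                 set_point = set_point, version = "rqtwin-gain-1"),
            class = "gain_model")
}

#' @export
print.gain_model <- function(x, ...) {
  cat(sprintf("Random-forest gain model (%d trees, %d training rows, seed %d)\n",
              x$n_trees, x$n_rows, x$seed))
  invisible(x)
}

#' Predict the gain and the required agitation
#'
#' `predict_gain()` returns the forest's adaptive gain prediction (the
#' arithmetic mean of the per-tree predictions). `predict_agitation()`
#' returns the implied required agitation
#' `N_pred = n_rpm + (rq - set_point) * K_P`, both quantities read from the
#' feature vector; because the map is affine in the gain, the predicted
#' agitation is equally the mean of the per-tree implied agitations.
#'
#' @param model a [gain_model][train_gain_model()].
#' @param x named list or one-row data frame matching the model schema.
#' @param all_trees if `TRUE`, also return the individual tree predictions.
#' @return predicted gain (rpm per RQ unit) / agitation (rpm), or a list
#'   with `mean` and `trees` when `all_trees = TRUE`.
#' @export
predict_gain <- function(model, x, all_trees = FALSE) {
  x <- as.data.frame(x)
  if (!all(model$schema %in% names(x)))
    stop("feature schema mismatch; expected: ",
         paste(model$schema, collapse = ", "))
  if (anyNA(x[model$schema])) stop("missing feature values at predict time")
  x <- x[model$schema]
  if (all_trees) {
    pr <- stats::predict(model$forest, x, predict.all = TRUE)
    list(mean = unname(pr$aggregate), trees = as.numeric(pr$individual))
  } else {
    unname(stats::predict(model$forest, x))
  }
}

#' @rdname predict_gain
#' @export
predict_agitation <- function(model, x, all_trees = FALSE) {
  xdf <- as.data.frame(x)
  eps <- xdf$rq - model$set_point
  if (all_trees) {
    pr <- predict_gain(model, x, all_trees = TRUE)
    list(mean = xdf$n_rpm + eps * pr$mean,
         trees = xdf$n_rpm + eps * pr$trees)
  } else {
    xdf$n_rpm + eps * predict_gain(model, x)
  }
}

#' Derive the adaptive proportional gain
#'
#' Supplies the gain of the adaptive-proportional law
#' `delta_rpm = epsilon * K_P` from the model, together with the implied
#' required agitation `N_pred = N_current + epsilon * K_P` — so
#' `K_P = (N_pred - N_current) / epsilon` holds exactly. `K_P` is clamped to
#' a non-negative range; the clamp can shrink the step to zero but never
#' flips its sign.
#'
#' @param model a [gain_model][train_gain_model()].
#' @param x feature vector (see [predict_agitation()]).
#' @param current_N current agitation (rpm).
#' @param rq current RQ; `rq - set_point` must be nonzero.
#' @param set_point RQ set-point.
#' @param kp_range numeric length-2 clamp for `K_P` (both non-negative).
#' @return list with `k_p` (rpm per RQ unit), `delta_rpm`, `n_pred`.
#' @export
derive_kp <- function(model, x, current_N, rq, set_point = 1.4,
                      kp_range = c(0, 5000)) {
  eps <- rq - set_point
  if (eps == 0) stop("K_P undefined at zero error; treat as no action")
  if (any(kp_range < 0)) stop("kp_range must be non-negative")
  k_p <- min(max(predict_gain(model, x), kp_range[1]), kp_range[2])
  list(k_p = k_p, delta_rpm = eps * k_p, n_pred = current_N + eps * k_p)
}

#' Persist and reload a gain model
#'
#' The model is stored with its schema version and training metadata.
#'
#' @param model a [gain_model][train_gain_model()].
#' @param path file path.
#' @return `read_gain_model()` returns the `gain_model`.
#' @export
write_gain_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_gain_model
#' @export
read_gain_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "gain_model") || !identical(m$version, "rqtwin-gain-1"))
    stop("not a compatible gain-model file")
  m
}
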