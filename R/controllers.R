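#' A control action on the agitation rate
#'
#' @param t time (h).
#' @param delta_rpm applied agitation change (rpm; 0 for `NONE`).
#' @param new_N agitation after the action (rpm).
#' @param rule which rule fired: `MHC_UP`, `BLC_UP`, `BLC_DOWN`, `APC`,
#'   `NONE`.
#' @param epsilon,k_p for adaptive-proportional actions, the RQ error and the
#'   gain of `delta_rpm = epsilon * k_p`.
#' @return object of class `control_action`.
#' @export
control_action <- function(t, delta_rpm, new_N,
                           rule = c("NONE", "MHC_UP", "BLC_UP", "BLC_DOWN",
                                    "APC"),
                           epsilon = NULL, k_p = NULL) {
  rule <- match.arg(rule)
  if (new_N <= 0) stop("new_N must be positive")
  structure(list(t = t, delta_rpm = delta_rpm, new_N = new_N, rule = rule,
                 epsilon = epsilon, k_p = k_p),
            class = "control_action")
}

none_action <- function(t, N) control_action(t, 0, N, "NONE")

#' Time-indexed step-size schedule
#'
#' Piecewise-constant mapping from fed-batch time to the agitation step
#' magnitude, mirroring the manual practice of raising the step as the
#' process dynamics accelerate.
#'
#' @param breaks increasing times (h) at which the step changes.
#' @param steps step magnitudes (rpm), one more than `breaks`.
#' @return object of class `step_schedule`.
#' @examples
#' s <- step_schedule(c(6, 12), c(10, 15, 25))
#' schedule_step(s, 3); schedule_step(s, 15)
#' @export
step_schedule <- function(breaks, steps) {
  if (length(steps) != length(breaks) + 1)
    stop("steps must have one element more than breaks")
  if (any(steps <= 0)) stop("step magnitudes must be positive")
  if (is.unsorted(breaks, strictly = TRUE) && length(breaks) > 1)
    stop("breaks must be strictly increasing")
  structure(list(breaks = breaks, steps = steps), class = "step_schedule")
}

#' @rdname step_schedule
#' @param sched a `step_schedule`.
#' @param t time (h).
#' @export
schedule_step <- function(sched, t) {
  sched$steps[findInterval(t, sched$breaks) + 1]
}

#' Controller clock
#'
#' @param check_interval minutes between rule evaluations.
#' @param min_action_gap minimum minutes between applied actions.
#' @param last_action_t time (h) of the last applied action.
#' @return object of class `controller_clock`.
#' @export
controller_clock <- function(check_interval, min_action_gap = check_interval,
                             last_action_t = -Inf) {
  if (check_interval <= 0 || min_action_gap <= 0)
    stop("clock intervals must be positive")
  structure(list(check_interval = check_interval,
                 min_action_gap = min_action_gap,
                 last_action_t = last_action_t),
            class = "controller_clock")
}

# the control loop runs on a 1-min grid; a check instant is a grid point
# that is a multiple of the clock's check interval
is_check_instant <- function(clock, t) {
  minutes <- t * 60
  abs(minutes - round(minutes / clock$check_interval) *
        clock$check_interval) < 1e-6
}

#' Manual-heuristic control decision
#'
#' Automated emulation of the operator heuristic: at check instants (default
#' every 30 min) the agitation is increased by the scheduled step only when
#' RQ exceeds 1.6; the agitation is never decreased.
#'
#' @param rq soft-sensed RQ (`NA` when undefined).
#' @param t time (h).
#' @param current_N current agitation (rpm).
#' @param sched [step_schedule()] of up-step magnitudes.
#' @param clock [controller_clock()].
#' @param threshold RQ above which the rule fires.
#' @return a `control_action` (`NONE` off check instants, below threshold, or
#'   when RQ is undefined).
#' @export
mhc_decide <- function(rq, t, current_N, sched, clock, threshold = 1.6) {
  if (!is_check_instant(clock, t) || is.na(rq) || rq <= threshold)
    return(none_action(t, current_N))
  step <- schedule_step(sched, t)
  control_action(t, step, current_N + step, "MHC_UP")
}

#' Boolean-logic control decision
#'
#' Boolean law evaluated at check instants (default every 10 min): increase
#' agitation by the scheduled step when RQ > 1.4, decrease it by a fixed step
#' when RQ < 1.3, do nothing inside the deadband.
#'
#' @inheritParams mhc_decide
#' @param up_threshold,down_threshold RQ thresholds of the up and down rules.
#' @param down_step magnitude (rpm) of the down action.
#' @return a `control_action`.
#' @export
blc_decide <- function(rq, t, current_N, sched, clock,
                       up_threshold = 1.4, down_threshold = 1.3,
                       down_step = 10) {
  if (!is_check_instant(clock, t) || is.na(rq))
    return(none_action(t, current_N))
  if (rq < down_threshold)
    return(control_action(t, -down_step, current_N - down_step, "BLC_DOWN"))
  if (rq > up_threshold) {
    step <- schedule_step(sched, t)
    return(control_action(t, step, current_N + step, "BLC_UP"))
  }
  none_action(t, current_N)
}

#' Adaptive-proportional control decision
#'
#' Every minute the required agitation is predicted by the gain model, the
#' adaptive gain `K_P` is derived so that `delta_rpm = epsilon * K_P`
#' reproduces the prediction (see [derive_kp()]), and the action is applied
#' only if at least `min_action_gap` minutes passed since the last applied
#' action and `|delta_rpm| >= deadband` (2 rpm by default); otherwise the
#' controller re-evaluates at the next minute. Negative errors lower the
#' agitation.
#'
#' @inheritParams mhc_decide
#' @param model a trained [gain_model][train_gain_model()]; `NULL` yields
#'   `NONE` with a warning.
#' @param features named feature list matching the model schema.
#' @param set_point RQ set-point.
#' @param deadband minimum |delta_rpm| that is actually applied.
#' @param kp_range allowed (non-negative) range for `K_P`.
#' @return a `control_action` with `epsilon` and `k_p` filled in for applied
#'   actions.
#' @export
apc_decide <- function(rq, t, current_N, model, clock, features,
                       set_point = 1.4, deadband = 2,
                       kp_range = c(0, 5000)) {
  if (is.na(rq)) return(none_action(t, current_N))
  if (is.null(model)) {
    warning("gain model unavailable; APC takes no action")
    return(none_action(t, current_N))
  }
  if ((t - clock$last_action_t) * 60 < clock$min_action_gap - 1e-6)
    return(none_action(t, current_N))
  eps <- rq - set_point
  if (eps == 0) return(none_action(t, current_N))
  g <- derive_kp(model, features, current_N, rq, set_point,
                 kp_range = kp_range)
  if (abs(g$delta_rpm) < deadband) return(none_action(t, current_N))
  control_action(t, g$delta_rpm, current_N + g$delta_rpm, "APC",
                 epsilon = eps, k_p = g$k_p)
}

#' Controller constructors
#'
#' Bundle a control policy with its clock, schedule, thresholds and initial
#' agitation for use with [simulate_fedbatch()]. `null_controller()` never
#' acts (open loop). The defaults mirror the plant practice: the manual
#' heuristic starts at 600 rpm and checks every 30 min with +50 rpm steps;
#' the Boolean-logic controller starts at 550 rpm on a 10-min clock with
#' scheduled +10/15/25 steps and a -10 down-step; the adaptive-proportional
#' controller starts at 550 rpm, predicts every minute, applies actions at
#' least 7 min apart and ignores |delta| < 2 rpm.
#'
#' @param init_N initial agitation (rpm).
#' @param check_interval minutes between rule evaluations.
#' @param threshold,up_threshold,down_threshold,down_step rule thresholds
#'   (RQ) and the fixed down-step (rpm).
#' @param sched [step_schedule()] of up-steps.
#' @param model trained [gain_model][train_gain_model()] (APC only).
#' @param set_point RQ set-point (APC only).
#' @param min_action_gap minimum minutes between applied APC actions.
#' @param deadband minimum applied |delta_rpm| (APC only).
#' @param kp_range non-negative clamp for the derived gain (APC only).
#' @return a controller object.
#' @name controllers
NULL

#' @rdname controllers
#' @export
null_controller <- function(init_N = 575) {
  structure(list(type = "null", init_N = init_N), class = "rq_controller")
}

#' @rdname controllers
#' @export
mhc_controller <- function(init_N = 600, check_interval = 30, threshold = 1.6,
                           sched = step_schedule(numeric(0), 50)) {
  structure(list(type = "mhc", init_N = init_N, threshold = threshold,
                 sched = sched,
                 clock = controller_clock(check_interval)),
            class = "rq_controller")
}

#' @rdname controllers
#' @export
blc_controller <- function(init_N = 550, check_interval = 10,
                           up_threshold = 1.4, down_threshold = 1.3,
                           down_step = 10,
                           sched = step_schedule(c(6, 12), c(10, 15, 25))) {
  structure(list(type = "blc", init_N = init_N, up_threshold = up_threshold,
                 down_threshold = down_threshold, down_step = down_step,
                 sched = sched,
                 clock = controller_clock(check_interval)),
            class = "rq_controller")
}

#' @rdname controllers
#' @export
apc_controller <- function(model, init_N = 550, set_point = 1.4,
                           min_action_gap = 7, deadband = 2,
                           kp_range = c(0, 5000)) {
  structure(list(type = "apc", init_N = init_N, model = model,
                 set_point = set_point, deadband = deadband,
                 kp_range = kp_range,
                 clock = controller_clock(1, min_action_gap)),
            class = "rq_controller")
}

controller_init <- function(controller) {
  list(clock = controller$clock)
}

# dispatch one observation to the controller; returns the action (or NULL
# for NONE) and the updated memory
controller_decide <- function(controller, obs, mem) {
  act <- switch(
    controller$type,
    null = none_action(obs$t, obs$N),
    mhc = mhc_decide(obs$rq, obs$t, obs$N, controller$sched, mem$clock,
                     threshold = controller$threshold),
    blc = blc_decide(obs$rq, obs$t, obs$N, controller$sched, mem$clock,
                     up_threshold = controller$up_threshold,
                     down_threshold = controller$down_threshold,
                     down_step = controller$down_step),
    apc = apc_decide(obs$rq, obs$t, obs$N, controller$model, mem$clock,
                     features = obs_features(obs),
                     set_point = controller$set_point,
                     deadband = controller$deadband,
                     kp_range = controller$kp_range),
    stop("unknown controller type: ", controller$type)
  )
  if (act$rule != "NONE") mem$clock$last_action_t <- obs$t
  list(action = if (act$rule == "NONE") NULL else act, mem = mem)
}

# the nine default gain-model features, in schema order
obs_features <- function(obs) {
  list(t_h = obs$t, n_rpm = obs$N, rq = obs$rq, our = obs$our,
       cer = obs$cer, feed_lh = obs$feed_lh, cum_glc_g = obs$cum_glc,
       y_o2_in = obs$y_o2_in, x_total_est = obs$x_total_est)
}
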