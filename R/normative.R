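#' Load the packaged published coefficient table
#'
#' The bundled table covers timing and angle equations for all 21 hip, knee
#' and ankle key-points, including NS (not-retained) predictor flags, the
#' per-equation RMSE, and the constant cycle-boundary timings (samples 1 and
#' 101). Predictor units: dimensionless walking speed, age in years, sex
#' coded 0 (female) / 1 (male), BMI in kg/m^2.
#'
#' @return a `coef_table` with source `"published"`.
#' @export
load_published_table <- function() {
  path <- system.file("extdata", "published_coefficients.csv",
                      package = "normgait", mustWork = TRUE)
  read_coefficient_table(path, source = "published")
}

# default sweep medians when no dataset is attached: population medians of
# the reference database emulated by the synth module
DEFAULT_MEDIANS <- c(v_star = 0.45, age = 38, sex = 1, bmi = 24)

# calibration envelope of the regression equations (dimensionless speed)
SPEED_ENVELOPE <- c(0.2, 0.7)

# enforce schema ordering on predicted timings: strictly increasing with at
# least `min_sep` samples between neighbours, endpoints pinned at 1 and 101
repair_timings <- function(t, min_sep = 1) {
  n <- length(t)
  out <- t
  out[1] <- 1
  out[n] <- 101
  for (i in 2:(n - 1)) out[i] <- max(out[i], out[i - 1] + min_sep)
  for (i in (n - 1):2) out[i] <- min(out[i], out[i + 1] - min_sep)
  if (any(diff(out) <= 0)) {
    stop("cannot repair key-point timing order (too many key-points ",
         "collapsed)", call. = FALSE)
  }
  if (max(abs(out - t)) > 1e-9) {
    warning("predicted key-point timings were out of order and have been ",
            "repaired to the schema order")
  }
  out
}

#' Predict key-point states from a coefficient table
#'
#' Evaluates every (key-point, parameter) equation at the predictor vector:
#' intercept plus the retained coefficients times the predictors; NS
#' coefficients contribute nothing and constants pass through. Predicted
#' timings are then repaired to the schema order (extrapolation at extreme
#' predictor values can invert neighbouring key-points). Predictions outside
#' the 0.2-0.7 dimensionless-speed calibration envelope are allowed but
#' flagged in the `"speed_extrapolated"` attribute.
#'
#' @param table a `coef_table` covering the requested joints.
#' @param p a [predictor_vector()].
#' @param joints joints to predict (default all three).
#' @return data frame with columns `joint`, `keypoint_id`, `timing`,
#'   `angle` (and `velocity`/`acceleration` when the table models them).
#' @export
predict_keypoints <- function(table, p, joints = JOINTS) {
  stopifnot(inherits(table, "coef_table"))
  p <- as_predictor_vector(p)
  pars <- intersect(c("timing", "angle", "velocity", "acceleration"),
                    unique(table$parameter))
  out <- list()
  for (joint in joints) {
    ids <- vapply(builtin_schema(joint)$defs, `[[`, "", "id")
    df <- data.frame(joint = joint, keypoint_id = ids)
    for (par in pars) {
      df[[par]] <- vapply(ids, function(kid) {
        eval_record(coef_record(table, kid, par), p)
      }, numeric(1))
    }
    df$timing <- repair_timings(df$timing)
    out[[joint]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "speed_extrapolated") <-
    p[["v_star"]] < SPEED_ENVELOPE[1] || p[["v_star"]] > SPEED_ENVELOPE[2]
  res
}

as_predictor_vector <- function(p) {
  if (inherits(p, "predictor_vector")) return(p)
  if (is.numeric(p) && length(p) == 4) {
    if (is.null(names(p))) names(p) <- PREDICTOR_COLS
    return(predictor_vector(p[["v_star"]], p[["age"]], p[["sex"]], p[["bmi"]]))
  }
  stop("expected a predictor_vector or a named numeric of length 4",
       call. = FALSE)
}

# fill in velocity/acceleration from a periodic cubic spline through the
# (timing, angle) knots; used when the coefficient table models only timing
# and angle
complete_derivatives <- function(states) {
  t <- states$timing
  a <- states$angle
  # splinefun(periodic) needs the closing knot to repeat the opening value
  a[length(a)] <- a[1]
  f <- stats::splinefun(t, a, method = "periodic")
  states$angle <- a
  states$velocity <- f(t, deriv = 1)
  states$acceleration <- f(t, deriv = 2)
  states$velocity[length(t)] <- states$velocity[1]
  states$acceleration[length(t)] <- states$acceleration[1]
  states
}

#' Predict full normative waveforms
#'
#' Predicts key-point states, completes missing angular derivatives with a
#' periodic cubic spline through the predicted (timing, angle) knots (a
#' user-supplied table that models velocity and acceleration overrides
#' this), and reconstructs each joint's waveform by piecewise quintic
#' interpolation.
#'
#' @inheritParams predict_keypoints
#' @param side side label for the returned waveforms.
#' @return named list of [gait_waveform()] objects, one per joint, with the
#'   predicted key-point states in the `"keypoints"` attribute.
#' @export
predict_waveforms <- function(table, p, joints = JOINTS, side = "left") {
  kps <- predict_keypoints(table, p, joints)
  out <- lapply(joints, function(joint) {
    st <- kps[kps$joint == joint, ]
    if (is.null(st$velocity) || anyNA(st$velocity)) {
      st <- complete_derivatives(st)
    }
    wf <- reconstruct_waveform(st, joint, side)
    attr(wf, "keypoints") <- st
    wf
  })
  names(out) <- joints
  out
}

#' Sweep one predictor over a range
#'
#' Evaluates the model at `n` evenly spaced values of one predictor (only
#' the two codes for sex) while the others stay at their median values, the
#' design used to isolate each predictor's contribution.
#'
#' @param table a `coef_table`.
#' @param which `"speed"`, `"age"`, `"sex"` or `"bmi"`.
#' @param n number of sweep values (default 15; sex always uses 2).
#' @param range length-2 numeric; defaults to the study population range for
#'   age (19-67 years) and BMI (17-31 kg/m^2). Required for speed (the
#'   calibration range is the usual choice).
#' @param medians named values for the non-swept predictors (defaults:
#'   v_star 0.45, age 38, sex 1, bmi 24).
#' @param joints joints to predict.
#' @return list with `predictor`, `values`, and `predictions` (one
#'   [predict_keypoints()] frame per value).
#' @export
sweep_predictor <- function(table, which = c("speed", "age", "sex", "bmi"),
                            n = 15, range = NULL,
                            medians = DEFAULT_MEDIANS, joints = JOINTS) {
  which <- match.arg(which)
  med <- DEFAULT_MEDIANS
  med[names(medians)] <- medians
  if (which == "sex") {
    values <- c(0, 1)
  } else {
    if (is.null(range)) {
      range <- switch(which, age = c(19, 67), bmi = c(17, 31),
                      stop("a sweep range must be supplied for the speed ",
                           "predictor", call. = FALSE))
    }
    if (range[1] >= range[2]) {
      stop("degenerate sweep range: min must be < max", call. = FALSE)
    }
    values <- seq(range[1], range[2], length.out = n)
  }
  target <- switch(which, speed = "v_star", which)
  preds <- lapply(values, function(val) {
    pv <- med
    pv[target] <- val
    predict_keypoints(table, as_predictor_vector(pv), joints)
  })
  list(predictor = which, values = values, predictions = preds)
}

#' Maximum contribution of one predictor over selected key-points
#'
#' Because predictions are linear in each predictor, the largest change a
#' predictor can induce over a sweep equals the absolute retained
#' coefficient times the sweep width (times 1 for the binary sex code); NS
#' coefficients contribute exactly 0.
#'
#' @param table a `coef_table`.
#' @param which `"speed"`, `"age"`, `"sex"` or `"bmi"`.
#' @param keypoint_ids key-point identifiers to scan.
#' @param range length-2 sweep range (ignored for sex).
#' @param parameter `"angle"` (default) or `"timing"`.
#' @return list with `deltas` (named per key-point) and `max`.
#' @export
contribution_range <- function(table, which = c("speed", "age", "sex", "bmi"),
                               keypoint_ids, range = NULL,
                               parameter = "angle") {
  which <- match.arg(which)
  beta_col <- switch(which, speed = "beta_speed", age = "beta_age",
                     sex = "beta_sex", bmi = "beta_bmi")
  width <- if (which == "sex") 1 else {
    if (is.null(range)) {
      range <- switch(which, age = c(19, 67), bmi = c(17, 31),
                      stop("a sweep range must be supplied for the speed ",
                           "predictor", call. = FALSE))
    }
    if (range[1] >= range[2]) {
      stop("a non-degenerate range is required for ", which, call. = FALSE)
    }
    range[2] - range[1]
  }
  deltas <- vapply(keypoint_ids, function(kid) {
    rec <- coef_record(table, kid, parameter)
    b <- rec[[beta_col]]
    if (is.na(b) || isTRUE(rec$is_constant)) 0 else abs(b) * width
  }, numeric(1))
  list(deltas = deltas, max = unname(max(deltas)))
}

#' Classify predictor-induced differences by clinical significance
#'
#' Angular differences: below 2 degrees no consequence is expected
#' (`"none"`), from 2 up to 5 degrees they warrant consideration during
#' interpretation (`"consider"`), and above 5 degrees they may mislead
#' clinical interpretation (`"may_mislead"`). Timing shifts are clinically
#' significant above 3% of the gait cycle.
#'
#' @param delta_timing non-negative timing shift(s) in % gait cycle.
#' @param delta_angle non-negative angular difference(s) in degrees.
#' @return list with character vectors `timing` (`"not_significant"` /
#'   `"significant"`) and `angle` (`"none"` / `"consider"` /
#'   `"may_mislead"`).
#' @export
classify_clinical <- function(delta_timing, delta_angle) {
  if (any(delta_timing < 0) || any(delta_angle < 0)) {
    stop("clinical deltas must be non-negative", call. = FALSE)
  }
  timing <- ifelse(delta_timing > 3, "significant", "not_significant")
  angle <- ifelse(delta_angle > 5, "may_mislead",
                  ifelse(delta_angle < 2, "none", "consider"))
  list(timing = timing, angle = angle)
}

#' Predictor-contribution report across all key-points
#'
#' Sweeps one predictor and reports, for every key-point, the maximal
#' induced timing shift (% gait cycle) and angular difference (degrees)
#' with their clinical significance labels.
#'
#' @inheritParams sweep_predictor
#' @return data frame with columns `joint`, `keypoint_id`, `delta_timing`,
#'   `delta_angle`, `timing_label`, `angle_label`.
#' @export
contribution_report <- function(table, which = c("speed", "age", "sex", "bmi"),
                                n = 15, range = NULL,
                                medians = DEFAULT_MEDIANS, joints = JOINTS) {
  which <- match.arg(which)
  sw <- sweep_predictor(table, which, n = n, range = range,
                        medians = medians, joints = joints)
  base <- sw$predictions[[1]]
  tim <- sapply(sw$predictions, `[[`, "timing")
  ang <- sapply(sw$predictions, `[[`, "angle")
  dt <- apply(tim, 1, function(x) diff(range(x)))
  da <- apply(ang, 1, function(x) diff(range(x)))
  labels <- classify_clinical(dt, da)
  data.frame(joint = base$joint, keypoint_id = base$keypoint_id,
             delta_timing = dt, delta_angle = da,
             timing_label = labels$timing, angle_label = labels$angle)
}
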