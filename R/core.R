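#' normgait: virtual normative databases for sagittal gait kinematics
#'
#' Tools to discretise hip/knee/ankle sagittal joint-angle waveforms into
#' clinically meaningful key-points, fit robust multilinear regressions of
#' each key-point parameter on walking speed, age, sex and BMI, and rebuild
#' continuous patient-matched normative waveforms by piecewise quintic-spline
#' interpolation.
#'
#' @keywords internal
"_PACKAGE"

JOINTS <- c("hip", "knee", "ankle")
SIDES <- c("left", "right")
N_SAMPLES <- 101L
CYCLE_PERIOD <- 100 # samples per gait cycle on the 1..101 grid

#' A joint-angle waveform over one normalized gait cycle
#'
#' Sample `k` corresponds to `(k - 1)`% of the gait cycle, so a cycle is
#' exactly 101 samples. Angles are in degrees with hip flexion, knee flexion
#' and ankle dorsiflexion positive.
#'
#' @param values numeric vector of 101 finite joint angles (degrees).
#' @param joint one of `"hip"`, `"knee"`, `"ankle"`.
#' @param side one of `"left"`, `"right"`.
#' @return a `gait_waveform` object (numeric vector with `joint`/`side`
#'   attributes).
#' @export
gait_waveform <- function(values, joint, side = "left") {
  joint <- match.arg(joint, JOINTS)
  side <- match.arg(side, SIDES)
  values <- as.numeric(values)
  if (length(values) != N_SAMPLES) {
    stop("a gait waveform must have exactly ", N_SAMPLES, " samples, got ",
         length(values), call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("gait waveform contains non-finite samples", call. = FALSE)
  }
  structure(values, joint = joint, side = side, class = "gait_waveform")
}

#' @export
print.gait_waveform <- function(x, ...) {
  cat(sprintf("<gait_waveform> %s (%s), 101 samples, range [%.2f, %.2f] deg\n",
              attr(x, "joint"), attr(x, "side"), min(x), max(x)))
  invisible(x)
}

#' Gait-event timings for one cycle
#'
#' Timings are in % gait cycle. The ipsilateral foot strike opens the cycle
#' at 0% and the next ipsilateral foot strike closes it at 100%; the three
#' interior events must be strictly ordered between them.
#'
#' @param contra_foot_off contralateral foot off (% gait cycle).
#' @param contra_foot_strike contralateral foot strike (% gait cycle).
#' @param ipsi_foot_off ipsilateral foot off (% gait cycle).
#' @return a `gait_events` object (named list of the five event timings).
#' @export
gait_events <- function(contra_foot_off, contra_foot_strike, ipsi_foot_off) {
  t <- c(ipsi_foot_strike = 0,
         contra_foot_off = as.numeric(contra_foot_off),
         contra_foot_strike = as.numeric(contra_foot_strike),
         ipsi_foot_off = as.numeric(ipsi_foot_off),
         next_ipsi_foot_strike = 100)
  if (any(!is.finite(t))) stop("gait events must be finite", call. = FALSE)
  if (any(diff(t) <= 0)) {
    stop("gait events out of order: need 0 < contralateral foot off < ",
         "contralateral foot strike < ipsilateral foot off < 100",
         call. = FALSE)
  }
  structure(as.list(t), class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat("<gait_events> (% gait cycle)\n")
  for (nm in names(x)) cat(sprintf("  %-22s %6.2f\n", nm, x[[nm]]))
  invisible(x)
}

#' A study participant
#'
#' Sex is coded 0 for female and 1 for male. BMI is checked against
#' mass/height^2 when height and mass are both given (tolerance 0.1).
#'
#' @param id subject identifier.
#' @param age age in years (> 0).
#' @param sex 0 (female) or 1 (male).
#' @param height stature in m (optional if `bmi` given).
#' @param mass body mass in kg (optional if `bmi` given).
#' @param bmi body mass index in kg/m^2; derived from mass/height^2 when
#'   missing.
#' @param leg_length leg length in m (anterior iliac spine to medial
#'   malleolus), used to make walking speed dimensionless.
#' @return a `subject` object.
#' @export
subject <- function(id, age, sex, height = NA_real_, mass = NA_real_,
                    bmi = NA_real_, leg_length) {
  sex <- as.numeric(sex)
  if (!sex %in% c(0, 1)) stop("sex must be coded 0 (female) or 1 (male)",
                              call. = FALSE)
  if (!is.finite(age) || age <= 0) stop("age must be positive", call. = FALSE)
  if (!is.finite(leg_length) || leg_length <= 0) {
    stop("leg_length must be positive", call. = FALSE)
  }
  if (is.na(bmi)) {
    if (is.na(height) || is.na(mass)) {
      stop("either bmi or both height and mass must be given", call. = FALSE)
    }
    bmi <- mass / height^2
  } else if (!is.na(height) && !is.na(mass) &&
             abs(bmi - mass / height^2) > 0.1) {
    stop("bmi inconsistent with mass/height^2 (tolerance 0.1)", call. = FALSE)
  }
  if (bmi <= 0) stop("bmi must be positive", call. = FALSE)
  structure(list(id = as.character(id), age = age, sex = sex, height = height,
                 mass = mass, bmi = bmi, leg_length = leg_length),
            class = "subject")
}

#' Dimensionless walking speed
#'
#' Raw walking speed divided by the square root of leg length times the
#' gravitational constant (the square root of the Froude number). Removes
#' stature effects; the walk-run transition sits near 0.7 on this scale.
#'
#' @param v raw walking speed in m/s (>= 0).
#' @param leg_length leg length in m (> 0).
#' @param g gravitational constant in m/s^2 (default 9.81).
#' @return dimensionless walking speed.
#' @examples
#' dimensionless_speed(1.25, 0.9) # ~0.42
#' @export
dimensionless_speed <- function(v, leg_length, g = 9.81) {
  if (any(!is.finite(leg_length)) || any(leg_length <= 0)) {
    stop("leg_length must be positive", call. = FALSE)
  }
  if (!is.finite(g) || g <= 0) stop("g must be positive", call. = FALSE)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("walking speed must be non-negative", call. = FALSE)
  }
  v / sqrt(g * leg_length)
}

#' Build the predictor vector for one subject and walking speed
#'
#' Predictors enter the regressions in raw units: dimensionless walking
#' speed, age in years, sex coded 0/1, BMI in kg/m^2. No centering or
#' scaling is applied.
#'
#' @param subj a [subject()].
#' @param v raw walking speed in m/s.
#' @param g gravitational constant, passed to [dimensionless_speed()].
#' @return a `predictor_vector`: named numeric `c(v_star, age, sex, bmi)`.
#' @export
encode_predictors <- function(subj, v, g = 9.81) {
  stopifnot(inherits(subj, "subject"))
  predictor_vector(dimensionless_speed(v, subj$leg_length, g),
                   subj$age, subj$sex, subj$bmi)
}

#' @rdname encode_predictors
#' @param v_star dimensionless walking speed (>= 0).
#' @param age age in years.
#' @param sex sex code, 0 female / 1 male.
#' @param bmi body mass index in kg/m^2.
#' @export
predictor_vector <- function(v_star, age, sex, bmi) {
  p <- c(v_star = as.numeric(v_star), age = as.numeric(age),
         sex = as.numeric(sex), bmi = as.numeric(bmi))
  if (any(!is.finite(p))) stop("predictors must be finite", call. = FALSE)
  if (p[["v_star"]] < 0) stop("v_star must be >= 0", call. = FALSE)
  if (!p[["sex"]] %in% c(0, 1)) stop("sex must be 0 or 1", call. = FALSE)
  structure(p, class = "predictor_vector")
}

# convert between the 1..101 sample scale and % gait cycle
sample_to_pct <- function(s) s - 1
pct_to_sample <- function(p) p + 1

# round half away from zero, as in round-half-up on positive timings
round_half_up <- function(x) floor(x + 0.5)
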