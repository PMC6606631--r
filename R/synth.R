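#' Configuration for the synthetic reference database
#'
#' The defaults emulate the study population behind the published
#' coefficient table: 54 adults (24 women / 30 men), ages 19-67 years
#' (37.9 +/- 13.7), BMI 17-31 kg/m^2, five walking-speed conditions (three
#' imposed bands plus spontaneous and maximal self-selected speed) and five
#' gait trials per condition. Key-point parameters are generated from the
#' supplied coefficient table with Gaussian noise scaled by each equation's
#' published RMSE; `noise_scale = 0` gives the exact model predictions.
#'
#' @param seed integer seed; mandatory, drives every random draw.
#' @param n_subjects number of subjects (default 54).
#' @param trials_per_condition gait trials per speed condition (default 5).
#' @param noise_scale multiplier on the per-equation RMSE used as the
#'   key-point noise SD (default 1; 0 = noiseless).
#' @param wf_noise_sd SD in degrees of smooth band-limited waveform-level
#'   noise added after reconstruction (default 0); used for reconstruction
#'   stress tests, not for regression datasets.
#' @param table generating `coef_table` (default the published table).
#' @param g gravitational constant (m/s^2).
#' @return a `synth_config` list.
#' @export
synth_config <- function(seed, n_subjects = 54, trials_per_condition = 5,
                         noise_scale = 1, wf_noise_sd = 0,
                         table = load_published_table(), g = 9.81) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("seed must be a single finite integer", call. = FALSE)
  }
  if (noise_scale < 0 || wf_noise_sd < 0) {
    stop("noise scales must be non-negative", call. = FALSE)
  }
  if (n_subjects < 1 || trials_per_condition < 1) {
    stop("need at least one subject and one trial per condition",
         call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 trials_per_condition = as.integer(trials_per_condition),
                 noise_scale = noise_scale, wf_noise_sd = wf_noise_sd,
                 table = table, g = g),
            class = "synth_config")
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Sample a synthetic study population
#'
#' Age is drawn from a Normal(35.2, 13.7) truncated to [19, 67] years: the
#' location is adjusted below the target mean because truncating at the
#' study bounds shifts the mean upward, and 35.2 is the location whose
#' truncated mean equals the study's 37.9 years. Sex ~ Bernoulli(30/54) for
#' the male code; height ~ Normal(1.74, 0.10) m; BMI ~ Normal(24, 3)
#' truncated to [17, 31] kg/m^2; mass derived from BMI and height; leg
#' length 0.53 x height plus ~1 cm of individual variation.
#'
#' @param n number of subjects.
#' @param seed optional seed (set it here when sampling outside
#'   [generate_dataset()]).
#' @return data frame of subjects (`id`, `age`, `sex`, `height`, `mass`,
#'   `bmi`, `leg_length`).
#' @export
sample_population <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 1)
  # location 35.21 gives a truncated mean of 37.9 years on [19, 67]
  age <- rtruncnorm1(n, 35.21, 13.7, 19, 67)
  sex <- stats::rbinom(n, 1, 30 / 54)
  height <- rtruncnorm1(n, 1.74, 0.10, 1.4, 2.1)
  bmi <- rtruncnorm1(n, 24, 3, 17, 31)
  leg <- 0.53 * height + stats::rnorm(n, 0, 0.01)
  data.frame(id = sprintf("S%03d", seq_len(n)), age = age, sex = sex,
             height = height, mass = bmi * height^2, bmi = bmi,
             leg_length = leg)
}

#' Draw the five walking-speed conditions for one subject
#'
#' Conditions C1-C3 are drawn uniformly within the imposed bands (0.1-0.4,
#' 0.4-0.8, 0.8-1.2 m/s; the slowest band is floored at 0.1 m/s since
#' slower walking degenerates into stepping in place); C4 (spontaneous) ~
#' Normal(1.3, 0.15) and C5 (maximal) ~ Normal(1.9, 0.2) m/s.
#'
#' @param leg_length subject leg length in m, for the dimensionless
#'   conversion.
#' @param g gravitational constant.
#' @return data frame with `condition`, `v` (m/s), `v_star`.
#' @export
assign_conditions <- function(leg_length, g = 9.81) {
  v <- c(stats::runif(1, 0.1, 0.4),
         stats::runif(1, 0.4, 0.8),
         stats::runif(1, 0.8, 1.2),
         max(0.8, stats::rnorm(1, 1.3, 0.15)),
         max(1.2, stats::rnorm(1, 1.9, 0.2)))
  data.frame(condition = paste0("C", 1:5), v = v,
             v_star = dimensionless_speed(v, leg_length, g))
}

# smooth periodic band-limited noise over the 101-sample cycle
smooth_cycle_noise <- function(sd, n_harmonics = 6) {
  if (sd == 0) return(rep(0, N_SAMPLES))
  a <- stats::rnorm(n_harmonics, 0, sd / sqrt(n_harmonics))
  b <- stats::rnorm(n_harmonics, 0, sd / sqrt(n_harmonics))
  t <- 0:(N_SAMPLES - 1)
  out <- rep(0, N_SAMPLES)
  for (k in seq_len(n_harmonics)) {
    w <- 2 * pi * k * t / CYCLE_PERIOD
    out <- out + a[k] * cos(w) + b[k] * sin(w)
  }
  out
}

# derive plausible gait events from the predicted foot-off timing:
# symmetric gait puts contralateral events 50% of the cycle away
events_from_keypoints <- function(kps) {
  ifo <- sample_to_pct(kps$timing[kps$keypoint_id == "HIS4"])
  ifo <- min(max(ifo, 52), 95)
  gait_events(contra_foot_off = ifo - 50, contra_foot_strike = 50,
              ipsi_foot_off = ifo)
}

#' Simulate one gait trial
#'
#' Key-point parameters are the generating-table predictions at the trial's
#' predictor vector plus independent Gaussian noise with SD `noise_scale`
#' times each equation's RMSE (constants stay exact). Timings are then
#' repaired to the schema order, angular derivatives completed by a
#' periodic cubic spline, and waveforms reconstructed by piecewise quintic
#' interpolation, optionally with smooth band-limited waveform-level noise.
#'
#' @param p a [predictor_vector()].
#' @param config a [synth_config()].
#' @param seed optional per-trial seed.
#' @param waveforms reconstruct waveforms (`TRUE`) or return key-points
#'   only.
#' @return list with `keypoints` (data frame), `events`, and `waveforms`
#'   (named list per joint, or `NULL`).
#' @export
simulate_trial <- function(p, config, seed = NULL, waveforms = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  p <- as_predictor_vector(p)
  kps <- suppressWarnings(predict_keypoints(config$table, p))
  if (config$noise_scale > 0) {
    for (i in seq_len(nrow(kps))) {
      for (par in c("timing", "angle")) {
        rec <- coef_record(config$table, kps$keypoint_id[i], par)
        if (!isTRUE(rec$is_constant) && rec$rmse > 0) {
          kps[[par]][i] <- kps[[par]][i] +
            stats::rnorm(1, 0, config$noise_scale * rec$rmse)
        }
      }
    }
    for (joint in JOINTS) {
      sel <- kps$joint == joint
      kps$timing[sel] <- suppressWarnings(repair_timings(kps$timing[sel]))
    }
  }
  events <- events_from_keypoints(kps)
  wfs <- NULL
  states_all <- list()
  for (joint in JOINTS) {
    st <- complete_derivatives(kps[kps$joint == joint, ])
    states_all[[joint]] <- st
  }
  kps <- do.call(rbind, states_all)
  rownames(kps) <- NULL
  if (waveforms) {
    wfs <- lapply(JOINTS, function(joint) {
      wf <- reconstruct_waveform(states_all[[joint]], joint)
      if (config$wf_noise_sd > 0) {
        noisy <- as.numeric(wf) + smooth_cycle_noise(config$wf_noise_sd)
        wf <- gait_waveform(noisy, joint)
      }
      wf
    })
    names(wfs) <- JOINTS
  }
  list(keypoints = kps, events = events, waveforms = wfs)
}

#' Generate a full synthetic reference dataset
#'
#' `n_subjects` x 5 conditions x `trials_per_condition` trials, each with
#' predictors, key-point states, gait events and (optionally) reconstructed
#' waveforms, plus the generating coefficient table for recovery tests.
#' Every trial gets its own seed derived from the configuration seed and
#' its (subject, condition, trial) indices, so the dataset is reproducible
#' and individual trials differ.
#'
#' @param config a [synth_config()].
#' @param waveforms reconstruct and store waveforms (default `TRUE`; skip
#'   for large regression-only datasets).
#' @return a `gait_dataset`: list with `subjects`, `trials`, `keypoints`,
#'   `waveforms`, `events`, `config`.
#' @export
generate_dataset <- function(config, waveforms = TRUE) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  subjects <- sample_population(config$n_subjects)
  cond <- lapply(seq_len(config$n_subjects), function(i) {
    cbind(subject_id = subjects$id[i],
          assign_conditions(subjects$leg_length[i], config$g))
  })
  cond <- do.call(rbind, cond)
  trials <- list(); kps <- list(); wfs <- list(); evs <- list()
  for (i in seq_len(nrow(cond))) {
    si <- match(cond$subject_id[i], subjects$id)
    ci <- match(cond$condition[i], paste0("C", 1:5))
    subj <- subjects[si, ]
    p <- predictor_vector(cond$v_star[i], subj$age, subj$sex, subj$bmi)
    for (ti in seq_len(config$trials_per_condition)) {
      uid <- sprintf("%s_%s_T%d", subj$id, cond$condition[i], ti)
      child <- (config$seed + 1000003 * si + 1009 * ci + ti) %% 2147483647
      tr <- simulate_trial(p, config, seed = child, waveforms = waveforms)
      trials[[uid]] <- data.frame(
        trial_uid = uid, subject_id = subj$id, condition = cond$condition[i],
        trial = ti, v = cond$v[i], v_star = cond$v_star[i], age = subj$age,
        sex = subj$sex, bmi = subj$bmi)
      k <- tr$keypoints
      k$trial_uid <- uid
      kps[[uid]] <- k
      evs[[uid]] <- tr$events
      if (waveforms) wfs[[uid]] <- tr$waveforms
    }
  }
  structure(list(subjects = subjects,
                 trials = do.call(rbind, c(trials, make.row.names = FALSE)),
                 keypoints = do.call(rbind, c(kps, make.row.names = FALSE)),
                 waveforms = if (waveforms) wfs else NULL,
                 events = evs, config = config),
            class = "gait_dataset")
}

#' @export
print.gait_dataset <- function(x, ...) {
  cat(sprintf(paste0("<gait_dataset> %d subjects, %d trials, noise_scale ",
                     "%.2f, seed %d\n"),
              nrow(x$subjects), nrow(x$trials), x$config$noise_scale,
              x$config$seed))
  invisible(x)
}
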