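# full-precision numeric formatting so CSV round trips are exact
fmt_num <- function(x) {
  ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
}

#' Read gait waveforms and their events
#'
#' The waveform CSV holds 101 rows per cycle with columns `cycle_id`,
#' `joint`, `side`, `sample` (1..101) and `angle` (degrees). The companion
#' JSON maps each `cycle_id` to its event timings (`contra_foot_off`,
#' `contra_foot_strike`, `ipsi_foot_off`, in % gait cycle). Malformed
#' inputs (wrong sample counts, non-finite angles, unordered events) are
#' rejected with a diagnostic naming the offending cycle.
#'
#' @param csv_path waveform CSV path.
#' @param events_path events JSON path.
#' @return list of cycles; each is a list with `cycle_id`, `waveform`
#'   ([gait_waveform()]) and `events` ([gait_events()]).
#' @export
read_waveforms <- function(csv_path, events_path) {
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  need <- c("cycle_id", "joint", "side", "sample", "angle")
  if (!all(need %in% names(df))) {
    stop("waveform CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ev <- jsonlite::fromJSON(events_path, simplifyVector = TRUE)
  out <- list()
  for (cid in unique(df$cycle_id)) {
    sub <- df[df$cycle_id == cid, ]
    for (joint in unique(sub$joint)) {
      seg <- sub[sub$joint == joint, ]
      seg <- seg[order(seg$sample), ]
      if (nrow(seg) != N_SAMPLES || !identical(as.integer(seg$sample), 1:101)) {
        stop("cycle ", cid, " (", joint, "): expected ", N_SAMPLES,
             " samples numbered 1..101, got ", nrow(seg), " rows",
             call. = FALSE)
      }
      if (any(!is.finite(seg$angle))) {
        stop("cycle ", cid, " (", joint, "): non-finite angle values",
             call. = FALSE)
      }
      e <- ev[[as.character(cid)]]
      if (is.null(e)) {
        stop("no events found for cycle ", cid, call. = FALSE)
      }
      out[[length(out) + 1]] <- list(
        cycle_id = cid,
        waveform = gait_waveform(seg$angle, joint, seg$side[1]),
        events = gait_events(e$contra_foot_off, e$contra_foot_strike,
                             e$ipsi_foot_off))
    }
  }
  out
}

#' Write gait waveforms and events in the package's native layout
#'
#' @param cycles list of cycles as returned by [read_waveforms()].
#' @param csv_path,events_path output paths.
#' @return invisibly, the two paths.
#' @export
write_waveforms <- function(cycles, csv_path, events_path) {
  rows <- lapply(cycles, function(cy) {
    data.frame(cycle_id = cy$cycle_id, joint = attr(cy$waveform, "joint"),
               side = attr(cy$waveform, "side"), sample = 1:101,
               angle = fmt_num(as.numeric(cy$waveform)))
  })
  utils::write.csv(do.call(rbind, rows), csv_path, row.names = FALSE,
                   quote = FALSE)
  ev <- list()
  for (cy in cycles) {
    ev[[as.character(cy$cycle_id)]] <- cy$events[
      c("contra_foot_off", "contra_foot_strike", "ipsi_foot_off")]
  }
  jsonlite::write_json(ev, events_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, events_path))
}

#' Read / write a coefficient table
#'
#' The CSV layout mirrors the published table: one row per (key-point,
#' parameter) with the intercept, the four predictor coefficients (the
#' literal marker `NS` for predictors not retained by the stepwise
#' selection), the per-equation RMSE, the number of retained predictors and
#' the constant flag for cycle-boundary timings. An `NS` in the intercept
#' column is a format error: every equation has an intercept.
#'
#' @param path CSV file path.
#' @param source provenance label stored on the table (`"published"` or
#'   `"fitted"`).
#' @return a `coef_table`.
#' @export
read_coefficient_table <- function(path, source = "fitted") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("joint", "keypoint", "parameter", "beta0", "beta_speed",
            "beta_age", "beta_sex", "beta_bmi", "rmse", "n_predictors")
  if (!all(need %in% names(df))) {
    stop("coefficient CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$beta0 == "NS")) {
    stop("malformed coefficient table: the intercept can never be NS",
         call. = FALSE)
  }
  known <- names(boundary_timings())
  known <- unique(c(known, unlist(lapply(JOINTS, function(j) {
    vapply(builtin_schema(j)$defs, `[[`, "", "id")
  }))))
  bad <- setdiff(unique(df$keypoint), known)
  if (length(bad)) {
    stop("unknown key-point id(s) in coefficient table: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ns_to_na <- function(x) {
    out <- suppressWarnings(as.numeric(ifelse(x == "NS", NA, x)))
    if (any(is.na(out) & x != "NS")) {
      stop("malformed coefficient entry (expected a number or NS)",
           call. = FALSE)
    }
    out
  }
  out <- data.frame(
    joint = df$joint, keypoint_id = df$keypoint, parameter = df$parameter,
    beta0 = as.numeric(df$beta0),
    beta_speed = ns_to_na(df$beta_speed), beta_age = ns_to_na(df$beta_age),
    beta_sex = ns_to_na(df$beta_sex), beta_bmi = ns_to_na(df$beta_bmi),
    rmse = as.numeric(df$rmse), n_predictors = as.integer(df$n_predictors),
    is_constant = if ("is_constant" %in% names(df)) {
      as.logical(df$is_constant)
    } else FALSE)
  new_coef_table(out, source = source)
}

#' @rdname read_coefficient_table
#' @param table a `coef_table` to write.
#' @export
write_coefficient_table <- function(table, path) {
  stopifnot(inherits(table, "coef_table"))
  na_to_ns <- function(x) ifelse(is.na(x), "NS", fmt_num(x))
  df <- data.frame(
    joint = table$joint, keypoint = table$keypoint_id,
    parameter = table$parameter, beta0 = fmt_num(table$beta0),
    beta_speed = na_to_ns(table$beta_speed),
    beta_age = na_to_ns(table$beta_age),
    beta_sex = na_to_ns(table$beta_sex),
    beta_bmi = na_to_ns(table$beta_bmi),
    rmse = fmt_num(table$rmse), n_predictors = table$n_predictors,
    is_constant = table$is_constant)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a synthetic dataset as a directory of plain-text files
#'
#' `subjects.csv`, `trials.csv`, `keypoints.csv`, `waveforms.csv` (long
#' format) and `manifest.json` (seed and configuration). Numeric values are
#' written at full precision so a round trip reproduces them exactly.
#'
#' @param dataset a `gait_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "gait_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  num_fmt <- function(df) {
    for (cn in names(df)) if (is.numeric(df[[cn]])) df[[cn]] <- fmt_num(df[[cn]])
    df
  }
  utils::write.csv(num_fmt(dataset$subjects), file.path(dir, "subjects.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(num_fmt(dataset$trials), file.path(dir, "trials.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(num_fmt(dataset$keypoints), file.path(dir, "keypoints.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(dataset$waveforms)) {
    rows <- lapply(names(dataset$waveforms), function(uid) {
      do.call(rbind, lapply(JOINTS, function(joint) {
        data.frame(trial_uid = uid, joint = joint, sample = 1:101,
                   angle = fmt_num(as.numeric(dataset$waveforms[[uid]][[joint]])))
      }))
    })
    utils::write.csv(do.call(rbind, rows), file.path(dir, "waveforms.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  ev <- lapply(dataset$events, function(e) {
    e[c("contra_foot_off", "contra_foot_strike", "ipsi_foot_off")]
  })
  jsonlite::write_json(ev, file.path(dir, "events.json"), auto_unbox = TRUE,
                       digits = NA)
  cfg <- dataset$config
  manifest <- list(seed = cfg$seed, n_subjects = cfg$n_subjects,
                   trials_per_condition = cfg$trials_per_condition,
                   noise_scale = cfg$noise_scale,
                   wf_noise_sd = cfg$wf_noise_sd, g = cfg$g,
                   package_version = as.character(utils::packageVersion("normgait")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  config <- synth_config(seed = manifest$seed,
                         n_subjects = manifest$n_subjects,
                         trials_per_condition = manifest$trials_per_condition,
                         noise_scale = manifest$noise_scale,
                         wf_noise_sd = manifest$wf_noise_sd,
                         g = manifest$g)
  subjects <- utils::read.csv(file.path(dir, "subjects.csv"))
  trials <- utils::read.csv(file.path(dir, "trials.csv"))
  keypoints <- utils::read.csv(file.path(dir, "keypoints.csv"))
  wfs <- NULL
  wf_path <- file.path(dir, "waveforms.csv")
  if (file.exists(wf_path)) {
    long <- utils::read.csv(wf_path)
    wfs <- list()
    for (uid in unique(long$trial_uid)) {
      sub <- long[long$trial_uid == uid, ]
      wfs[[uid]] <- lapply(stats::setNames(JOINTS, JOINTS), function(joint) {
        seg <- sub[sub$joint == joint, ]
        gait_waveform(seg$angle[order(seg$sample)], joint)
      })
    }
  }
  ev_raw <- jsonlite::fromJSON(file.path(dir, "events.json"))
  events <- lapply(ev_raw, function(e) {
    gait_events(e$contra_foot_off, e$contra_foot_strike, e$ipsi_foot_off)
  })
  structure(list(subjects = subjects, trials = trials, keypoints = keypoints,
                 waveforms = wfs, events = events, config = config),
            class = "gait_dataset")
}
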