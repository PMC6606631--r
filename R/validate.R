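#' Variance Accounted For
#'
#' `100 * (1 - var(y - yhat) / var(y))`, a waveform goodness-of-fit measure
#' in percent. Insensitive to a constant offset between the waveforms and
#' at most 100; undefined (`NA` with a warning) for a constant reference.
#'
#' @param y reference waveform (numeric, length >= 2).
#' @param yhat predicted waveform of the same length.
#' @return VAF in percent.
#' @export
vaf <- function(y, yhat) {
  y <- as.numeric(y); yhat <- as.numeric(yhat)
  if (length(y) != length(yhat) || length(y) < 2) {
    stop("waveforms must have equal length >= 2", call. = FALSE)
  }
  vy <- stats::var(y)
  if (vy == 0) {
    warning("VAF undefined for a constant reference waveform")
    return(NA_real_)
  }
  100 * (1 - stats::var(y - yhat) / vy)
}

#' Coefficient of determination between two waveforms
#'
#' The squared Pearson correlation of reference and prediction; undefined
#' (`NA` with a warning) when either waveform is constant.
#'
#' @inheritParams vaf
#' @return R^2 in `[0, 1]`.
#' @export
r_squared <- function(y, yhat) {
  y <- as.numeric(y); yhat <- as.numeric(yhat)
  if (length(y) != length(yhat) || length(y) < 2) {
    stop("waveforms must have equal length >= 2", call. = FALSE)
  }
  if (stats::var(y) == 0 || stats::var(yhat) == 0) {
    warning("R^2 undefined for a constant waveform")
    return(NA_real_)
  }
  stats::cor(y, yhat)^2
}

#' Leave-one-out cross validation of the full pipeline
#'
#' For every subject: refit the coefficient table on all other subjects'
#' trials, predict that subject's waveforms at their own predictor values,
#' and score prediction against the measured waveforms with RMSE, R^2 and
#' VAF. The hold-out unit is the subject, so no fold ever trains on data
#' from the subject it is scored on. Fold-level fit failures are flagged
#' and skipped; the remaining folds proceed.
#'
#' @param dataset a `gait_dataset` (see [generate_dataset()]) with
#'   waveforms.
#' @param alpha stepwise threshold passed to [fit_dataset()].
#' @param bin_width dimensionless-speed bin width for the summary (default
#'   0.05).
#' @return list with `results` (one row per trial x joint: `subject_id`,
#'   `condition`, `v_star`, `joint`, `rmse`, `r2`, `vaf`), `summary`
#'   (means per speed bin x joint) and `failed_folds`.
#' @export
loocv <- function(dataset, alpha = 0.01, bin_width = 0.05) {
  stopifnot(inherits(dataset, "gait_dataset"))
  subjects <- unique(dataset$trials$subject_id)
  if (length(subjects) < 3) {
    stop("leave-one-out validation needs at least 3 subjects", call. = FALSE)
  }
  if (is.null(dataset$waveforms)) {
    stop("dataset carries no waveforms; regenerate with waveforms = TRUE",
         call. = FALSE)
  }
  results <- list()
  failed <- character(0)
  for (sid in subjects) {
    holdout <- dataset$trials[dataset$trials$subject_id == sid, ]
    train_trials <- dataset$trials[dataset$trials$subject_id != sid, ]
    train_kp <- dataset$keypoints[
      dataset$keypoints$trial_uid %in% train_trials$trial_uid, ]
    table <- tryCatch(
      fit_dataset(train_kp, train_trials,
                  parameters = c("timing", "angle"), alpha = alpha),
      error = function(e) {
        warning("fold for subject ", sid, " failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(table)) {
      failed <- c(failed, sid)
      next
    }
    for (k in seq_len(nrow(holdout))) {
      tr <- holdout[k, ]
      p <- predictor_vector(tr$v_star, tr$age, tr$sex, tr$bmi)
      pred <- predict_waveforms(table, p)
      for (joint in JOINTS) {
        y <- dataset$waveforms[[tr$trial_uid]][[joint]]
        yhat <- pred[[joint]]
        results[[length(results) + 1]] <- data.frame(
          subject_id = sid, condition = tr$condition, v_star = tr$v_star,
          joint = joint, rmse = waveform_rmse(y, yhat),
          r2 = r_squared(y, yhat), vaf = vaf(y, yhat))
      }
    }
  }
  res <- do.call(rbind, results)
  rownames(res) <- NULL
  res$speed_bin <- floor(res$v_star / bin_width) * bin_width
  summ <- aggregate(cbind(rmse, r2, vaf) ~ joint + speed_bin, res, mean)
  summ$n <- aggregate(rmse ~ joint + speed_bin, res, length)$rmse
  list(results = res, summary = summ[order(summ$joint, summ$speed_bin), ],
       failed_folds = failed)
}
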