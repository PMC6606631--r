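PREDICTOR_COLS <- c("v_star", "age", "sex", "bmi")
BETA_COLS <- c("beta_speed", "beta_age", "beta_sex", "beta_bmi")

# residual sum of squares of an OLS fit with intercept on X[, cols]
rss_of <- function(X, y, cols) {
  M <- cbind(1, X[, cols, drop = FALSE])
  fit <- stats::lm.fit(M, y)
  sum(fit$residuals^2)
}

#' Stepwise predictor selection by partial-F p-values
#'
#' Forward-backward selection starting from the intercept-only model. At
#' each step the candidate whose partial F-test (equivalently squared
#' t-test) has the smallest p-value below `alpha` enters; included
#' predictors whose p-value rises to or above `alpha` are removed. Entry
#' and removal thresholds are both `alpha`, candidates are scanned in the
#' fixed order speed, age, sex, BMI, and the intercept is never subject to
#' selection. Once the model fits the response to numerical precision no
#' further predictor can enter (its partial F is indeterminate).
#'
#' @param design numeric matrix with columns `v_star`, `age`, `sex`, `bmi`
#'   (one row per observation).
#' @param response numeric vector.
#' @param alpha significance threshold for entry and removal (default 0.01).
#' @return named logical mask over the four predictors.
#' @export
stepwise_select <- function(design, response, alpha = 0.01) {
  X <- as.matrix(design)
  if (is.null(colnames(X))) colnames(X) <- PREDICTOR_COLS
  y <- as.numeric(response)
  n <- length(y)
  p_all <- ncol(X)
  if (n < p_all + 2) stop("need at least ", p_all + 2, " observations",
                          call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant predictor column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  }
  sst <- sum((y - mean(y))^2)
  included <- rep(FALSE, p_all)
  names(included) <- colnames(X)
  if (sst == 0) return(included)
  repeat {
    changed <- FALSE
    rss_cur <- rss_of(X, y, which(included))
    # entry: skip when the current model is already numerically exact
    if (rss_cur / sst > 1e-14) {
      cand <- which(!included)
      p_enter <- rep(NA_real_, length(cand))
      for (i in seq_along(cand)) {
        cols <- c(which(included), cand[i])
        rss_new <- rss_of(X, y, cols)
        df2 <- n - length(cols) - 1
        f <- (rss_cur - rss_new) / (rss_new / df2)
        p_enter[i] <- if (is.finite(f) && f >= 0) {
          stats::pf(f, 1, df2, lower.tail = FALSE)
        } else NA_real_
      }
      ok <- which(!is.na(p_enter) & p_enter < alpha)
      if (length(ok)) {
        best <- ok[which.min(p_enter[ok])]
        included[cand[best]] <- TRUE
        changed <- TRUE
        rss_cur <- rss_of(X, y, which(included))
      }
    }
    # removal: drop the least significant included predictor at >= alpha
    if (any(included)) {
      inc <- which(included)
      df2 <- n - length(inc) - 1
      p_rm <- vapply(inc, function(j) {
        rss_wo <- rss_of(X, y, setdiff(inc, j))
        f <- (rss_wo - rss_cur) / (rss_cur / df2)
        if (is.finite(f) && f >= 0) stats::pf(f, 1, df2, lower.tail = FALSE)
        else 1 # indeterminate partial F: the predictor explains nothing
      }, numeric(1))
      if (any(p_rm >= alpha)) {
        worst <- inc[which.max(p_rm)]
        included[worst] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  included
}

#' Robust multilinear fit by IRLS with Tukey bisquare weights
#'
#' Starts from ordinary least squares and iterates weighted least squares
#' with bisquare weights `w = (1 - (r / (c s))^2)^2` for `|r| < c s` (0
#' otherwise), tuning constant `c = 4.685` and residual scale
#' `s = MAD / 0.6745`. On exactly linear data all weights stay 1 and the
#' result equals ordinary least squares.
#'
#' @param design numeric matrix including the intercept column; must be full
#'   rank.
#' @param response numeric vector.
#' @param tuning bisquare tuning constant (default 4.685, 95% Gaussian
#'   efficiency).
#' @param tol convergence threshold on `max |delta beta|` (default 1e-8).
#' @param max_iter iteration cap (default 100); non-convergence returns the
#'   last iterate with a warning and `converged = FALSE`.
#' @return list with `coefficients`, `residuals`, `weights`, `iterations`,
#'   `converged`.
#' @export
robust_fit <- function(design, response, tuning = 4.685, tol = 1e-8,
                       max_iter = 100) {
  X <- as.matrix(design)
  y <- as.numeric(response)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("design matrix is rank deficient", call. = FALSE)
  beta <- qr.coef(qrX, y)
  converged <- TRUE
  iter <- 0L
  scale_floor <- 1e-10 * (stats::sd(y) + 1)
  w <- rep(1, length(y))
  repeat {
    r <- y - drop(X %*% beta)
    s <- stats::median(abs(r)) / 0.6745
    if (s < scale_floor) break # residuals at numerical zero: OLS is exact
    u <- r / (tuning * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w > 0) < ncol(X)) {
      warning("bisquare weights vanished on too many observations; ",
              "returning last iterate")
      converged <- FALSE
      break
    }
    beta_new <- stats::lm.wfit(X, y, w)$coefficients
    iter <- iter + 1L
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) break
    if (iter >= max_iter) {
      warning("robust fit did not converge in ", max_iter, " iterations")
      converged <- FALSE
      break
    }
  }
  r <- y - drop(X %*% beta)
  list(coefficients = as.numeric(beta), residuals = r, weights = w,
       iterations = iter, converged = converged)
}

# key-points whose timing is pinned to the cycle boundary
boundary_timings <- function() {
  c(HIS1 = 1, HIS6 = 101, KNS1 = 1, KNS8 = 101, ANS1 = 1, ANS7 = 101)
}

keypoint_joint <- function(keypoint_id) {
  c(H = "hip", K = "knee", A = "ankle")[substr(keypoint_id, 1, 1)]
}

new_coef_table <- function(df, source) {
  rownames(df) <- NULL
  structure(df, class = c("coef_table", "data.frame"), source = source)
}

#' @export
print.coef_table <- function(x, ...) {
  cat(sprintf("<coef_table> %d records (%s)\n", nrow(x),
              attr(x, "source") %||% "unknown"))
  print.data.frame(x, digits = 5, ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the full coefficient table from a trial dataset
#'
#' One regression per (key-point, parameter): stepwise predictor selection
#' at `alpha`, then a robust IRLS fit on the retained predictors. Cycle
#' boundary timings (fixed at samples 1 and 101) are emitted as constants.
#' A response with zero variance yields an intercept-only record. The RMSE
#' column is the root mean square residual of each fitted equation, in the
#' parameter's own units.
#'
#' @param keypoints data frame with one row per (trial, key-point):
#'   columns `trial_uid`, `keypoint_id`, and the parameter columns
#'   (`timing`, `angle`, optionally `velocity`, `acceleration`).
#' @param predictors data frame with one row per trial: columns
#'   `trial_uid`, `v_star`, `age`, `sex`, `bmi`.
#' @param parameters which key-point parameters to model; defaults to the
#'   parameter columns present in `keypoints`.
#' @param alpha stepwise significance threshold (default 0.01).
#' @return a `coef_table` (source `"fitted"`): one row per (key-point,
#'   parameter) with intercept, the four predictor coefficients (`NA` when
#'   not retained), `rmse`, `n_predictors` and `is_constant`.
#' @export
fit_dataset <- function(keypoints, predictors,
                        parameters = intersect(
                          c("timing", "angle", "velocity", "acceleration"),
                          names(keypoints)),
                        alpha = 0.01) {
  if (inherits(keypoints, "gait_dataset")) {
    predictors <- keypoints$trials
    keypoints <- keypoints$keypoints
  }
  stopifnot(all(c("trial_uid", "keypoint_id") %in% names(keypoints)),
            all(c("trial_uid", PREDICTOR_COLS) %in% names(predictors)))
  if (length(unique(predictors$trial_uid)) < 20) {
    stop("need at least 20 trials to fit the coefficient table", call. = FALSE)
  }
  bounds <- boundary_timings()
  kp_ids <- unique(keypoints$keypoint_id)
  rows <- list()
  for (kid in kp_ids) {
    sub <- keypoints[keypoints$keypoint_id == kid, ]
    m <- match(sub$trial_uid, predictors$trial_uid)
    if (anyNA(m)) stop("key-point rows reference unknown trials", call. = FALSE)
    X <- as.matrix(predictors[m, PREDICTOR_COLS])
    for (par in parameters) {
      y <- sub[[par]]
      if (is.null(y) || all(is.na(y))) next
      rec <- data.frame(joint = unname(keypoint_joint(kid)), keypoint_id = kid,
                        parameter = par, beta0 = NA_real_,
                        beta_speed = NA_real_, beta_age = NA_real_,
                        beta_sex = NA_real_, beta_bmi = NA_real_,
                        rmse = NA_real_, n_predictors = 0L,
                        is_constant = FALSE)
      if (par == "timing" && kid %in% names(bounds)) {
        rec$beta0 <- unname(bounds[kid])
        rec$rmse <- 0
        rec$is_constant <- TRUE
      } else if (stats::sd(y) < 1e-12) {
        rec$beta0 <- mean(y)
        rec$rmse <- sqrt(mean((y - mean(y))^2))
      } else {
        mask <- stepwise_select(X, y, alpha = alpha)
        M <- cbind(1, X[, mask, drop = FALSE])
        fit <- robust_fit(M, y)
        rec$beta0 <- fit$coefficients[1]
        rec[BETA_COLS[mask]] <- as.list(fit$coefficients[-1])
        rec$rmse <- sqrt(mean(fit$residuals^2))
        rec$n_predictors <- sum(mask)
      }
      rows[[length(rows) + 1]] <- rec
    }
  }
  df <- do.call(rbind, rows)
  df <- df[order(match(df$joint, JOINTS), df$keypoint_id,
                 match(df$parameter, c("timing", "angle", "velocity",
                                       "acceleration"))), ]
  new_coef_table(df, source = "fitted")
}

# fetch one record from a coefficient table
coef_record <- function(table, keypoint_id, parameter) {
  i <- which(table$keypoint_id == keypoint_id & table$parameter == parameter)
  if (length(i) != 1) {
    stop("coefficient table has no record for (", keypoint_id, ", ",
         parameter, ")", call. = FALSE)
  }
  table[i, ]
}

# evaluate one record at a predictor vector
eval_record <- function(rec, p) {
  if (isTRUE(rec$is_constant)) return(rec$beta0)
  betas <- unlist(rec[BETA_COLS])
  keep <- !is.na(betas)
  rec$beta0 + sum(betas[keep] * as.numeric(p)[keep])
}
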