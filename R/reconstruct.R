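#' Solve one quintic interpolation segment
#'
#' The unique degree-5 polynomial matching angle, angular velocity and
#' angular acceleration at both segment ends. The system is solved in a
#' local coordinate `u = (t - t_left) / (t_right - t_left)` for numerical
#' conditioning; derivative constraints are rescaled accordingly.
#'
#' @param left,right key-point states: lists or one-row data frames with
#'   `timing`, `angle`, `velocity`, `acceleration` (derivatives in deg per
#'   % gait cycle and deg per (% gait cycle)^2).
#' @return a `quintic_segment`: list with `t_left`, `t_right` and the six
#'   polynomial coefficients `coef` (ascending powers of `u`).
#' @export
solve_quintic_segment <- function(left, right) {
  tl <- as.numeric(left$timing); tr <- as.numeric(right$timing)
  if (!is.finite(tl) || !is.finite(tr) || tl >= tr) {
    stop("degenerate segment: need left timing < right timing", call. = FALSE)
  }
  h <- tr - tl
  b <- c(left$angle, left$velocity * h, left$acceleration * h^2,
         right$angle, right$velocity * h, right$acceleration * h^2)
  if (any(!is.finite(b))) {
    stop("non-finite boundary state in quintic segment", call. = FALSE)
  }
  # rows: p(0), p'(0), p''(0), p(1), p'(1), p''(1) in u-coordinates
  A <- rbind(c(1, 0, 0, 0, 0, 0),
             c(0, 1, 0, 0, 0, 0),
             c(0, 0, 2, 0, 0, 0),
             c(1, 1, 1, 1, 1, 1),
             c(0, 1, 2, 3, 4, 5),
             c(0, 0, 2, 6, 12, 20))
  coef <- solve(A, b)
  structure(list(t_left = tl, t_right = tr, coef = as.numeric(coef)),
            class = "quintic_segment")
}

# evaluate a quintic segment (and derivatives w.r.t. t) at timings t
eval_quintic <- function(seg, t, deriv = 0) {
  h <- seg$t_right - seg$t_left
  u <- (t - seg$t_left) / h
  cf <- seg$coef
  k <- seq_along(cf) - 1
  for (d in seq_len(deriv)) {
    cf <- cf[-1] * k[-1]
    k <- seq_along(cf) - 1
  }
  val <- rep(0, length(u))
  for (i in rev(seq_along(cf))) val <- val * u + cf[i]
  val / h^deriv
}

#' Rebuild a continuous waveform from key-point states
#'
#' Piecewise quintic interpolation through the states: each segment matches
#' angle, velocity and acceleration at both of its knots, so the result is
#' C2-continuous across knots and, because the closing state equals the
#' opening one, continuous across gait cycles. The piecewise polynomial is
#' evaluated on the integer 1..101 sample grid; knot timings may be
#' non-integer.
#'
#' @param states data frame of key-point states sorted by `timing`, with the
#'   first at sample 1 and the last at sample 101; columns `timing`,
#'   `angle`, `velocity`, `acceleration`.
#' @param joint joint name for the returned waveform.
#' @param side side label.
#' @return a [gait_waveform()].
#' @export
reconstruct_waveform <- function(states, joint, side = "left") {
  t <- as.numeric(states$timing)
  if (length(t) < 2) stop("need at least two key-point states", call. = FALSE)
  if (is.unsorted(t, strictly = TRUE)) {
    stop("key-point timings must be strictly increasing; repair the ",
         "ordering before reconstruction", call. = FALSE)
  }
  if (abs(t[1] - 1) > 1e-9 || abs(t[length(t)] - 101) > 1e-9) {
    stop("states must start at sample 1 and close at sample 101", call. = FALSE)
  }
  segs <- lapply(seq_len(length(t) - 1), function(i) {
    solve_quintic_segment(states[i, ], states[i + 1, ])
  })
  knots <- t
  s <- 1:101
  idx <- findInterval(s, knots, rightmost.closed = TRUE)
  idx[idx < 1] <- 1L
  idx[idx > length(segs)] <- length(segs)
  vals <- vapply(seq_along(s), function(i) eval_quintic(segs[[idx[i]]], s[i]),
                 numeric(1))
  gait_waveform(vals, joint, side)
}

#' Root-mean-square error between two waveforms
#'
#' @param a,b [gait_waveform()] objects (or plain 101-sample vectors) for
#'   the same joint.
#' @return RMSE in degrees.
#' @export
waveform_rmse <- function(a, b) {
  if (length(a) != length(b)) {
    stop("waveform lengths differ (", length(a), " vs ", length(b), ")",
         call. = FALSE)
  }
  if (inherits(a, "gait_waveform") && inherits(b, "gait_waveform") &&
      attr(a, "joint") != attr(b, "joint")) {
    stop("waveforms are for different joints", call. = FALSE)
  }
  sqrt(mean((as.numeric(a) - as.numeric(b))^2))
}
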