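EVENT_NAMES <- c("ipsi_foot_strike", "contra_foot_off", "contra_foot_strike",
                 "ipsi_foot_off", "next_ipsi_foot_strike")

#' Anchors for key-point definitions
#'
#' An anchor is either a gait event, or a fractional position between two
#' events ("middle time", "one quarter", "three quarters" in the clinical
#' descriptions).
#'
#' @param event an event name (see `gait_events()` fields).
#' @return an `anchor` object.
#' @export
anchor_event <- function(event) {
  event <- match.arg(event, EVENT_NAMES)
  structure(list(from = event, to = NA_character_, frac = 0), class = "anchor")
}

#' @rdname anchor_event
#' @param from,to event names bounding the interpolation.
#' @param frac fractional position in `[0, 1]` between `from` and `to`.
#' @export
anchor_between <- function(from, to, frac) {
  from <- match.arg(from, EVENT_NAMES)
  to <- match.arg(to, EVENT_NAMES)
  stopifnot(is.numeric(frac), frac >= 0, frac <= 1)
  structure(list(from = from, to = to, frac = frac), class = "anchor")
}

#' Key-point definition
#'
#' A key-point is either the angle at a single anchored instant, or an
#' extremum (minimum/maximum) over a window bounded by two anchors.
#'
#' @param id key-point identifier (e.g. `"HIS3"`).
#' @param item `"angle_at_event"`, `"min_in_window"` or `"max_in_window"`.
#' @param at single anchor for `angle_at_event` items.
#' @param from,to window anchors for extremum items.
#' @return a `keypoint_def` object.
#' @export
keypoint_def <- function(id, item, at = NULL, from = NULL, to = NULL) {
  item <- match.arg(item, c("angle_at_event", "min_in_window", "max_in_window"))
  if (item == "angle_at_event") {
    stopifnot(inherits(at, "anchor"))
    from <- at
    to <- at
  } else {
    stopifnot(inherits(from, "anchor"), inherits(to, "anchor"))
  }
  structure(list(id = id, item = item, from = from, to = to),
            class = "keypoint_def")
}

#' Key-point schema for one joint
#'
#' @param joint `"hip"`, `"knee"` or `"ankle"`.
#' @param defs ordered list of [keypoint_def()]; the first must be anchored
#'   at the cycle start and the last at the cycle end.
#' @return a `keypoint_schema` object.
#' @export
keypoint_schema <- function(joint, defs) {
  joint <- match.arg(joint, JOINTS)
  stopifnot(length(defs) >= 2, all(vapply(defs, inherits, TRUE, "keypoint_def")))
  first <- defs[[1]]; last <- defs[[length(defs)]]
  if (!(first$from$from == "ipsi_foot_strike" && first$from$frac == 0)) {
    stop("first key-point must be anchored at the ipsilateral foot strike",
         call. = FALSE)
  }
  if (!(last$to$from == "next_ipsi_foot_strike" ||
        identical(last$to$to, "next_ipsi_foot_strike") && last$to$frac == 1)) {
    stop("last key-point must be anchored at the next ipsilateral foot strike",
         call. = FALSE)
  }
  structure(list(joint = joint, defs = defs), class = "keypoint_schema")
}

#' @export
print.keypoint_schema <- function(x, ...) {
  cat(sprintf("<keypoint_schema> %s, %d key-points: %s\n", x$joint,
              length(x$defs),
              paste(vapply(x$defs, `[[`, "", "id"), collapse = " ")))
  invisible(x)
}

#' Built-in clinical key-point schemas
#'
#' The bundled definitions: 6 hip key-points (HIS1-HIS6), 8 knee key-points
#' (KNS1-KNS8) and 7 ankle key-points (ANS1-ANS7), each anchored on gait
#' events or fractional positions between them. HIS5's "one quarter" /
#' "three quarters" anchors are read as the bounds of its maximum-search
#' window.
#'
#' @param joint `"hip"`, `"knee"` or `"ankle"`.
#' @return a [keypoint_schema()].
#' @export
builtin_schema <- function(joint) {
  joint <- match.arg(joint, JOINTS)
  ifs <- anchor_event("ipsi_foot_strike")
  cfo <- anchor_event("contra_foot_off")
  cfs <- anchor_event("contra_foot_strike")
  ifo <- anchor_event("ipsi_foot_off")
  nfs <- anchor_event("next_ipsi_foot_strike")
  mid_stance <- anchor_between("ipsi_foot_strike", "ipsi_foot_off", 0.5)
  defs <- switch(joint,
    hip = list(
      keypoint_def("HIS1", "angle_at_event", at = ifs),
      keypoint_def("HIS2", "angle_at_event", at = mid_stance),
      keypoint_def("HIS3", "min_in_window", from = ifs, to = ifo),
      keypoint_def("HIS4", "angle_at_event", at = ifo),
      keypoint_def("HIS5", "max_in_window",
                   from = anchor_between("ipsi_foot_off",
                                         "next_ipsi_foot_strike", 0.25),
                   to = anchor_between("ipsi_foot_off",
                                       "next_ipsi_foot_strike", 0.75)),
      keypoint_def("HIS6", "angle_at_event", at = nfs)),
    knee = list(
      keypoint_def("KNS1", "angle_at_event", at = ifs),
      keypoint_def("KNS2", "max_in_window", from = ifs, to = mid_stance),
      keypoint_def("KNS3", "min_in_window", from = mid_stance, to = ifo),
      keypoint_def("KNS4", "angle_at_event",
                   at = anchor_between("ipsi_foot_strike",
                                       "ipsi_foot_off", 0.75)),
      keypoint_def("KNS5", "angle_at_event", at = ifo),
      keypoint_def("KNS6", "max_in_window", from = ifo, to = nfs),
      keypoint_def("KNS7", "angle_at_event",
                   at = anchor_between("ipsi_foot_off",
                                       "next_ipsi_foot_strike", 0.75)),
      keypoint_def("KNS8", "angle_at_event", at = nfs)),
    ankle = list(
      keypoint_def("ANS1", "angle_at_event", at = ifs),
      keypoint_def("ANS2", "min_in_window", from = ifs, to = cfo),
      keypoint_def("ANS3", "angle_at_event", at = mid_stance),
      keypoint_def("ANS4", "max_in_window", from = ifs, to = ifo),
      keypoint_def("ANS5", "min_in_window", from = cfs,
                   to = anchor_between("ipsi_foot_off",
                                       "next_ipsi_foot_strike", 0.5)),
      keypoint_def("ANS6", "max_in_window", from = ifo,
                   to = anchor_between("ipsi_foot_off",
                                       "next_ipsi_foot_strike", 0.75)),
      keypoint_def("ANS7", "angle_at_event", at = nfs)))
  keypoint_schema(joint, defs)
}

#' Evenly spaced technical key-point schema
#'
#' `k` angle-at-instant key-points evenly spaced over the cycle; used to
#' study reconstruction error versus key-point count.
#'
#' @param joint joint name.
#' @param k number of key-points (>= 2); `k = 101` places one at every
#'   sample and makes reconstruction exact.
#' @return a [keypoint_schema()].
#' @export
uniform_schema <- function(joint, k) {
  stopifnot(k >= 2)
  defs <- lapply(seq_len(k), function(i) {
    keypoint_def(sprintf("U%03d", i), "angle_at_event",
                 at = anchor_between("ipsi_foot_strike",
                                     "next_ipsi_foot_strike",
                                     (i - 1) / (k - 1)))
  })
  keypoint_schema(joint, defs)
}

resolve_anchor <- function(a, events) {
  stopifnot(inherits(a, "anchor"), inherits(events, "gait_events"))
  p0 <- events[[a$from]]
  pct <- if (is.na(a$to)) p0 else (1 - a$frac) * p0 + a$frac * events[[a$to]]
  as.integer(round_half_up(pct_to_sample(pct)))
}

#' Resolve a key-point definition to a sample window
#'
#' Maps the definition's anchors onto the 1..101 sample grid: fractional
#' anchors are linear interpolations between their two events, rounded
#' half-up to the nearest sample. Windows are inclusive at both ends.
#'
#' @param def a [keypoint_def()].
#' @param events a [gait_events()].
#' @return integer `c(start_sample, end_sample)`.
#' @export
resolve_window <- function(def, events) {
  s <- resolve_anchor(def$from, events)
  e <- resolve_anchor(def$to, events)
  if (s > e) {
    stop("key-point ", def$id, ": resolved window start (", s,
         ") after end (", e, "); schema and events are inconsistent",
         call. = FALSE)
  }
  c(s, e)
}

# central finite differences with periodic wrap (period 100 samples;
# sample 101 is the same instant of the cycle as sample 1)
waveform_derivatives <- function(values) {
  v <- values[1:100]
  vp <- v[c(2:100, 1)]
  vm <- v[c(100, 1:99)]
  vel <- (vp - vm) / 2
  acc <- vp - 2 * v + vm
  list(velocity = c(vel, vel[1]), acceleration = c(acc, acc[1]))
}

#' Extract key-point states from a waveform
#'
#' For angle-at-instant key-points the timing is the resolved sample and the
#' angle the waveform value there; for extremum key-points the timing is the
#' arg-min/arg-max over the inclusive window (first occurrence on ties).
#' Angular velocity (deg per % gait cycle) and acceleration (deg per
#' (% gait cycle)^2) come from central finite differences with periodic
#' wrap. The cycle-end state copies the cycle-start state so that
#' consecutive cycles join continuously.
#'
#' @param waveform a [gait_waveform()].
#' @param events a [gait_events()].
#' @param schema a [keypoint_schema()] for the same joint; defaults to the
#'   built-in clinical schema.
#' @return data frame with columns `keypoint_id`, `timing` (1..101 sample
#'   scale), `angle`, `velocity`, `acceleration`.
#' @export
extract_keypoints <- function(waveform, events,
                              schema = builtin_schema(attr(waveform, "joint"))) {
  stopifnot(inherits(waveform, "gait_waveform"), inherits(schema, "keypoint_schema"))
  if (attr(waveform, "joint") != schema$joint) {
    stop("waveform joint (", attr(waveform, "joint"),
         ") does not match schema joint (", schema$joint, ")", call. = FALSE)
  }
  v <- as.numeric(waveform)
  d <- waveform_derivatives(v)
  rows <- lapply(schema$defs, function(def) {
    w <- resolve_window(def, events)
    seg <- v[w[1]:w[2]]
    if (any(!is.finite(seg))) {
      stop("non-finite samples in window of key-point ", def$id, call. = FALSE)
    }
    s <- switch(def$item,
                angle_at_event = w[1],
                min_in_window = w[1] + which.min(seg) - 1L,
                max_in_window = w[1] + which.max(seg) - 1L)
    data.frame(keypoint_id = def$id, timing = as.numeric(s), angle = v[s],
               velocity = d$velocity[s], acceleration = d$acceleration[s])
  })
  out <- do.call(rbind, rows)
  n <- nrow(out)
  # enforce cycle continuity: end state equals start state
  out$angle[n] <- out$angle[1]
  out$velocity[n] <- out$velocity[1]
  out$acceleration[n] <- out$acceleration[1]
  rownames(out) <- NULL
  out
}

#' Reconstruction error as a function of the key-point set
#'
#' Discretises and reconstructs every waveform under each candidate schema
#' variant and reports the mean RMSE, quantifying how reconstruction
#' fidelity depends on the number and placement of key-points.
#'
#' @param waveforms list of [gait_waveform()] objects.
#' @param events a single [gait_events()] or a list parallel to `waveforms`.
#' @param variants named list of schema variants; each variant is either a
#'   [keypoint_schema()] or a list of schemas keyed by joint.
#' @return data frame with columns `variant`, `joint`, `n_keypoints`,
#'   `mean_rmse`.
#' @export
discretisation_study <- function(waveforms, events, variants) {
  if (length(variants) == 0) stop("no schema variants supplied", call. = FALSE)
  if (length(waveforms) == 0) stop("no waveforms supplied", call. = FALSE)
  if (inherits(events, "gait_events")) events <- rep(list(events), length(waveforms))
  stopifnot(length(events) == length(waveforms))
  if (is.null(names(variants))) names(variants) <- paste0("variant", seq_along(variants))
  out <- list()
  for (vn in names(variants)) {
    variant <- variants[[vn]]
    errs <- lapply(seq_along(waveforms), function(i) {
      wf <- waveforms[[i]]
      joint <- attr(wf, "joint")
      schema <- if (inherits(variant, "keypoint_schema")) variant else variant[[joint]]
      if (is.null(schema)) return(NULL)
      if (schema$joint != joint) return(NULL)
      kp <- extract_keypoints(wf, events[[i]], schema)
      kp <- kp[order(kp$timing), ]
      kp <- kp[!duplicated(kp$timing), ] # extrema can land on window edges
      rec <- reconstruct_waveform(kp, joint)
      data.frame(joint = joint, n_keypoints = length(schema$defs),
                 rmse = waveform_rmse(wf, rec))
    })
    errs <- do.call(rbind, errs)
    if (is.null(errs)) next
    agg <- aggregate(rmse ~ joint + n_keypoints, errs, mean)
    out[[vn]] <- data.frame(variant = vn, joint = agg$joint,
                            n_keypoints = agg$n_keypoints,
                            mean_rmse = agg$rmse)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Serialize a key-point schema to JSON
#'
#' The layout mirrors the clinical definition table: one record per
#' key-point with joint, notation, item and its At/From and To anchors.
#'
#' @param schema a [keypoint_schema()].
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when writing to file).
#' @export
schema_to_json <- function(schema, path = NULL) {
  recs <- lapply(schema$defs, function(d) {
    list(joint = schema$joint, notation = d$id, item = d$item,
         at_from = d$from[c("from", "to", "frac")],
         to = d$to[c("from", "to", "frac")])
  })
  js <- jsonlite::toJSON(recs, auto_unbox = TRUE, pretty = TRUE,
                         null = "null", na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname schema_to_json
#' @param json JSON string or file path produced by [schema_to_json()].
#' @export
schema_from_json <- function(json) {
  recs <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  joint <- recs[[1]]$joint
  mk_anchor <- function(a) {
    if (is.null(a$to) || is.na(a$to)) anchor_event(a$from)
    else anchor_between(a$from, a$to, a$frac)
  }
  defs <- lapply(recs, function(r) {
    if (r$item == "angle_at_event") {
      keypoint_def(r$notation, r$item, at = mk_anchor(r$at_from))
    } else {
      keypoint_def(r$notation, r$item, from = mk_anchor(r$at_from),
                   to = mk_anchor(r$to))
    }
  })
  keypoint_schema(joint, defs)
}
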