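test_that("built-in schemas have the clinical key-point sets", {
  expect_length(builtin_schema("hip")$defs, 6)
  expect_length(builtin_schema("knee")$defs, 8)
  expect_length(builtin_schema("ankle")$defs, 7)
  expect_error(builtin_schema("pelvis"))
  his3 <- builtin_schema("hip")$defs[[3]]
  expect_equal(his3$id, "HIS3")
  expect_equal(his3$item, "min_in_window")
  expect_equal(his3$from$from, "ipsi_foot_strike")
  expect_equal(his3$to$from, "ipsi_foot_off")
  ans2 <- builtin_schema("ankle")$defs[[2]]
  expect_equal(ans2$item, "min_in_window")
  expect_equal(ans2$to$from, "contra_foot_off")
})

test_that("windows resolve to the 1..101 grid by linear interpolation", {
  ev <- typical_events()
  mid <- keypoint_def("X", "angle_at_event",
                      at = anchor_between("ipsi_foot_strike",
                                          "ipsi_foot_off", 0.5))
  expect_equal(resolve_window(mid, ev), c(31L, 31L)) # 30% GC
  tq <- keypoint_def("X", "angle_at_event",
                     at = anchor_between("ipsi_foot_off",
                                         "next_ipsi_foot_strike", 0.75))
  expect_equal(resolve_window(tq, ev), c(91L, 91L)) # 60 + 0.75*40 = 90% GC
  at <- keypoint_def("X", "angle_at_event", at = anchor_event("ipsi_foot_strike"))
  expect_equal(resolve_window(at, ev), c(1L, 1L))
  bad <- keypoint_def("X", "min_in_window",
                      from = anchor_event("ipsi_foot_off"),
                      to = anchor_event("contra_foot_off"))
  expect_error(resolve_window(bad, ev), "inconsistent")
})

test_that("extraction finds values at events and extrema in windows", {
  ev <- typical_events()
  # constant waveform: extremum tie-break is the first window sample
  kp <- extract_keypoints(gait_waveform(rep(0, 101), "knee"), ev)
  expect_true(all(kp$angle == 0))
  expect_equal(kp$timing[kp$keypoint_id == "KNS2"], 1)   # window [1, 31]
  expect_equal(kp$timing[kp$keypoint_id == "KNS3"], 31)  # window [31, 61]
  # fixture with a unique maximum of 17.2 deg at sample 13 in KNS2's window
  v <- -10 + 0.05 * (0:100)
  v[13] <- 17.2
  kp <- extract_keypoints(gait_waveform(v, "knee"), ev)
  expect_equal(kp$timing[kp$keypoint_id == "KNS2"], 13)
  expect_equal(kp$angle[kp$keypoint_id == "KNS2"], 17.2)
  # extremum angle equals the exact window extremum
  wf <- model_waveform("ankle")
  kp <- extract_keypoints(wf, ev)
  w <- resolve_window(builtin_schema("ankle")$defs[[4]], ev) # ANS4 max
  expect_identical(kp$angle[kp$keypoint_id == "ANS4"],
                   max(as.numeric(wf)[w[1]:w[2]]))
})

test_that("cycle-end state copies the cycle-start state", {
  ev <- typical_events()
  wf <- model_waveform("hip")
  kp <- extract_keypoints(wf, ev)
  n <- nrow(kp)
  expect_equal(kp$timing[c(1, n)], c(1, 101))
  expect_identical(kp$angle[n], kp$angle[1])
  expect_identical(kp$velocity[n], kp$velocity[1])
  expect_identical(kp$acceleration[n], kp$acceleration[1])
})

test_that("discretise then reconstruct is a fixed point of extraction", {
  ev <- typical_events()
  for (joint in c("hip", "knee", "ankle")) {
    wf <- model_waveform(joint)
    kp <- extract_keypoints(wf, ev)
    rec <- reconstruct_waveform(kp, joint)
    kp2 <- extract_keypoints(rec, ev)
    expect_equal(kp2$timing, kp$timing)
    expect_equal(kp2$angle, kp$angle, tolerance = 1e-9)
  }
})

test_that("key-point timings are non-decreasing in schema order", {
  ev <- typical_events()
  for (joint in c("hip", "knee", "ankle")) {
    for (vs in c(0.25, 0.45, 0.65)) {
      wf <- model_waveform(joint, predictor_vector(vs, 38, 1, 24))
      kp <- extract_keypoints(wf, ev)
      expect_true(all(diff(kp$timing) >= 0))
    }
  }
})

test_that("reconstruction error shrinks as key-points are added", {
  set.seed(401)
  ps <- replicate(6, predictor_vector(runif(1, 0.25, 0.65),
                                      runif(1, 20, 65),
                                      rbinom(1, 1, 0.5),
                                      runif(1, 18, 30)),
                  simplify = FALSE)
  wfs <- lapply(ps, function(p) model_waveform("knee", p))
  ev <- typical_events()
  variants <- list(all = uniform_schema("knee", 101),
                   coarse = uniform_schema("knee", 6),
                   fine = uniform_schema("knee", 11)) # supersets coarse
  res <- discretisation_study(wfs, ev, variants)
  expect_lt(res$mean_rmse[res$variant == "all"], 1e-9)
  expect_lte(res$mean_rmse[res$variant == "fine"],
             res$mean_rmse[res$variant == "coarse"])
  expect_error(discretisation_study(wfs, ev, list()), "variant")
})

test_that("schemas round-trip through JSON", {
  for (joint in c("hip", "knee", "ankle")) {
    s <- builtin_schema(joint)
    s2 <- schema_from_json(schema_to_json(s))
    expect_equal(s2, s)
  }
})
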