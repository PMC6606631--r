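pub <- load_published_table()

test_that("the bundled table matches its printed records", {
  r <- coef_record(pub, "HIS2", "timing")
  expect_equal(r$beta0, 37.0166)
  expect_equal(r$beta_speed, -10.9165)
  expect_equal(r$beta_sex, -0.2067)
  expect_true(is.na(r$beta_age) && is.na(r$beta_bmi))
  a <- coef_record(pub, "ANS2", "timing")
  expect_equal(a$beta0, 7.2097)
  expect_equal(a$n_predictors, 0L)
  expect_true(all(is.na(unlist(a[c("beta_speed", "beta_age", "beta_sex",
                                   "beta_bmi")]))))
  # cycle start/end share one equation
  k1 <- coef_record(pub, "KNS1", "angle")
  k8 <- coef_record(pub, "KNS8", "angle")
  expect_equal(k8[-match("keypoint_id", names(k8))],
               k1[-match("keypoint_id", names(k1))], ignore_attr = TRUE)
  expect_identical(attr(pub, "source"), "published")
  expect_equal(nrow(pub), 42) # timing + angle for 21 key-points
})

test_that("key-point prediction is the retained-coefficient dot product", {
  p <- predictor_vector(0.40, 40, 0, 24)
  kp <- predict_keypoints(pub, p)
  # HIS2 timing: 37.0166 - 10.9165 * 0.40 (sex term * 0 drops out)
  expect_equal(kp$timing[kp$keypoint_id == "HIS2"], 32.650, tolerance = 1e-3)
  expect_equal(kp$timing[kp$keypoint_id == "ANS2"], 7.2097)
  p2 <- predictor_vector(0.45, 38, 1, 24)
  kp2 <- predict_keypoints(pub, p2)
  expect_equal(kp2$angle[kp2$keypoint_id == "HIS1"], 23.354, tolerance = 1e-3)
  expect_false(attr(kp2, "speed_extrapolated"))
  expect_true(attr(predict_keypoints(pub, predictor_vector(0.1, 38, 1, 24)),
                   "speed_extrapolated"))
})

test_that("waveform prediction is deterministic and speed-monotone at KNS6", {
  p <- predictor_vector(0.45, 38, 1, 24)
  expect_identical(predict_waveforms(pub, p), predict_waveforms(pub, p))
  peaks <- vapply(seq(0.25, 0.65, length.out = 9), function(vs) {
    kp <- predict_keypoints(pub, predictor_vector(vs, 38, 1, 24))
    kp$angle[kp$keypoint_id == "KNS6"]
  }, numeric(1))
  expect_true(all(diff(peaks) > 0)) # positive printed speed coefficient
})

test_that("sweeps honour the 15-condition design and leave NS terms fixed", {
  sw_sex <- sweep_predictor(pub, "sex")
  expect_length(sw_sex$predictions, 2)
  sw_age <- sweep_predictor(pub, "age", range = c(19, 67))
  expect_length(sw_age$predictions, 15)
  expect_equal(sw_age$values[c(1, 15)], c(19, 67))
  # BMI endpoints differ at HIS1 angle by coefficient * range width
  sw_bmi <- sweep_predictor(pub, "bmi", range = c(17, 31))
  his1 <- vapply(sw_bmi$predictions, function(k) {
    k$angle[k$keypoint_id == "HIS1"]
  }, numeric(1))
  expect_equal(his1[15] - his1[1], 0.4698 * 14, tolerance = 1e-9)
  # sweeping a predictor that an equation does not retain leaves it unchanged
  ans1 <- vapply(sw_age$predictions, function(k) {
    k$angle[k$keypoint_id == "ANS1"]
  }, numeric(1))
  expect_identical(ans1, rep(ans1[1], 15)) # age is NS for ANS1 angle
  expect_error(sweep_predictor(pub, "age", range = c(30, 30)), "degenerate")
  expect_error(sweep_predictor(pub, "speed"), "range")
})

test_that("contribution ranges reproduce the printed maxima", {
  sex <- contribution_range(pub, "sex", c("HIS3", "HIS4", "HIS5"))
  expect_equal(round(sex$max, 1), 6.4)
  expect_equal(sex$max, 6.4275)
  bmi <- contribution_range(pub, "bmi", c("HIS1", "HIS3", "HIS6"),
                            range = c(17, 31))
  expect_equal(round(bmi$max, 1), 6.6)
  expect_equal(bmi$max, 0.4698 * 14)
  # NS coefficient contributes exactly zero
  expect_identical(contribution_range(pub, "age", "ANS1")$deltas[["ANS1"]], 0)
  # age and BMI default to the study ranges; speed has no printed range
  expect_equal(contribution_range(pub, "bmi", "HIS1")$max, bmi$max)
  expect_error(contribution_range(pub, "speed", "HIS1"), "range")
  expect_error(contribution_range(pub, "sex", "XYZ9"), "no record")
})

test_that("contributions equal the linear-sweep extremes exactly", {
  rep_bmi <- contribution_report(pub, "bmi", range = c(17, 31))
  cr <- contribution_range(pub, "bmi",
                           rep_bmi$keypoint_id[rep_bmi$joint == "hip"],
                           range = c(17, 31), parameter = "angle")
  expect_equal(rep_bmi$delta_angle[rep_bmi$joint == "hip"],
               unname(cr$deltas), tolerance = 1e-9)
})

test_that("clinical classification follows the 3% and 2/5 degree bands", {
  expect_equal(classify_clinical(1, 1.5), list(timing = "not_significant",
                                               angle = "none"))
  expect_equal(classify_clinical(4, 3.5), list(timing = "significant",
                                               angle = "consider"))
  expect_equal(classify_clinical(0, 6), list(timing = "not_significant",
                                             angle = "may_mislead"))
  expect_equal(classify_clinical(3, 2)$timing, "not_significant") # > 3 only
  expect_equal(classify_clinical(3.01, 5)$angle, "consider")
  expect_error(classify_clinical(-1, 0), "non-negative")
})

test_that("timing repair restores schema order with unit separation", {
  t <- c(1, 40, 38, 70, 101)
  expect_warning(out <- repair_timings(t), "repaired")
  expect_true(all(diff(out) >= 1))
  expect_equal(out[c(1, 5)], c(1, 101))
  expect_silent(repair_timings(c(1, 30, 60, 101)))
})
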