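test_that("spline gap filling is exact on polynomials and leaves clean input alone", {
  rate <- 60
  n <- 120
  t <- (seq_len(n) - 1) / rate
  # quadratic channel with 3 interior samples removed
  drop <- c(40, 41, 80)
  acc <- cbind(t^2, 2 * t^2 - t, t)
  rec <- sensor_recording("trunk_a", t[-drop], acc[-drop, ],
                          gyro = acc[-drop, ], mag = acc[-drop, ], rate = rate)
  filled <- fill_gaps(rec)
  expect_equal(length(filled$t), n)
  expect_lt(max(abs(filled$acc[drop, 1] - t[drop]^2)), 1e-9)
  expect_lt(max(abs(filled$acc[drop, 2] - (2 * t[drop]^2 - t[drop]))), 1e-9)
  # observed samples bit-identical
  expect_identical(filled$acc[-drop, ], rec$acc)

  # one missing sample on a straight line -> linear prediction
  rec_lin <- sensor_recording("trunk_a", t[-50], cbind(3 * t, t, 1 - t)[-50, ],
                              gyro = acc[-50, ], mag = acc[-50, ], rate = rate)
  fl <- fill_gaps(rec_lin)
  expect_equal(unname(fl$acc[50, 1]), 3 * t[50], tolerance = 1e-12)

  clean <- make_recording(duration = 2)
  expect_equal(fill_gaps(clean)$acc, clean$acc)
})

test_that("gaps longer than the limit are masked, not trusted", {
  rate <- 60
  t <- (0:599) / rate
  gap <- t > 3 & t < 4.5  # 1.5 s gap
  x <- cbind(sin(t), cos(t), t)
  rec <- sensor_recording("trunk_a", t[!gap], x[!gap, ], x[!gap, ], x[!gap, ], rate)
  filled <- fill_gaps(rec, max_gap_s = 1)
  expect_true(all(filled$mask[gap]))
  expect_false(any(filled$mask[!gap]))
})

test_that("resampling is identity at 60 Hz and accurate polyphase at 40 Hz", {
  rec <- make_recording(duration = 5, rate = 60)
  expect_identical(resample_to_target(rec), rec)

  # constant channels -> constant, edges included
  n40 <- 400
  t40 <- (seq_len(n40) - 1) / 40
  const <- matrix(7, n40, 3)
  rec40 <- sensor_recording("trunk_a", t40, const, const, const, 40)
  out <- resample_to_target(rec40)
  expect_equal(out$rate, 60)
  expect_lt(max(abs(out$acc - 7)), 1e-6)

  # 2 Hz sinusoid, 10 s: amplitude within 1% away from edges
  t40 <- (0:399) / 40
  s <- sin(2 * pi * 2 * t40)
  rec40 <- sensor_recording("trunk_a", t40, cbind(s, s, s), cbind(s, s, s),
                            cbind(s, s, s), 40)
  out <- resample_to_target(rec40)
  ref <- sin(2 * pi * 2 * out$t)
  mid <- out$t > 1 & out$t < 9
  expect_lt(max(abs(out$acc[mid, 1] - ref[mid])), 0.01)
})

test_that("low-variance artefact masking flags stillness and spares real noise", {
  rate <- 60
  n <- 600
  t <- (seq_len(n) - 1) / rate
  set.seed(3)
  acc <- matrix(rnorm(3 * n, sd = 0.1), n, 3)
  acc[, 3] <- acc[, 3] + 9.81
  still <- t >= 4  # displaced sensor lying still
  acc[still, ] <- matrix(c(1, 2, 3), sum(still), 3, byrow = TRUE)
  rec <- sensor_recording("trunk_a", t, acc, acc, acc, rate)
  out <- mask_artifacts(rec)
  expect_true(all(out$mask[still]))
  expect_false(any(out$mask[!still]))

  # monotone in threshold, with all/nothing at the extremes
  cfg_inf <- preprocess_config(artifact_var_threshold = Inf)
  cfg_zero <- preprocess_config(artifact_var_threshold = 0)
  expect_true(all(mask_artifacts(rec, cfg_inf)$mask[seq_len(600 %/% 6 * 6)]))
  expect_false(any(mask_artifacts(rec, cfg_zero)$mask))

  # invariant to adding a constant to all channels
  rec_shift <- rec
  rec_shift$acc <- rec$acc + 5
  expect_equal(mask_artifacts(rec_shift)$mask, out$mask)
})

test_that("accelerometer decomposition separates gravity from movement", {
  rate <- 60
  n <- 1200
  t <- (seq_len(n) - 1) / rate
  const <- cbind(rep(0, n), rep(0, n), rep(9.81, n))
  rec <- sensor_recording("trunk_a", t, const, const * 0, const * 0, rate)
  d <- derive_signals(rec)
  expect_lt(max(abs(d$channels[, "acc_lp_z"] - 9.81)), 1e-6)
  expect_lt(max(abs(d$channels[, c("acc_hp_x", "acc_hp_y", "acc_hp_z")])), 1e-6)
  expect_equal(unname(d$channels[1, "norm"]), 9.81)

  # complementary split: lp + hp == raw exactly when the cutoffs coincide
  rec2 <- make_recording(duration = 10, seed = 7, noise = 0.5)
  d2 <- derive_signals(rec2)
  recon <- d2$channels[, c("acc_lp_x", "acc_lp_y", "acc_lp_z")] +
    d2$channels[, c("acc_hp_x", "acc_hp_y", "acc_hp_z")]
  expect_lt(max(abs(recon - rec2$acc)), 1e-9)

  # 10 Hz sinusoid with 1 Hz cutoff: LP residual under 5%
  s10 <- sin(2 * pi * 10 * t)
  rec3 <- sensor_recording("trunk_a", t, cbind(s10, s10, s10), const * 0,
                           const * 0, rate)
  d3 <- derive_signals(rec3)
  mid <- t > 2 & t < 18
  expect_lt(max(abs(d3$channels[mid, "acc_lp_x"])), 0.05)

  # 3-4-5 triple
  tri <- matrix(c(3, 4, 0), 10, 3, byrow = TRUE)
  rec4 <- sensor_recording("trunk_a", (0:9) / 60, tri, tri, tri, 60)
  expect_equal(unname(acc_magnitude(tri)[1]), 5)
  expect_equal(unname(derive_signals(rec4)$channels[5, "norm"]), 5)
})

test_that("roll and pitch follow the aerospace tilt convention", {
  g <- 9.81
  rp <- roll_pitch(matrix(c(0, 0, g), 1))
  expect_equal(rp$roll, 0)
  expect_equal(rp$pitch, 0)

  rp2 <- roll_pitch(matrix(c(-g, 0, 0), 1))
  expect_equal(rp2$pitch, pi / 2)
  expect_equal(rp2$roll, 0)

  rp3 <- roll_pitch(matrix(c(0, g, 0), 1))
  expect_equal(rp3$roll, pi / 2)
  expect_equal(rp3$pitch, 0)

  # invariant to positive scaling
  set.seed(1)
  A <- matrix(rnorm(30), 10, 3)
  expect_equal(roll_pitch(A), roll_pitch(3.7 * A))

  # zero-norm samples propagate as missing
  z <- roll_pitch(matrix(0, 2, 3))
  expect_true(all(is.na(z$roll)))
})

test_that("preprocessing is idempotent on clean 60 Hz input", {
  rec <- make_recording(duration = 5, seed = 2, noise = 0.2)
  once <- preprocess_recording(rec)
  twice <- preprocess_recording(once)
  expect_lt(max(abs(once$acc - twice$acc)), 1e-9)
  expect_identical(once$mask, twice$mask)
})

test_that("clap-based sync recovers constructed delays", {
  rate <- 60
  t <- (0:(30 * rate - 1)) / rate
  mk <- function(peak_times) {
    x <- 9.81 + 0.05 * sin(2 * pi * 1.3 * t)
    for (tc in peak_times) x <- x + 30 * exp(-((t - tc) / 0.02)^2)
    x
  }
  audio <- c(10, 11, 12, 13, 14)
  cg <- data.frame(t = t, left = mk(audio + 0.5), right = mk(audio + 0.5))
  expect_equal(estimate_sync_delay(cg, audio), 0.5, tolerance = 1 / 60)

  cg0 <- data.frame(t = t, left = mk(audio), right = mk(audio))
  expect_equal(estimate_sync_delay(cg0, audio), 0, tolerance = 1e-9)

  # one spurious extra peak: ordered best-effort matching still recovers it
  cg6 <- data.frame(t = t, left = mk(c(audio + 0.5, 3)), right = mk(c(audio + 0.5, 3)))
  expect_warning(d6 <- estimate_sync_delay(cg6, audio), "best-effort")
  expect_equal(d6, 0.5, tolerance = 1 / 60)

  expect_error(estimate_sync_delay(
    data.frame(t = t, left = rep(9.81, length(t)), right = rep(9.81, length(t))),
    audio), "sync error")
})
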