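test_that("identical seeds reproduce byte-identical session files", {
  td <- withr::local_tempdir()
  cfg <- simulation_config(duration_s = 30)
  mp1 <- simulate_session(cfg, "i01", 1, file.path(td, "a"), seed = 9)
  mp2 <- simulate_session(cfg, "i01", 1, file.path(td, "b"), seed = 9)
  for (f in list.files(dirname(mp1))) {
    expect_identical(readBin(file.path(dirname(mp1), f), "raw", 1e7),
                     readBin(file.path(dirname(mp2), f), "raw", 1e7),
                     label = f)
  }
  mp3 <- simulate_session(cfg, "i01", 1, file.path(td, "c"), seed = 10)
  expect_false(identical(readBin(file.path(dirname(mp1), "trunk_a.csv"), "raw", 1e7),
                         readBin(file.path(dirname(mp3), "trunk_a.csv"), "raw", 1e7)))
})

test_that("the noiseless single-position limit reduces to pure gravity", {
  td <- withr::local_tempdir()
  cfg <- simulation_config(duration_s = 30, noise_sd = rep(0, 5) |>
                             stats::setNames(position_classes()),
                           jitter_sd = 0, gyro_noise_sd = 0, mag_noise_sd = 0,
                           dropout_per_min = 0, artifact_prob = 0,
                           rate_switch_prob = 0, sync_delay_range = c(0, 0),
                           dwell_meanlog = rep(log(1e6), 5) |>
                             stats::setNames(position_classes()))
  mp <- simulate_session(cfg, "i01", 1, td, seed = 6)
  truth <- attr(mp, "truth")
  expect_equal(nrow(truth$intervals), 1)  # one dwell covers the session
  cl <- truth$intervals$class[1]
  sess <- read_session(mp)
  # artefact masking disabled: a noiseless constant is exactly the
  # displaced-sensor signature the filter targets
  prep <- preprocess_config(artifact_var_threshold = 0)
  sess <- preprocess_session(sess, prep)
  rec <- sess$recordings$trunk_a
  expected <- 9.81 * cfg$orientations[[cl]]$trunk_a
  expect_lt(max(abs(sweep(rec$acc, 2, expected))), 1e-9)
  d <- derive_signals(rec, prep)
  expect_lt(max(abs(sweep(d$channels[, c("acc_lp_x", "acc_lp_y", "acc_lp_z")],
                          2, expected))), 1e-6)
  w <- segment_session(sess, sensor_set = "trunk_a")
  expect_true(all(w$label == cl))
})

test_that("simulated class time shares track the dwell-time expectation", {
  td <- withr::local_tempdir()
  mp <- make_benchmark_suite("separable", td, seed = 31, n_infants = 8,
                             sessions_per_infant = 1, duration_s = 120)
  truths <- attr(mp, "truth")
  tot <- stats::setNames(numeric(5), position_classes())
  for (tr in truths) {
    d <- tapply(tr$intervals$end - tr$intervals$start, tr$intervals$class, sum)
    tot[names(d)] <- tot[names(d)] + d
  }
  share <- tot / sum(tot)
  # uniform Markov chain: expected share proportional to the mean dwell
  mean_dwell <- exp(simulation_config()$dwell_meanlog +
                      simulation_config()$dwell_sdlog^2 / 2)
  expected <- mean_dwell / sum(mean_dwell)
  # crude 3-sigma band from the dwell-count variability
  expect_lt(max(abs(share - expected)), 0.12)
  expect_lt(share["Hands and Knees"], min(share[setdiff(names(share),
                                                        "Hands and Knees")]))
})

test_that("true sync delays are recovered within one sample", {
  td <- withr::local_tempdir()
  cfg <- simulation_config(duration_s = 30)
  errs <- c()
  for (s in 1:12) {
    mp <- simulate_session(cfg, sprintf("i%02d", s), 1, td, seed = 200 + s)
    truth <- attr(mp, "truth")
    sess <- read_session(mp)
    est <- estimate_sync_delay(sess$caregiver, sess$clap_times_audio)
    errs <- c(errs, abs(est - truth$sync_delay))
  }
  expect_true(all(errs <= 1 / 60 + 1e-9))
})

test_that("class orientations are recoverable from per-class mean LP acceleration", {
  td <- withr::local_tempdir()
  cfg <- simulation_config(duration_s = 60, dropout_per_min = 0,
                           artifact_prob = 0, rate_switch_prob = 0)
  mp <- simulate_session(cfg, "i01", 1, td, seed = 17)
  truth <- attr(mp, "truth")
  sess <- preprocess_session(read_session(mp))
  d <- derive_signals(sess$recordings$trunk_a)
  lp <- d$channels[, c("acc_lp_x", "acc_lp_y", "acc_lp_z")]
  for (cl in unique(truth$intervals$class)) {
    iv <- truth$intervals[truth$intervals$class == cl, , drop = FALSE]
    sel <- rep(FALSE, nrow(lp))
    for (i in seq_len(nrow(iv))) {
      sel <- sel | (d$t >= iv$start[i] + 1 & d$t < iv$end[i] - 1)
    }
    if (sum(sel) < 60) next
    u_hat <- colMeans(lp[sel, ]); u_hat <- u_hat / sqrt(sum(u_hat^2))
    u_true <- cfg$orientations[[cl]]$trunk_a
    expect_gt(sum(u_hat * u_true), 0.99)
  }
})

test_that("benchmark presets exist, regenerate identically and order difficulty", {
  td <- withr::local_tempdir()
  expect_error(make_benchmark_suite("impossible", td), "arg")
  m1 <- make_benchmark_suite("noisy", file.path(td, "n1"), seed = 5,
                             n_infants = 2, sessions_per_infant = 1,
                             duration_s = 20)
  m2 <- make_benchmark_suite("noisy", file.path(td, "n2"), seed = 5,
                             n_infants = 2, sessions_per_infant = 1,
                             duration_s = 20)
  expect_identical(readLines(m1[1]), readLines(m2[1]))
  expect_identical(readBin(file.path(dirname(m1[1]), "trunk_a.csv"), "raw", 1e7),
                   readBin(file.path(dirname(m2[1]), "trunk_a.csv"), "raw", 1e7))

  # the noisy preset is designed to be harder on Hands and Knees
  hk_f1 <- function(preset, seed) {
    dd <- file.path(td, paste0(preset, seed))
    mp <- make_benchmark_suite(preset, dd, seed = seed, n_infants = 6,
                               sessions_per_infant = 1, duration_s = 90)
    cfg <- run_config(seed = seed,
                      model_params = list(gradient_boosted_trees =
                                            list(iterations = 60)))
    res <- run_pipeline(mp, cfg, file.path(dd, "out"))
    res$cv[[1]]$summary$mean_f1[5]
  }
  sep <- mean(vapply(1:3, function(s) hk_f1("separable", s), numeric(1)))
  noi <- mean(vapply(1:3, function(s) hk_f1("noisy", s), numeric(1)))
  expect_lt(noi, sep)
})
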