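test_that("statistical features match hand computations and conventions", {
  v <- statistical_features(c(1, 2, 3, 4, 5))
  expect_equal(unname(v["mean"]), 3)
  expect_equal(unname(v["median"]), 3)
  expect_equal(unname(v["min"]), 1)
  expect_equal(unname(v["max"]), 5)
  expect_equal(unname(v["sd"]), sqrt(2.5))
  expect_equal(unname(v["q25"]), 2)
  expect_equal(unname(v["q75"]), 4)

  cv <- statistical_features(rep(4.2, 50))
  expect_equal(unname(cv[c("mean", "median", "min", "max")]), rep(4.2, 4))
  expect_equal(unname(cv[c("sd", "skew", "kurt")]), c(0, 0, 0))

  sym <- c(-3, -1, 0, 1, 3)
  expect_lt(abs(statistical_features(sym)["skew"]), 1e-12)

  # cross-check the moment formulas against an independent implementation
  set.seed(10)
  x <- rnorm(120)
  v2 <- statistical_features(x)
  expect_equal(unname(v2["skew"]), e1071::skewness(x, type = 2), tolerance = 1e-12)
  expect_equal(unname(v2["kurt"]), e1071::kurtosis(x, type = 1), tolerance = 1e-12)
})

test_that("frequency features resolve pure and mixed tones", {
  rate <- 60
  t <- (0:119) / rate
  s5 <- sin(2 * pi * 5 * t)
  v <- frequency_features(s5, rate)
  expect_equal(unname(v["fmax"]), 5)
  expect_equal(unname(v["centroid"]), 5, tolerance = 1e-9)
  expect_lt(unname(v["bandwidth"]), 1e-6)

  expect_equal(unname(frequency_features(rep(2, 120), rate)),
               c(0, 0, 0, 0, 0))

  mix <- sin(2 * pi * 5 * t) + sin(2 * pi * 15 * t)
  expect_equal(unname(frequency_features(mix, rate)["centroid"]), 10,
               tolerance = 1e-9)
})

test_that("summary and difference features reduce to their constant-case values", {
  g <- 9.81
  n <- 120
  chans <- function(u) {
    ch <- list()
    for (fam in c("acc", "acc_lp", "acc_hp", "gyro", "mag")) {
      for (i in 1:3) ch[[paste0(fam, "_", c("x", "y", "z")[i])]] <- rep(u[i], n)
    }
    for (s in c("norm", "norm_lp", "norm_hp", "roll", "pitch")) {
      ch[[s]] <- rep(sqrt(sum(u^2)), n)
    }
    ch
  }
  win <- list(leg_left = chans(c(0, 0, g)), leg_right = chans(c(0, 0, g)))
  cfg <- feature_config(sensor_set = c("leg_left", "leg_right"))

  sm <- summary_features(win, cfg)
  expect_equal(unname(sm["leg_left|acc_lp|axsum.mean"]), g)
  expect_equal(unname(sm["all|acc_lp|z.locsum.mean"]), 2 * g)

  df <- difference_features(win, cfg)
  expect_equal(unname(df["leg_left|acc_lp|mdiff.x.y"]), 0)
  expect_equal(unname(df["leg_left|acc_lp|mdiff.x.z"]), -g)
  expect_equal(unname(df["leg_left|acc_lp|mdiff.y.z"]), -g)
  expect_true(all(df[grepl("&", names(df))] == 0))  # identical locations

  # singleton sensor set: location sums equal the single sensor's series
  cfg1 <- feature_config(sensor_set = "leg_left")
  sm1 <- summary_features(win["leg_left"], cfg1)
  expect_equal(unname(sm1["all|acc_lp|z.locsum.mean"]), g)
})

test_that("correlation features match hand Pearson values", {
  n <- 120
  set.seed(8)
  a <- rnorm(n)
  mkwin <- function(x, y) {
    ch <- list()
    for (fam in c("acc", "acc_lp", "acc_hp", "gyro", "mag")) {
      ch[[paste0(fam, "_x")]] <- x
      ch[[paste0(fam, "_y")]] <- y
      ch[[paste0(fam, "_z")]] <- rnorm(length(x))
    }
    for (s in c("norm", "norm_lp", "norm_hp", "roll", "pitch")) {
      ch[[s]] <- rnorm(length(x))
    }
    list(trunk_a = ch)
  }
  cfg <- feature_config(sensor_set = "trunk_a")
  cr <- correlation_features(mkwin(a, a), cfg)
  expect_equal(unname(cr["trunk_a|acc|corr.x.y"]), 1)
  cr2 <- correlation_features(mkwin(a, -a), cfg)
  expect_equal(unname(cr2["trunk_a|acc|corr.x.y"]), -1)

  w3 <- mkwin(c(1, 2, 3), c(1, 3, 2))
  cr3 <- correlation_features(w3, feature_config(sensor_set = "trunk_a"))
  expect_equal(unname(cr3["trunk_a|acc|corr.x.y"]), 0.5)

  # zero variance -> 0 by convention
  cr4 <- correlation_features(mkwin(rep(1, n), a), cfg)
  expect_equal(unname(cr4["trunk_a|acc|corr.x.y"]), 0)
})

test_that("the feature matrix matches the enumerated layout and an independent oracle", {
  sess <- preprocess_session(make_session(duration = 20, seed = 21, noise = 0.4))
  cfg <- feature_config(sensor_set = c("trunk_a", "leg_left"))
  w <- segment_session(sess, sensor_set = cfg$sensor_set)
  tab <- build_feature_matrix(sess, w, cfg)
  desc <- enumerate_feature_descriptors(cfg)
  expect_identical(tab$descriptors, desc)
  expect_equal(nrow(tab$values), sum(w$label != "UNASSIGNED"))
  # hand count of the column inventory: 2 sensors, 10 signal families
  n_ch <- 2 * (5 * 3 + 5)
  expect_equal(sum(desc$group == "statistical"), n_ch * 9)
  expect_equal(sum(desc$group == "frequency"), n_ch * 5)
  expect_equal(sum(desc$group == "summary"), 2 * 5 + 20)
  expect_equal(sum(desc$group == "difference"), 2 * 15 + 20)
  expect_equal(sum(desc$group == "correlation"), 2 * 15 + 20)

  err <- oracle_check_table(sess, tab, cfg, rows = seq_len(min(8, nrow(tab$values))))
  expect_lt(err, 1e-9)
})

test_that("features are equivariant under unit scaling and time reversal", {
  sess <- preprocess_session(make_session(duration = 12, seed = 5, noise = 0.3))
  cfg <- feature_config(sensor_set = c("trunk_a", "leg_left"))
  w <- segment_session(sess, sensor_set = cfg$sensor_set)
  tab <- build_feature_matrix(sess, w, cfg)

  c_scale <- 3.7
  sc <- sess
  for (l in names(sc$recordings)) {
    sc$recordings[[l]]$acc <- sc$recordings[[l]]$acc * c_scale
    sc$recordings[[l]]$gyro <- sc$recordings[[l]]$gyro * c_scale
    sc$recordings[[l]]$mag <- sc$recordings[[l]]$mag * c_scale
  }
  tab_s <- build_feature_matrix(sc, w, cfg)
  d <- tab$descriptors
  lin <- !d$signal %in% c("roll", "pitch") &
    (d$group %in% c("summary", "difference") |
       (d$group == "statistical" & !grepl("skew|kurt", d$name)))
  expect_equal(tab_s$values[, lin], c_scale * tab$values[, lin],
               tolerance = 1e-9)
  corr <- d$group == "correlation"
  expect_equal(tab_s$values[, corr], tab$values[, corr], tolerance = 1e-9)

  # time reversal of a window leaves distribution- and power-based features
  # unchanged
  set.seed(77)
  X <- matrix(rnorm(120 * 6), 120)
  Xr <- X[120:1, , drop = FALSE]
  expect_equal(statistical_features(X), statistical_features(Xr))
  expect_equal(frequency_features(X), frequency_features(Xr), tolerance = 1e-9)
  expect_equal(colMeans(X), colMeans(Xr))  # summary/difference building block
  r_fwd <- imuposture:::pair_correlation(X[, 1, drop = FALSE], X[, 2, drop = FALSE])
  r_rev <- imuposture:::pair_correlation(Xr[, 1, drop = FALSE], Xr[, 2, drop = FALSE])
  expect_equal(r_fwd, r_rev)
})

test_that("an empty window set yields an empty table with full column metadata", {
  sess <- preprocess_session(make_session(duration = 10, seed = 2))
  w <- segment_session(sess)
  w$label[] <- "UNASSIGNED"
  cfg <- feature_config(sensor_set = c("trunk_a", "leg_left"))
  tab <- build_feature_matrix(sess, w, cfg)
  expect_equal(nrow(tab$values), 0)
  expect_identical(tab$descriptors, enumerate_feature_descriptors(cfg))
})

test_that("feature tables are invariant to sensor recording order", {
  sess <- preprocess_session(make_session(duration = 12, seed = 13))
  cfg <- feature_config(sensor_set = c("trunk_a", "leg_left"))
  w <- segment_session(sess, sensor_set = cfg$sensor_set)
  tab1 <- build_feature_matrix(sess, w, cfg)
  sess2 <- sess
  sess2$recordings <- rev(sess2$recordings)
  tab2 <- build_feature_matrix(sess2, w, cfg)
  expect_identical(tab1$values, tab2$values)
})
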