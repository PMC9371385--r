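make_wrec <- function(duration, rate = 50, value = 0) {
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  m <- matrix(value, n, 3,
              dimnames = list(NULL, c("acc_x", "acc_y", "acc_z")))
  g <- matrix(value, n, 3,
              dimnames = list(NULL, c("gyr_x", "gyr_y", "gyr_z")))
  structure(list(time = t, accel_world = m, gyro = g, sample_rate = rate),
            class = "world_frame_recording")
}

test_that("window counts follow the closed-form formula across the grid", {
  w <- segment_windows(make_wrec(60), window_config(6, 1.0))
  expect_length(w, 10L)
  expect_equal(vapply(w, `[[`, numeric(1), "start"), seq(0, 54, by = 6))

  w <- segment_windows(make_wrec(60), window_config(6, 0.5))
  expect_length(w, 19L)

  expect_warning(out <- segment_windows(make_wrec(5), window_config(6, 1)),
                 "shorter")
  expect_length(out, 0L)

  # property: count formula for every grid combination
  for (ws in 3:10) for (sr in c(1, 0.8, 0.5, 0.2)) {
    wrec <- make_wrec(47)
    dur <- length(wrec$time) / 50  # n samples at 50 Hz cover n/50 s
    w <- segment_windows(wrec, window_config(ws, sr))
    expect_length(w, floor((dur - ws) / (sr * ws) + 1e-9) + 1)
    lens <- vapply(w, function(x) nrow(x$channels), numeric(1))
    expect_true(all(lens == ws * 50))
  }
})

test_that("autocorrelation normalises to 1 at lag 0 and finds periods", {
  rate <- 50
  t <- (0:399) / rate  # 8 s
  x <- sin(2 * pi * 1 * t)  # 8 periods
  ac <- autocorrelate(x)
  expect_equal(ac[1], 1)
  expect_gt(ac[rate + 1], 0.7)  # secondary peak at the 1-s period lag
  expect_equal(which.max(ac[(rate - 10):(rate + 10)]), 11, tolerance = 2)

  set.seed(31)
  noise_ac <- autocorrelate(rnorm(2000))
  expect_lt(max(abs(noise_ac[-1])), 0.1)

  expect_equal(autocorrelate(rep(3, 10)), c(1, rep(0, 9)))
})

test_that("level crossings count sign changes with at-level samples inheriting", {
  expect_equal(crossings(rep(2, 50), 0), 0L)
  t <- (0:199) / 100
  expect_equal(crossings(cos(2 * pi * 1 * t), 0), 4L)  # 2 periods about mean
  expect_equal(crossings(seq(-1, 1, length.out = 50), 0), 1L)
  # touching the level without crossing does not count
  expect_equal(crossings(c(1, 0, 1, 0, 1), 0), 0L)
  expect_equal(crossings(c(-1, 0, 1, 0, -1), 0), 2L)
})

test_that("window features match closed forms on constant and sinusoid windows", {
  w <- list(start = 0, end = 2,
            channels = matrix(3, 100, 6,
                              dimnames = list(NULL, c("acc_x", "acc_y", "acc_z",
                                                      "gyr_x", "gyr_y", "gyr_z"))))
  f <- window_features(w)
  expect_equal(f[["acc_x__raw__mean"]], 3)
  expect_equal(f[["acc_x__raw__sd"]], 0)
  expect_equal(f[["acc_x__raw__rms"]], 3)
  expect_equal(f[["acc_x__raw__variance"]], 0)
  expect_equal(f[["acc_x__raw__mad"]], 0)
  expect_equal(f[["acc_x__raw__crossings_mean"]], 0)
  expect_equal(f[["gyr_z__raw__median"]], 3)

  # energy of a unit sine over whole periods is 1/2 (mean-square convention)
  t <- (0:199) / 50
  sine <- sin(2 * pi * 1 * t)
  w2 <- w
  w2$channels <- matrix(sine, 200, 6,
                        dimnames = dimnames(w$channels))
  f2 <- window_features(w2)
  expect_equal(f2[["acc_x__raw__energy"]], 0.5, tolerance = 1e-12)

  # SMA with constant |ax| = 1, |ay| = 2, |az| = 3
  w3 <- w
  w3$channels <- cbind(matrix(rep(c(1, -2, 3), each = 100), 100, 3),
                       matrix(0, 100, 3))
  colnames(w3$channels) <- colnames(w$channels)
  expect_equal(window_features(w3)[["sma"]], 6)
  expect_length(f, 169L)
})

test_that("feature statistics shift and reflect as their definitions demand", {
  set.seed(32)
  base <- matrix(rnorm(600), 100, 6,
                 dimnames = list(NULL, c("acc_x", "acc_y", "acc_z",
                                         "gyr_x", "gyr_y", "gyr_z")))
  w <- list(start = 0, end = 2, channels = base)
  f <- window_features(w)
  w_shift <- w
  w_shift$channels <- base + 5
  fs <- window_features(w_shift)
  for (feat in c("mean", "min", "max", "median"))
    expect_equal(fs[[paste0("acc_x__raw__", feat)]],
                 f[[paste0("acc_x__raw__", feat)]] + 5, tolerance = 1e-9)
  for (feat in c("sd", "variance", "mad", "crossings_mean", "crossings_p50"))
    expect_equal(fs[[paste0("acc_x__raw__", feat)]],
                 f[[paste0("acc_x__raw__", feat)]], tolerance = 1e-9)

  # autocorrelation is sign-flip invariant, so its even features are too
  w_neg <- w
  w_neg$channels <- -base
  fn <- window_features(w_neg)
  for (feat in c("energy", "sd"))
    expect_equal(fn[[paste0("acc_y__ac__", feat)]],
                 f[[paste0("acc_y__ac__", feat)]], tolerance = 1e-12)
})

test_that("skiing windows carry more autocorrelation energy than idle ones", {
  ses <- generate_session(random_session_spec(n_runs = 2, seed = 17))
  world <- to_world(ses$recording, track_orientation(ses$recording))
  world <- two_stage_filter(world)
  wins <- segment_windows(world, window_config(8, 1))
  feats <- extract_features(wins)
  mid <- (attr(feats, "starts") + attr(feats, "ends")) / 2
  truth <- per_sample_classes(mid, ses$truth)
  ac_energy <- rowMeans(feats[, grep("^acc_[xyz]__ac__energy$",
                                     colnames(feats)), drop = FALSE])
  expect_gt(mean(ac_energy[truth == "Skiing"]),
            mean(ac_energy[truth == "Not_Skiing"]))
})

test_that("min-max normalisation maps to [-1, 1] hitting both bounds", {
  m <- make_fm(cbind(a = c(2, 4, 6), b = c(1, 1, 1), c = c(0, 10, 5)))
  nfs <- normalize_minmax(m)
  expect_equal(as.numeric(nfs[, "a"]), c(-1, 0, 1))
  expect_equal(as.numeric(nfs[, "b"]), c(0, 0, 0))
  expect_true(all(nfs >= -1 & nfs <= 1))
  for (j in c("a", "c")) {
    expect_equal(min(nfs[, j]), -1)
    expect_equal(max(nfs[, j]), 1)
  }
  expect_error(normalize_minmax(make_fm(matrix(1, 1, 3))), "2 windows")
  expect_identical(attr(nfs, "feature_set"), "NFS")
})

test_that("PCA keeps exactly the components needed for the variance target", {
  set.seed(33)
  # variance confined to two orthogonal directions in 5-D
  scores <- cbind(rnorm(200, sd = 3), rnorm(200, sd = 1))
  basis <- qr.Q(qr(matrix(rnorm(25), 5)))[, 1:2]
  m <- make_fm(scores %*% t(basis))
  red <- pca_reduce(m, 0.95)
  expect_equal(ncol(red), 2L)
  expect_identical(attr(red, "feature_set"), "PCA")

  # full variance: orthogonal rotation preserves total variance (lossless)
  full <- pca_reduce(m, 1)
  expect_equal(sum(apply(full, 2, var)), sum(apply(m, 2, var)),
               tolerance = 1e-9)
  # component variances are non-increasing
  v <- apply(full, 2, var)
  expect_true(all(diff(v) <= 1e-9))
  expect_error(pca_reduce(m, 0), "variance_kept")
  expect_error(pca_reduce(m, 1.2), "variance_kept")
})
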