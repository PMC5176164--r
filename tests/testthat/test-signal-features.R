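make_trace <- function(x, y, z, rate = 25) {
  df <- data.frame(time_s = (seq_along(x) - 1) / rate, x = x, y = y, z = z,
                   place = "surface", stringsAsFactors = FALSE)
  attr(df, "sampling_rate") <- rate
  attr(df, "subject_id") <- "T01"
  df
}

test_that("constant trace decomposes to zero dynamic motion", {
  tr <- make_trace(rep(0, 100), rep(0, 100), rep(1, 100))
  dec <- decompose_acceleration(tr)
  expect_equal(dec$static, dec$raw)
  expect_equal(max(abs(dec$dynamic)), 0)
  expect_equal(max(dec$odba), 0)
  expect_equal(max(dec$vedba), 0)
  expect_equal(unname(dec$q), rep(1, 100))
  expect_equal(unname(dec$inclination), rep(0, 100))
})

test_that("ODBA and VeDBA follow their defining arithmetic", {
  # dynamic components (0.1, 0.2, 0.2) -> ODBA 0.5, VeDBA 0.3
  dyn <- c(0.1, 0.2, 0.2)
  expect_equal(sum(abs(dyn)), 0.5)
  n <- 200
  tr <- make_trace(rnorm(n, 0, 0.3), rnorm(n, 0, 0.3), 1 + rnorm(n, 0, 0.3))
  dec <- decompose_acceleration(tr)
  expect_equal(dec$odba, rowSums(abs(dec$dynamic)))
  expect_equal(dec$vedba, sqrt(rowSums(dec$dynamic^2)))
  # reconstruction is exact and the norm inequality holds everywhere
  expect_equal(dec$static + dec$dynamic, dec$raw)
  expect_true(all(dec$vedba <= dec$odba + 1e-12))
  expect_true(all(dec$odba <= sqrt(3) * dec$vedba + 1e-12))
})

test_that("mean ODBA of a pure sine recovers 2A/pi", {
  # zero-mean window: integrate |A sin| over whole periods -> mean 2A/pi
  rate <- 25; A <- 0.8; f <- 1 # Hz; static window 75 samples = 3 whole periods
  n <- 4000
  t <- (seq_len(n) - 1) / rate
  tr <- make_trace(A * sin(2 * pi * f * t), rep(0, n), rep(1, n))
  dec <- decompose_acceleration(tr)
  core <- 100:(n - 100)  # drop edge-truncated windows
  expect_equal(mean(dec$odba[core]), 2 * A / pi, tolerance = 0.01)
})

test_that("static running mean uses a centered symmetrically truncated window", {
  x <- rnorm(300)
  tr <- make_trace(x, x, x)
  dec <- decompose_acceleration(tr, static_window_s = 3)
  expect_equal(dec$static[, 1], oracle_running_mean(x, 75))
  # interior sample: plain 75-sample centered mean
  expect_equal(unname(dec$static[150, 1]), mean(x[(150 - 37):(150 + 37)]))
  # first sample: window shrinks to the sample itself
  expect_equal(unname(dec$static[1, 1]), x[1])
})

test_that("non-uniform sampling is rejected", {
  tr <- make_trace(rnorm(50), rnorm(50), rnorm(50))
  tr$time_s[30] <- tr$time_s[30] + 0.02
  expect_error(decompose_acceleration(tr), "non-uniform")
})

test_that("epoch count follows floor((n - len)/stride) + 1", {
  tr <- make_trace(rnorm(130), rnorm(130), rnorm(130))
  dec <- decompose_acceleration(tr)
  expect_equal(nrow(epoch_features(dec, tr)), 10)
  expect_equal(nrow(epoch_features(dec, tr, epoch_len = 13, stride = 1)), 118)
  expect_warning(ft <- epoch_features(dec, tr, epoch_len = 200), "empty")
  expect_equal(nrow(ft), 0)
})

test_that("a constant epoch is degenerate: spread, DBA and dependence stats all zero", {
  tr <- make_trace(rep(0, 13), rep(0, 13), rep(1, 13))
  dec <- decompose_acceleration(tr)
  ft <- epoch_features(dec, tr)
  expect_equal(nrow(ft), 1)
  zero_cols <- c("x_sd", "x_skew", "x_kurt", "x_ar1", "x_icv",
                 "corr_xy", "corr_yz", "corr_xz",
                 "odba_mean", "odba_sd", "odba_min", "odba_max",
                 "vedba_mean", "auc_odba", "auc_vedba")
  for (cl in zero_cols) expect_equal(ft[[cl]], 0, info = cl)
  expect_equal(attr(ft, "degenerate"), 1L)
  expect_equal(ft$z_mean, 1)
  expect_equal(ft$q_mean, 1)
})

test_that("every statistic matches the brute-force oracle within 1e-10", {
  for (seed in c(42, 7)) {
    tr <- make_random_trace(403, seed = seed)
    dec <- decompose_acceleration(tr)
    ft <- epoch_features(dec, tr)
    expect_equal(nrow(ft), 31)
    for (e in seq_len(nrow(ft))) {
      idx <- ((e - 1) * 13 + 1):((e - 1) * 13 + 13)
      raw <- cbind(tr$x[idx], tr$y[idx], tr$z[idx])
      static <- cbind(oracle_running_mean(tr$x, 75)[idx],
                      oracle_running_mean(tr$y, 75)[idx],
                      oracle_running_mean(tr$z, 75)[idx])
      want <- oracle_epoch_stats(raw, 25, static)
      got <- unlist(ft[e, feature_names()])
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("epoch features are scale-equivariant", {
  tr <- make_random_trace(260, seed = 5)
  c_mult <- 3.7
  tr2 <- tr
  tr2$x <- tr$x * c_mult; tr2$y <- tr$y * c_mult; tr2$z <- tr$z * c_mult
  attr(tr2, "sampling_rate") <- 25; attr(tr2, "subject_id") <- "T01"
  f1 <- epoch_features(decompose_acceleration(tr), tr)
  f2 <- epoch_features(decompose_acceleration(tr2), tr2)
  scaled <- c(paste0(rep(c("x", "y", "z"), each = 6), "_",
                     c("mean", "median", "sd", "min", "max", "absmean")),
              paste0("q_", c("mean", "sd", "min", "max")),
              paste0("pdba_", c("x", "y", "z"), "_mean"),
              paste0("odba_", c("mean", "sd", "min", "max")),
              paste0("vedba_", c("mean", "sd", "min", "max")),
              "auc_odba", "auc_vedba")
  invariant <- c(paste0(rep(c("x", "y", "z"), each = 4), "_",
                        c("skew", "kurt", "ar1", "icv")),
                 "corr_xy", "corr_yz", "corr_xz", "incl_mean", "azim_mean")
  for (cl in scaled) expect_equal(f2[[cl]], c_mult * f1[[cl]], tolerance = 1e-9, info = cl)
  for (cl in invariant) expect_equal(f2[[cl]], f1[[cl]], tolerance = 1e-9, info = cl)
})

test_that("inclination and azimuth are computed from the static vector", {
  tr <- make_trace(rep(0, 80), rep(0, 80), rep(1, 80))
  dec <- decompose_acceleration(tr)
  expect_equal(unname(inclination_azimuth(dec)$inclination), rep(0, 80))
  tr <- make_trace(rep(1, 80), rep(0, 80), rep(0, 80))
  dec <- decompose_acceleration(tr)
  ia <- inclination_azimuth(dec)
  expect_equal(unname(ia$inclination), rep(pi / 2, 80))
  expect_equal(unname(ia$azimuth), rep(0, 80))
  # static (1, 1, sqrt(2))/2: |static| = 1, z-component sqrt(2)/2 -> pi/4
  v <- c(1, 1, sqrt(2)) / 2
  tr <- make_trace(rep(v[1], 80), rep(v[2], 80), rep(v[3], 80))
  dec <- decompose_acceleration(tr)
  expect_equal(unname(dec$inclination), rep(pi / 4, 80))
})

test_that("featurizing concatenated traces equals concatenating feature rows", {
  # with stride = epoch_len there is no cross-boundary leakage, provided the
  # static estimate is supplied per segment
  tr1 <- make_random_trace(130, seed = 1)
  tr2 <- make_random_trace(130, seed = 2)
  both <- rbind(tr1, tr2)
  both$time_s <- (seq_len(nrow(both)) - 1) / 25
  attr(both, "sampling_rate") <- 25; attr(both, "subject_id") <- "T01"
  # decompose per segment (the static window would otherwise straddle the seam)
  f1 <- epoch_features(decompose_acceleration(tr1), tr1)
  f2 <- epoch_features(decompose_acceleration(tr2), tr2)
  dec1 <- decompose_acceleration(tr1); dec2 <- decompose_acceleration(tr2)
  dec_cat <- dec1
  for (nm in c("raw", "static", "dynamic", "pdba")) {
    dec_cat[[nm]] <- rbind(dec1[[nm]], dec2[[nm]])
  }
  for (nm in c("odba", "vedba", "q", "inclination", "azimuth")) {
    dec_cat[[nm]] <- c(dec1[[nm]], dec2[[nm]])
  }
  f_cat <- epoch_features(dec_cat, both)
  expect_equal(nrow(f_cat), nrow(f1) + nrow(f2))
  got <- f_cat[, feature_names()]
  want <- rbind(f1[, feature_names()], f2[, feature_names()])
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("feature tables round-trip through CSV", {
  tr <- make_random_trace(130, seed = 3)
  ft <- epoch_features(decompose_acceleration(tr), tr)
  path <- tempfile(fileext = ".csv")
  write_features(ft, path)
  back <- read_features(path)
  expect_equal(back[, feature_names()], ft[, feature_names()], tolerance = 1e-12)
  expect_equal(attr(back, "epoch_len"), 13L)
})
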