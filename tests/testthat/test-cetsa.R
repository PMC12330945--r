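test_that("band normalization divides by the lowest-temperature band", {
  d <- data.frame(temperature_c = c(40, 50, 60, 70),
                  band_intensity = c(100, 80, 50, 20))
  out <- normalize_bands(d)
  expect_equal(out$rel_intensity, c(1.0, 0.8, 0.5, 0.2))
  # already-normalized series pass through unchanged
  d2 <- data.frame(temperature_c = d$temperature_c,
                   band_intensity = out$rel_intensity)
  expect_equal(normalize_bands(d2)$rel_intensity, out$rel_intensity)
  d$band_intensity[1] <- 0
  expect_error(normalize_bands(d), "reference")
})

test_that("interpolated Tm50 is the linear midpoint of the 0.5 bracket", {
  s <- data.frame(temperature_c = c(45, 50, 55, 60),
                  rel_intensity = c(1.0, 0.6, 0.4, 0.1))
  r <- apparent_tm50(s, method = "interpolate")
  expect_equal(r$tm50, 52.5)
  expect_identical(r$method, "interpolate")
})

test_that("fit and interpolation agree on dense noise-free curves", {
  tt <- seq(40, 70, by = 1)
  s <- data.frame(temperature_c = tt,
                  rel_intensity = rel_model(tt, -0.6, 53, 0))
  r_fit <- apparent_tm50(s, method = "fit")
  r_int <- apparent_tm50(s, method = "interpolate")
  expect_equal(r_fit$tm50, 53, tolerance = 0.05)
  expect_equal(r_int$tm50, 53, tolerance = 0.05)
  expect_lt(abs(r_fit$tm50 - r_int$tm50), 1.0)
})

test_that("series never reaching 0.5 report no crossing", {
  s <- data.frame(temperature_c = c(45, 50, 55, 60),
                  rel_intensity = c(1.0, 0.8, 0.65, 0.55))
  r <- apparent_tm50(s, method = "interpolate")
  expect_true(is.na(r$tm50))
  expect_identical(r$reason, "no_crossing")
  expect_error(
    cetsa_delta_tm(
      simulate_cetsa(50, 0, noise_cv = 0)[1:16, ],
      data.frame(target_name = "x", condition = "treated", replicate = 1,
                 temperature_c = c(45, 50, 55, 60),
                 band_intensity = c(1.0, 0.8, 0.65, 0.55))),
    "no_crossing")
})

test_that("interpolated Tm50 ignores the raw intensity scale", {
  tt <- seq(44, 64, by = 4)
  base <- data.frame(temperature_c = tt,
                     band_intensity = rel_model(tt, -0.5, 54, 0.05) * 100)
  scaled <- transform(base, band_intensity = band_intensity * 37.3)
  t1 <- apparent_tm50(normalize_bands(base), method = "interpolate")$tm50
  t2 <- apparent_tm50(normalize_bands(scaled), method = "interpolate")$tm50
  expect_equal(t1, t2)
})

test_that("monotone noise-free series yield exactly one crossing or none", {
  set.seed(9)
  for (i in 1:25) {
    a <- runif(1, -1.5, -0.2)
    b <- runif(1, 45, 62)
    p <- runif(1, 0, 0.45)
    tt <- seq(40, 66, by = 2)
    s <- data.frame(temperature_c = tt, rel_intensity = rel_model(tt, a, b, p))
    r <- apparent_tm50(s, method = "interpolate")
    crossings <- sum(diff(sign(s$rel_intensity - 0.5)) != 0)
    if (is.na(r$tm50)) {
      expect_identical(r$reason, "no_crossing")
      expect_identical(crossings, 0L)
    } else {
      expect_lte(crossings, 1L)
      expect_true(r$tm50 >= min(tt) && r$tm50 <= max(tt))
    }
  }
})

test_that("worked thermal-shift examples come out exactly", {
  # LSS in situ: control Tm50 50, treated 55 => +5
  lss <- simulate_cetsa(tm_control = 50, delta_tm = 5, noise_cv = 0,
                        temperatures = seq(40, 70, by = 1))
  r <- cetsa_delta_tm(lss[lss$condition == "vehicle", ],
                      lss[lss$condition == "treated", ], method = "fit")
  expect_equal(r$tm_control, 50, tolerance = 1e-6)
  expect_equal(r$tm_treated, 55, tolerance = 1e-6)
  expect_equal(r$delta_tm, 5, tolerance = 1e-6)
  # CYP51A1: control 56, treated 64 => +8
  cyp <- simulate_cetsa(tm_control = 56, delta_tm = 8, noise_cv = 0,
                        temperatures = seq(45, 78, by = 1))
  r2 <- cetsa_delta_tm(cyp[cyp$condition == "vehicle", ],
                       cyp[cyp$condition == "treated", ], method = "fit")
  expect_equal(r2$delta_tm, 8, tolerance = 1e-6)
  # identical conditions give a zero shift
  same <- simulate_cetsa(52, 0, noise_cv = 0)
  r3 <- cetsa_delta_tm(same[same$condition == "vehicle", ],
                       same[same$condition == "treated", ])
  expect_equal(r3$delta_tm, 0, tolerance = 1e-8)
})

test_that("replicate pairs feed a paired t-test on Tm50 differences", {
  cc <- simulate_cetsa(50, 5, noise_cv = 0.05, n_replicates = 4, seed = 2,
                       temperatures = seq(40, 70, by = 2))
  r <- cetsa_delta_tm(cc[cc$condition == "vehicle", ],
                      cc[cc$condition == "treated", ])
  expect_identical(r$n_replicate_pairs, 4L)
  expect_false(is.na(r$p_value))
  expect_lt(r$p_value, 0.05)
  expect_equal(r$delta_tm, 5, tolerance = 0.6)
})

test_that("shift estimates track truth on dense low-noise grids", {
  set.seed(33)
  for (delta in c(2, 5, -3)) {
    cc <- simulate_cetsa(51, delta, noise_cv = 0.05, n_replicates = 1,
                         temperatures = seq(40, 68, by = 2))
    r <- cetsa_delta_tm(cc[cc$condition == "vehicle", ],
                        cc[cc$condition == "treated", ])
    expect_lt(abs(r$delta_tm - delta), 0.5)
  }
})
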