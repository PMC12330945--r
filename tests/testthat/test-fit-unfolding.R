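test_that("noise-free curves are recovered to high precision", {
  cases <- list(c(-0.8, 51, 0.1), c(-0.4, 47, 0.0), c(-1.5, 53, 0.25),
                c(-0.3, 50, 0.05))
  for (cs in cases) {
    curve <- make_rel_curve(cs[1], cs[2], cs[3])
    fit <- fit_unfolding(curve)
    expect_true(fit$converged)
    expect_equal(unname(coef(fit)), cs, tolerance = 1e-6)
    expect_equal(fit$tm, melting_point(cs[1], cs[2], cs[3]),
                 tolerance = 1e-4)
    expect_gt(fit$r_squared, 0.999999)
  }
})

test_that("formula interface agrees with the data-frame method", {
  curve <- make_rel_curve(-0.7, 50, 0.15)
  f1 <- fit_unfolding(curve)
  f2 <- fit_unfolding(rel_abundance ~ temperature_c, data = curve)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
})

test_that("replicate points are pooled into a single fit", {
  curve <- make_rel_curve(-0.9, 49, 0.1)
  pooled <- rbind(transform(curve, replicate = 1),
                  transform(curve, replicate = 2))
  fit <- fit_unfolding(pooled)
  expect_equal(unname(coef(fit)), c(-0.9, 49, 0.1), tolerance = 1e-6)
  expect_identical(fit$n_points, 6L)
  expect_length(residuals(fit), 12L)
})

test_that("too few distinct temperatures skips the fit with a reason", {
  curve <- make_rel_curve(-0.8, 51, 0.1, temperatures = c(43, 50, 60))
  fit <- fit_unfolding(curve)
  expect_false(fit$converged)
  expect_identical(fit$reason, "insufficient_points")
  expect_true(is.na(fit$tm))
})

test_that("a flat curve carries no melting signal", {
  flat <- data.frame(temperature_c = seq(43, 60, length.out = 6),
                     rel_abundance = rep(1, 6))
  fit <- fit_unfolding(flat)
  expect_true(!fit$converged || is.na(fit$r_squared))
  qc <- qc_filter(fit, fit)
  expect_false(qc$pass)
})

test_that("predict, fitted and residuals are mutually consistent", {
  curve <- make_rel_curve(-0.6, 52, 0.1)
  fit <- fit_unfolding(curve)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(curve$rel_abundance - fitted(fit), residuals(fit))
  # absolute fraction folded crosses 0.5 exactly at the melting point
  expect_equal(predict(fit, fit$tm, type = "folded"), 0.5,
               tolerance = 1e-8)
  # relative prediction equals 1 at the reference
  expect_equal(predict(fit, 43), 1)
})

test_that("simulate() draws noisy replicates around the fitted curve", {
  fit <- fit_unfolding(make_rel_curve(-0.8, 50, 0.1))
  clean <- simulate(fit, nsim = 2, seed = 1, noise_cv = 0)
  expect_identical(nrow(clean), 12L)
  expect_equal(clean$rel_abundance[clean$replicate == 1],
               predict(fit, sort(unique(clean$temperature_c))))
  noisy <- simulate(fit, nsim = 1, seed = 1, noise_cv = 0.2)
  expect_false(all(noisy$rel_abundance == clean$rel_abundance[1:6]))
})

test_that("print and summary render without error", {
  fit <- fit_unfolding(make_rel_curve(-0.8, 50, 0.1))
  expect_output(print(fit), "Tm")
  expect_output(print(summary(fit)), "observations")
})
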