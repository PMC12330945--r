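test_that("spiked class counts equal the rounded configured fractions", {
  sim <- simulate_dataset(sim_config(n_proteins = 100,
                                     fraction_stabilized = 0.10,
                                     fraction_destabilized = 0, seed = 7))
  counts <- table(sim$truth$true_class)
  expect_identical(unname(counts[["stabilized"]]), 10L)
  expect_false("destabilized" %in% names(counts))
  expect_identical(nrow(sim$truth), 100L)
  # sign of the spiked shift is consistent with the class
  with(sim$truth, {
    expect_true(all(true_delta_tm[true_class == "stabilized"] > 0))
    expect_true(all(true_delta_tm[true_class == "unchanged"] == 0))
  })
})

test_that("no noise, no missingness, no effect: treated equals control", {
  sim <- simulate_dataset(sim_config(n_proteins = 20, noise_cv = 0,
                                     missing_rate = 0,
                                     fraction_stabilized = 0,
                                     fraction_destabilized = 0, seed = 2))
  tab <- sim$table
  tr <- tab[tab$condition == "treated", ]
  ve <- tab[tab$condition == "vehicle", ]
  m <- merge(tr, ve, by = c("protein_id", "replicate", "temperature_c"))
  expect_identical(nrow(m), nrow(tr))
  expect_equal(m$intensity.x, m$intensity.y)
})

test_that("noise-free relative abundances equal the model exactly", {
  sim <- simulate_dataset(sim_config(n_proteins = 10, noise_cv = 0,
                                     missing_rate = 0, seed = 5))
  cv <- normalize_to_reference(sim$table)$curves
  m <- merge(cv, sim$truth, by = "protein_id")
  b_eff <- ifelse(m$condition == "treated", m$b_control + m$true_delta_tm,
                  m$b_control)
  expected <- rel_model(m$temperature_c, m$a_control, b_eff, m$p_control,
                        t_ref = min(sim$table$temperature_c))
  expect_equal(m$rel_abundance, expected, tolerance = 1e-12)
})

test_that("identical configs with the same seed are bit-identical", {
  cfg <- sim_config(n_proteins = 30, seed = 99)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$table, s2$table)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_dataset(sim_config(n_proteins = 30, seed = 100))
  expect_false(identical(s1$table, s3$table))
})

test_that("log-noise factors are centered on zero", {
  cfg <- sim_config(n_proteins = 300, noise_cv = 0.25, missing_rate = 0,
                    fraction_stabilized = 0, fraction_destabilized = 0,
                    n_replicates = 3, seed = 31)
  sim <- simulate_dataset(cfg)
  m <- merge(sim$table, sim$truth, by = "protein_id")
  mu <- m$base_intensity *
    eval_unfolding(m$temperature_c, m$a_control, m$b_control, m$p_control)
  lf <- log(m$intensity / mu)
  expect_gt(length(lf), 1e4)
  sigma <- sqrt(log(1 + 0.25^2))
  expect_lt(abs(mean(lf)), 3 * sigma / sqrt(length(lf)))
  # linear-scale CV close to the configured value
  expect_equal(sd(exp(lf)) / mean(exp(lf)), 0.25, tolerance = 0.05)
})

test_that("invalid configurations name the offending field", {
  expect_error(sim_config(slope_range = c(0.1, 0.5)), "slope_range")
  expect_error(sim_config(plateau_range = c(0, 0.6)), "plateau_range")
  expect_error(sim_config(temperatures = c(50, 45, 55, 60)), "temperatures")
  expect_error(sim_config(temperatures = c(43, 50, 60)), "temperatures")
  expect_error(sim_config(fraction_stabilized = 0.7,
                          fraction_destabilized = 0.6),
               "fraction_stabilized")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(noise_cv = -0.1), "noise_cv")
})

test_that("default temperature grid is the six-point 43-60 gradient", {
  cfg <- sim_config()
  expect_equal(cfg$temperatures, c(43.0, 46.4, 49.8, 53.2, 56.6, 60.0))
  expect_identical(cfg$n_replicates, 3L)
})

test_that("CETSA simulation is noiseless and symmetric when asked", {
  cc <- simulate_cetsa(tm_control = 50, delta_tm = 0, noise_cv = 0)
  tr <- cc[cc$condition == "treated", ]
  ve <- cc[cc$condition == "vehicle", ]
  expect_equal(tr$band_intensity, ve$band_intensity)
  expect_equal(ve$band_intensity[1], 1)
  expect_error(simulate_cetsa(50, 5, p = 0.5), "p")
  expect_error(simulate_cetsa(50, 5, temperatures = c(50, 45, 60)),
               "temperatures")
})
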