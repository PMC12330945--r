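fit_at <- function(tm) {
  fit_unfolding(make_rel_curve(-0.8, tm, 0,
                               temperatures = seq(42, 74, by = 4)))
}

test_that("delta Tm is the treated-minus-control melting-point difference", {
  expect_equal(compute_shift(fit_at(50), fit_at(55)), 5, tolerance = 1e-6)
  expect_equal(compute_shift(fit_at(56), fit_at(64)), 8, tolerance = 1e-6)
  f <- fit_at(51.3)
  expect_equal(compute_shift(f, f), 0)
  # antisymmetry under swapping conditions
  expect_equal(compute_shift(fit_at(55), fit_at(50)),
               -compute_shift(fit_at(50), fit_at(55)))
})

test_that("undefined melting points make the shift undefined", {
  no_tm <- fit_unfolding(make_rel_curve(-0.8, 50, 0.55))
  expect_true(is.na(compute_shift(no_tm, fit_at(50))))
  expect_true(is.na(compute_shift(fit_at(50), no_tm)))
})

test_that("a lone large shift dominates the proteome null", {
  set.seed(17)
  d <- stats::rnorm(999, 0, 0.5)
  names(d) <- sprintf("N%03d", 1:999)
  d <- c(d, TARGET = 6)
  sc <- significance_scores(d, mode = "proteome_null")
  expect_identical(sc$protein_id[which.max(abs(sc$z_score))], "TARGET")
  expect_lt(sc$q_value[sc$protein_id == "TARGET"], 0.05)
  # brute-force rank check: the target has the most extreme shift
  expect_identical(names(which.max(abs(d - stats::median(d)))), "TARGET")
})

test_that("a degenerate all-identical null gives z = 0 everywhere", {
  d <- rep(1.5, 10)
  names(d) <- letters[1:10]
  sc <- significance_scores(d, mode = "proteome_null")
  expect_equal(sc$z_score, rep(0, 10))
  expect_error(significance_scores(c(a = 1, b = 2), mode = "proteome_null"),
               "at least 3")
})

test_that("replicate mode matches the closed-form t statistic", {
  d <- c(5.0, 5.1, 4.9)
  sc <- significance_scores(list(PROT = d), mode = "replicate")
  t_oracle <- mean(d) / (sd(d) / sqrt(3))
  p_oracle <- 2 * stats::pt(-abs(t_oracle), df = 2)
  expect_equal(sc$z_score, t_oracle)
  expect_equal(sc$p_value, p_oracle)
  expect_lt(sc$p_value, 0.01)
  # fewer than two replicate shifts cannot be scored
  sc2 <- significance_scores(list(A = 1.0, B = c(1, 2)), mode = "replicate")
  expect_true(is.na(sc2$p_value[sc2$protein_id == "A"]))
  expect_false(is.na(sc2$p_value[sc2$protein_id == "B"]))
})

test_that("classification thresholds and tie-broken ranking are exact", {
  res <- data.frame(
    protein_id = c("A", "B", "C", "D", "E"),
    delta_tm = c(6.4, 1.0, -3.0, 2.0, -6.4),
    q_value = c(0.001, 0.001, 0.01, 0.04, 0.001),
    qc_pass = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  st <- classify_and_rank(res, delta_threshold = 2.0, q_cutoff = 0.05)
  cls <- setNames(st$stability_class, st$protein_id)
  expect_identical(unname(cls[c("A", "B", "C", "D", "E")]),
                   c("stabilized", "unchanged", "destabilized",
                     "stabilized", "qc_failed"))
  # rank over QC-pass rows by |delta|, ties by q then id; qc_failed unranked
  expect_identical(st$rank[st$protein_id == "A"], 1L)
  expect_identical(st$rank[st$protein_id == "C"], 2L)
  expect_identical(st$rank[st$protein_id == "D"], 3L)
  expect_identical(st$rank[st$protein_id == "B"], 4L)
  expect_true(is.na(st$rank[st$protein_id == "E"]))
  expect_identical(sort(st$rank[st$qc_pass]), 1:4)
  expect_error(classify_and_rank(res[0, ]), "empty")
})

test_that("rank ties break by q-value then protein id", {
  res <- data.frame(protein_id = c("Z", "A", "M"),
                    delta_tm = c(3, 3, 3),
                    q_value = c(0.01, 0.01, 0.001),
                    qc_pass = TRUE)
  st <- classify_and_rank(res)
  expect_identical(st$protein_id[match(1:3, st$rank)], c("M", "A", "Z"))
})

test_that("condition swap negates shifts and mirrors the class counts", {
  sim <- simulate_dataset(sim_config(n_proteins = 60,
                                     fraction_stabilized = 0.1,
                                     fraction_destabilized = 0.1,
                                     missing_rate = 0, seed = 23))
  tab <- sim$table
  st1 <- tpp_shifts(tab)
  swapped <- tab
  swapped$condition <- ifelse(tab$condition == "treated", "vehicle",
                              "treated")
  st2 <- tpp_shifts(swapped)
  m <- merge(st1, st2, by = "protein_id")
  ok <- !is.na(m$delta_tm.x) & !is.na(m$delta_tm.y)
  expect_equal(m$delta_tm.x[ok], -m$delta_tm.y[ok], tolerance = 1e-6)
  s1 <- summary(st1)$counts
  s2 <- summary(st2)$counts
  expect_identical(s1$stabilized, s2$destabilized)
  expect_identical(s1$destabilized, s2$stabilized)
})

test_that("stability classes always partition the proteome", {
  for (seed in c(4, 11)) {
    sim <- simulate_dataset(sim_config(n_proteins = 40, seed = seed))
    st <- tpp_shifts(sim$table)
    counts <- table(factor(st$stability_class,
                           levels = c("stabilized", "destabilized",
                                      "unchanged", "qc_failed")))
    expect_identical(sum(counts), nrow(st))
    expect_identical(nrow(st), length(unique(sim$table$protein_id)))
  }
})

test_that("BH adjustment agrees with the brute-force step-up", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(2:20, 1)
    d <- stats::rnorm(n)
    names(d) <- sprintf("P%02d", seq_len(n))
    if (n < 3) next
    sc <- significance_scores(d, mode = "proteome_null")
    expect_equal(sc$q_value, bh_brute(sc$p_value))
  }
})

test_that("two-fold rule is inclusive at the boundary", {
  mk <- function(pid, veh, trt) {
    rbind(data.frame(protein_id = pid, condition = "vehicle",
                     replicate = 1:3, temperature_c = 43, intensity = veh),
          data.frame(protein_id = pid, condition = "treated",
                     replicate = 1:3, temperature_c = 43, intensity = trt))
  }
  tab <- rbind(
    mk("UP",   c(99.9, 100.1, 100), c(199.8, 200.2, 200)),  # fc exactly 2
    mk("MID",  c(99.9, 100.1, 100), c(198.8, 199.2, 199)),  # fc 1.99
    mk("DOWN", c(199.8, 200.2, 200), c(99.9, 100.1, 100)),  # fc exactly 0.5
    mk("ZERO", c(0, 0, 0), c(10, 11, 12)))
  dep <- classify_dep(tab, q_cutoff = 0.05)
  cls <- setNames(dep$dep_class, dep$protein_id)
  expect_identical(unname(cls[c("UP", "MID", "DOWN", "ZERO")]),
                   c("up", "unchanged", "down", "undefined"))
  expect_equal(dep$log2_fold_change[dep$protein_id == "UP"], 1)
  expect_equal(dep$log2_fold_change[dep$protein_id == "DOWN"], -1)
  expect_true(is.na(dep$log2_fold_change[dep$protein_id == "ZERO"]))
})

test_that("DEP comparison uses the lowest-temperature abundances", {
  sim <- simulate_dataset(sim_config(n_proteins = 10, missing_rate = 0,
                                     seed = 6))
  dep <- classify_dep(sim$table)
  expect_identical(nrow(dep), 10L)
  # base abundance is shared across conditions: no protein should be called
  expect_true(all(dep$dep_class %in% c("unchanged", "undefined")))
})
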