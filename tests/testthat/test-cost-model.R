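test_that("activity cost prorates the hourly rate linearly", {
  expect_equal(activity_cost(20, 30, 0), 10)
  expect_equal(activity_cost(4.97, 120, 0), 9.94)
  expect_equal(activity_cost(0, 100, 55), 55)
  expect_error(activity_cost(-1, 30), "non-negative")
  expect_error(activity_cost(10, -30), "non-negative")
})

test_that("arm mean costs are the exact dot products of the published table", {
  p <- cost_model_params()
  expect_equal(arm_mean_cost(p$dist_intervention, p$unit_costs), 213.25,
               tolerance = 1e-12)
  expect_equal(arm_mean_cost(p$dist_comparator, p$unit_costs), 261.49,
               tolerance = 1e-12)
  expect_equal(arm_mean_cost(arm_distribution(c(F = 1)), c(F = 163)), 163)
  expect_error(arm_mean_cost(arm_distribution(c(Q = 1)), c(F = 163)),
               "missing unit cost")
  # dot product agrees with a brute-force per-patient enumeration at large N
  N <- 200000
  counts <- round(as.numeric(p$dist_comparator) * N)
  per_patient <- rep(p$unit_costs[names(p$dist_comparator)], counts)
  expect_equal(mean(per_patient) * sum(counts) / N,
               arm_mean_cost(p$dist_comparator, p$unit_costs),
               tolerance = 1e-3)
})

test_that("incremental and overall savings follow the printed arithmetic", {
  expect_equal(incremental_saving(261.49, 213.25), 48.24)
  expect_equal(incremental_saving(100, 100), 0)
  expect_equal(total_saving(0, 563), 0)
  expect_equal(total_saving(45, 563), 25335)
  # the printed overall saving implies a per-referral saving of 25251/563
  expect_equal(total_saving(25251 / 563, 563), 25251)
  expect_equal(25251 / 563, 44.85, tolerance = 1e-3)
})

test_that("the unpaired t test matches the hand Welch formula", {
  # identical samples carry no evidence
  r0 <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  # hand evaluation of the Welch statistic for a=(1,2,3), b=(4,5,6)
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  se2 <- var(a) / 3 + var(b) / 3
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  p_hand <- 2 * stats::pt(-abs(t_hand), df_hand)
  r <- welch_t_test(a, b)
  expect_equal(r$t, t_hand, tolerance = 1e-12)
  expect_equal(r$df, df_hand, tolerance = 1e-12)
  expect_equal(r$p, p_hand, tolerance = 1e-12)
  # degenerate inputs are flagged
  expect_error(welch_t_test(c(1), c(1, 2)), "two observations")
  expect_error(welch_t_test(c(2, 2, 2), c(3, 3, 3)), "zero variance")
})

test_that("cost samples from the two arms differ significantly", {
  p <- cost_model_params()
  ci <- sample_referral_costs(p, "intervention", 563, seed = 3)
  cc <- sample_referral_costs(p, "comparator", 4011, seed = 4)
  expect_equal(nrow(ci), 563)
  expect_true(all(ci$cost %in% p$unit_costs))
  r <- welch_t_test(ci$cost, cc$cost)
  expect_lt(r$p, 0.001)
})

test_that("PSA collapses to the deterministic saving when SEs are zero", {
  p0 <- cost_model_params(psa_se_frac = 0)
  psa <- run_psa(p0, n_iter = 200, seed = 9)
  expect_equal(psa$per_iteration_savings, rep(48.24, 200),
               tolerance = 1e-12)
  expect_equal(psa$mean, 48.24, tolerance = 1e-12)
  expect_equal(psa$prob_saving_positive, 1)
})

test_that("PSA is seed-reproducible and centred on the deterministic saving", {
  p <- cost_model_params()
  a <- run_psa(p, 1000, seed = 7)
  b <- run_psa(p, 1000, seed = 7)
  expect_identical(a$per_iteration_savings, b$per_iteration_savings)
  expect_true(a$ci95[1] <= a$mean && a$mean <= a$ci95[2])
  # symmetric zero-mean noise on unit costs leaves the mean at the
  # deterministic value up to Monte Carlo error
  mc_se <- stats::sd(a$per_iteration_savings) / sqrt(a$n_iter)
  expect_lt(abs(a$mean - 48.24), 4 * mc_se)
  # quadrupling the iteration count roughly halves the Monte Carlo SE
  small <- run_psa(p, 400, seed = 11)
  big <- run_psa(p, 1600, seed = 12)
  se_small <- stats::sd(small$per_iteration_savings) / sqrt(400)
  se_big <- stats::sd(big$per_iteration_savings) / sqrt(1600)
  expect_gt(se_small / se_big, 1.6)
  expect_lt(se_small / se_big, 2.5)
})

test_that("one-way DSA matches hand recomputation and is monotone in biopsies", {
  p <- cost_model_params()
  base <- run_dsa(p, "unit_cost.G", 364, 364)
  expect_equal(base$saving_low, 48.24, tolerance = 1e-12)
  expect_equal(base$saving_high, 48.24, tolerance = 1e-12)
  # dot-product oracle at a shifted bound
  r <- run_dsa(p, "unit_cost.G", 364 * 0.8, 364 * 1.2)
  expect_equal(r$saving_high,
               (0.51 * 163 + 0.49 * 364 * 1.2) - 213.25,
               tolerance = 1e-12)
  # moving intervention mass out of the expensive biopsy pathways strictly
  # increases the saving
  shift <- run_dsa(p, "biopsy_share.intervention", 0.10, 0.31)
  expect_gt(shift$saving_low, shift$base)
  expect_equal(shift$saving_high, shift$base, tolerance = 1e-9)
  expect_error(run_dsa(p, "nonsense", 0, 1), "unknown parameter")
  torn <- dsa_tornado(p, data.frame(
    parameter = c("unit_cost.G", "unit_cost.A"),
    low = c(300, 40), high = c(430, 70)))
  expect_equal(nrow(torn), 2)
  expect_true(all(diff(torn$swing) <= 0))
})

test_that("inflation indexing is a simple ratio with an exact inverse", {
  idx <- c(`2021` = 1.00, `2023` = 1.10)
  expect_equal(inflate_cost(100, 2021, 2021, idx), 100)
  expect_equal(inflate_cost(100, 2021, 2023, idx), 110)
  rt <- inflate_cost(inflate_cost(123.45, 2021, 2023, idx), 2023, 2021, idx)
  expect_equal(rt, 123.45, tolerance = 1e-9)
  expect_error(inflate_cost(100, 2020, 2023, idx), "missing")
})

test_that("the full cost comparison reports coherent results", {
  cca <- run_cca(n_iter = 300, seed = 21)
  expect_equal(cca$deterministic_saving, 48.24, tolerance = 1e-12)
  expect_equal(cca$overall_saving,
               cca$saving_per_referral * 563, tolerance = 1e-9)
  expect_lt(cca$t_test$p, 0.001)
  expect_true(cca$psa$prob_saving_positive > 0.8)
})
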