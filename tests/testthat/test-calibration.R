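test_that("missing pathway means solve the weighted-average equation", {
  dist <- referral_distribution("comparator", "des")
  f <- solve_missing_pathway_mean(73.16, dist, c(G = 131.1))
  expect_equal(unname(f["F"]), (73.16 - 0.48 * 131.1) / 0.52,
               tolerance = 1e-12)
  expect_equal(unname(f["F"]), 19.68, tolerance = 0.005)
  # round trip to the overall anchor is exact
  w <- weighted_average_time(c(f, G = 131.1), dist)
  expect_equal(w$mean, 73.16, tolerance = 1e-12)

  di <- referral_distribution("intervention", "des")
  solved <- solve_missing_pathway_mean(18.97, di, c(A = 8, C = 52.4,
                                                    D = 52.4))
  # B and E (tied) share the single solved value
  expect_equal(sort(names(solved)), c("B", "E"))
  expect_equal(unname(solved["B"]), unname(solved["E"]))
  expect_equal(unname(solved["B"]),
               (18.97 - (0.53 * 8 + 0.22 * 52.4)) / 0.25,
               tolerance = 1e-12)
  expect_equal(unname(solved["B"]), 12.8, tolerance = 0.05)
  w2 <- weighted_average_time(c(A = 8, C = 52.4, D = 52.4, solved), di)
  expect_equal(w2$mean, 18.97, tolerance = 1e-12)
})

test_that("infeasible or unidentifiable linear solves are flagged", {
  expect_error(
    solve_missing_pathway_mean(10, c(A = 1, B = 0), c(A = 10)),
    "zero proportion")
  expect_error(
    solve_missing_pathway_mean(5, c(A = 0.9, B = 0.1), c(A = 10)),
    "negative")
  expect_error(
    solve_missing_pathway_mean(10, c(A = 1), c(A = 10)),
    "no unknown")
})

test_that("delay distributions hit their target mean exactly", {
  d0 <- fit_delay_distribution(3, cv = 0)
  expect_equal(d0$family, "fixed")
  expect_equal(d0$params$value, 3)
  dl <- fit_delay_distribution(5, cv = 0.5, family = "lognormal")
  # closed-form lognormal moment identity
  expect_equal(exp(dl$params$meanlog + dl$params$sdlog^2 / 2), 5,
               tolerance = 1e-12)
  expect_equal(sqrt(exp(dl$params$sdlog^2) - 1), 0.5, tolerance = 1e-12)
  dg <- fit_delay_distribution(5, cv = 0.5, family = "gamma")
  expect_equal(dg$params$shape / dg$params$rate, 5, tolerance = 1e-12)
  expect_error(fit_delay_distribution(5, 0.5, "weibull"), "unsupported")
  # Monte Carlo agreement of the sample mean at large n
  set.seed(77)
  s2 <- log(1 + 0.5^2)
  x <- stats::rlnorm(1e5, dl$params$meanlog, dl$params$sdlog)
  expect_lt(abs(mean(x) - 5), 3 * stats::sd(x) / sqrt(1e5))
})

test_that("analytic assignment needs no correction without congestion", {
  cfg <- default_arm_config("comparator", annual_volume = 400, cv = 0,
                            staffing = c(HCA_Band3 = Inf, Band5 = Inf,
                                         Band9 = Inf, Consultant = Inf,
                                         GP = Inf),
                            calendar = rota_calendar(always_open = TRUE))
  cal <- calibrate_arm(cfg, n_rep = 1, max_iter = 2, seed = 2)
  expect_true(cal$converged)
  expect_equal(cal$iterations, 1L)
  expect_lt(max(abs(cal$report$residual)), 1e-8)
})

test_that("calibration absorbs rota and queueing bias under congestion", {
  # one consultant for 2000 referrals/year: queueing and rota waits bias
  # every endpoint upward until the delay means are recalibrated
  cfg <- default_arm_config("comparator", annual_volume = 2000,
                            staffing = c(HCA_Band3 = 1, Band5 = 1,
                                         Band9 = 1, Consultant = 1, GP = 1))
  cal <- calibrate_arm(cfg, tolerance = 0.2, n_rep = 3, n_rep_max = 12,
                       max_iter = 5, seed = 3)
  expect_true(cal$converged)
  ok <- abs(cal$report$residual) <= pmax(0.2, 2 * cal$report$se)
  expect_true(all(ok))
  # calibrated means moved downwards to absorb the positive waiting bias
  expect_lt(cal$config$delays$consult_wait$mean,
            cfg$delays$consult_wait$mean)
})

test_that("endpoint means increase monotonically in the delay scale", {
  scale_cfg <- function(cfg, f) {
    cfg$delays <- lapply(cfg$delays, function(d)
      delay_spec(d$mean * f, d$cv, d$family))
    cfg
  }
  base <- default_arm_config("comparator", annual_volume = 300)
  lo <- simulate_arm(scale_cfg(base, 0.8), seed = 6)
  hi <- simulate_arm(scale_cfg(base, 1.2), seed = 6)
  expect_lt(mean(lo$log$t_communication), mean(hi$log$t_communication))
  expect_lt(mean(lo$log$t_clinical_diagnosis),
            mean(hi$log$t_clinical_diagnosis))
})

test_that("synthetic cohorts reproduce the target demographics", {
  co <- generate_cohort(5000, seed = 19, arm = "intervention")
  expect_equal(nrow(co), 5000)
  expect_true(all(co$age >= 18))
  # truncation at 18 lifts the mean slightly above 61.5; stay within 3 SEs
  # of the truncated-normal moments
  expect_lt(abs(mean(co$age) - 61.5), 0.35 + 3 * 17.6 / sqrt(5000))
  expect_lt(abs(stats::sd(co$age) - 17.6), 0.35 + 3 * 17.6 / sqrt(10000))
  p_f <- mean(co$sex == "female")
  expect_lt(abs(p_f - 0.575), 3 * sqrt(0.575 * 0.425 / 5000))
  # expected female count at the study cohort size
  expect_equal(round(0.575 * 563), 324)
  # pathway labels follow the arm distribution
  expect_true(all(co$pathway %in% c("A", "B", "C", "D", "E")))
  # seed reproducibility
  expect_identical(generate_cohort(100, seed = 3), generate_cohort(100, seed = 3))
})

test_that("cohort ages pass a KS test against the truncated normal", {
  co <- generate_cohort(1e4, seed = 23)
  p18 <- stats::pnorm(18, 61.5, 17.6)
  cdf <- function(q) {
    (stats::pnorm(q, 61.5, 17.6) - p18) / (1 - p18)
  }
  ks <- suppressWarnings(stats::ks.test(co$age, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("an empty cohort still carries all columns", {
  co <- generate_cohort(0, seed = 1)
  expect_equal(nrow(co), 0L)
  expect_equal(names(co),
               c("id", "arm", "pathway", "referral_time", "age", "sex"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, f)
  expect_equal(readLines(f)[1],
               "\"id\",\"arm\",\"pathway\",\"referral_time\",\"age\",\"sex\"")
})
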