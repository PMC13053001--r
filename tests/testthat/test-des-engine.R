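test_that("capacity calendar applies the weekend floor rule and GP exclusion", {
  cc <- build_capacity_calendar(c(Consultant = 10), 0.7)
  expect_equal(cc$weekend[["Consultant"]], 7)
  cc1 <- build_capacity_calendar(c(Consultant = 1), 0.7)
  expect_equal(cc1$weekend[["Consultant"]], 0)  # floor rule
  gp <- build_capacity_calendar(c(GP = 5), 0.7)
  expect_equal(gp$weekend[["GP"]], 0)
  expect_error(build_capacity_calendar(c(Consultant = -1), 0.7), ">= 0")
})

test_that("arrival stream has the configured volume and seasonality", {
  expect_error(arrival_process(3000, rep(0, 12)), "all be zero")
  expect_error(arrival_process(3000, c(-1, rep(1, 11))), "non-negative")
  # expected yearly count equals the annual volume (Monte Carlo check)
  set.seed(42)
  p <- arrival_process(3650)
  n <- replicate(60, length(generate_arrivals(p)))
  expect_lt(abs(mean(n) - 3650), 3 * sqrt(3650 / 60))
  # a zero-weight month receives no arrivals (February here)
  w <- rep(1, 12); w[2] <- 0
  a <- generate_arrivals(arrival_process(2000, w), seed = 5)
  expect_false(any(a >= 31 & a < 59))
  expect_true(all(a >= 0 & a < 365))
})

test_that("a deterministic chain adds its delays exactly", {
  cfg <- toy_arm_config(p_y = 1, means = c(wx = 2, wy1 = 2, wy2 = 0.1),
                        comm_mean = 1, cv = 0, dur_min = 0)
  s <- simulate_arm(cfg, seed = 1, arrivals = 3.2)
  expect_equal(s$log$t_clinical_diagnosis, 2)
  expect_equal(s$log$t_histopath_diagnosis, 2.1)
  expect_equal(s$log$t_communication, 3.1)
})

test_that("two simultaneous arrivals share one consultant head-to-tail", {
  cfg <- toy_arm_config(p_y = 0, means = c(wx = 0, wy1 = 1, wy2 = 1),
                        comm_mean = 0, cv = 0, dur_min = 20, staff_n = 1,
                        always_open = FALSE)
  # day 10 is a Thursday; 0.4 d = 09:36, inside the rota window
  s <- simulate_arm(cfg, seed = 1, arrivals = c(10.4, 10.4))
  srv <- s$services[order(s$services$start_time), ]
  expect_equal(nrow(srv), 2)
  expect_equal(srv$start_time[2] - srv$start_time[1], 20 / 1440,
               tolerance = 1e-9)
  expect_equal(srv$start_time[2], srv$end_time[1], tolerance = 1e-9)
})

test_that("services wait for the rota window to open", {
  cfg <- toy_arm_config(p_y = 0, means = c(wx = 0, wy1 = 1, wy2 = 1),
                        comm_mean = 0, cv = 0, dur_min = 30, staff_n = 2,
                        always_open = FALSE)
  # arrival at 02:24 on a weekday: service cannot start before 08:30
  s <- simulate_arm(cfg, seed = 1, arrivals = 9.1)
  expect_equal(s$services$start_time, 9 + 8.5 / 24, tolerance = 1e-9)
})

test_that("zero-variance unlimited-capacity limit equals closed-form sums", {
  means <- c(wx = 2, wy1 = 3, wy2 = 4)
  cfg <- toy_arm_config(p_y = 0.4, means = means, comm_mean = 1, cv = 0,
                        dur_min = 30, annual_volume = 300)
  s <- simulate_arm(cfg, seed = 3)
  cf <- toy_closed_form(means, comm_mean = 1, dur_min = 30)
  lx <- s$log[s$log$pathway == "X", ]
  ly <- s$log[s$log$pathway == "Y", ]
  expect_lt(max(abs(lx$t_clinical_diagnosis - cf$X[["clinical"]])), 1e-9)
  expect_lt(max(abs(lx$t_communication - cf$X[["communication"]])), 1e-9)
  expect_true(all(is.na(lx$t_histopath_diagnosis)))
  expect_lt(max(abs(ly$t_histopath_diagnosis - cf$Y[["histopath"]])), 1e-9)
  expect_lt(max(abs(ly$t_communication - cf$Y[["communication"]])), 1e-9)
  # the simulated weighted average equals the analytic dot product
  sm <- summarize_endpoints(s$log, cfg$distribution)
  expect_equal(sm$weighted$mean,
               0.6 * cf$X[["communication"]] + 0.4 * cf$Y[["communication"]],
               tolerance = 1e-9)
})

test_that("queueing is first-come first-served within a role", {
  cfg <- toy_arm_config(p_y = 0, means = c(wx = 1, wy1 = 1, wy2 = 1),
                        comm_mean = 0.5, cv = 0.8, dur_min = 30,
                        staff_n = 1, always_open = FALSE,
                        annual_volume = 500)
  s <- simulate_arm(cfg, seed = 8)
  srv <- s$services[order(s$services$start_time), ]
  expect_true(all(diff(srv$enqueue_time) >= -1e-9))
})

test_that("every arriving patient exits with exactly one communication", {
  cfg <- toy_arm_config(p_y = 0.3, means = c(wx = 1, wy1 = 2, wy2 = 3),
                        comm_mean = 0.5, cv = 0.5, dur_min = 15,
                        staff_n = 2, always_open = FALSE,
                        annual_volume = 400)
  s <- simulate_arm(cfg, seed = 12)
  expect_false(any(is.na(s$log$t_communication)))
  expect_true(all(s$log$t_communication >= 0))
})

test_that("timestamps are non-decreasing along every patient's stages", {
  cfg <- default_arm_config("intervention", annual_volume = 500)
  s <- simulate_arm(cfg, seed = 4)
  ord <- c("t_image_capture", "t_clinical_diagnosis", "t_biopsy",
           "t_histopath_diagnosis", "t_communication")
  for (i in seq_len(nrow(s$log))) {
    tt <- as.numeric(s$log[i, ord])
    tt <- tt[!is.na(tt)]
    expect_true(all(diff(tt) >= -1e-9))
    expect_true(all(tt >= 0))
  }
  # histopathology timestamps exist exactly for biopsy-reliant pathways
  expect_true(all(is.na(
    s$log$t_histopath_diagnosis[s$log$pathway %in% c("A", "B", "E")])))
  expect_false(any(is.na(
    s$log$t_histopath_diagnosis[s$log$pathway %in% c("C", "D")])))
})

test_that("identical seeds give identical event logs", {
  cfg <- default_arm_config("comparator", annual_volume = 300)
  a <- simulate_arm(cfg, seed = 99)
  b <- simulate_arm(cfg, seed = 99)
  expect_identical(a$log, b$log)
  expect_identical(a$services, b$services)
})

test_that("replication pooling conserves patients and derives seeds", {
  cfg <- toy_arm_config(p_y = 0.3, cv = 0.5, comm_mean = 1,
                        annual_volume = 150)
  reps <- replicate_arm(cfg, n_runs = 3, master_seed = 5)
  expect_equal(nrow(reps$log),
               sum(vapply(1:3, function(r)
                 sum(reps$log$replication == r), 0L)))
  one <- replicate_arm(cfg, n_runs = 1, master_seed = 5)
  direct <- simulate_arm(cfg, seed = one$seeds[1], keep_services = FALSE)
  expect_identical(one$log[names(direct$log)], direct$log)
})

test_that("reducing staff never shortens waits (congestion monotonicity)", {
  mk <- function(n_staff) {
    toy_arm_config(p_y = 0, means = c(wx = 0.5, wy1 = 1, wy2 = 1),
                   comm_mean = 0.2, cv = 0.5, dur_min = 45,
                   staff_n = n_staff, always_open = FALSE,
                   annual_volume = 2500)
  }
  few <- suppressWarnings(simulate_arm(mk(1), seed = 31))
  many <- suppressWarnings(simulate_arm(mk(3), seed = 31))
  expect_gt(mean(few$log$t_communication),
            mean(many$log$t_communication) - 1e-9)
  # pre-sampled patient randomness is identical across capacity settings
  expect_identical(few$log$pathway, many$log$pathway)
})

test_that("unstable configurations trigger the utilisation warning", {
  cfg <- toy_arm_config(p_y = 0, means = c(wx = 0.5, wy1 = 1, wy2 = 1),
                        comm_mean = 0.2, cv = 0, dur_min = 120, staff_n = 1,
                        always_open = FALSE, annual_volume = 20000)
  expect_gt(check_utilization(cfg)[["Consultant"]], 1)
  expect_warning(simulate_arm(cfg, arrivals = c(1, 2)), "utilisation")
})

test_that("endpoint summaries match hand statistics and absence rules", {
  log <- data.frame(
    id = 1:3, arm = "comparator", pathway = "F", referral_time = 0,
    t_image_capture = NA_real_, t_clinical_diagnosis = c(1, 2, 3),
    t_biopsy = NA_real_, t_histopath_diagnosis = NA_real_,
    t_communication = c(2, 4, 6))
  sm <- summarize_endpoints(log)
  comm <- sm$endpoints[sm$endpoints$endpoint == "communication", ]
  expect_equal(comm$mean, 4)
  expect_equal(comm$se, stats::sd(c(2, 4, 6)) / sqrt(3))
  expect_equal(comm$max, 6)
  histo <- sm$endpoints[sm$endpoints$endpoint == "histopath_diagnosis", ]
  expect_equal(histo$n, 0L)       # absent, not zero
  expect_true(is.na(histo$mean))
  expect_error(summarize_endpoints(log[0, ]), "empty")
})

test_that("weighted average time reproduces the published comparator value", {
  w <- weighted_average_time(c(F = 19.68, G = 131.1), c(F = 0.52, G = 0.48),
                             pathway_ses = c(F = 0.1, G = 0.5))
  expect_equal(w$mean, 0.52 * 19.68 + 0.48 * 131.1, tolerance = 1e-12)
  expect_equal(w$mean, 73.16, tolerance = 0.005)
  expect_equal(w$se, sqrt(0.52^2 * 0.1^2 + 0.48^2 * 0.5^2),
               tolerance = 1e-12)
  expect_equal(weighted_average_time(c(G = 131.1), c(G = 1))$mean, 131.1)
  expect_error(weighted_average_time(c(F = 19.68), c(F = 0.5, G = 0.5)),
               "missing mean")
})

test_that("incremental times subtract pooled means with combined SEs", {
  cfg <- toy_arm_config(p_y = 0.4, cv = 0, comm_mean = 1,
                        annual_volume = 150)
  s <- simulate_arm(cfg, seed = 2)
  sm <- summarize_endpoints(s$log)
  d0 <- incremental_times(sm, sm)
  expect_true(all(abs(d0$delta) < 1e-12))
  # histopathology absent in one arm is an error, not a zero
  cfg_nb <- toy_arm_config(p_y = 0, cv = 0, comm_mean = 1,
                           annual_volume = 150)
  sm_nb <- summarize_endpoints(simulate_arm(cfg_nb, seed = 2)$log)
  expect_error(incremental_times(sm_nb, sm), "absent")
})
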