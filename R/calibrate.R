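#' Stage delay distribution
#'
#' Inter-stage waiting times are right-skewed and non-negative; the default
#' family is a lognormal parameterised by its mean (days) and coefficient of
#' variation. `cv = 0` collapses to a point mass.
#'
#' @param mean mean delay in days, `>= 0`.
#' @param cv coefficient of variation, `>= 0` (default 0.5).
#' @param family `"lognormal"`, `"gamma"` or `"fixed"`.
#' @return an object of class `delay_spec`.
#' @export
delay_spec <- function(mean, cv = 0.5, family = "lognormal") {
  stopifnot(mean >= 0, cv >= 0)
  if (!family %in% c("lognormal", "gamma", "fixed")) {
    stop("unsupported delay family: ", family, call. = FALSE)
  }
  if (cv == 0) family <- "fixed"
  structure(list(mean = mean, cv = cv, family = family),
            class = "delay_spec")
}

#' Fit a delay distribution to a target mean
#'
#' Returns distribution parameters whose analytic mean equals `target_mean`
#' exactly. For the lognormal, `meanlog = log(m / sqrt(1 + cv^2))` and
#' `sdlog = sqrt(log(1 + cv^2))`; for the gamma, `shape = 1 / cv^2` and
#' `rate = shape / m`. `cv = 0` gives a degenerate point mass.
#'
#' @inheritParams delay_spec
#' @param target_mean target mean delay in days, `> 0` (0 allowed only for
#'   the degenerate case).
#' @return a [delay_spec()] with an additional `params` element holding the
#'   closed-form parameters.
#' @export
fit_delay_distribution <- function(target_mean, cv = 0.5,
                                   family = "lognormal") {
  spec <- delay_spec(target_mean, cv, family)
  spec$params <- switch(spec$family,
    lognormal = {
      s2 <- log(1 + cv^2)
      list(meanlog = log(target_mean) - s2 / 2, sdlog = sqrt(s2))
    },
    gamma = list(shape = 1 / cv^2, rate = (1 / cv^2) / target_mean),
    fixed = list(value = target_mean)
  )
  spec
}

#' Published waiting-time anchors
#'
#' The aggregate waiting-time statistics of the evaluated service to which
#' the baseline configurations are calibrated. Stage-level delay
#' distributions were not published; the calibration module reconstructs
#' them so that the simulated endpoint means reproduce these anchors.
#'
#' @return an object of class `anchor_set`: per-arm clinical-diagnosis,
#'   histopathological-diagnosis and weighted communication means (days,
#'   with SEs), and per-pathway communication means (pathway A, combined
#'   C&D, pathway G).
#' @export
anchor_set <- function() {
  structure(list(
    clinical = c(intervention = 7.38, comparator = 17.29),
    clinical_se = c(intervention = 0.07, comparator = 0.11),
    histopath = c(intervention = 66.42, comparator = 129.21),
    histopath_se = c(intervention = 0.55, comparator = 1.45),
    comm_arm = c(intervention = 18.97, comparator = 73.16),
    comm_arm_se = c(intervention = 0.92, comparator = 1.48),
    comm_pathway = c(A = 8, C = 52.4, D = 52.4, G = 131.1),
    origin = c(clinical = "arm-level clinical-diagnosis summary",
               histopath = "arm-level histopathology summary",
               comm_arm = "arm-level weighted communication summary",
               comm_pathway = "per-pathway communication means")
  ), class = "anchor_set")
}

#' Solve for unprinted pathway means from a weighted average
#'
#' Given the overall weighted mean of an arm and the means of some of its
#' pathways, solves for the missing mean(s) so that `sum(p_i * t_i)` equals
#' the overall mean. All unknown pathways take a single common value (the
#' tie rule); supply all but one mean (or tie the unknowns deliberately, as
#' for the cancelled-biopsy pathway E, whose mean is tied to B).
#'
#' @param overall the arm-level weighted mean (days).
#' @param proportions an [arm_distribution()] (or named proportions).
#' @param known_means named vector of known per-pathway means.
#' @return named vector of solved means for the unknown pathways (all
#'   equal). Errors if the unknowns carry zero proportion or the solution is
#'   negative (infeasible anchors).
#' @export
solve_missing_pathway_mean <- function(overall, proportions, known_means) {
  ids <- names(proportions)
  unknown <- setdiff(ids, names(known_means))
  if (!length(unknown)) {
    stop("no unknown pathway mean to solve for", call. = FALSE)
  }
  p_unknown <- sum(proportions[unknown])
  if (p_unknown <= 0) {
    stop("unknown pathway(s) carry zero proportion; mean is unidentifiable",
         call. = FALSE)
  }
  known <- intersect(ids, names(known_means))
  x <- (overall - sum(proportions[known] * known_means[known])) / p_unknown
  if (x < 0) {
    stop("solved mean is negative (", format(x),
         "); anchors are infeasible for these proportions", call. = FALSE)
  }
  stats::setNames(rep(x, length(unknown)), unknown)
}

#' Per-pathway communication targets implied by the anchors
#'
#' Pathway A, the combined C&D pathways and pathway G have published
#' communication means; the remaining pathway means (B, with E tied to B,
#' and F) are obtained with [solve_missing_pathway_mean()] against the
#' arm-level weighted means.
#'
#' @param arm `"intervention"` or `"comparator"`.
#' @param dist the pathway distribution used for the weighted average.
#' @param anchors an [anchor_set()].
#' @return named vector of per-pathway communication means (days).
#' @export
communication_targets <- function(arm = c("intervention", "comparator"),
                                  dist = referral_distribution(arm, "des"),
                                  anchors = anchor_set()) {
  arm <- match.arg(arm)
  known <- anchors$comm_pathway[intersect(names(dist),
                                          names(anchors$comm_pathway))]
  solved <- solve_missing_pathway_mean(anchors$comm_arm[[arm]], dist, known)
  out <- c(known, solved)
  out[names(dist)]
}

# --- analytic stage-mean assignment -----------------------------------------

# split a chain total over named delays by fixed ratios
split_chain <- function(total, ratios) {
  stats::setNames(total * ratios / sum(ratios), names(ratios))
}

#' Baseline arm configuration with analytic stage means
#'
#' Builds the shipped configuration of either arm with delay means assigned
#' analytically from the anchors in the no-congestion limit: the shared
#' referral-to-triage chain sums to the clinical-diagnosis anchor (minus
#' staffed service time), the intervention's shared communication delay is
#' the pathway A margin over clinical diagnosis, and each pathway tail
#' absorbs the remainder of its communication (or, for the histopathology
#' profile, histopathological-diagnosis) target. Under rota constraints and
#' queueing these analytic means leave a small positive bias that
#' [calibrate_arm()] removes by simulation.
#'
#' The intervention's published C&D communication mean (52.4 d) is smaller
#' than its histopathology mean (66.42 d), which no single monotone
#' configuration can satisfy; `profile` selects which endpoint the biopsy
#' chains of C and D are anchored to. The comparator anchors are mutually
#' consistent, so its single configuration serves both profiles.
#'
#' @param arm `"intervention"` or `"comparator"`.
#' @param analysis which pathway distribution to use (`"des"` or `"cca"`).
#' @param profile `"communication"` or `"histopathology"` (intervention
#'   only; see Details).
#' @param anchors an [anchor_set()].
#' @param annual_volume expected referrals per year.
#' @param cv coefficient of variation of every stage delay.
#' @param staffing named staffing counts (see [default_staffing()]).
#' @param calendar a [rota_calendar()].
#' @return an [arm_config()].
#' @export
default_arm_config <- function(arm = c("intervention", "comparator"),
                               analysis = "des",
                               profile = c("communication",
                                           "histopathology"),
                               anchors = anchor_set(),
                               annual_volume = 3000,
                               cv = 0.5,
                               staffing = default_staffing(),
                               calendar = rota_calendar()) {
  arm <- match.arg(arm)
  profile <- match.arg(profile)
  dist <- referral_distribution(arm, analysis)
  acts <- default_activities()
  srv <- function(a) minutes_to_days(acts[[a]]$duration)
  comm_t <- communication_targets(arm, dist, anchors)
  clin <- anchors$clinical[[arm]]
  histo <- anchors$histopath[[arm]]

  # in the deterministic limit (cv = 0) communication delays are
  # method-independent, so the configuration is exactly reproducible
  rel <- if (cv == 0) {
    c(email = 1, telephone = 1, letter = 1, f2f_appointment = 1)
  } else {
    c(email = 0.3, telephone = 0.5, letter = 1, f2f_appointment = 3)
  }
  cspec <- function(mean, mix) comm_spec(mean, mix, cv = cv, rel = rel)
  if (arm == "intervention") {
    comm_mean <- comm_t[["A"]] - clin          # one free scale per arm
    chain <- clin - srv("photography") - srv("remote_review")
    delays <- list(
      img_wait = delay_spec(chain * 2 / 3, cv),
      review_wait = delay_spec(chain * 1 / 3, cv),
      fu_wait_B = delay_spec(
        max(comm_t[["B"]] - clin - comm_mean - srv("f2f_followup"), 0.05),
        cv),
      cancel_wait_E = delay_spec(
        max(comm_t[["E"]] - clin - comm_mean, 0.05), cv)
    )
    tail_C <- if (profile == "communication") {
      comm_t[["C"]] - clin - comm_mean
    } else {
      histo - clin
    }
    tail_C <- tail_C - srv("f2f_followup") - srv("biopsy")
    sc <- split_chain(tail_C, c(fu_wait_C = 0.15, biopsy_wait_C = 0.35,
                                histo_wait_C = 0.5))
    tail_D <- if (profile == "communication") {
      comm_t[["D"]] - clin - comm_mean
    } else {
      histo - clin
    }
    tail_D <- tail_D - srv("biopsy")
    sd_ <- split_chain(tail_D, c(biopsy_wait_D = 0.4, histo_wait_D = 0.6))
    for (nm in names(sc)) delays[[nm]] <- delay_spec(sc[[nm]], cv)
    for (nm in names(sd_)) delays[[nm]] <- delay_spec(sd_[[nm]], cv)
    mix_fast <- c(email = 0.55, letter = 0.25, telephone = 0.2)
    mix_biop <- c(letter = 0.4, email = 0.2, telephone = 0.2,
                  f2f_appointment = 0.2)
    communication <- list(
      A = cspec(comm_mean, mix_fast), B = cspec(comm_mean, mix_fast),
      C = cspec(comm_mean, mix_biop), D = cspec(comm_mean, mix_biop),
      E = cspec(comm_mean, mix_fast)
    )
  } else {
    chain <- clin - srv("f2f_consult")
    delays <- list(consult_wait = delay_spec(chain, cv))
    tail_G <- histo - clin - srv("biopsy")
    sg <- split_chain(tail_G, c(biopsy_wait_G = 0.35, histo_wait_G = 0.65))
    for (nm in names(sg)) delays[[nm]] <- delay_spec(sg[[nm]], cv)
    communication <- list(
      F = cspec(comm_t[["F"]] - clin,
                c(letter = 0.7, telephone = 0.2, email = 0.1)),
      G = cspec(comm_t[["G"]] - histo,
                c(letter = 0.5, f2f_appointment = 0.3, telephone = 0.2))
    )
  }
  arm_config(
    arm = arm,
    distribution = dist,
    pathways = default_pathways(arm),
    delays = delays,
    communication = communication,
    activities = acts,
    staffing = staffing,
    arrivals = arrival_process(annual_volume),
    calendar = calendar
  )
}

# --- simulation-based calibration -------------------------------------------

# scale the delays in `names` so their total mean shifts by `shift` days
shift_delay_group <- function(delays, names, shift, floor_mean = 0.02) {
  tot <- sum(vapply(delays[names], function(d) d$mean, 0))
  f <- (tot + shift) / tot
  infeasible <- FALSE
  for (nm in names) {
    m <- delays[[nm]]$mean * f
    if (m < floor_mean) { m <- floor_mean; infeasible <- TRUE }
    delays[[nm]] <- delay_spec(m, delays[[nm]]$cv, delays[[nm]]$family)
  }
  attr(delays, "infeasible") <- infeasible
  delays
}

#' Calibrate an arm configuration against the anchors
#'
#' Refines the analytically assigned stage delay means by simulation so
#' that the simulated endpoint means match the anchors under the configured
#' staffing, rota windows and congestion. Because each endpoint mean is
#' additive in the upstream delay means with unit slope, every iteration
#' simulates the arm, measures the residual of each calibration group
#' (shared referral-to-triage chain, shared communication delay, per-pathway
#' tails) and rescales the group's delay means to absorb the residual; this
#' converges in one or two iterations up to Monte Carlo noise, and stops
#' once every residual is within `tolerance` or within twice its own
#' simulation SE.
#'
#' @param config an [arm_config()] (typically [default_arm_config()]).
#' @param anchors an [anchor_set()].
#' @param profile which endpoint the intervention's biopsy chains are
#'   anchored to (see [default_arm_config()]).
#' Because the residual of a low-volume pathway is measured with
#' appreciable Monte Carlo error, each iteration doubles the number of
#' replications (capped at `n_rep_max`), so successive corrections carry
#' less noise and the iteration settles instead of random-walking.
#'
#' @param tolerance target absolute residual in days; a group is also
#'   accepted when its residual is within twice its own simulation SE.
#' @param n_rep replications in the first calibration iteration; doubled
#'   each iteration up to `n_rep_max`.
#' @param n_rep_max cap on replications per iteration.
#' @param max_iter iteration cap; non-convergence raises a warning.
#' @param seed RNG seed for the calibration simulations.
#' @return an object of class `arm_calibration`: `config` (calibrated),
#'   `report` (data frame of group, target, achieved, se, residual),
#'   `converged`, `iterations`.
#' @export
calibrate_arm <- function(config, anchors = anchor_set(),
                          profile = c("communication", "histopathology"),
                          tolerance = 0.1, n_rep = 3, n_rep_max = 12,
                          max_iter = 5, seed = 1L) {
  profile <- match.arg(profile)
  arm <- config$arm
  dist <- config$distribution
  comm_t <- communication_targets(arm, dist, anchors)
  clin_t <- anchors$clinical[[arm]]
  histo_t <- anchors$histopath[[arm]]

  clin_group <- if (arm == "intervention") c("img_wait", "review_wait")
                else "consult_wait"
  tails <- if (arm == "intervention") {
    list(B = "fu_wait_B",
         C = c("fu_wait_C", "biopsy_wait_C", "histo_wait_C"),
         D = c("biopsy_wait_D", "histo_wait_D"),
         E = "cancel_wait_E")
  } else {
    list(G = c("biopsy_wait_G", "histo_wait_G"))
  }
  tail_endpoint <- function(pw) {
    if (arm == "intervention" && profile == "histopathology" &&
        pw %in% c("C", "D")) "histopath_diagnosis" else "communication"
  }
  tail_target <- function(pw) {
    if (tail_endpoint(pw) == "histopath_diagnosis") histo_t
    else comm_t[[pw]]
  }

  report <- NULL
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    reps <- min(n_rep * 2^(iter - 1L), n_rep_max)
    sims <- replicate_arm(config, n_runs = reps,
                          master_seed = seed + iter - 1L)
    sm <- sims$summary
    pwt <- sm$pathways
    get_pw <- function(pw, ep, what) {
      r <- pwt[pwt$pathway == pw & pwt$endpoint == ep, ]
      if (nrow(r) == 0L || r$n == 0L) NA_real_ else r[[what]]
    }
    clin_row <- sm$endpoints[sm$endpoints$endpoint == "clinical_diagnosis", ]
    resid_clin <- clin_t - clin_row$mean

    rows <- data.frame(group = "clinical", pathway = NA_character_,
                       endpoint = "clinical_diagnosis", target = clin_t,
                       achieved = clin_row$mean, se = clin_row$se,
                       residual = resid_clin, stringsAsFactors = FALSE)

    resid_comm_shared <- 0
    if (arm == "intervention") {
      a_comm <- get_pw("A", "communication", "mean")
      a_se <- get_pw("A", "communication", "se")
      resid_comm_shared <- (comm_t[["A"]] - a_comm) - resid_clin
      rows <- rbind(rows, data.frame(
        group = "communication", pathway = "A", endpoint = "communication",
        target = comm_t[["A"]], achieved = a_comm, se = a_se,
        residual = resid_comm_shared, stringsAsFactors = FALSE))
    }
    for (pw in names(tails)) {
      ep <- tail_endpoint(pw)
      ach <- get_pw(pw, ep, "mean"); se <- get_pw(pw, ep, "se")
      resid <- (tail_target(pw) - ach) - resid_clin -
        if (ep == "communication" && arm == "intervention")
          resid_comm_shared else 0
      rows <- rbind(rows, data.frame(
        group = paste0("tail_", pw), pathway = pw, endpoint = ep,
        target = tail_target(pw), achieved = ach, se = se,
        residual = resid, stringsAsFactors = FALSE))
    }
    if (arm == "comparator") {
      # comparator communication delays are pinned per pathway
      for (pw in names(dist)) {
        ach <- get_pw(pw, "communication", "mean")
        se <- get_pw(pw, "communication", "se")
        upstream <- resid_clin +
          if (pw %in% names(tails))
            rows$residual[rows$group == paste0("tail_", pw)] else 0
        rows <- rbind(rows, data.frame(
          group = paste0("comm_", pw), pathway = pw,
          endpoint = "communication", target = comm_t[[pw]],
          achieved = ach, se = se,
          residual = (comm_t[[pw]] - ach) - upstream,
          stringsAsFactors = FALSE))
      }
    }
    report <- rows
    ok <- abs(rows$residual) <= pmax(tolerance, 2 * rows$se)
    if (all(ok, na.rm = TRUE) && !anyNA(rows$achieved)) {
      converged <- TRUE
      break
    }

    # apply the corrections
    config$delays <- shift_delay_group(config$delays, clin_group, resid_clin)
    if (arm == "intervention") {
      for (pw in names(config$communication)) {
        cs <- config$communication[[pw]]
        config$communication[[pw]] <-
          comm_spec(max(cs$mean + resid_comm_shared, 0.02), cs$mix, cs$cv,
                    rel = cs$rel)
      }
    }
    for (pw in names(tails)) {
      r <- rows$residual[rows$group == paste0("tail_", pw)]
      if (!is.na(r)) {
        config$delays <- shift_delay_group(config$delays, tails[[pw]], r)
      }
    }
    if (arm == "comparator") {
      for (pw in names(dist)) {
        r <- rows$residual[rows$group == paste0("comm_", pw)]
        cs <- config$communication[[pw]]
        if (!is.na(r)) {
          config$communication[[pw]] <-
            comm_spec(max(cs$mean + r, 0.02), cs$mix, cs$cv, rel = cs$rel)
        }
      }
    }
  }
  if (!converged) {
    warning("calibration did not converge within ", max_iter,
            " iterations; largest residual ",
            format(max(abs(report$residual), na.rm = TRUE), digits = 3),
            " d", call. = FALSE)
  }
  structure(list(config = config, report = report, converged = converged,
                 iterations = iter, profile = profile),
            class = "arm_calibration")
}

#' @export
print.arm_calibration <- function(x, ...) {
  cat("<arm_calibration> ", x$config$arm, " (", x$profile, " profile): ",
      x$iterations, " iteration(s), ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  print(x$report, digits = 4)
  invisible(x)
}

# --- synthetic cohort --------------------------------------------------------

#' Generate a synthetic patient cohort
#'
#' Referral records emulating the evaluated service's cohort: age drawn from
#' a normal distribution with mean 61.5 and SD 17.6 years truncated at 18
#' (adult urgent-suspected-cancer referrals), sex female with probability
#' 0.575, pathway sampled from the arm's distribution, referral times
#' uniform over the horizon. Seed-reproducible; `n = 0` returns an empty
#' table with all columns.
#'
#' @param n number of referrals.
#' @param seed RNG seed.
#' @param arm `"intervention"` or `"comparator"`.
#' @param distribution pathway distribution (defaults to the simulation
#'   distribution of `arm`).
#' @param demographics list with `age_mean`, `age_sd`, `age_min`,
#'   `p_female`.
#' @param horizon_days referral window length in days.
#' @return data frame with `id`, `arm`, `pathway`, `referral_time`, `age`,
#'   `sex`.
#' @export
generate_cohort <- function(n, seed = 1L,
                            arm = c("intervention", "comparator"),
                            distribution = NULL,
                            demographics = default_demographics(),
                            horizon_days = 365) {
  stopifnot(n >= 0)
  arm <- match.arg(arm)
  if (is.null(distribution)) distribution <- referral_distribution(arm, "des")
  set.seed(seed)
  if (n == 0L) {
    return(data.frame(id = integer(), arm = character(),
                      pathway = character(), referral_time = numeric(),
                      age = numeric(), sex = character(),
                      stringsAsFactors = FALSE))
  }
  pw <- sample(names(distribution), n, replace = TRUE,
               prob = as.numeric(distribution) / sum(distribution))
  data.frame(
    id = seq_len(n),
    arm = arm,
    pathway = pw,
    referral_time = sort(stats::runif(n, 0, horizon_days)),
    age = rtruncnorm(n, demographics$age_mean, demographics$age_sd,
                     lower = demographics$age_min),
    sex = ifelse(stats::runif(n) < demographics$p_female, "female", "male"),
    stringsAsFactors = FALSE
  )
}

#' Write a cohort to CSV (header always present)
#'
#' @param cohort a [generate_cohort()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
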