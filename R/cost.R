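#' Cost comparison analysis
#'
#' The cost model compares the direct cost per referral, from referral to
#' diagnosis, between the teledermatology intervention and face-to-face
#' standard care. Each arm's mean cost per referral is the dot product of
#' its pathway distribution with the per-pathway unit costs; the incremental
#' saving is the comparator mean minus the intervention mean. Uncertainty is
#' handled with a Monte Carlo probabilistic sensitivity analysis (PSA) and a
#' one-way deterministic sensitivity analysis (DSA).
#'
#' @name cost_model
NULL

#' Cost model parameters
#'
#' @param unit_costs named vector of per-pathway unit costs in GBP.
#' @param dist_intervention,dist_comparator [arm_distribution()]s; defaults
#'   are the cost-analysis distributions.
#' @param n_referrals size of the intervention cohort used to scale the
#'   per-referral saving to an overall saving.
#' @param psa_se_frac PSA uncertainty spec: each pathway unit cost is drawn
#'   from a normal distribution centred on its baseline value with standard
#'   error `psa_se_frac` times the cost, truncated at zero. Pathway
#'   proportions are held fixed. Set to 0 for a degenerate (deterministic)
#'   PSA.
#' @param inflation_index named numeric vector mapping year (as character)
#'   to a price index used by [inflate_cost()].
#' @return an object of class `cost_model_params`.
#' @export
cost_model_params <- function(unit_costs = default_unit_costs(),
                              dist_intervention =
                                referral_distribution("intervention", "cca"),
                              dist_comparator =
                                referral_distribution("comparator", "cca"),
                              n_referrals = 563,
                              psa_se_frac = 0.12,
                              inflation_index = NULL) {
  if (any(unit_costs < 0)) stop("unit costs must be >= 0", call. = FALSE)
  if (n_referrals <= 0) stop("`n_referrals` must be > 0", call. = FALSE)
  if (psa_se_frac < 0) stop("`psa_se_frac` must be >= 0", call. = FALSE)
  structure(
    list(unit_costs = unit_costs,
         dist_intervention = dist_intervention,
         dist_comparator = dist_comparator,
         n_referrals = n_referrals,
         psa_se_frac = psa_se_frac,
         inflation_index = inflation_index),
    class = "cost_model_params"
  )
}

#' Cost of one staffed activity
#'
#' Linear proration of the staff hourly rate over the activity duration plus
#' any procedure-tariff or licensing add-on.
#'
#' @param duration minutes of staff time, `>= 0`.
#' @param rate staff hourly rate in GBP, `>= 0`.
#' @param add_on additive cost in GBP (procedure tariff, licence share).
#' @return cost in GBP.
#' @export
activity_cost <- function(duration, rate, add_on = 0) {
  if (any(duration < 0) || any(rate < 0) || any(add_on < 0)) {
    stop("`duration`, `rate` and `add_on` must be non-negative",
         call. = FALSE)
  }
  duration / 60 * rate + add_on
}

#' Bottom-up unit cost of a pathway
#'
#' Sums [activity_cost()] over the staffed activities of a pathway's stage
#' list. The baseline analyses use published unit costs directly; this
#' decomposition supports what-if costing when staff rates or durations
#' change.
#'
#' @param pathway a [pathway_definition()].
#' @param activities,staff activity and staff definitions (see
#'   [default_activities()], [default_staff()]).
#' @return cost in GBP.
#' @export
pathway_bottom_up_cost <- function(pathway, activities = default_activities(),
                                   staff = default_staff()) {
  steps <- Filter(function(s) s$kind == "service", pathway$stages)
  sum(vapply(steps, function(s) {
    a <- activities[[s$ref]]
    activity_cost(a$duration, staff[[a$role]]$hourly_rate,
                  a$procedure_cost + a$license_cost)
  }, 0))
}

#' Mean cost per referral of an arm
#'
#' Exact dot product of the pathway proportions with the unit costs. When a
#' published percentage table sums to 99% after rounding the dot product is
#' taken as printed, without renormalisation.
#'
#' @param dist an [arm_distribution()].
#' @param unit_costs named vector of unit costs covering every pathway in
#'   `dist`.
#' @return mean cost per referral in GBP.
#' @export
arm_mean_cost <- function(dist, unit_costs) {
  ids <- names(dist)
  miss <- setdiff(ids, names(unit_costs))
  if (length(miss)) {
    stop("missing unit cost for pathway(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  sum(as.numeric(dist) * unit_costs[ids])
}

#' Incremental saving per referral
#'
#' @param comparator_mean,intervention_mean mean cost per referral (GBP).
#' @return comparator minus intervention; positive values are savings.
#' @export
incremental_saving <- function(comparator_mean, intervention_mean) {
  stopifnot(is.finite(comparator_mean), is.finite(intervention_mean))
  comparator_mean - intervention_mean
}

#' Scale a per-referral saving to the cohort
#'
#' @param per_referral saving per referral (GBP).
#' @param n_referrals number of referrals.
#' @return overall saving in GBP.
#' @export
total_saving <- function(per_referral, n_referrals) {
  stopifnot(n_referrals >= 0)
  per_referral * n_referrals
}

#' Unpaired t test on per-referral costs
#'
#' Welch's unequal-variance test by default (`stats::t.test`); Student's
#' pooled-variance variant available via `var_equal = TRUE`. Degenerate
#' samples (fewer than two observations or zero variance in both samples)
#' are flagged as an error.
#'
#' @param costs_a,costs_b numeric cost samples.
#' @param var_equal use the pooled-variance (Student) test instead of Welch.
#' @return list with `t`, `p`, `df`, `method`.
#' @export
welch_t_test <- function(costs_a, costs_b, var_equal = FALSE) {
  if (length(costs_a) < 2 || length(costs_b) < 2) {
    stop("each sample needs at least two observations", call. = FALSE)
  }
  if (stats::var(costs_a) == 0 && stats::var(costs_b) == 0) {
    if (isTRUE(all.equal(mean(costs_a), mean(costs_b)))) {
      # identical constants: no evidence of any difference
      return(list(t = 0, p = 1, df = NA_real_,
                  method = "degenerate (zero variance)"))
    }
    stop("both samples have zero variance; t test is undefined",
         call. = FALSE)
  }
  ht <- stats::t.test(costs_a, costs_b, var.equal = var_equal)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), method = ht$method)
}

#' Draw a synthetic per-referral cost sample from an arm's pathway mixture
#'
#' Assigns each referral a pathway from the arm's distribution and the
#' pathway's unit cost; used to feed the unpaired t test at the two cohort
#' sizes.
#'
#' @param params a [cost_model_params()].
#' @param arm `"intervention"` or `"comparator"`.
#' @param n sample size.
#' @param seed RNG seed.
#' @return data frame with `patient_id`, `arm`, `pathway`, `cost`.
#' @export
sample_referral_costs <- function(params, arm = c("intervention",
                                                  "comparator"),
                                  n, seed = 1L) {
  arm <- match.arg(arm)
  dist <- if (arm == "intervention") params$dist_intervention
          else params$dist_comparator
  set.seed(seed)
  pw <- sample(names(dist), n, replace = TRUE,
               prob = as.numeric(dist) / sum(dist))
  data.frame(patient_id = seq_len(n), arm = arm, pathway = pw,
             cost = unname(params$unit_costs[pw]),
             stringsAsFactors = FALSE)
}

# inverse-CDF draw from a normal truncated below at `lower`
rtruncnorm <- function(n, mean, sd, lower = 0) {
  if (sd == 0) return(rep(mean, n))
  p0 <- stats::pnorm(lower, mean, sd)
  stats::qnorm(stats::runif(n, p0, 1), mean, sd)
}

#' Probabilistic sensitivity analysis
#'
#' Per iteration, draws every pathway unit cost from its uncertainty spec
#' (normal, SE = `psa_se_frac` x cost, truncated at 0), recomputes both arm
#' means and the incremental saving. Pathway proportions are held fixed.
#' Reproducible under a fixed seed.
#'
#' @param params a [cost_model_params()].
#' @param n_iter number of Monte Carlo iterations (1000 in the baseline
#'   analysis).
#' @param seed RNG seed.
#' @return an object of class `psa_result`: `per_iteration_savings`, `mean`,
#'   `ci95` (2.5/97.5 percentiles), `prob_saving_positive`, `n_iter`, `seed`.
#' @export
run_psa <- function(params, n_iter = 1000, seed = 1L) {
  stopifnot(inherits(params, "cost_model_params"), n_iter >= 1)
  set.seed(seed)
  ids_i <- names(params$dist_intervention)
  ids_c <- names(params$dist_comparator)
  ids <- union(ids_i, ids_c)
  base <- params$unit_costs[ids]
  se <- params$psa_se_frac * base
  draws <- matrix(NA_real_, nrow = n_iter, ncol = length(ids),
                  dimnames = list(NULL, ids))
  for (j in seq_along(ids)) {
    draws[, j] <- rtruncnorm(n_iter, base[[j]], se[[j]], lower = 0)
  }
  pi_ <- as.numeric(params$dist_intervention)
  pc_ <- as.numeric(params$dist_comparator)
  savings <- drop(draws[, ids_c, drop = FALSE] %*% pc_ -
                  draws[, ids_i, drop = FALSE] %*% pi_)
  ci <- unname(stats::quantile(savings, c(0.025, 0.975), type = 7))
  structure(
    list(per_iteration_savings = savings,
         mean = mean(savings),
         ci95 = ci,
         prob_saving_positive = mean(savings > 0),
         n_iter = n_iter, seed = seed),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf(
    "<psa_result> %d iterations (seed %s)\n  mean saving/referral: %.2f GBP (95%% CI %.2f-%.2f)\n  P(saving > 0): %.1f%%\n",
    x$n_iter, format(x$seed), x$mean, x$ci95[1], x$ci95[2],
    100 * x$prob_saving_positive))
  invisible(x)
}

# apply a one-way parameter setting to cost model params -----------------

set_cost_parameter <- function(params, parameter, value) {
  if (grepl("^unit_cost\\.", parameter)) {
    id <- sub("^unit_cost\\.", "", parameter)
    if (!id %in% names(params$unit_costs)) {
      stop("unknown pathway in `parameter`: ", id, call. = FALSE)
    }
    params$unit_costs[[id]] <- value
  } else if (grepl("^biopsy_share\\.", parameter)) {
    arm <- sub("^biopsy_share\\.", "", parameter)
    slot <- switch(arm,
                   intervention = "dist_intervention",
                   comparator = "dist_comparator",
                   stop("unknown arm in `parameter`: ", arm, call. = FALSE))
    d <- params[[slot]]
    biop <- intersect(names(d), c("C", "D", "G"))
    non <- setdiff(names(d), biop)
    if (!length(biop)) stop("arm has no biopsy-reliant pathway", call. = FALSE)
    if (value < 0 || value > sum(d)) {
      stop("biopsy share must lie in [0, total mass]", call. = FALSE)
    }
    old_b <- sum(d[biop]); old_n <- sum(d[non])
    d[biop] <- if (old_b > 0) d[biop] * value / old_b
               else rep(value / length(biop), length(biop))
    d[non] <- d[non] * (old_b + old_n - value) / old_n
    params[[slot]] <- arm_distribution(stats::setNames(as.numeric(d),
                                                       names(d)))
  } else if (parameter == "n_referrals") {
    params$n_referrals <- value
  } else {
    stop("unknown parameter: ", parameter, call. = FALSE)
  }
  params
}

deterministic_saving <- function(params) {
  incremental_saving(
    arm_mean_cost(params$dist_comparator, params$unit_costs),
    arm_mean_cost(params$dist_intervention, params$unit_costs)
  )
}

#' One-way deterministic sensitivity analysis
#'
#' Recomputes the deterministic saving with one parameter fixed at each
#' bound, all other parameters at baseline. Supported parameter labels:
#' `"unit_cost.<pathway>"` (set a pathway unit cost), `"biopsy_share.<arm>"`
#' (set the combined mass of biopsy-reliant pathways, redistributing within
#' the biopsy/non-biopsy groups proportionally), `"n_referrals"`.
#'
#' @param params a [cost_model_params()].
#' @param parameter parameter label.
#' @param low,high bounds with `low <= high`.
#' @return list with `parameter`, `base`, `saving_low`, `saving_high`
#'   (saving per referral at each bound).
#' @export
run_dsa <- function(params, parameter, low, high) {
  stopifnot(low <= high)
  list(parameter = parameter,
       base = deterministic_saving(params),
       saving_low = deterministic_saving(
         set_cost_parameter(params, parameter, low)),
       saving_high = deterministic_saving(
         set_cost_parameter(params, parameter, high)))
}

#' Tornado table over several parameters
#'
#' @param params a [cost_model_params()].
#' @param scenarios data frame with columns `parameter`, `low`, `high`.
#' @return data frame with one row per parameter, savings at each bound and
#'   the absolute swing, sorted by swing (tornado order).
#' @export
dsa_tornado <- function(params, scenarios) {
  rows <- lapply(seq_len(nrow(scenarios)), function(i) {
    r <- run_dsa(params, scenarios$parameter[i], scenarios$low[i],
                 scenarios$high[i])
    data.frame(parameter = r$parameter, base = r$base,
               saving_low = r$saving_low, saving_high = r$saving_high,
               swing = abs(r$saving_high - r$saving_low),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$swing), , drop = FALSE]
}

#' Adjust a cost between price years
#'
#' @param cost cost in GBP.
#' @param from_year,to_year price years present in `index`.
#' @param index named numeric vector mapping year to a price index (e.g.
#'   national unit-cost inflators).
#' @return `cost * index[to_year] / index[from_year]`.
#' @export
inflate_cost <- function(cost, from_year, to_year, index) {
  f <- as.character(from_year); t <- as.character(to_year)
  miss <- setdiff(c(f, t), names(index))
  if (length(miss)) {
    stop("year(s) missing from inflation index: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  cost * index[[t]] / index[[f]]
}

#' Full cost comparison analysis
#'
#' Deterministic arm means and incremental saving, the 1000-iteration PSA,
#' the overall saving scaled to the cohort, and the unpaired t test on
#' synthetic per-referral cost samples at the two cohort sizes.
#'
#' @param params a [cost_model_params()].
#' @param n_iter PSA iterations.
#' @param seed RNG seed.
#' @param n_comparator comparator cohort size for the t test.
#' @return an object of class `cca_result`.
#' @export
run_cca <- function(params = cost_model_params(), n_iter = 1000, seed = 1L,
                    n_comparator = 4011) {
  mean_i <- arm_mean_cost(params$dist_intervention, params$unit_costs)
  mean_c <- arm_mean_cost(params$dist_comparator, params$unit_costs)
  det <- incremental_saving(mean_c, mean_i)
  psa <- run_psa(params, n_iter = n_iter, seed = seed)
  ttest <- welch_t_test(
    sample_referral_costs(params, "intervention", params$n_referrals,
                          seed = seed)$cost,
    sample_referral_costs(params, "comparator", n_comparator,
                          seed = seed + 1L)$cost)
  structure(
    list(mean_intervention = mean_i, mean_comparator = mean_c,
         deterministic_saving = det, psa = psa,
         saving_per_referral = psa$mean,
         saving_ci95 = psa$ci95,
         overall_saving = total_saving(psa$mean, params$n_referrals),
         overall_ci95 = total_saving(psa$ci95, params$n_referrals),
         t_test = ttest, params = params),
    class = "cca_result"
  )
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf("<cca_result>\n  mean cost/referral: intervention %.2f, comparator %.2f GBP\n",
              x$mean_intervention, x$mean_comparator))
  cat(sprintf("  deterministic saving/referral: %.2f GBP\n",
              x$deterministic_saving))
  cat(sprintf("  PSA saving/referral: %.2f GBP (95%% CI %.2f-%.2f)\n",
              x$saving_per_referral, x$saving_ci95[1], x$saving_ci95[2]))
  cat(sprintf("  overall saving (n=%d): %.0f GBP (95%% CI %.0f-%.0f)\n",
              x$params$n_referrals, x$overall_saving, x$overall_ci95[1],
              x$overall_ci95[2]))
  cat(sprintf("  unpaired t test: t = %.2f, p %s\n", x$t_test$t,
              format.pval(x$t_test$p, eps = 0.001)))
  invisible(x)
}
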