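#' Render result tables
#'
#' Assembles the analysis outputs into the standard report tables: cost
#' savings (per referral and overall, with 95% CIs), per-pathway referral
#' percentages and unit costs, arm-level weighted communication times,
#' per-endpoint summaries, and the incremental waiting-time analysis.
#' Currency is rounded to 2 decimal places and days to 2 decimal places in
#' the rendered tables; all underlying objects keep full precision.
#'
#' @param cost a [run_cca()] result, or `NULL`.
#' @param sim_summaries named list of `sim_summary` objects (names =
#'   arm labels), or `NULL` to omit the simulation section.
#' @param incrementals an [incremental_times()] data frame, or `NULL`.
#' @param tornado a [dsa_tornado()] data frame, or `NULL`.
#' @return named list of data frames (class `dermflow_report`).
#' @export
render_results <- function(cost = NULL, sim_summaries = NULL,
                           incrementals = NULL, tornado = NULL) {
  if (is.null(cost) && is.null(sim_summaries)) {
    stop("at least one analysis result must be supplied", call. = FALSE)
  }
  tables <- list()
  if (!is.null(cost)) {
    tables$cost_savings <- data.frame(
      economic_parameter = c("cost_saving_per_referral",
                             "overall_cost_saving"),
      saving = round(c(cost$saving_per_referral, cost$overall_saving), 2),
      ci_low = round(c(cost$saving_ci95[1], cost$overall_ci95[1]), 2),
      ci_high = round(c(cost$saving_ci95[2], cost$overall_ci95[2]), 2),
      stringsAsFactors = FALSE
    )
    uc <- cost$params$unit_costs
    di <- cost$params$dist_intervention; dc <- cost$params$dist_comparator
    tables$pathway_costs <- data.frame(
      arm = c(rep("intervention", length(di)),
              rep("comparator", length(dc))),
      pathway = c(names(di), names(dc)),
      referral_pct = round(100 * c(as.numeric(di), as.numeric(dc)), 2),
      unit_cost = round(unname(uc[c(names(di), names(dc))]), 2),
      stringsAsFactors = FALSE
    )
  }
  if (!is.null(sim_summaries)) {
    tables$waiting_times <- do.call(rbind, lapply(names(sim_summaries),
      function(arm) {
        s <- sim_summaries[[arm]]
        w <- s$weighted
        comm <- s$endpoints[s$endpoints$endpoint == "communication", ]
        data.frame(arm = arm,
                   weighted_mean = round(if (!is.null(w)) w$mean
                                         else comm$mean, 2),
                   weighted_se = round(if (!is.null(w)) w$se else comm$se, 2),
                   max_time = round(comm$max, 2),
                   stringsAsFactors = FALSE)
      }))
    tables$endpoints <- do.call(rbind, lapply(names(sim_summaries),
      function(arm) {
        e <- sim_summaries[[arm]]$endpoints
        data.frame(arm = arm, endpoint = e$endpoint, n = e$n,
                   mean = round(e$mean, 2), se = round(e$se, 2),
                   ci_low = round(e$ci_low, 2), ci_high = round(e$ci_high, 2),
                   max = round(e$max, 2), stringsAsFactors = FALSE)
      }))
  }
  if (!is.null(incrementals)) {
    tables$incremental <- data.frame(
      endpoint = incrementals$endpoint,
      delta = round(incrementals$delta, 2),
      ci_low = round(incrementals$ci_low, 2),
      ci_high = round(incrementals$ci_high, 2),
      stringsAsFactors = FALSE
    )
  }
  if (!is.null(tornado)) {
    tables$tornado <- data.frame(
      parameter = tornado$parameter,
      base = round(tornado$base, 2),
      saving_low = round(tornado$saving_low, 2),
      saving_high = round(tornado$saving_high, 2),
      swing = round(tornado$swing, 2),
      stringsAsFactors = FALSE
    )
  }
  structure(tables, class = c("dermflow_report", "list"))
}

#' Write report tables to disk
#'
#' Each table is written as `<name>.csv`, and the whole set as
#' `results.json`.
#'
#' @param tables a [render_results()] list.
#' @param dir output directory (created if needed).
#' @return named character vector of written files, invisibly.
#' @export
write_report <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  for (nm in names(tables)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], f, row.names = FALSE)
    files[nm] <- f
  }
  jf <- file.path(dir, "results.json")
  jsonlite::write_json(lapply(tables, identity), jf, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  files["results_json"] <- jf
  invisible(files)
}

#' Run manifest
#'
#' Every pipeline output directory carries exactly one manifest recording
#' the command, configuration hashes, master and derived seeds, package
#' version and a timestamp, so a run can be reproduced exactly.
#'
#' @param command label of the invoking command.
#' @param config_paths named character vector of configuration files (hashed
#'   with MD5), or `NULL`.
#' @param seed master seed.
#' @param replication_seeds derived seeds, if any.
#' @return list of class `run_manifest`.
#' @export
run_manifest <- function(command, config_paths = NULL, seed = NA_integer_,
                         replication_seeds = NULL) {
  hashes <- if (!is.null(config_paths)) {
    stats::setNames(unname(tools::md5sum(config_paths)),
                    names(config_paths) %||% basename(config_paths))
  }
  structure(list(
    command = command,
    config = hashes,
    master_seed = seed,
    replication_seeds = replication_seeds,
    package_version = as.character(utils::packageVersion("dermflow")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest a `run_manifest` object.
#' @param dir output directory.
#' @export
write_manifest <- function(manifest, dir) {
  jsonlite::write_json(unclass(manifest), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file.path(dir, "manifest.json"))
}

#' End-to-end reproduction pipeline
#'
#' Runs the full analysis: the cost comparison (deterministic means, PSA,
#' DSA tornado, t test), then -- unless `skip_des` -- calibrates both arms,
#' simulates `replications` one-year instances of each, summarises the
#' waiting-time endpoints and the incremental analysis, and writes every
#' table plus a run manifest to `out_dir`. Deterministic under a fixed
#' seed: `results.json` is byte-identical across reruns.
#'
#' @param out_dir output directory.
#' @param seed master seed; every stage derives its own stream from it.
#' @param replications simulated one-year instances per arm.
#' @param annual_volume referrals per simulated year per arm.
#' @param skip_des run the cost analysis only.
#' @param n_iter PSA iterations.
#' @param intervention_config,comparator_config optional pre-built
#'   [arm_config()]s; defaults are the shipped baselines.
#' @param calibrate whether to calibrate the configs before simulating.
#' @return invisibly, a list with `manifest`, `tables`, `files`, and the
#'   underlying result objects.
#' @export
run_pipeline <- function(out_dir, seed = 1L, replications = 5,
                         annual_volume = 3000, skip_des = FALSE,
                         n_iter = 1000,
                         intervention_config = NULL,
                         comparator_config = NULL,
                         calibrate = TRUE) {
  stage <- "setup"
  result <- tryCatch({
    set.seed(seed)
    sub_seeds <- sample.int(.Machine$integer.max, 8)

    stage <- "cost"
    cca <- run_cca(seed = sub_seeds[1], n_iter = n_iter)
    stage <- "dsa"
    tornado <- dsa_tornado(cca$params, data.frame(
      parameter = c("unit_cost.G", "unit_cost.D",
                    "biopsy_share.intervention", "biopsy_share.comparator"),
      low = c(364 * 0.8, 542 * 0.8, 0.10, 0.39),
      high = c(364 * 1.2, 542 * 1.2, 0.50, 0.59),
      stringsAsFactors = FALSE))

    sims <- incr <- NULL
    if (!skip_des) {
      stage <- "calibrate"
      ic <- intervention_config %||%
        default_arm_config("intervention", annual_volume = annual_volume)
      cc <- comparator_config %||%
        default_arm_config("comparator", annual_volume = annual_volume)
      if (calibrate) {
        ic <- calibrate_arm(ic, seed = sub_seeds[2])$config
        cc <- calibrate_arm(cc, seed = sub_seeds[3])$config
      }
      stage <- "simulate"
      ri <- replicate_arm(ic, n_runs = replications,
                          master_seed = sub_seeds[4])
      rc <- replicate_arm(cc, n_runs = replications,
                          master_seed = sub_seeds[5])
      stage <- "summarise"
      sims <- list(intervention = ri$summary, comparator = rc$summary)
      incr <- incremental_times(ri$summary, rc$summary)
    }
    stage <- "render"
    tables <- render_results(cost = cca, sim_summaries = sims,
                             incrementals = incr, tornado = tornado)
    files <- write_report(tables, out_dir)
    manifest <- run_manifest("run_pipeline", seed = seed,
                             replication_seeds = sub_seeds)
    write_manifest(manifest, out_dir)
    list(manifest = manifest, tables = tables, files = files,
         cca = cca, sims = sims, incrementals = incr)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
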