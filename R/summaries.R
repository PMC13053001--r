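#' Waiting-time endpoint summaries
#'
#' The simulation measures three endpoints per patient, all in days from the
#' patient's own referral: time to clinical diagnosis (remote review or
#' face-to-face consultation), time to histopathological diagnosis (only for
#' patients on biopsy-reliant pathways) and time to diagnosis communication
#' (pathway exit).
#'
#' @param log pooled event log (`log` element of an [simulate_arm()] or
#'   [replicate_arm()] result).
#' @param dist optional [arm_distribution()]; when supplied, the
#'   pathway-proportion-weighted communication mean ([weighted_average_time()]
#'   with these weights) is included.
#' @param endpoints endpoint names to summarise.
#' @return an object of class `sim_summary` with elements `endpoints` (data
#'   frame: endpoint, n, mean, se, ci_low, ci_high, max), `pathways` (data
#'   frame: pathway, endpoint, n, mean, se), `weighted` (optional weighted
#'   communication mean and SE), `n_patients`.
#' @export
summarize_endpoints <- function(log, dist = NULL,
                                endpoints = c("clinical_diagnosis",
                                              "histopath_diagnosis",
                                              "communication")) {
  if (nrow(log) == 0L) stop("empty event log", call. = FALSE)
  one <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) {
      return(data.frame(n = 0L, mean = NA_real_, se = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        max = NA_real_))
    }
    m <- mean(x)
    se <- stats::sd(x) / sqrt(length(x))
    data.frame(n = length(x), mean = m, se = se,
               ci_low = m - 1.96 * se, ci_high = m + 1.96 * se,
               max = max(x))
  }
  ep_rows <- do.call(rbind, lapply(endpoints, function(e) {
    cbind(data.frame(endpoint = e, stringsAsFactors = FALSE),
          one(log[[paste0("t_", e)]]))
  }))
  # an endpoint with no eligible patients is reported as absent (n = 0,
  # NA statistics), never as zero
  pw_rows <- do.call(rbind, lapply(split(log, log$pathway), function(d) {
    do.call(rbind, lapply(endpoints, function(e) {
      cbind(data.frame(pathway = d$pathway[1], endpoint = e,
                       stringsAsFactors = FALSE),
            one(d[[paste0("t_", e)]])[, c("n", "mean", "se")])
    }))
  }))
  row.names(ep_rows) <- row.names(pw_rows) <- NULL
  weighted <- NULL
  if (!is.null(dist)) {
    cm <- pw_rows[pw_rows$endpoint == "communication" & pw_rows$n > 0, ]
    means <- stats::setNames(cm$mean, cm$pathway)
    ses <- stats::setNames(cm$se, cm$pathway)
    weighted <- weighted_average_time(means, dist, ses)
  }
  structure(list(endpoints = ep_rows, pathways = pw_rows,
                 weighted = weighted, n_patients = nrow(log),
                 n_replications = length(unique(log$replication %||% 1L))),
            class = "sim_summary")
}

#' @export
print.sim_summary <- function(x, ...) {
  cat("<sim_summary> ", x$n_patients, " patients\n", sep = "")
  e <- x$endpoints
  for (i in seq_len(nrow(e))) {
    if (e$n[i] == 0L) {
      cat(sprintf("  %-20s absent (no eligible patients)\n", e$endpoint[i]))
    } else {
      cat(sprintf("  %-20s mean %7.2f d (SE %.2f, 95%% CI %.2f-%.2f, max %.1f, n=%d)\n",
                  e$endpoint[i], e$mean[i], e$se[i], e$ci_low[i],
                  e$ci_high[i], e$max[i], e$n[i]))
    }
  }
  if (!is.null(x$weighted)) {
    cat(sprintf("  weighted communication mean %.2f d (SE %.2f)\n",
                x$weighted$mean, x$weighted$se))
  }
  invisible(x)
}

#' Pathway-proportion-weighted average waiting time
#'
#' Combines per-pathway mean times with the arm's pathway proportions:
#' the weighted mean is `sum(p_i * t_i)` (weights renormalised over the
#' pathways supplied must cover every pathway with positive proportion), and
#' the weighted SE is propagated from per-pathway SEs as
#' `sqrt(sum(p_i^2 * se_i^2))`.
#'
#' @param pathway_means named vector of per-pathway mean times (days).
#' @param dist an [arm_distribution()] (or named proportions).
#' @param pathway_ses optional named vector of per-pathway SEs.
#' @return list with `mean` and `se` (NA if no SEs supplied).
#' @export
weighted_average_time <- function(pathway_means, dist, pathway_ses = NULL) {
  ids <- names(dist)[as.numeric(dist) > 0]
  miss <- setdiff(ids, names(pathway_means))
  if (length(miss)) {
    stop("missing mean for pathway(s) with positive proportion: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  w <- as.numeric(dist[ids])
  m <- sum(w * pathway_means[ids])
  se <- NA_real_
  if (!is.null(pathway_ses) && all(ids %in% names(pathway_ses))) {
    se <- sqrt(sum(w^2 * pathway_ses[ids]^2))
  }
  list(mean = m, se = se)
}

#' Incremental waiting-time analysis between arms
#'
#' Per-endpoint difference in pooled means, comparator minus intervention
#' (positive = time saved by the intervention), with a 95% CI from the
#' combined SEs under a normal approximation.
#'
#' @param intervention,comparator `sim_summary` objects (see
#'   [summarize_endpoints()]).
#' @return data frame with `endpoint`, `delta`, `se`, `ci_low`, `ci_high`.
#' @export
incremental_times <- function(intervention, comparator) {
  stopifnot(inherits(intervention, "sim_summary"),
            inherits(comparator, "sim_summary"))
  ei <- intervention$endpoints; ec <- comparator$endpoints
  eps <- intersect(ei$endpoint, ec$endpoint)
  rows <- lapply(eps, function(e) {
    ri <- ei[ei$endpoint == e, ]; rc <- ec[ec$endpoint == e, ]
    if (ri$n == 0L || rc$n == 0L) {
      stop("endpoint ", e, " absent in one arm; cannot form the increment",
           call. = FALSE)
    }
    d <- rc$mean - ri$mean
    se <- sqrt(ri$se^2 + rc$se^2)
    data.frame(endpoint = e, delta = d, se = se,
               ci_low = d - 1.96 * se, ci_high = d + 1.96 * se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}
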