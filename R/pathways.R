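#' @title Referral pathways for the two service models
#'
#' @description
#' The intervention arm (community-based store-and-forward teledermatology)
#' routes every referral through a community photography appointment and a
#' remote consultant review, after which five outcomes are possible:
#'
#' * **A** — discharged directly after remote review;
#' * **B** — face-to-face follow-up, then discharged;
#' * **C** — face-to-face follow-up, then diagnostic biopsy;
#' * **D** — listed directly for diagnostic biopsy after remote review;
#' * **E** — diagnostic biopsy scheduled but cancelled (no histopathology).
#'
#' The comparator arm (standard of care) sends every referral to a
#' face-to-face consultant clinic, after which the patient is either
#' discharged (**F**) or undergoes a diagnostic biopsy (**G**).
#'
#' Pathways C, D and G are *biopsy-reliant*: their diagnosis requires a full
#' diagnostic biopsy and therefore a histopathological diagnosis endpoint.
#'
#' @name pathways
NULL

ENDPOINTS <- c("image_capture", "clinical_diagnosis", "biopsy",
               "histopath_diagnosis", "communication")

COMM_METHODS <- c("letter", "email", "telephone", "f2f_appointment")

# --- stage step constructors -------------------------------------------------

#' Pathway stage steps
#'
#' A pathway is an ordered list of steps. A *delay* step is an unstaffed
#' waiting period drawn from a named delay distribution in the arm
#' configuration; a *service* step is a staffed activity that queues for a
#' staff role within rota windows; a *comm* step is the terminal diagnosis
#' communication, whose delay is drawn from the pathway's communication
#' method mix. A step may mark a waiting-time `endpoint` recorded at its
#' completion.
#'
#' @param ref name of the delay spec (`step_delay`) or activity
#'   (`step_service`) in the arm configuration.
#' @param endpoint optional endpoint name, one of `"image_capture"`,
#'   `"clinical_diagnosis"`, `"biopsy"`, `"histopath_diagnosis"`,
#'   `"communication"`.
#' @return a list describing the step.
#' @export
step_delay <- function(ref, endpoint = NA_character_) {
  list(kind = "delay", ref = ref, endpoint = endpoint)
}

#' @rdname step_delay
#' @export
step_service <- function(ref, endpoint = NA_character_) {
  list(kind = "service", ref = ref, endpoint = endpoint)
}

#' @rdname step_delay
#' @export
step_comm <- function() {
  list(kind = "comm", ref = "communication", endpoint = "communication")
}

# --- pathway definition ------------------------------------------------------

#' Define a referral pathway
#'
#' @param id single letter pathway id (`A`--`E` intervention, `F`--`G`
#'   comparator by convention).
#' @param arm `"intervention"` or `"comparator"`.
#' @param stages ordered list of steps built with [step_delay()],
#'   [step_service()], [step_comm()]. The last step must be the
#'   communication step.
#' @param unit_cost direct cost per referral completing this pathway (GBP).
#' @param biopsy_reliant logical; if `NULL` (default), derived from whether
#'   the stages record a histopathological diagnosis endpoint. Supplying a
#'   value inconsistent with the stages is an error.
#' @return an object of class `pathway_definition`.
#' @export
pathway_definition <- function(id, arm, stages, unit_cost,
                               biopsy_reliant = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nchar(id) == 1L)
  arm <- match.arg(arm, c("intervention", "comparator"))
  if (!is.list(stages) || length(stages) == 0L) {
    stop("`stages` must be a non-empty list of steps", call. = FALSE)
  }
  last <- stages[[length(stages)]]
  if (!identical(last$endpoint, "communication")) {
    stop("the final stage of every pathway must record the communication ",
         "endpoint", call. = FALSE)
  }
  eps <- vapply(stages, function(s) s$endpoint %||% NA_character_, "")
  bad <- setdiff(eps[!is.na(eps)], ENDPOINTS)
  if (length(bad)) {
    stop("unknown endpoint(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(unit_cost) || unit_cost < 0) {
    stop("`unit_cost` must be >= 0", call. = FALSE)
  }
  structural <- "histopath_diagnosis" %in% eps
  if (is.null(biopsy_reliant)) {
    biopsy_reliant <- structural
  } else if (!identical(isTRUE(biopsy_reliant), structural)) {
    stop("`biopsy_reliant` flag contradicts the stage list of pathway ", id,
         call. = FALSE)
  }
  structure(
    list(id = id, arm = arm, stages = stages,
         unit_cost = as.numeric(unit_cost), biopsy_reliant = biopsy_reliant),
    class = "pathway_definition"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Baseline structural interpretation of pathways A--G
#'
#' Returns the shipped stage lists. The delay names referenced here are
#' defined in [default_arm_config()]; any of them can be overridden in a
#' configuration file.
#'
#' @param arm `"intervention"` or `"comparator"`.
#' @param unit_costs named vector of per-pathway unit costs; defaults to the
#'   published per-pathway unit costs (GBP, 2023).
#' @return named list of [pathway_definition()] objects.
#' @export
default_pathways <- function(arm = c("intervention", "comparator"),
                             unit_costs = default_unit_costs()) {
  arm <- match.arg(arm)
  shared_int <- list(
    step_delay("img_wait"),
    step_service("photography", endpoint = "image_capture"),
    step_delay("review_wait"),
    step_service("remote_review", endpoint = "clinical_diagnosis")
  )
  if (arm == "intervention") {
    list(
      A = pathway_definition("A", arm, c(shared_int, list(step_comm())),
                             unit_costs[["A"]]),
      B = pathway_definition("B", arm, c(shared_int, list(
            step_delay("fu_wait_B"), step_service("f2f_followup"),
            step_comm())), unit_costs[["B"]]),
      C = pathway_definition("C", arm, c(shared_int, list(
            step_delay("fu_wait_C"), step_service("f2f_followup"),
            step_delay("biopsy_wait_C"),
            step_service("biopsy", endpoint = "biopsy"),
            step_delay("histo_wait_C", endpoint = "histopath_diagnosis"),
            step_comm())), unit_costs[["C"]]),
      D = pathway_definition("D", arm, c(shared_int, list(
            step_delay("biopsy_wait_D"),
            step_service("biopsy", endpoint = "biopsy"),
            step_delay("histo_wait_D", endpoint = "histopath_diagnosis"),
            step_comm())), unit_costs[["D"]]),
      # biopsy scheduled then cancelled: waiting time but no procedure,
      # straight to communication afterwards
      E = pathway_definition("E", arm, c(shared_int, list(
            step_delay("cancel_wait_E"), step_comm())),
            unit_costs[["E"]])
    )
  } else {
    shared_comp <- list(
      step_delay("consult_wait"),
      step_service("f2f_consult", endpoint = "clinical_diagnosis")
    )
    list(
      F = pathway_definition("F", arm, c(shared_comp, list(step_comm())),
                             unit_costs[["F"]]),
      G = pathway_definition("G", arm, c(shared_comp, list(
            step_delay("biopsy_wait_G"),
            step_service("biopsy", endpoint = "biopsy"),
            step_delay("histo_wait_G", endpoint = "histopath_diagnosis"),
            step_comm())), unit_costs[["G"]])
    )
  }
}

#' Published per-pathway unit costs (GBP, 2023 prices)
#' @return named numeric vector over pathways A--G.
#' @export
default_unit_costs <- function() {
  c(A = 55, B = 219, C = 371, D = 542, E = 137, F = 163, G = 364)
}

# --- arm distribution --------------------------------------------------------

#' Pathway distribution of an arm
#'
#' @param proportions named numeric vector mapping pathway id to the fraction
#'   of referrals following it. Fractions must lie in `[0, 1]` and sum to 1
#'   within `tol`. The default tolerance accommodates published percentage
#'   tables that sum to 99% after rounding; such distributions are used as
#'   printed, without renormalisation.
#' @param tol allowed deviation of the sum from 1.
#' @return an object of class `arm_distribution` (a named numeric vector).
#' @export
arm_distribution <- function(proportions, tol = 0.015) {
  if (is.null(names(proportions)) || any(names(proportions) == "")) {
    stop("`proportions` must be a named vector of pathway fractions",
         call. = FALSE)
  }
  if (any(!is.finite(proportions)) || any(proportions < 0) ||
      any(proportions > 1)) {
    stop("pathway fractions must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(proportions) - 1) > tol) {
    stop("pathway fractions sum to ", format(sum(proportions)),
         ", not 1 (tolerance ", tol, ")", call. = FALSE)
  }
  structure(as.numeric(proportions), names = names(proportions),
            class = "arm_distribution")
}

#' Shipped pathway distributions
#'
#' Two distributions are shipped per arm: the distribution used by the cost
#' comparison analysis (`"cca"`) and the one used by the discrete event
#' simulation (`"des"`), which reflects six additional months of service
#' data. They differ and are both available by name.
#'
#' @param arm `"intervention"` or `"comparator"`.
#' @param analysis `"des"` (default) or `"cca"`.
#' @return an [arm_distribution()].
#' @export
referral_distribution <- function(arm = c("intervention", "comparator"),
                                  analysis = c("des", "cca")) {
  arm <- match.arg(arm)
  analysis <- match.arg(analysis)
  tab <- list(
    cca = list(
      intervention = c(A = 0.44, B = 0.21, C = 0.17, D = 0.14, E = 0.03),
      comparator   = c(F = 0.51, G = 0.49)
    ),
    des = list(
      intervention = c(A = 0.53, B = 0.24, C = 0.05, D = 0.17, E = 0.01),
      comparator   = c(F = 0.52, G = 0.48)
    )
  )
  arm_distribution(tab[[analysis]][[arm]])
}

# --- communication -----------------------------------------------------------

#' Communication method mix for a pathway
#'
#' Diagnosis is communicated by letter, email (via the platform), telephone
#' call or a face-to-face appointment. Each pathway has a mix over methods
#' and a mean communication delay; individual delays are drawn from a
#' lognormal whose mean is the pathway mean scaled by the method's relative
#' speed, so the mixture mean equals `mean` exactly.
#'
#' @param mean mean communication delay in days.
#' @param mix named fractions over `"letter"`, `"email"`, `"telephone"`,
#'   `"f2f_appointment"`, summing to 1.
#' @param cv coefficient of variation of the delay within a method.
#' @param rel named relative mean multipliers per method (letters slower than
#'   emails etc.); internally normalised against the mix.
#' @return an object of class `comm_spec`.
#' @export
comm_spec <- function(mean, mix = c(email = 0.5, letter = 0.25,
                                    telephone = 0.2, f2f_appointment = 0.05),
                      cv = 0.5,
                      rel = c(email = 0.3, telephone = 0.5, letter = 1,
                              f2f_appointment = 3)) {
  stopifnot(mean >= 0, cv >= 0)
  mix <- mix[mix > 0]
  if (!all(names(mix) %in% COMM_METHODS)) {
    stop("unknown communication method in `mix`", call. = FALSE)
  }
  if (abs(sum(mix) - 1) > 1e-9) {
    stop("communication method mix must sum to 1", call. = FALSE)
  }
  rel <- rel[names(mix)]
  # per-method means scaled so that sum(mix * method_mean) == mean
  method_mean <- mean * rel / sum(mix * rel)
  structure(list(mean = mean, mix = mix, cv = cv, rel = rel,
                 method_mean = method_mean),
            class = "comm_spec")
}

# --- arm configuration -------------------------------------------------------

#' Assemble a simulateable arm configuration
#'
#' An `arm_config` bundles everything needed to cost and simulate one arm:
#' its pathway distribution, pathway stage structure, activity and staff
#' definitions, staffing counts, stage delay distributions, communication
#' specs, arrival process and rota calendar.
#'
#' @param arm `"intervention"` or `"comparator"`.
#' @param distribution an [arm_distribution()] over this arm's pathways.
#' @param pathways named list of [pathway_definition()]s covering every
#'   pathway in `distribution`.
#' @param delays named list of [delay_spec()]s covering every delay name
#'   referenced by the pathway stages.
#' @param communication named list of [comm_spec()]s, one per pathway.
#' @param activities,staff activity and staff-role definitions.
#' @param staffing named integer vector of concurrent staff per role
#'   (weekday level); `Inf` is allowed for uncapacitated experiments.
#' @param arrivals an [arrival_process()].
#' @param calendar a [rota_calendar()].
#' @param priority named per-pathway integer priority class (1 = highest);
#'   all referrals are urgent suspected cancer so the default is a single
#'   class.
#' @return an object of class `arm_config`.
#' @export
arm_config <- function(arm, distribution, pathways, delays, communication,
                       activities = default_activities(),
                       staff = default_staff(),
                       staffing = default_staffing(),
                       arrivals = arrival_process(),
                       calendar = rota_calendar(),
                       priority = NULL) {
  arm <- match.arg(arm, c("intervention", "comparator"))
  ids <- names(distribution)
  missing_pw <- setdiff(ids, names(pathways))
  if (length(missing_pw)) {
    stop("unknown pathway id(s) in distribution: ",
         paste(missing_pw, collapse = ", "), call. = FALSE)
  }
  refs <- unique(unlist(lapply(pathways[ids], function(p) {
    vapply(Filter(function(s) s$kind == "delay", p$stages),
           function(s) s$ref, "")
  })))
  missing_d <- setdiff(refs, names(delays))
  if (length(missing_d)) {
    stop("missing delay spec(s): ", paste(missing_d, collapse = ", "),
         call. = FALSE)
  }
  acts <- unique(unlist(lapply(pathways[ids], function(p) {
    vapply(Filter(function(s) s$kind == "service", p$stages),
           function(s) s$ref, "")
  })))
  missing_a <- setdiff(acts, names(activities))
  if (length(missing_a)) {
    stop("missing activity definition(s): ",
         paste(missing_a, collapse = ", "), call. = FALSE)
  }
  missing_c <- setdiff(ids, names(communication))
  if (length(missing_c)) {
    stop("missing communication spec(s) for pathway(s): ",
         paste(missing_c, collapse = ", "), call. = FALSE)
  }
  if (is.null(priority)) priority <- stats::setNames(rep(1L, length(ids)), ids)
  structure(
    list(arm = arm, distribution = distribution, pathways = pathways[ids],
         delays = delays, communication = communication[ids],
         activities = activities, staff = staff, staffing = staffing,
         arrivals = arrivals, calendar = calendar, priority = priority),
    class = "arm_config"
  )
}

#' Default weekday staffing levels
#'
#' Concurrent staff per role on weekdays. Workforce counts for the modelled
#' service are not published; these defaults are sized so that baseline
#' utilisation stays well below 1 (a stability check warns otherwise) and
#' are fully configurable.
#'
#' @return named numeric vector.
#' @export
default_staffing <- function() {
  c(HCA_Band3 = 2, Band5 = 2, Band9 = 1, Consultant = 3, GP = 2)
}

#' @export
print.arm_config <- function(x, ...) {
  cat("<arm_config> ", x$arm, "\n", sep = "")
  cat("  pathways: ", paste(names(x$distribution), collapse = " "), "\n")
  cat("  proportions: ",
      paste(sprintf("%s=%.2f", names(x$distribution),
                    as.numeric(x$distribution)), collapse = " "), "\n")
  cat("  annual volume: ", x$arrivals$annual_volume, "\n", sep = "")
  invisible(x)
}

# --- routing graph -----------------------------------------------------------

#' Build the stage routing graph of an arm
#'
#' Merges the arm's pathway stage lists into a directed acyclic stage
#' network by common prefix: stages shared by several pathways (for the
#' comparator, the face-to-face consultation; for the intervention, the
#' photography appointment and remote review) become shared nodes, and
#' branch probabilities at each decision node are the conditional
#' probabilities of the pathway subsets passing through it. Every referral
#' reaches exactly one terminal communication node, and enumerating
#' root-to-terminal paths recovers the configured pathway distribution.
#'
#' @param config an [arm_config()].
#' @return an object of class `pathway_graph` with elements `nodes` (data
#'   frame: id, label, kind, terminal, pathway) and `edges` (data frame:
#'   from, to, prob).
#' @export
build_pathway_graph <- function(config) {
  stopifnot(inherits(config, "arm_config"))
  dist <- config$distribution
  ids <- names(dist)
  # sequences of step labels per pathway (label = kind:ref, comm labelled per
  # pathway so terminals stay distinct)
  seqs <- lapply(ids, function(id) {
    st <- config$pathways[[id]]$stages
    vapply(seq_along(st), function(j) {
      s <- st[[j]]
      if (s$kind == "comm") paste0("comm:", id)
      else paste0(s$kind, ":", s$ref)
    }, "")
  })
  names(seqs) <- ids

  nodes <- data.frame(id = "referral", label = "referral", kind = "root",
                      terminal = FALSE, pathway = NA_character_,
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = character(), to = character(),
                      prob = numeric(), stringsAsFactors = FALSE)

  # recursive prefix-merge: `active` = pathway ids sharing prefix up to parent
  build <- function(parent, active, depth, parent_mass) {
    nexts <- vapply(active, function(id) {
      if (depth > length(seqs[[id]])) NA_character_ else seqs[[id]][depth]
    }, "")
    groups <- split(active, nexts)
    for (lab in names(groups)) {
      grp <- groups[[lab]]
      mass <- sum(dist[grp])
      node_id <- paste0(lab, "@", depth, "/", paste(grp, collapse = ""))
      is_comm <- startsWith(lab, "comm:")
      nodes <<- rbind(nodes, data.frame(
        id = node_id, label = lab,
        kind = sub(":.*$", "", lab),
        terminal = is_comm,
        pathway = if (length(grp) == 1L) grp else NA_character_,
        stringsAsFactors = FALSE))
      edges <<- rbind(edges, data.frame(
        from = parent, to = node_id, prob = mass / parent_mass,
        stringsAsFactors = FALSE))
      if (!is_comm) build(node_id, grp, depth + 1L, mass)
    }
  }
  build("referral", ids, 1L, sum(dist))
  structure(list(nodes = nodes, edges = edges, distribution = dist),
            class = "pathway_graph")
}

#' Enumerate root-to-terminal paths of a pathway graph
#'
#' @param graph a `pathway_graph`.
#' @return data frame with one row per terminal node: `pathway` and the
#'   product of branch probabilities along its path (`prob`), scaled by the
#'   total configured mass.
#' @export
enumerate_paths <- function(graph) {
  edges <- graph$edges
  nodes <- graph$nodes
  total <- sum(graph$distribution)
  walk <- function(node, p) {
    out <- edges[edges$from == node, , drop = FALSE]
    if (nrow(out) == 0L) {
      pw <- nodes$pathway[nodes$id == node]
      return(data.frame(pathway = pw, prob = p * total,
                        stringsAsFactors = FALSE))
    }
    do.call(rbind, lapply(seq_len(nrow(out)), function(i) {
      walk(out$to[i], p * out$prob[i])
    }))
  }
  res <- walk("referral", 1)
  res[order(res$pathway), , drop = FALSE]
}

#' @export
print.pathway_graph <- function(x, ...) {
  term <- x$nodes[x$nodes$terminal, ]
  cat("<pathway_graph> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges, ", nrow(term), " terminal communication node(s)\n", sep = "")
  invisible(x)
}

#' Emit the arm's distribution/unit-cost table
#'
#' One row per pathway with referral percentage and unit cost, in the layout
#' of the published pathway tables.
#'
#' @param config an [arm_config()].
#' @return data frame with columns `arm`, `pathway`, `referral_pct`,
#'   `unit_cost`.
#' @export
pathway_table <- function(config) {
  ids <- names(config$distribution)
  data.frame(
    arm = config$arm,
    pathway = ids,
    referral_pct = round(100 * as.numeric(config$distribution), 2),
    unit_cost = vapply(config$pathways[ids], function(p) p$unit_cost, 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
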