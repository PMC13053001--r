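#' Staff rota calendar
#'
#' Weekday service windows run 08:30--18:30; weekends run the same window
#' with a reduced staff fraction. Day 0 of the simulation clock is a Monday,
#' so days with `day %% 7 >= 5` are weekend days. `always_open = TRUE`
#' removes the rota entirely (24/7 service at weekday capacity), which is
#' used by the closed-form verification limits.
#'
#' @param open_hour,close_hour window bounds in hours since midnight.
#' @param weekend_fraction fraction of weekday staff rostered at weekends.
#' @param always_open disable the rota (24/7 availability).
#' @return an object of class `rota_calendar`.
#' @export
rota_calendar <- function(open_hour = 8.5, close_hour = 18.5,
                          weekend_fraction = 0.7, always_open = FALSE) {
  stopifnot(open_hour >= 0, close_hour <= 24, open_hour < close_hour,
            weekend_fraction >= 0, weekend_fraction <= 1)
  structure(list(open_hour = open_hour, close_hour = close_hour,
                 weekend_fraction = weekend_fraction,
                 always_open = isTRUE(always_open)),
            class = "rota_calendar")
}

#' Per-role weekday and weekend server counts
#'
#' Weekday capacity equals the staffing count during the service window;
#' weekend capacity is `floor(weekend_fraction * count)` (rounding down, so
#' a single-handed service has no weekend cover), and zero for roles not
#' available at weekends (GPs).
#'
#' @param staff_counts named numeric vector of weekday concurrent staff per
#'   role; `Inf` allowed.
#' @param weekend_fraction fraction of staff rostered at weekends.
#' @param staff staff-role definitions (for weekend availability flags).
#' @param calendar a [rota_calendar()].
#' @return an object of class `capacity_calendar` with `weekday` and
#'   `weekend` named vectors plus the calendar.
#' @export
build_capacity_calendar <- function(staff_counts,
                                    weekend_fraction = 0.7,
                                    staff = default_staff(),
                                    calendar = rota_calendar(
                                      weekend_fraction = weekend_fraction)) {
  if (any(staff_counts < 0)) {
    stop("staff counts must be >= 0", call. = FALSE)
  }
  stopifnot(weekend_fraction >= 0, weekend_fraction <= 1)
  wknd <- floor(weekend_fraction * staff_counts)
  for (r in names(staff_counts)) {
    if (!is.null(staff[[r]]) && !staff[[r]]$weekend_available) wknd[[r]] <- 0
  }
  structure(list(weekday = staff_counts, weekend = wknd,
                 calendar = calendar),
            class = "capacity_calendar")
}

#' Seasonal referral arrival process
#'
#' Nonhomogeneous Poisson process over a 365-day year with
#' piecewise-constant monthly intensity proportional to `monthly_weights`
#' (normalised to sum to 12, so uniform weights give the annual volume
#' spread evenly). The expected total number of referrals equals
#' `annual_volume`.
#'
#' @param annual_volume expected referrals per year.
#' @param monthly_weights 12 non-negative weights (January--December).
#' @return an object of class `arrival_process`.
#' @export
arrival_process <- function(annual_volume = 3000,
                            monthly_weights = rep(1, 12)) {
  stopifnot(annual_volume > 0, length(monthly_weights) == 12)
  if (any(monthly_weights < 0)) {
    stop("monthly weights must be non-negative", call. = FALSE)
  }
  if (sum(monthly_weights) == 0) {
    stop("monthly weights must not all be zero", call. = FALSE)
  }
  structure(list(annual_volume = annual_volume,
                 monthly_weights = monthly_weights * 12 /
                   sum(monthly_weights)),
            class = "arrival_process")
}

MONTH_BOUNDS <- cumsum(c(0, 31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31))

#' Draw a referral arrival stream
#'
#' @param process an [arrival_process()].
#' @param seed optional RNG seed; if `NULL` the current RNG stream is used.
#' @return sorted numeric vector of arrival times in days from horizon
#'   start.
#' @export
generate_arrivals <- function(process, seed = NULL) {
  stopifnot(inherits(process, "arrival_process"))
  if (!is.null(seed)) set.seed(seed)
  lambda <- process$annual_volume * process$monthly_weights / 12
  times <- lapply(1:12, function(m) {
    n <- stats::rpois(1, lambda[m])
    stats::runif(n, MONTH_BOUNDS[m], MONTH_BOUNDS[m + 1])
  })
  sort(unlist(times))
}

#' Analytic staff utilisation check
#'
#' Offered load per role: expected service minutes per week divided by
#' rostered capacity minutes per week. Values near or above 1 make queues
#' grow without bound.
#'
#' @param config an [arm_config()].
#' @return named numeric vector of utilisations per role in use.
#' @export
check_utilization <- function(config) {
  dist <- config$distribution / sum(config$distribution)
  rate_day <- config$arrivals$annual_volume / 365
  demand <- c()
  for (id in names(dist)) {
    for (s in config$pathways[[id]]$stages) {
      if (s$kind != "service") next
      a <- config$activities[[s$ref]]
      cur <- if (a$role %in% names(demand)) demand[[a$role]] else 0
      demand[a$role] <- cur + rate_day[[1]] * 7 * dist[[id]] * a$duration
    }
  }
  cal <- config$calendar
  open_min <- (cal$close_hour - cal$open_hour) * 60
  util <- c()
  for (r in names(demand)) {
    wk <- config$staffing[[r]]
    cap <- build_capacity_calendar(stats::setNames(wk, r),
                                   cal$weekend_fraction,
                                   config$staff, cal)
    supply <- if (cal$always_open) wk * 7 * 24 * 60
              else 5 * wk * open_min + 2 * cap$weekend[[r]] * open_min
    util[r] <- demand[[r]] / supply
  }
  util
}

# --- internal: compile an arm config for the event loop ----------------------

compile_arm <- function(config) {
  ids <- names(config$distribution)
  delay_names <- names(config$delays)
  role_names <- names(config$staffing)
  cal <- config$calendar
  cap <- build_capacity_calendar(config$staffing, cal$weekend_fraction,
                                 config$staff, cal)
  ep_idx <- stats::setNames(seq_along(ENDPOINTS), ENDPOINTS)
  pw <- lapply(ids, function(id) {
    st <- config$pathways[[id]]$stages
    k <- length(st)
    kind <- integer(k); dcol <- integer(k); role <- integer(k)
    dur <- numeric(k); ep <- integer(k)
    ndel <- 0L
    for (j in seq_len(k)) {
      s <- st[[j]]
      ep[j] <- if (is.na(s$endpoint)) 0L else ep_idx[[s$endpoint]]
      if (s$kind == "service") {
        a <- config$activities[[s$ref]]
        kind[j] <- 2L
        role[j] <- match(a$role, role_names)
        if (is.na(role[j])) {
          stop("no staffing entry for role ", a$role, call. = FALSE)
        }
        dur[j] <- minutes_to_days(a$duration)
      } else {
        kind[j] <- 1L  # delay and comm steps are both pre-sampled waits
        ndel <- ndel + 1L
        dcol[j] <- ndel
      }
    }
    list(id = id, kind = kind, dcol = dcol, role = role, dur = dur, ep = ep,
         n_delay = ndel,
         delay_refs = vapply(st, function(s) s$ref, ""),
         is_comm = vapply(st, function(s) s$kind == "comm", TRUE),
         n_service = sum(kind == 2L))
  })
  names(pw) <- ids
  # roles actually used must have weekday capacity > 0
  used <- unique(unlist(lapply(pw, function(p) p$role[p$role > 0])))
  bad <- used[cap$weekday[used] <= 0]
  if (length(bad)) {
    stop("role(s) with zero weekday staffing are required by the pathways: ",
         paste(role_names[bad], collapse = ", "), call. = FALSE)
  }
  list(ids = ids, pathways = pw, cap = cap, cal = cal,
       role_names = role_names)
}

# sample one delay column for `n` patients from a delay spec
sample_delay <- function(spec, n) {
  if (spec$mean == 0 || spec$cv == 0) return(rep(spec$mean, n))
  switch(spec$family,
    lognormal = {
      s2 <- log(1 + spec$cv^2)
      stats::rlnorm(n, log(spec$mean) - s2 / 2, sqrt(s2))
    },
    gamma = {
      shape <- 1 / spec$cv^2
      stats::rgamma(n, shape = shape, rate = shape / spec$mean)
    },
    fixed = rep(spec$mean, n),
    stop("unsupported delay family: ", spec$family, call. = FALSE)
  )
}

default_demographics <- function() {
  list(age_mean = 61.5, age_sd = 17.6, age_min = 18, p_female = 0.575)
}

#' Simulate one replication of an arm
#'
#' Event-driven simulation of one year of referrals. Every referral samples
#' a pathway from the arm distribution, then moves through the pathway's
#' stages: unstaffed delays elapse unconditionally, staffed activities queue
#' first-come first-served (within priority class) for a server of the
#' required role inside rota windows, and the patient exits when the
#' diagnosis communication completes. Arrivals stop at day 365 but the
#' simulation runs to drain, so every patient contributes to endpoint means.
#' All patient-level randomness (pathway, demographics, delays,
#' communication method) is drawn up front, so the same seed yields an
#' identical event log regardless of capacity settings.
#'
#' @param config an [arm_config()].
#' @param seed RNG seed.
#' @param keep_services keep the per-service audit log (queue entry, start,
#'   end times) used by queue-discipline diagnostics.
#' @param warn_unstable warn when analytic utilisation exceeds 0.95.
#' @param arrivals optional numeric vector of referral times (days) that
#'   replaces the sampled arrival stream, e.g. to trace specific scenarios.
#' @return an object of class `arm_sim` with elements `log` (one row per
#'   patient; endpoint timestamps in days since the patient's own referral),
#'   `services`, `seed`, `config`.
#' @export
simulate_arm <- function(config, seed = 1L, keep_services = TRUE,
                         warn_unstable = TRUE, arrivals = NULL) {
  stopifnot(inherits(config, "arm_config"))
  if (warn_unstable) {
    u <- check_utilization(config)
    if (any(u > 0.95)) {
      warning("sustained utilisation > 0.95 for role(s): ",
              paste(names(u)[u > 0.95], collapse = ", "),
              "; queues may grow without bound", call. = FALSE)
    }
  }
  cm <- compile_arm(config)
  set.seed(seed)

  arr <- if (is.null(arrivals)) generate_arrivals(config$arrivals)
         else sort(as.numeric(arrivals))
  n <- length(arr)
  ids <- cm$ids
  if (n == 0L) {
    log <- data.frame(id = integer(), arm = character(),
                      pathway = character(), referral_time = numeric(),
                      age = numeric(), sex = character(),
                      priority = integer(), comm_method = character(),
                      stringsAsFactors = FALSE)
    for (e in ENDPOINTS) log[[paste0("t_", e)]] <- numeric()
    return(structure(list(log = log, services = NULL, seed = seed,
                          max_queue = 0L, config = config),
                     class = "arm_sim"))
  }
  p_norm <- as.numeric(config$distribution) / sum(config$distribution)
  pwi <- sample.int(length(ids), n, replace = TRUE, prob = p_norm)
  demo <- default_demographics()
  age <- rtruncnorm(n, demo$age_mean, demo$age_sd, lower = demo$age_min)
  sex <- ifelse(stats::runif(n) < demo$p_female, "female", "male")
  prio <- as.integer(config$priority[ids][pwi])
  comm_method <- rep(NA_character_, n)

  # pre-sample every delay column per pathway (deterministic draw order)
  rowid <- integer(n)
  draws <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    idx <- which(pwi == k)
    rowid[idx] <- seq_along(idx)
    p <- cm$pathways[[k]]
    if (p$n_delay > 0L) {
      M <- matrix(0, nrow = length(idx), ncol = p$n_delay)
      if (length(idx)) {
        for (j in seq_along(p$kind)) {
          if (p$kind[j] != 1L) next
          col <- p$dcol[j]
          if (p$is_comm[j]) {
            cs <- config$communication[[ids[k]]]
            mi <- sample.int(length(cs$mix), length(idx), replace = TRUE,
                             prob = as.numeric(cs$mix))
            comm_method[idx] <- names(cs$mix)[mi]
            mm <- cs$method_mean[mi]
            if (cs$cv == 0) {
              M[, col] <- mm
            } else {
              s2 <- log(1 + cs$cv^2)
              M[, col] <- stats::rlnorm(length(idx), log(mm) - s2 / 2,
                                        sqrt(s2))
            }
          } else {
            M[, col] <- sample_delay(config$delays[[p$delay_refs[j]]],
                                     length(idx))
          }
        }
      }
      draws[[k]] <- M
    } else {
      draws[[k]] <- matrix(0, nrow = length(idx), ncol = 0)
    }
  }

  # --- event state ------------------------------------------------------
  n_ep <- length(ENDPOINTS)
  ts <- matrix(NA_real_, nrow = n, ncol = n_ep)
  cur <- integer(n)

  n_roles <- length(cm$role_names)
  wk_cap <- as.numeric(cm$cap$weekday)
  we_cap <- as.numeric(cm$cap$weekend)
  open_f <- cm$cal$open_hour / 24
  close_f <- cm$cal$close_hour / 24
  always <- cm$cal$always_open
  busy <- integer(n_roles)
  wake_at <- rep(Inf, n_roles)

  prio_levels <- sort(unique(prio))
  n_prio <- length(prio_levels)
  prio_of <- match(prio, prio_levels)
  # FIFO queues: [[role]][[prio]] growing int vectors + head/tail counters
  qbuf <- rep(list(rep(list(integer(64)), n_prio)), n_roles)
  qtime <- rep(list(rep(list(numeric(64)), n_prio)), n_roles)
  qhead <- matrix(0L, n_roles, n_prio)
  qtail <- matrix(0L, n_roles, n_prio)

  # service audit log
  n_srv_total <- sum(vapply(seq_len(n), function(i)
    cm$pathways[[pwi[i]]]$n_service, 0L))
  s_ct <- 0L
  s_pat <- integer(n_srv_total); s_role <- integer(n_srv_total)
  s_enq <- numeric(n_srv_total); s_start <- numeric(n_srv_total)
  s_end <- numeric(n_srv_total)
  pend_srv <- integer(n)  # row in service log while queued/in service

  # binary min-heap keyed on (time, event id)
  hcap <- max(64L, 2L * n)
  h_time <- numeric(hcap); h_ev <- integer(hcap); h_n <- 0L
  e_type <- integer(hcap); e_who <- integer(hcap); e_ct <- 0L

  push <- function(time, type, who) {
    e_ct <<- e_ct + 1L
    if (e_ct > length(e_type)) {
      e_type <<- c(e_type, integer(length(e_type)))
      e_who <<- c(e_who, integer(length(e_who)))
    }
    e_type[e_ct] <<- type
    e_who[e_ct] <<- who
    h_n <<- h_n + 1L
    if (h_n > length(h_time)) {
      h_time <<- c(h_time, numeric(length(h_time)))
      h_ev <<- c(h_ev, integer(length(h_ev)))
    }
    i <- h_n
    h_time[i] <<- time
    h_ev[i] <<- e_ct
    while (i > 1L) {
      p <- i %/% 2L
      if (h_time[p] > h_time[i] ||
          (h_time[p] == h_time[i] && h_ev[p] > h_ev[i])) {
        tt <- h_time[p]; h_time[p] <<- h_time[i]; h_time[i] <<- tt
        te <- h_ev[p]; h_ev[p] <<- h_ev[i]; h_ev[i] <<- te
        i <- p
      } else break
    }
  }

  pop <- function() {
    ev <- h_ev[1L]; tm <- h_time[1L]
    h_time[1L] <<- h_time[h_n]; h_ev[1L] <<- h_ev[h_n]
    h_n <<- h_n - 1L
    i <- 1L
    repeat {
      l <- 2L * i; r <- l + 1L
      if (l > h_n) break
      m <- l
      if (r <= h_n && (h_time[r] < h_time[l] ||
                       (h_time[r] == h_time[l] && h_ev[r] < h_ev[l]))) m <- r
      if (h_time[m] < h_time[i] ||
          (h_time[m] == h_time[i] && h_ev[m] < h_ev[i])) {
        tt <- h_time[m]; h_time[m] <<- h_time[i]; h_time[i] <<- tt
        te <- h_ev[m]; h_ev[m] <<- h_ev[i]; h_ev[i] <<- te
        i <- m
      } else break
    }
    c(tm, ev)
  }

  day_cap <- function(r, day) {
    if (day %% 7 >= 5) we_cap[r] else wk_cap[r]
  }

  # earliest future window opening; only called when the role is currently
  # closed or without weekend cover
  next_open <- function(r, t) {
    day <- floor(t)
    if (day_cap(r, day) > 0 && t < day + open_f - 1e-12) {
      return(day + open_f)
    }
    for (d in (day + 1L):(day + 8L)) {
      if (day_cap(r, d) > 0) return(d + open_f)
    }
    stop("no open window found for role ", cm$role_names[r], call. = FALSE)
  }

  enqueue <- function(r, i, t) {
    k <- prio_of[i]
    tl <- qtail[r, k] + 1L
    if (tl > length(qbuf[[r]][[k]])) {
      qbuf[[r]][[k]] <<- c(qbuf[[r]][[k]],
                           integer(length(qbuf[[r]][[k]])))
      qtime[[r]][[k]] <<- c(qtime[[r]][[k]],
                            numeric(length(qtime[[r]][[k]])))
    }
    qbuf[[r]][[k]][tl] <<- i
    qtime[[r]][[k]][tl] <<- t
    qtail[r, k] <<- tl
  }

  dispatch <- function(r, t) {
    repeat {
      kq <- 0L
      for (k in seq_len(n_prio)) {
        if (qhead[r, k] < qtail[r, k]) { kq <- k; break }
      }
      if (kq == 0L) return(invisible())
      if (always) {
        cap <- wk_cap[r]
      } else {
        day <- floor(t)
        cap <- day_cap(r, day)
        if (cap <= 0 || t < day + open_f - 1e-12 ||
            t >= day + close_f - 1e-12) {
          w <- next_open(r, t)
          if (w < wake_at[r] - 1e-12) {
            push(w, 3L, r)
            wake_at[r] <<- w
          }
          return(invisible())
        }
      }
      if (busy[r] >= cap) return(invisible())
      hd <- qhead[r, kq] + 1L
      i <- qbuf[[r]][[kq]][hd]
      enq_t <- qtime[[r]][[kq]][hd]
      qhead[r, kq] <<- hd
      busy[r] <<- busy[r] + 1L
      p <- cm$pathways[[pwi[i]]]
      st <- cur[i]
      s_ct <<- s_ct + 1L
      s_pat[s_ct] <<- i; s_role[s_ct] <<- r
      s_enq[s_ct] <<- enq_t; s_start[s_ct] <<- t
      pend_srv[i] <<- s_ct
      push(t + p$dur[st], 2L, i)
    }
  }

  start_next <- function(i, t) {
    p <- cm$pathways[[pwi[i]]]
    s <- cur[i] + 1L
    if (s > length(p$kind)) return(invisible())
    cur[i] <<- s
    if (p$kind[s] == 1L) {
      push(t + draws[[pwi[i]]][rowid[i], p$dcol[s]], 1L, i)
    } else {
      enqueue(p$role[s], i, t)
      dispatch(p$role[s], t)
    }
  }

  for (i in seq_len(n)) start_next(i, arr[i])

  max_q <- 0L
  while (h_n > 0L) {
    pe <- pop()
    t <- pe[1]; ev <- as.integer(pe[2])
    type <- e_type[ev]; who <- e_who[ev]
    if (type == 1L) {            # delay / communication completed
      p <- cm$pathways[[pwi[who]]]
      epi <- p$ep[cur[who]]
      if (epi > 0L) ts[who, epi] <- t
      start_next(who, t)
    } else if (type == 2L) {     # service completed
      p <- cm$pathways[[pwi[who]]]
      r <- p$role[cur[who]]
      busy[r] <- busy[r] - 1L
      s_end[pend_srv[who]] <- t
      epi <- p$ep[cur[who]]
      if (epi > 0L) ts[who, epi] <- t
      start_next(who, t)
      dispatch(r, t)
    } else {                     # rota window opens
      wake_at[who] <- Inf
      dispatch(who, t)
    }
    ql <- sum(qtail - qhead)
    if (ql > max_q) max_q <- ql
  }

  rel <- ts - arr  # timestamps in days since each patient's referral
  log <- data.frame(
    id = seq_len(n),
    arm = config$arm,
    pathway = ids[pwi],
    referral_time = arr,
    age = age, sex = sex, priority = prio,
    comm_method = comm_method,
    stringsAsFactors = FALSE
  )
  for (j in seq_along(ENDPOINTS)) log[[paste0("t_", ENDPOINTS[j])]] <- rel[, j]

  services <- NULL
  if (keep_services && s_ct > 0L) {
    services <- data.frame(
      patient = s_pat[seq_len(s_ct)],
      role = cm$role_names[s_role[seq_len(s_ct)]],
      enqueue_time = s_enq[seq_len(s_ct)],
      start_time = s_start[seq_len(s_ct)],
      end_time = s_end[seq_len(s_ct)],
      stringsAsFactors = FALSE
    )
  }
  structure(list(log = log, services = services, seed = seed,
                 max_queue = max_q, config = config),
            class = "arm_sim")
}

#' @export
print.arm_sim <- function(x, ...) {
  cat("<arm_sim> ", x$config$arm, ": ", nrow(x$log),
      " patients (seed ", format(x$seed), ")\n", sep = "")
  invisible(x)
}

#' Run several independent one-year replications
#'
#' Replication seeds are derived from the master seed, and the per-patient
#' logs are pooled with a `replication` column. With `n_runs = 1` the result
#' is exactly [simulate_arm()] under the first derived seed.
#'
#' @param config an [arm_config()].
#' @param n_runs number of independent one-year instances (default 5).
#' @param master_seed master RNG seed.
#' @param keep_services keep per-service audit logs.
#' @return an object of class `arm_replications` with pooled `log`,
#'   `summary` (a [summarize_endpoints()] result), `seeds`, `n_runs`.
#' @export
replicate_arm <- function(config, n_runs = 5, master_seed = 1L,
                          keep_services = FALSE) {
  stopifnot(n_runs >= 1)
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max, n_runs)
  runs <- lapply(seq_len(n_runs), function(r) {
    s <- simulate_arm(config, seed = seeds[r],
                      keep_services = keep_services,
                      warn_unstable = (r == 1L))
    s$log$replication <- r
    s
  })
  log <- do.call(rbind, lapply(runs, `[[`, "log"))
  services <- if (keep_services) {
    do.call(rbind, lapply(seq_len(n_runs), function(r) {
      sv <- runs[[r]]$services
      if (!is.null(sv)) sv$replication <- r
      sv
    }))
  }
  structure(list(log = log, services = services,
                 summary = summarize_endpoints(log,
                                               dist = config$distribution),
                 seeds = seeds, n_runs = n_runs, config = config),
            class = "arm_replications")
}

#' @export
print.arm_replications <- function(x, ...) {
  cat("<arm_replications> ", x$config$arm, ": ", x$n_runs,
      " replications, ", nrow(x$log), " patients pooled\n", sep = "")
  print(x$summary)
  invisible(x)
}
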