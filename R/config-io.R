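#' Arm configuration files
#'
#' Arm configurations serialise to a declarative YAML (or JSON) document
#' with a versioned schema: arm, pathway distribution, pathway stage lists,
#' delay and communication specs, staffing, arrivals and rota calendar.
#' Reading a written file reconstructs a behaviourally identical
#' [arm_config()].
#'
#' @param config an [arm_config()].
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_arm_config()` returns `path` invisibly;
#'   `read_arm_config()` returns an [arm_config()].
#' @name config_io
NULL

CONFIG_SCHEMA <- "dermflow/arm-config/1"

as_config_list <- function(config) {
  list(
    schema = CONFIG_SCHEMA,
    arm = config$arm,
    distribution = as.list(stats::setNames(as.numeric(config$distribution),
                                           names(config$distribution))),
    pathways = lapply(config$pathways, function(p) {
      list(id = p$id, unit_cost = p$unit_cost,
           stages = lapply(p$stages, function(s) {
             out <- list(kind = s$kind, ref = s$ref)
             if (!is.na(s$endpoint)) out$endpoint <- s$endpoint
             out
           }))
    }),
    delays = lapply(config$delays, function(d) {
      list(mean = d$mean, cv = d$cv, family = d$family)
    }),
    communication = lapply(config$communication, function(cs) {
      list(mean = cs$mean, cv = cs$cv,
           mix = as.list(stats::setNames(as.numeric(cs$mix),
                                         names(cs$mix))),
           rel = as.list(stats::setNames(as.numeric(cs$rel),
                                         names(cs$rel))))
    }),
    activities = lapply(config$activities, function(a) {
      list(name = a$name, duration = a$duration, role = a$role,
           procedure_cost = a$procedure_cost, license_cost = a$license_cost)
    }),
    staff = lapply(config$staff, function(s) {
      list(name = s$name, hourly_rate = s$hourly_rate,
           weekend_available = s$weekend_available)
    }),
    staffing = as.list(config$staffing),
    arrivals = list(annual_volume = config$arrivals$annual_volume,
                    monthly_weights = config$arrivals$monthly_weights),
    calendar = unclass(config$calendar),
    priority = as.list(config$priority)
  )
}

config_from_list <- function(lst) {
  if (!identical(lst$schema, CONFIG_SCHEMA)) {
    stop("unsupported config schema: ", lst$schema %||% "<missing>",
         call. = FALSE)
  }
  arm <- lst$arm
  pathways <- lapply(lst$pathways, function(p) {
    stages <- lapply(p$stages, function(s) {
      list(kind = s$kind, ref = s$ref,
           endpoint = s$endpoint %||% NA_character_)
    })
    pathway_definition(p$id, arm, stages, p$unit_cost)
  })
  names(pathways) <- vapply(lst$pathways, `[[`, "", "id")
  arm_config(
    arm = arm,
    distribution = arm_distribution(unlist(lst$distribution)),
    pathways = pathways,
    delays = lapply(lst$delays, function(d) {
      delay_spec(d$mean, d$cv, d$family)
    }),
    communication = lapply(lst$communication, function(cs) {
      comm_spec(cs$mean, unlist(cs$mix), cs$cv, rel = unlist(cs$rel))
    }),
    activities = lapply(lst$activities, function(a) {
      activity(a$name, a$duration, a$role, a$procedure_cost, a$license_cost)
    }),
    staff = lapply(lst$staff, function(s) {
      staff_role(s$name, s$hourly_rate, s$weekend_available)
    }),
    staffing = unlist(lst$staffing),
    arrivals = arrival_process(lst$arrivals$annual_volume,
                               unlist(lst$arrivals$monthly_weights)),
    calendar = rota_calendar(lst$calendar$open_hour, lst$calendar$close_hour,
                             lst$calendar$weekend_fraction,
                             lst$calendar$always_open),
    priority = unlist(lst$priority)
  )
}

#' @rdname config_io
#' @export
write_arm_config <- function(config, path) {
  stopifnot(inherits(config, "arm_config"))
  lst <- as_config_list(config)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(lst, path, precision = 15)
  }
  invisible(path)
}

#' @rdname config_io
#' @export
read_arm_config <- function(path) {
  lst <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  # yaml/json deserialise named numeric maps as lists of length-1 entries
  config_from_list(lst)
}
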