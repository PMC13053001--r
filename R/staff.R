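#' Staff roles and clinical activities
#'
#' A `staff_role` describes one grade of health care staff involved in the
#' urgent suspected skin cancer (USC) pathway: its Agenda-for-Change band (or
#' consultant / GP status), an hourly unit cost at 2023 prices, and whether
#' the role works reduced weekend shifts. GPs never work weekend shifts in
#' this service model.
#'
#' @param name one of `"HCA_Band3"`, `"Band5"`, `"Band9"`, `"Consultant"`,
#'   `"GP"`.
#' @param hourly_rate hourly unit cost in GBP (2023 prices), must be > 0.
#' @param weekend_available logical; whether the role is rostered at weekends.
#' @return an object of class `staff_role`.
#' @export
staff_role <- function(name, hourly_rate, weekend_available = TRUE) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(hourly_rate) || length(hourly_rate) != 1L ||
      !is.finite(hourly_rate) || hourly_rate <= 0) {
    stop("`hourly_rate` must be a single positive number", call. = FALSE)
  }
  if (identical(name, "GP") && isTRUE(weekend_available)) {
    stop("GPs are not available for weekend shifts", call. = FALSE)
  }
  structure(
    list(name = name, hourly_rate = as.numeric(hourly_rate),
         weekend_available = isTRUE(weekend_available)),
    class = "staff_role"
  )
}

#' Default staff roles
#'
#' Hourly unit costs are illustrative 2023 values in the spirit of national
#' unit-cost schedules (cost per working hour including overheads); they only
#' matter for optional bottom-up activity costing, since the baseline cost
#' analysis uses per-pathway unit costs directly.
#'
#' @return named list of [staff_role()] objects.
#' @export
default_staff <- function() {
  list(
    HCA_Band3  = staff_role("HCA_Band3", 29),
    Band5      = staff_role("Band5", 43),
    Band9      = staff_role("Band9", 104),
    Consultant = staff_role("Consultant", 127),
    GP         = staff_role("GP", 90, weekend_available = FALSE)
  )
}

#' Define a clinical activity
#'
#' An activity is a staffed service step (photography appointment, remote
#' image review, face-to-face consultation or follow-up, diagnostic biopsy)
#' with a fixed duration, the staff role that delivers it, and optional
#' procedure-tariff and platform-licensing cost add-ons used by bottom-up
#' costing.
#'
#' @param name activity label.
#' @param duration duration in minutes, `>= 0`.
#' @param role name of the [staff_role()] delivering the activity.
#' @param procedure_cost procedure tariff add-on in GBP, `>= 0`.
#' @param license_cost platform licensing allocation in GBP, `>= 0`.
#' @return an object of class `activity`.
#' @export
activity <- function(name, duration, role, procedure_cost = 0,
                     license_cost = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(duration) || duration < 0 || !is.finite(duration)) {
    stop("`duration` must be a non-negative number of minutes", call. = FALSE)
  }
  if (procedure_cost < 0) {
    stop("`procedure_cost` must be >= 0", call. = FALSE)
  }
  structure(
    list(name = name, duration = as.numeric(duration), role = role,
         procedure_cost = as.numeric(procedure_cost),
         license_cost = as.numeric(license_cost)),
    class = "activity"
  )
}

#' Default activity set
#'
#' Durations reflect the modelled service: 20-minute photography appointment
#' by a Band 3 health care assistant at a community diagnostic centre,
#' 4.97-minute remote dermatologist review on the teledermatology platform,
#' 20-minute face-to-face consultant consultation (dermoscopy included),
#' 15-minute face-to-face follow-up after remote review, and a diagnostic
#' biopsy procedure. Biopsy procedure tariff and platform licence figures are
#' configurable placeholders for bottom-up costing only.
#'
#' @return named list of [activity()] objects.
#' @export
default_activities <- function() {
  list(
    photography  = activity("photography", 20, "HCA_Band3", license_cost = 5),
    remote_review = activity("remote_review", 4.97, "Consultant",
                             license_cost = 5),
    f2f_consult  = activity("f2f_consult", 20, "Consultant"),
    f2f_followup = activity("f2f_followup", 15, "Consultant"),
    biopsy       = activity("biopsy", 30, "Consultant", procedure_cost = 150)
  )
}

# minutes of service time expressed in days of wall clock
minutes_to_days <- function(minutes) minutes / (24 * 60)
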