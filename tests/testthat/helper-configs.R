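# Small two-pathway arm used by engine tests: X exits after triage,
# Y adds a histopathology chain. Deterministic delays and 24/7 unlimited
# capacity by default so closed-form limits hold exactly.
toy_arm_config <- function(p_y = 0.4,
                           means = c(wx = 2, wy1 = 3, wy2 = 4),
                           comm_mean = 1, cv = 0, dur_min = 0,
                           staff_n = Inf, always_open = TRUE,
                           annual_volume = 200) {
  acts <- list(triage = activity("triage", dur_min, "Consultant"))
  pws <- list(
    X = pathway_definition("X", "intervention", list(
      step_delay("wx"),
      step_service("triage", endpoint = "clinical_diagnosis"),
      step_comm()), unit_cost = 100),
    Y = pathway_definition("Y", "intervention", list(
      step_delay("wy1"),
      step_service("triage", endpoint = "clinical_diagnosis"),
      step_delay("wy2", endpoint = "histopath_diagnosis"),
      step_comm()), unit_cost = 300)
  )
  dist <- if (p_y == 0) c(X = 1) else c(X = 1 - p_y, Y = p_y)
  arm_config(
    arm = "intervention",
    distribution = arm_distribution(dist),
    pathways = pws,
    delays = lapply(as.list(means), function(m) delay_spec(m, cv)),
    communication = list(X = comm_spec(comm_mean, c(email = 1), cv = cv),
                         Y = comm_spec(comm_mean, c(email = 1), cv = cv)),
    activities = acts,
    staffing = c(Consultant = staff_n),
    arrivals = arrival_process(annual_volume),
    calendar = rota_calendar(always_open = always_open)
  )
}

# closed-form endpoint sums of the toy config in the deterministic,
# uncapacitated limit
toy_closed_form <- function(means = c(wx = 2, wy1 = 3, wy2 = 4),
                            comm_mean = 1, dur_min = 0) {
  dur <- dur_min / (24 * 60)
  list(
    X = c(clinical = means[["wx"]] + dur,
          communication = means[["wx"]] + dur + comm_mean),
    Y = c(clinical = means[["wy1"]] + dur,
          histopath = means[["wy1"]] + dur + means[["wy2"]],
          communication = means[["wy1"]] + dur + means[["wy2"]] + comm_mean)
  )
}
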