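# Shared fixtures: the two published expert prior sets and small hand-built
# visit tables. Everything is constructed in code.

expert1_priors <- function() {
  build_expert_prior_set(list(
    elicited_interval("P1", 0.025, 0.095, "expert1"),
    elicited_interval("P0", 0.01, 0.06, "expert1"),
    elicited_interval("RR_UY", 1.1, 2.2, "expert1")
  ), expert_id = "expert1")
}

expert2_priors <- function() {
  build_expert_prior_set(list(
    elicited_interval("P1", 0.20, 0.40, "expert2"),
    elicited_interval("P0", 0.10, 0.20, "expert2"),
    elicited_interval("RR_UY", 1.1, 5, "expert2")
  ), expert_id = "expert2")
}

# Minimal visit table: one subject, chosen exposure/outcome/HIV sequences.
toy_visits <- function(subject_id, exposure, nbt, hiv = 0L) {
  k <- length(exposure)
  if (length(hiv) == 1L) hiv <- rep(hiv, k)
  data.frame(
    subject_id = subject_id, visit_index = seq_len(k),
    unsafe_injection = exposure, nbt = nbt, hiv_positive = hiv,
    gender = "male", age = 24, education_lths = 0L,
    incarcerated_baseline = 0L, incarcerated_recent = 0L,
    ever_tested_baseline = 0L
  )
}
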