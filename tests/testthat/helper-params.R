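# shared fixtures built in code

base_ps <- default_parameters()
base_values <- param_values(base_ps)

# a parameter vector with every transition hazard switched off
zero_values <- local({
  v <- base_values
  v[grep("^(bc_dev|oc_dev|p_met|rec_|oc_in_bc|bc_in_oc|mort_)", names(v))] <- 0
  v
})

# small random perturbation of the base values that stays inside domains
perturb_values <- function(seed) {
  set.seed(seed)
  suppressWarnings(sample_parameter_set(base_ps))
}

short_settings <- local({
  st <- base_ps$settings
  st$terminal_age <- st$entry_age + 9L
  st
})
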