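# shared fixtures: the reference operating point and calibrated cost model
smp_profile <- default_smp_profile()
smp_params <- default_smp_costs(calibrated = TRUE, profile = smp_profile)
smp_volume <- 15933 / 3  # annual robotic treatments, study-period average

# a small calibrated simulation config used by several simulation tests
smp_sim_config <- function(seed = 1L, ...) {
  laws <- default_smp_sim_laws()
  simulation_config(laws$caseload_laws, laws$dose_law, seed = seed, ...)
}
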