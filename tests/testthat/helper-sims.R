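# shared simulations, built once per test run and cached
.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, fun) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- fun()
  .sim_cache[[key]]
}

sizer_run <- function() cached_sim("sizer", function()
  simulate_population(scenario_config("sizer", seed = 42), 36, 700))

timer_run <- function() cached_sim("timer", function()
  simulate_population(scenario_config("null_timer", seed = 42), 36, 700))

feedback_run <- function() cached_sim("feedback", function()
  simulate_population(scenario_config("feedback_dips", seed = 42), 24, 1400))

# a no-noise configuration for exact arithmetic checks
exact_config <- function(...) {
  args <- list(growth_noise_cv = 0, rate_cv = 0, size_noise_cv = 0,
               nucleus_noise_cv = 0, track_jitter_cv = 0,
               division_fraction_sd = 0, timer_sd = 0, postg1_sd = 0,
               founder_size_cv = 0)
  do.call(sim_config, utils::modifyList(args, list(...)))
}
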