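# shared fixtures: small parameter sets and synthetic data builders

fitted_nonselective <- function(...) default_nonselective_params(...)
fitted_mitophagy <- function(...) default_mitophagy_params(...)

# deterministic mean pulse traces for both conditions at the generating
# parameters, peak-synchronized, with optional multiplicative noise
make_pulse_datasets <- function(params = fitted_nonselective(),
                                variant = model_variant(3),
                                noise_sd = 0, seed = 1,
                                horizon = 900, dt = 10) {
  set.seed(seed)
  times <- seq(0, horizon, by = dt)
  mk <- function(wrt) {
    A <- atg13dyn:::nonselective_solution(times, params, variant, wrt)
    if (noise_sd > 0) A <- A * exp(stats::rnorm(length(A), 0, noise_sd))
    data.frame(time_s = times - times[which.max(A)], intensity_au = A)
  }
  list(starvation = mk(FALSE), wortmannin = mk(TRUE))
}

# long-format traces for a mitophagy population with ids and condition
population_traces <- function(pop) {
  do.call(rbind, lapply(seq_along(pop), function(i) {
    data.frame(
      repeat_id = sprintf("r%02d", i), condition = "ivermectin",
      time_s = pop[[i]]$trace$time_s,
      intensity_au = pop[[i]]$trace$intensity_au,
      stringsAsFactors = FALSE
    )
  }))
}
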