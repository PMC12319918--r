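# Shared small synthetic sessions, built once per test run.

tiny_timeline <- function() trial_timeline(5, 4, 2, 6) # 60 frames

tiny_region <- function(n_bins = 20) {
  region_config(
    name = "SC", n_bins = n_bins, basal_rate_hz = 4.5, slope_amp = 21.4,
    gamma = gamma_params_for_fwhm(1.5, 0.8)
  )
}

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(
    region = tiny_region(),
    timeline = tiny_timeline(),
    grid_dim = c(60, 24),
    contrasts = c(0, 30, 100),
    n_trials = 6,
    noise_sd = 2,
    tip = c(12, 45),
    slope = 0
  )
  defaults[names(args)] <- args
  do.call(session_config, defaults)
}

.session_cache <- new.env(parent = emptyenv())

cached_session <- function(key, maker) {
  if (is.null(.session_cache[[key]])) .session_cache[[key]] <- maker()
  .session_cache[[key]]
}

# clean noiseless session (deterministic rates, mean drive): exact
# forward-model identities hold
noiseless_session <- function() {
  cached_session("noiseless", function() {
    gen_session(
      tiny_config(
        noise_sd = 0, poisson = FALSE, drive = "mean",
        contrasts = c(0, 100), n_trials = 2
      ),
      seed = 101
    )
  })
}

# realistic small session: Poisson spiking, spike-driven hemodynamics,
# moderate Doppler noise
noisy_session <- function() {
  cached_session("noisy", function() gen_session(tiny_config(), seed = 202))
}

# study-geometry noiseless session for alignment checks: discrimination
# between candidate trajectories needs the full 30-bin track and 170
# frames; cheap because a single noiseless trial needs no noise draw
alignment_session <- function() {
  cached_session("alignment", function() {
    gen_session(
      session_config(
        region = sc_config(), grid_dim = c(143, 32), contrasts = 100,
        n_trials = 1, noise_sd = 0, poisson = FALSE, drive = "mean",
        gain_sd = 0
      ),
      seed = 3
    )
  })
}
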