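# shared fixtures; expensive objects are built once per test run
.tk_cache <- new.env(parent = emptyenv())

tk_cached <- function(key, builder) {
  if (!exists(key, envir = .tk_cache)) assign(key, builder(), envir = .tk_cache)
  get(key, envir = .tk_cache)
}

tk_body <- function() body_params()

# noiseless quiet-stance run at default calibration
tk_quiet <- function() tk_cached("quiet", function() {
  simulate_stance(tk_body(), dt = 1e-3, t_start = -50, t_end = 30)
})

# noisy quiet-stance run (300 s) at default calibration
tk_noisy <- function() tk_cached("noisy", function() {
  simulate_stance(tk_body(), noise = noise_params(seed = 42L),
                  dt = 1e-3, t_start = 0, t_end = 330)
})

# perturbed noiseless run with the reflexive controller
tk_perturbed <- function() tk_cached("perturbed", function() {
  simulate_stance(tk_body(), reflex = reflex_params(),
                  perturbation = perturbation_profile(),
                  dt = 1e-3, t_start = -50, t_end = 6, perturbation_time = 0)
})

# small synthetic trial shared by posturography tests
tk_trial <- function() tk_cached("trial", function() {
  synth_trial(n_events = 2, interval = 20, settle = 20, tail = 16, seed = 3L)
})

# synthetic EEG at study scale (40 epochs, 250 Hz, single focal channel)
tk_eeg <- function() tk_cached("eeg", function() {
  synth_eeg(n_epochs = 40, fs = 250, channels = "Cz", seed = 5L)
})

# its wavelet decomposition on a reduced 2-40 Hz grid
tk_tfr <- function() tk_cached("tfr", function() {
  morlet_tfr(tk_eeg()$epochs, freqs = seq(2, 40, by = 0.5), decim = 10)
})
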