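# Shared fixtures: tiny deterministic cohorts and configs used across tests.

fixed_profile <- function(middle = 84.4, ring = 79.1, years = 10,
                          id = "data01") {
  data.frame(subject_id = id, middle_length_mm = middle,
             ring_length_mm = ring, training_years = years,
             stringsAsFactors = FALSE)
}

noiseless_config <- function(sets = 1L, keystrokes = 5L, seed = 11L, ...) {
  generator_config(n_subjects = 1L, sets_per_subject = sets,
                   keystrokes_per_set = keystrokes,
                   angle_noise_sd_deg = 0, position_noise_sd_mm = 0,
                   seed = seed, ...)
}

noisy_config <- function(sets = 2L, keystrokes = 5L, seed = 11L, ...) {
  generator_config(n_subjects = 1L, sets_per_subject = sets,
                   keystrokes_per_set = keystrokes, seed = seed, ...)
}

# Small deterministic regression problem on which the 13-unit network and the
# metaheuristics run fast.
tiny_sine_problem <- function(n = 120) {
  x <- matrix(seq(-1, 1, length.out = n), ncol = 1)
  list(X = x, y = sin(pi * x[, 1]))
}
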