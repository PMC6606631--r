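# shared fixtures built in code at test time

# typical gait events: contralateral foot off 10%, contralateral foot
# strike 50%, ipsilateral foot off 60%
typical_events <- function() {
  gait_events(contra_foot_off = 10, contra_foot_strike = 50,
              ipsi_foot_off = 60)
}

# a physiological model waveform for one joint at a given predictor vector
model_waveform <- function(joint = "knee",
                           p = predictor_vector(0.45, 38, 1, 24)) {
  predict_waveforms(load_published_table(), p, joints = joint)[[joint]]
}

# evaluate a polynomial given ascending coefficients (independent oracle
# for the quintic segment solver)
polyval_asc <- function(coef, x) {
  out <- rep(0, length(x))
  for (i in rev(seq_along(coef))) out <- out * x + coef[i]
  out
}

# key-point states sampled from a polynomial with ascending coefficients
states_from_poly <- function(coef, timings) {
  d1 <- coef[-1] * seq_len(length(coef) - 1)
  d2 <- d1[-1] * seq_len(length(d1) - 1)
  data.frame(timing = timings,
             angle = polyval_asc(coef, timings),
             velocity = polyval_asc(d1, timings),
             acceleration = polyval_asc(d2, timings))
}

# small synthetic dataset, memoised per options within one test file
small_dataset <- local({
  cache <- list()
  function(seed = 11, n_subjects = 10, trials = 1, noise = 0,
           wf_noise = 0, waveforms = TRUE) {
    key <- paste(seed, n_subjects, trials, noise, wf_noise, waveforms)
    if (is.null(cache[[key]])) {
      cfg <- synth_config(seed = seed, n_subjects = n_subjects,
                          trials_per_condition = trials,
                          noise_scale = noise, wf_noise_sd = wf_noise)
      cache[[key]] <<- generate_dataset(cfg, waveforms = waveforms)
    }
    cache[[key]]
  }
})
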