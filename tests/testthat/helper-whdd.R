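rmse <- function(a, b) sqrt(mean((a - b)^2))

# config whose error stage never fires (wide dead band): the stored window
# then equals the threshold-stage output, convenient for mean oracles
passthrough_config <- function(...) {
  filter_config(err_low_threshold = -1e6, err_high_threshold = 1e6, ...)
}

# stream data frame of constant channels
constant_stream <- function(n, hr = 70, skin = 33.5, gsr = 25,
                            amb = 25, rh = 60) {
  data.frame(t_s = seq_len(n) / 2, hr_bpm = hr, skin_temp_c = skin,
             gsr_us = gsr, amb_temp_c = amb, rh_pct = rh)
}

valid_baseline <- function(relax_hr = 70, relax_gsr = 25) {
  baseline_profile(relax_hr = relax_hr, relax_gsr = relax_gsr,
                   hr_valid = TRUE, gsr_valid = TRUE,
                   hr_attempts = 1L, gsr_attempts = 1L)
}
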