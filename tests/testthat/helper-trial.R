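# Calibrated trials used across test files.

zero_noise_trial <- function(seed = 1) {
  cal <- default_calibration(cv = 0)
  generate_trial(trial_design(seed = seed), cal$specs, cal$effects)
}

noisy_trial <- function(seed, cv = 0.05, replicates = 3) {
  cal <- default_calibration(cv = cv)
  generate_trial(trial_design(replicates = replicates, seed = seed),
                 cal$specs, cal$effects)
}

# Zero-noise treatment-mean SQI values under the default six-property set,
# worked out by hand from the calibrated means:
#   CK scores: salt 0.78, TN 1, avN 1/1.91, avP 1/1.49, avK 1/1.25, SOC 1
#   CS scores: all 1 (favourable extreme on every axis)
# then SQI = 0.5*sin(pi/3)*sum(Li^2).
SQI_CK_EXPECTED <- 1.7203358454
SQI_CS_EXPECTED <- 2.5980762114
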