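# memoized fixtures shared across test files (built once per test run)

.fixture_cache <- new.env(parent = emptyenv())

# rate-factor calibration in either convention
calib_cached <- function(normalize_start = FALSE, method = "mc") {
  key <- paste0("cal_", method, "_", normalize_start)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- calibrate_rate_factor(
      seed = 42, method = method, normalize_start = normalize_start)
  }
  .fixture_cache[[key]]
}

# two-condition synthetic stopped-flow campaign (reference 50 mM vs
# high-salt 160 mM), paper-like fold factors, 3 replicates each
condition_set_cached <- function() {
  if (is.null(.fixture_cache$cset)) {
    base <- trace_config(seed = 11, elongation_rate = 1, compaction_overshoot = 0.1)
    .fixture_cache$cset <- generate_condition_set(
      base,
      levels = list(
        list(salt_mM = 50),
        list(salt_mM = 160, lateral_factor = 1.48, elongation_rate = 2,
             mass_per_cs_factor = 1.6, compaction_overshoot = 0.3)),
      n_replicates = 3)
  }
  .fixture_cache$cset
}

# small noiseless trace for exact pipeline identities
noiseless_trace <- function(rate = 2, sample_rate_hz = 200) {
  generate_trace(trace_config(noise_sd = 0, compaction_overshoot = 0,
                              elongation_rate = rate,
                              sample_rate_hz = sample_rate_hz))
}
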