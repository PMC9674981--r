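#' Configuration for the synthetic stopped-flow generator
#'
#' Encodes the three kinetic phases of vimentin assembly seen in
#' dual-wavelength stopped-flow recordings, plus the instrument response:
#' 1. a sub-second lateral ramp (tetramers laterally associating into
#'    ULFs, raising the mass per length at both wavelengths equally),
#' 2. longitudinal annealing (1-100 s) that raises the 594/405 ratio via
#'    the rod shape factor,
#' 3. a radial-compaction overshoot: a transient excess in mass per
#'    length peaking near 30 s and decaying as loosely bound subunits
#'    shed.
#' The instrument model applies a first-order low-pass (1 ms), 1 kHz
#' sampling, a 3 ms dead time and additive Gaussian noise; bubble
#' transients can be injected with a per-trace probability.
#'
#' The lateral ramp is a phenomenological saturating double exponential
#' (no mechanistic tetramer kinetics): fast time constant
#' `lateral_tau_fast` with weight `lateral_fast_frac`, slow constant
#' `lateral_tau_slow`. `lateral_factor` rescales the ramp's *time axis*
#' (kinetic fold-change vs the reference condition) while
#' `mass_per_cs_factor` scales its *amplitude* (plateau mass per cross
#' section), so early-window condition ratios read the kinetic fold and
#' plateau-window ratios the mass fold.
#'
#' @param protein_mg_ml Protein concentration, mg/mL.
#' @param salt_mM NaCl concentration in the assembly chamber, mM.
#' @param lateral_amplitude Signal amplitude of the lateral plateau, a.u.
#' @param lateral_tau_fast,lateral_tau_slow,lateral_fast_frac Lateral ramp
#'   shape (s, s, fraction).
#' @param lateral_factor Kinetic fold-change of the lateral ramp vs the
#'   reference condition.
#' @param elongation_rate Longitudinal assembly rate, ULFs/min.
#' @param mass_per_cs_factor Mass-per-cross-section fold vs reference.
#' @param compaction_overshoot Fractional peak excess of the compaction
#'   pulse (0 disables phase 3).
#' @param compaction_peak_s,compaction_width Log-normal pulse peak time
#'   (s) and log-width.
#' @param noise_sd Additive Gaussian noise SD, a.u.
#' @param duration_s Recording length, s.
#' @param sample_rate_hz Sampling rate (default 1000).
#' @param dead_time_s Instrument dead time (default 0.003).
#' @param lowpass_tau_s Low-pass filter time constant (default 0.001).
#' @param bubble_probability Per-trace probability of a bubble transient.
#' @param seed Optional integer seed; all randomness (noise, bubbles,
#'   length samples) flows from it via named sub-streams.
#' @return An object of class `trace_config`.
#' @export
trace_config <- function(protein_mg_ml = 0.2, salt_mM = 50,
                         lateral_amplitude = 5,
                         lateral_tau_fast = 0.35, lateral_tau_slow = 2.5,
                         lateral_fast_frac = 0.7,
                         lateral_factor = 1,
                         elongation_rate = 1,
                         mass_per_cs_factor = 1,
                         compaction_overshoot = 0.1,
                         compaction_peak_s = 30, compaction_width = 0.8,
                         noise_sd = 0.02, duration_s = 600,
                         sample_rate_hz = 1000, dead_time_s = 0.003,
                         lowpass_tau_s = 0.001,
                         bubble_probability = 0, seed = NULL) {
  cfg <- as.list(environment())
  num <- vapply(cfg[setdiff(names(cfg), "seed")], is.numeric, logical(1))
  if (!all(num)) stop("all configuration fields except seed must be numeric")
  if (cfg$sample_rate_hz <= 0) stop("sample_rate_hz must be positive")
  if (cfg$duration_s <= cfg$dead_time_s) stop("duration must exceed the dead time")
  neg <- c("lateral_amplitude", "lateral_tau_fast", "lateral_tau_slow",
           "lateral_factor", "elongation_rate", "mass_per_cs_factor",
           "compaction_overshoot", "noise_sd", "dead_time_s", "lowpass_tau_s")
  for (f in neg) if (cfg[[f]] < 0) stop(f, " must be non-negative")
  if (cfg$lateral_fast_frac < 0 || cfg$lateral_fast_frac > 1)
    stop("lateral_fast_frac must be in [0, 1]")
  if (cfg$bubble_probability < 0 || cfg$bubble_probability > 1)
    stop("bubble_probability must be in [0, 1]")
  structure(cfg, class = "trace_config")
}

# saturating double-exponential ramp, 0 at t = 0, -> 1
.lateral_ramp <- function(t, cfg) {
  w <- cfg$lateral_fast_frac
  1 - w * exp(-t / cfg$lateral_tau_fast) - (1 - w) * exp(-t / cfg$lateral_tau_slow)
}

# log-normal-shaped compaction pulse, peak 1 at compaction_peak_s
.compaction_pulse <- function(t, cfg) {
  p <- numeric(length(t))
  pos <- t > 0
  p[pos] <- exp(-(log(t[pos] / cfg$compaction_peak_s))^2 / (2 * cfg$compaction_width^2))
  p
}

# elongation term <l^2 P(90)> / <l> along the growth path, normalized to
# its t = 0 value; evaluated on a grid of mean lengths and interpolated
.elongation_term <- function(t_s, rate, wavelength_nm, geometry,
                             start_length = 1, n_grid = 256) {
  if (rate == 0) return(rep(1, length(t_s)))
  gm <- growth_model(rate, start_length = start_length)
  lf_end <- mean_length_at(gm, max(t_s) / 60)
  lf_grid <- seq(start_length, lf_end, length.out = n_grid)
  e_grid <- vapply(lf_grid, function(lf) {
    sig <- sigma_ln_at(gm, lf)
    .lognormal_moment(lf, sig, wavelength_nm, p = 2, geometry = geometry, fast = TRUE) /
      .lognormal_moment(lf, sig, NULL, p = 1, geometry = geometry)
  }, numeric(1))
  e_grid <- e_grid / e_grid[1]
  lf_t <- mean_length_at(gm, t_s / 60)
  stats::approx(lf_grid, e_grid, xout = lf_t, rule = 2)$y
}

# first-order discrete low-pass, y[i] = a y[i-1] + (1-a) x[i]
.lowpass <- function(x, dt, tau) {
  if (tau <= 0) return(x)
  a <- exp(-dt / tau)
  as.numeric(stats::filter(x * (1 - a), a, method = "recursive"))
}

#' Generate a synthetic two-channel stopped-flow trace
#'
#' Builds the noise-free signal
#' `S_lambda(t) = lateral_amplitude * m(t) * (1 + overshoot * pulse(t)) *
#' E_lambda(t)`, where `m(t)` is the mass-per-length ramp (see
#' [trace_config()]) and `E_lambda(t)` the normalized ensemble shape term
#' `<l^2 P(90)> / <l>` for the log-normal length population growing at
#' `elongation_rate`; then applies the instrument model (low-pass,
#' sampling, dead-time blanking, additive Gaussian noise, optional bubble
#' transient). The generating parameters are attached as ground truth.
#'
#' By default the trace is emitted on the calibrated scale (water = 0,
#' buffer = 1). Supplying `water_baseline` and `buffer_reference` applies
#' the inverse calibration to produce a raw-scale trace instead.
#'
#' @param config A [trace_config()].
#' @param geometry A [ulf_geometry()].
#' @param water_baseline,buffer_reference Optional named vectors
#'   (`i405`, `i594`) to emit a raw trace.
#' @return An `sf_trace` in state `"calibrated"` (or `"raw"`), with the
#'   ground truth available via [trace_truth()].
#' @export
generate_trace <- function(config = trace_config(), geometry = ulf_geometry(),
                           water_baseline = NULL, buffer_reference = NULL) {
  stopifnot(inherits(config, "trace_config"))
  cfg <- config
  dt <- 1 / cfg$sample_rate_hz
  t <- seq(0, cfg$duration_s, by = dt)
  s_time <- if (cfg$mass_per_cs_factor > 0) cfg$lateral_factor / cfg$mass_per_cs_factor else 0
  m <- cfg$mass_per_cs_factor * .lateral_ramp(t * s_time, cfg)
  shared <- cfg$lateral_amplitude * m * (1 + cfg$compaction_overshoot * .compaction_pulse(t, cfg))
  s405 <- shared * .elongation_term(t, cfg$elongation_rate, 405, geometry)
  s594 <- shared * .elongation_term(t, cfg$elongation_rate, 594, geometry)
  s405 <- .lowpass(s405, dt, cfg$lowpass_tau_s)
  s594 <- .lowpass(s594, dt, cfg$lowpass_tau_s)
  blank <- t < cfg$dead_time_s
  s405[blank] <- 0
  s594[blank] <- 0
  bubble_time <- NA_real_
  if (cfg$bubble_probability > 0) {
    bub <- with_seed(sub_seed(cfg$seed, 3), {
      if (stats::runif(1) < cfg$bubble_probability)
        stats::runif(1, 0.05 * cfg$duration_s, 0.8 * cfg$duration_s)
      else NA_real_
    })
    if (is.finite(bub)) {
      bubble_time <- bub
      amp <- 10 * max(shared)
      spike <- amp * exp(-pmax(t - bub, 0) / 0.03) * (t >= bub)
      s405 <- s405 + spike
      s594 <- s594 + spike
    }
  }
  if (cfg$noise_sd > 0) {
    s405 <- s405 + with_seed(sub_seed(cfg$seed, 1),
                             stats::rnorm(length(t), 0, cfg$noise_sd))
    s594 <- s594 + with_seed(sub_seed(cfg$seed, 2),
                             stats::rnorm(length(t), 0, cfg$noise_sd))
  }
  state <- "calibrated"
  if (!is.null(water_baseline) && !is.null(buffer_reference)) {
    for (ch in c("i405", "i594")) {
      w <- water_baseline[[ch]]; b <- buffer_reference[[ch]]
      if (b <= w) stop("buffer reference must exceed water baseline")
    }
    s405 <- water_baseline[["i405"]] + (buffer_reference[["i405"]] - water_baseline[["i405"]]) * s405
    s594 <- water_baseline[["i594"]] + (buffer_reference[["i594"]] - water_baseline[["i594"]]) * s594
    state <- "raw"
  }
  truth <- c(unclass(cfg), list(bubble_time = bubble_time))
  sf_trace(t, s405, s594,
           meta = list(salt_mM = cfg$salt_mM, protein_mg_ml = cfg$protein_mg_ml,
                       synthetic = TRUE),
           state = state, truth = truth)
}

#' Generate time-resolved filament length samples
#'
#' Log-normal length populations at the requested times, with the
#' geometric mean growing linearly per the growth model and the width
#' following the empirical width law -- the synthetic counterpart of an
#' AFM length-measurement campaign.
#'
#' @param model A [growth_model()].
#' @param times_s Sampling times in seconds.
#' @param n_per_time Filaments measured per time point.
#' @param seed Optional integer seed.
#' @return `data.frame(time_s, length_ulf)`.
#' @export
generate_length_samples <- function(model, times_s, n_per_time = 300,
                                    seed = NULL) {
  if (n_per_time < 1) stop("n_per_time must be >= 1")
  out <- lapply(seq_along(times_s), function(i) {
    lf <- mean_length_at(model, times_s[i] / 60)
    data.frame(time_s = times_s[i],
               length_ulf = sample_lengths(lf, sigma_ln_at(model, lf),
                                           n_per_time, seed = sub_seed(seed, i)))
  })
  do.call(rbind, out)
}

#' Generate time-resolved filament diameter samples
#'
#' Gaussian diameter populations whose mean follows a transient
#' compaction excursion: baseline `final_nm` times
#' `1 + peak_excess * pulse(t)`, the pulse peaking at `peak_time_s`. A
#' stylized stand-in for EM diameter measurements during radial
#' compaction.
#'
#' @param times_s Sampling times in seconds.
#' @param n_per_time Filaments measured per time point.
#' @param final_nm Mature (post-compaction) mean diameter, nm.
#' @param peak_excess Fractional excess of the peak mean over `final_nm`.
#' @param peak_time_s,width Pulse peak time (s) and log-width.
#' @param sd_nm Within-time-point diameter SD, nm.
#' @param seed Optional integer seed.
#' @return `data.frame(time_s, diameter_nm)`.
#' @export
generate_diameter_samples <- function(times_s, n_per_time = 80,
                                      final_nm = 13, peak_excess = 0.3,
                                      peak_time_s = 30, width = 0.8,
                                      sd_nm = 2, seed = NULL) {
  if (n_per_time < 1) stop("n_per_time must be >= 1")
  cfgish <- list(compaction_peak_s = peak_time_s, compaction_width = width)
  out <- lapply(seq_along(times_s), function(i) {
    mu <- final_nm * (1 + peak_excess * .compaction_pulse(times_s[i], cfgish))
    data.frame(time_s = times_s[i],
               diameter_nm = with_seed(sub_seed(seed, i),
                                       stats::rnorm(n_per_time, mu, sd_nm)))
  })
  do.call(rbind, out)
}

#' Generate a set of traces across salt conditions
#'
#' Applies per-level fold factors (lateral kinetics, elongation rate,
#' mass per cross section, compaction overshoot) to a base configuration
#' and generates replicate traces per level with seeds derived from the
#' base seed. The first level is the reference condition.
#'
#' @param base A [trace_config()]; its seed is the master seed.
#' @param levels A list of named lists, one per salt level, each with
#'   `salt_mM` and any of `lateral_factor`, `elongation_rate`,
#'   `mass_per_cs_factor`, `compaction_overshoot`, `protein_mg_ml`.
#' @param n_replicates Traces per level.
#' @param geometry A [ulf_geometry()].
#' @return Named list (by salt level) of lists of `sf_trace` objects;
#'   each trace carries its generating parameters as ground truth.
#' @export
generate_condition_set <- function(base = trace_config(), levels,
                                   n_replicates = 3,
                                   geometry = ulf_geometry()) {
  if (length(levels) < 2) stop("need at least 2 levels (first is the reference)")
  out <- list()
  for (i in seq_along(levels)) {
    lv <- levels[[i]]
    cfg <- unclass(base)
    for (nm in names(lv)) {
      if (!nm %in% names(cfg)) stop("unknown level field: ", nm)
      cfg[[nm]] <- lv[[nm]]
    }
    reps <- lapply(seq_len(n_replicates), function(j) {
      cfg$seed <- sub_seed(base$seed, i * 1000 + j)
      generate_trace(do.call(trace_config, cfg[setdiff(names(cfg), character(0))]),
                     geometry = geometry)
    })
    out[[paste0(cfg$salt_mM, "mM")]] <- reps
  }
  out
}
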