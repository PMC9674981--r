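#' Construct a two-channel stopped-flow trace
#'
#' Container for a stopped-flow recording: a uniform, strictly increasing
#' time grid and the scattered intensities at 405 and 594 nm, plus
#' condition metadata and a processing-state marker. Stages of the
#' pipeline ([preprocess()] -> [normalize_channels()] -> [compute_ratio()]
#' -> [fit_ratio_model()]) refuse traces in the wrong state.
#'
#' @param time_s Time in seconds, strictly increasing.
#' @param i405,i594 Intensities (a.u.), finite, same length as `time_s`.
#' @param meta Named list of condition metadata (salt_mM,
#'   protein_mg_ml, ...).
#' @param state One of `"raw"`, `"calibrated"`, `"normalized"`.
#' @param truth Optional ground-truth record attached by the synthetic
#'   generator.
#' @return An object of class `sf_trace` (a data.frame with attributes).
#' @export
sf_trace <- function(time_s, i405, i594, meta = list(), state = "raw",
                     truth = NULL) {
  if (length(i405) != length(time_s) || length(i594) != length(time_s))
    stop("channels and time grid must have equal length")
  if (any(!is.finite(time_s)) || any(diff(time_s) <= 0))
    stop("time must be finite and strictly increasing")
  if (any(!is.finite(i405)) || any(!is.finite(i594)))
    stop("intensities must be finite")
  state <- match.arg(state, c("raw", "calibrated", "normalized"))
  structure(data.frame(time_s = time_s, i405 = i405, i594 = i594),
            meta = meta, state = state, truth = truth,
            class = c("sf_trace", "data.frame"))
}

#' @export
print.sf_trace <- function(x, ...) {
  cat(sprintf("sf_trace: %d samples, %.4g-%.4g s, state = %s\n",
              nrow(x), x$time_s[1], x$time_s[nrow(x)], trace_state(x)))
  if (length(attr(x, "meta"))) utils::str(attr(x, "meta"), give.attr = FALSE)
  invisible(x)
}

#' @rdname sf_trace
#' @param trace An `sf_trace`.
#' @export
trace_state <- function(trace) attr(trace, "state")

#' @rdname sf_trace
#' @export
trace_truth <- function(trace) attr(trace, "truth")

.set_state <- function(trace, state) {
  attr(trace, "state") <- state
  trace
}

.require_state <- function(trace, state) {
  if (!inherits(trace, "sf_trace")) stop("not an sf_trace")
  if (!trace_state(trace) %in% state)
    stop(sprintf("trace must be in state %s (is: %s)",
                 paste(state, collapse = "/"), trace_state(trace)))
  invisible(trace)
}

#' Baseline-subtract and calibrate a raw trace
#'
#' Before each assembly run the instrument records a water-only signal
#' (the baseline) and a buffer-only signal (the calibration reference).
#' Per channel, intensities are mapped to
#' `(I - water) / (buffer - water)`, so a water trace becomes 0 and a
#' buffer trace becomes 1.
#'
#' @param trace A raw `sf_trace`.
#' @param water_baseline,buffer_reference Named numeric vectors with
#'   elements `i405`, `i594` (a.u.).
#' @return The calibrated trace (state `"calibrated"`).
#' @export
preprocess <- function(trace, water_baseline = c(i405 = 0, i594 = 0),
                       buffer_reference = c(i405 = 1, i594 = 1)) {
  .require_state(trace, "raw")
  for (ch in c("i405", "i594")) {
    w <- water_baseline[[ch]]; b <- buffer_reference[[ch]]
    if (!is.finite(w) || !is.finite(b)) stop("baselines must be finite")
    if (b <= w) stop("buffer reference must exceed water baseline (invalid calibration)")
    trace[[ch]] <- (trace[[ch]] - w) / (b - w)
  }
  .set_state(trace, "calibrated")
}

#' Normalize both channels to their early-window mean
#'
#' During the first ~50 ms only lateral assembly has occurred, so the
#' shape factor is the same at both wavelengths and the two channels
#' carry the same signal up to gain. Dividing each channel by its mean
#' over the early window removes per-channel gains; afterwards the
#' 594/405 ratio reads the shape factor directly. Idempotent.
#'
#' @param trace A calibrated `sf_trace`.
#' @param window Window in seconds, default `c(0.003, 0.05)`: from the
#'   instrument dead time to 50 ms.
#' @return The normalized trace (state `"normalized"`).
#' @export
normalize_channels <- function(trace, window = c(0.003, 0.05)) {
  .require_state(trace, c("calibrated", "normalized"))
  idx <- trace$time_s >= window[1] & trace$time_s <= window[2]
  if (!any(idx)) stop("trace does not cover the normalization window")
  for (ch in c("i405", "i594")) {
    m <- mean(trace[[ch]][idx])
    if (!is.finite(m) || m <= 0) stop("non-positive window mean: cannot normalize")
    trace[[ch]] <- trace[[ch]] / m
  }
  .set_state(trace, "normalized")
}

#' Pointwise 594/405 intensity ratio of a normalized trace
#'
#' Samples with non-positive 405 nm denominator are masked (dropped) and
#' counted; if they exceed 1% of the samples the series is flagged.
#'
#' @param trace A normalized `sf_trace`.
#' @return `data.frame(time_s, ratio)` with attributes `masked_fraction`
#'   and `flag_masked` (TRUE above the 1% threshold).
#' @export
compute_ratio <- function(trace) {
  .require_state(trace, "normalized")
  bad <- trace$i405 <= 0
  out <- data.frame(time_s = trace$time_s[!bad],
                    ratio = trace$i594[!bad] / trace$i405[!bad])
  attr(out, "masked_fraction") <- mean(bad)
  attr(out, "flag_masked") <- mean(bad) > 0.01
  out
}

#' Flag traces with bubble-like artifacts
#'
#' Air bubbles in the observation chamber cause brief large excursions in
#' both channels; affected measurements are discarded, never repaired. A
#' trace is flagged when the high-pass residual (signal minus running
#' median) exceeds `k` robust standard deviations (1.4826 x MAD) for a
#' run of at least `min_run` consecutive samples in either channel.
#'
#' @param trace A calibrated or normalized `sf_trace`.
#' @param k Threshold in robust SDs (default 8).
#' @param min_run Minimum run length in samples (default 5).
#' @param median_window Running-median window in samples (odd, default 51).
#' @return List: `artifact` (logical), per-channel logical `exceed`
#'   vectors and the robust SDs used.
#' @export
detect_artifacts <- function(trace, k = 8, min_run = 5, median_window = 51) {
  .require_state(trace, c("calibrated", "normalized"))
  res <- list(artifact = FALSE, robust_sd = c(i405 = NA_real_, i594 = NA_real_))
  for (ch in c("i405", "i594")) {
    x <- trace[[ch]]
    win <- min(median_window, if (length(x) %% 2 == 1) length(x) else length(x) - 1)
    resid <- x - stats::runmed(x, win)
    s <- stats::mad(resid)
    if (s == 0) s <- stats::sd(resid)
    res$robust_sd[[ch]] <- s
    exceed <- s > 0 & abs(resid) > k * s
    r <- rle(exceed)
    hit <- any(r$values & r$lengths >= min_run)
    res[[paste0("exceed_", ch)]] <- exceed
    if (hit) res$artifact <- TRUE
  }
  res
}

#' Fit the exponential ratio model and convert to an assembly rate
#'
#' Fits `r(t) = 1 + A (1 - exp(-t / tau))` to a 594/405 ratio series by
#' nonlinear least squares. Because filament elongation spans four
#' decades in time, the series is first averaged in log-spaced time bins
#' (equal weight per decade) starting at `fit_start_s`; the sub-second
#' lateral-phase transient, where the ratio is ~1 and uninformative, is
#' excluded. The asymptote is fixed at 1 (perfect early-window
#' normalization); `A` is free because measured prefactors range ~0.3-0.5.
#' The longitudinal assembly rate is `r_la = factor_used / tau` with tau
#' in minutes.
#'
#' @param series `data.frame(time_s, ratio)` (e.g. from
#'   [compute_ratio()] or [ratio_curve()] with times converted to s).
#' @param factor_used Rate factor in ULFs (the established literature
#'   value 2.32, or the `factor` of a [calibrate_rate_factor()] result).
#'   `NA` skips the rate conversion.
#' @param fit_start_s Start of the fit window in seconds (default 1).
#' @param bins_per_decade Log-time bins per decade (default 12).
#' @param A_init Initial prefactor (default 0.46, the asymptotic
#'   shape-factor ratio minus one).
#' @return An object of class `ratio_fit`: `A`, `tau_min`, `r_la`,
#'   `factor_used`, `rms`, `n_points`, `fit_window_s`, and `flags`
#'   (`prefactor_out_of_range` if A outside [0.3, 0.5], `too_short` if
#'   A > 0.5, `tau_at_bound`).
#' @export
fit_ratio_model <- function(series, factor_used = 2.32, fit_start_s = 1,
                            bins_per_decade = 12, A_init = 0.46) {
  if (!all(c("time_s", "ratio") %in% names(series)))
    stop("series must have columns time_s and ratio")
  s <- series[is.finite(series$ratio) & series$time_s >= fit_start_s, ]
  if (nrow(s) < 10) stop("fewer than 10 usable points in the fit window")
  # log-spaced bin means so the long-time tail does not dominate
  lt <- log10(s$time_s)
  bin <- floor((lt - min(lt)) * bins_per_decade)
  t_b <- tapply(s$time_s, bin, mean)
  r_b <- tapply(s$ratio, bin, mean)
  tb <- as.numeric(t_b) / 60  # minutes
  rb <- as.numeric(r_b)
  tau0 <- tb[which(rb > 1 + A_init / 2)[1]]
  if (is.na(tau0)) tau0 <- max(tb) / 2
  tau_hi <- 100 * max(tb)
  fit <- minpack.lm::nlsLM(
    rb ~ 1 + A * (1 - exp(-tb / tau)),
    start = list(A = A_init, tau = tau0),
    lower = c(0, 1e-8), upper = c(2, tau_hi),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  A <- unname(cf["A"]); tau <- unname(cf["tau"])
  rms <- sqrt(mean(stats::resid(fit)^2))
  flags <- list(
    prefactor_out_of_range = A < 0.3 || A > 0.5,
    too_short = A > 0.5,
    tau_at_bound = tau <= 2e-8 || tau >= 0.99 * tau_hi)
  structure(list(A = A, tau_min = tau,
                 r_la = if (is.na(factor_used)) NA_real_ else factor_used / tau,
                 factor_used = factor_used, rms = rms, n_points = length(tb),
                 fit_window_s = c(fit_start_s, max(s$time_s)), flags = flags),
            class = "ratio_fit")
}

#' @export
print.ratio_fit <- function(x, ...) {
  cat(sprintf("ratio fit: A = %.4f, tau = %.4f min, r_la = %.3f ULFs/min (factor %.3g), rms %.2g\n",
              x$A, x$tau_min, x$r_la, x$factor_used, x$rms))
  fl <- names(Filter(isTRUE, x$flags))
  if (length(fl)) cat("flags:", paste(fl, collapse = ", "), "\n")
  invisible(x)
}
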