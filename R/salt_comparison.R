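#' Condition ratio of scattered intensities at one wavelength
#'
#' Ratio of the mean intensity across replicate traces of a test
#' condition to that of a reference condition, per time point, at a
#' single wavelength -- the "normalized by the low-salt signal" analysis.
#' Traces must be calibrated but *not* channel-normalized (normalization
#' would erase the lateral-kinetics and mass information the ratio
#' carries). Replicates are averaged before ratioing (ratio of means;
#' ratios of noisy small denominators are unstable); the standard error
#' of each window average is estimated by bootstrap over replicates.
#'
#' Three windows summarize the series:
#' * `early`: mean over 20-40 ms, reporting the lateral-kinetics fold
#'   (filaments longer than 1 ULF have not yet formed, so the value is
#'   wavelength independent);
#' * `peak`: mean over a 40 s window centered on the intensity-ratio
#'   peak (located on the series after 5 s moving-average smoothing),
#'   mixing lateral, longitudinal and transient-compaction contributions;
#' * `plateau`: mean over 500-600 s, reporting the mass per cross
#'   section fold once the shape factor has saturated.
#'
#' @param traces_num,traces_den Lists of calibrated `sf_trace` replicates
#'   (numerator = test condition, denominator = reference).
#' @param wavelength 405 or 594.
#' @param early_window,plateau_window Windows in seconds.
#' @param peak_width_s Width of the peak window (s).
#' @param smooth_s Moving-average span used to locate the peak (s).
#' @param n_boot Bootstrap resamples for window SEs.
#' @param seed Optional seed for the bootstrap.
#' @return An object of class `condition_ratio`: `series`
#'   (data.frame time_s, ratio), `windows` (named list with mean, se and,
#'   for the peak, its center), `wavelength`, replicate counts.
#' @export
condition_ratio <- function(traces_num, traces_den, wavelength = 405,
                            early_window = c(0.020, 0.040),
                            plateau_window = c(500, 600),
                            peak_width_s = 40, smooth_s = 5,
                            n_boot = 1000, seed = NULL) {
  if (length(traces_num) < 1 || length(traces_den) < 1)
    stop("need at least one trace per condition")
  ch <- paste0("i", match.arg(as.character(wavelength), c("405", "594")))
  for (tr in c(traces_num, traces_den)) .require_state(tr, "calibrated")
  grid <- traces_num[[1]]$time_s
  mat_on_grid <- function(traces) {
    vapply(traces, function(tr) {
      if (length(tr$time_s) == length(grid) && all(tr$time_s == grid)) tr[[ch]]
      else stats::approx(tr$time_s, tr[[ch]], xout = grid, rule = 2)$y
    }, numeric(length(grid)))
  }
  mn <- mat_on_grid(traces_num)
  md <- mat_on_grid(traces_den)
  num_mean <- rowMeans(mn)
  den_mean <- rowMeans(md)
  series <- data.frame(time_s = grid, ratio = num_mean / den_mean)

  win_idx <- function(w) {
    idx <- grid >= w[1] & grid <= w[2]
    if (!any(idx)) stop("window outside the trace duration")
    idx
  }
  # locate the peak on the smoothed series, past the lateral phase
  dt <- stats::median(diff(grid))
  k <- max(1, round(smooth_s / dt))
  sm <- stats::filter(series$ratio, rep(1 / k, k), sides = 2)
  cand <- which(grid > 1 & grid < max(grid) - peak_width_s / 2 & !is.na(sm))
  peak_center <- grid[cand[which.max(sm[cand])]]
  peak_window <- peak_center + c(-0.5, 0.5) * peak_width_s

  # per-trace window means; the window mean of a replicate-mean trace is
  # the mean of these, so the bootstrap can work on scalars
  wins <- list(early = early_window, peak = peak_window, plateau = plateau_window)
  wm_num <- lapply(wins, function(w) colMeans(mn[win_idx(w), , drop = FALSE]))
  wm_den <- lapply(wins, function(w) colMeans(md[win_idx(w), , drop = FALSE]))

  windows <- list(
    early = list(mean = mean(wm_num$early) / mean(wm_den$early), window = early_window),
    peak = list(mean = mean(wm_num$peak) / mean(wm_den$peak),
                window = peak_window, center_s = peak_center),
    plateau = list(mean = mean(wm_num$plateau) / mean(wm_den$plateau),
                   window = plateau_window))

  # bootstrap SE over replicates (ratio of resampled means)
  if (n_boot > 0 && (length(traces_num) > 1 || length(traces_den) > 1)) {
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        bi <- sample(ncol(mn), replace = TRUE)
        bj <- sample(ncol(md), replace = TRUE)
        vapply(names(wins), function(w)
          mean(wm_num[[w]][bi]) / mean(wm_den[[w]][bj]), numeric(1))
      }, numeric(3))
    })
    ses <- apply(boots, 1, stats::sd)
    windows$early$se <- ses[1]; windows$peak$se <- ses[2]; windows$plateau$se <- ses[3]
  }
  structure(list(series = series, windows = windows, wavelength = wavelength,
                 n_num = length(traces_num), n_den = length(traces_den),
                 seed = seed),
            class = "condition_ratio")
}

#' @export
print.condition_ratio <- function(x, ...) {
  w <- x$windows
  cat(sprintf("condition ratio @ %d nm (n = %d/%d): early %.3f, peak %.3f (at %.4g s), plateau %.3f\n",
              x$wavelength, x$n_num, x$n_den,
              w$early$mean, w$peak$mean, w$peak$center_s, w$plateau$mean))
  invisible(x)
}

#' Predicted condition ratio from elongation kinetics alone
#'
#' Ratio of the ensemble scattered intensities (`<l^2 P(90)> / <l>`) at
#' one wavelength for two growth models with equal mass per cross
#' section: the contribution of the different elongation rates to the
#' measured condition ratio in the absence of any lateral difference.
#' When the numerator condition elongates faster, its shape factor
#' saturates first, producing a transient peak > 1 that relaxes back to 1
#' as both conditions saturate.
#'
#' @param rate_num,rate_den Elongation rates, ULFs/min, `> 0`.
#' @param wavelength Wavelength in nm.
#' @param times_s Evaluation times in seconds.
#' @param start_length Start length in ULFs (default 1).
#' @param geometry A [ulf_geometry()].
#' @return List: `series` (data.frame time_s, ratio), `peak_value`,
#'   `peak_time_s` (NA when the series is flat).
#' @export
predict_elongation_only <- function(rate_num, rate_den, wavelength = 405,
                                    times_s = 10^seq(0, log10(600), length.out = 200),
                                    start_length = 1,
                                    geometry = ulf_geometry()) {
  if (rate_num <= 0 || rate_den <= 0) stop("rates must be positive")
  e_num <- .elongation_term(times_s, rate_num, wavelength, geometry, start_length)
  e_den <- .elongation_term(times_s, rate_den, wavelength, geometry, start_length)
  series <- data.frame(time_s = times_s, ratio = e_num / e_den)
  i <- which.max(series$ratio)
  has_peak <- max(series$ratio) - 1 > 1e-6
  list(series = series,
       peak_value = if (has_peak) series$ratio[i] else 1,
       peak_time_s = if (has_peak) series$time_s[i] else NA_real_)
}

#' Decompose a measured condition ratio into mass per cross section
#'
#' A measured window-averaged condition ratio combines the elongation
#' contribution (predictable from the fitted rates) with the relative
#' filament mass per cross section; dividing out the predicted
#' elongation-only ratio leaves the mass fold. For the plateau window the
#' predicted ratio is 1 by construction (both conditions past
#' shape-factor saturation).
#'
#' @param measured A [condition_ratio()] object, or a single measured
#'   window average.
#' @param predicted_ratio Elongation-only predicted ratio at the window
#'   (e.g. `peak_value` of [predict_elongation_only()]); must be positive.
#' @param window `"peak"` or `"plateau"` (selects the window when
#'   `measured` is a `condition_ratio`).
#' @return List of class `mass_per_cs`: `fold_factor`, `window`,
#'   `measured`, `predicted_ratio`.
#' @export
mass_per_cross_section <- function(measured, predicted_ratio = 1,
                                   window = c("plateau", "peak")) {
  window <- match.arg(window)
  if (!is.finite(predicted_ratio) || predicted_ratio <= 0)
    stop("predicted ratio must be positive")
  m <- if (inherits(measured, "condition_ratio"))
    measured$windows[[window]]$mean else as.numeric(measured)
  structure(list(fold_factor = m / predicted_ratio, window = window,
                 measured = m, predicted_ratio = predicted_ratio),
            class = "mass_per_cs")
}

#' @export
print.mass_per_cs <- function(x, ...) {
  cat(sprintf("mass per cross section: %.3f-fold (window %s: measured %.3f / predicted %.3f)\n",
              x$fold_factor, x$window, x$measured, x$predicted_ratio))
  invisible(x)
}
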