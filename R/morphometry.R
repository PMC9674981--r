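#' Fit a log-normal distribution to filament lengths
#'
#' Maximum-likelihood fit: geometric mean `exp(mean(log(x)))` and log-SD
#' with the population (divide by n) convention, optionally expressed in
#' a different logarithm base (base 10 matches the units of the empirical
#' width law, see [sigma_from_mean()]).
#'
#' @param lengths Positive lengths (any unit); at least 5 samples.
#' @param log_base Base for the reported log-SD (default natural).
#' @return List with `l_fil` (geometric mean, input units), `sigma`
#'   (log-SD in `log_base`), `n`.
#' @export
#' @examples
#' fit_lognormal(c(1, exp(2), 1, exp(2), 1))
fit_lognormal <- function(lengths, log_base = exp(1)) {
  if (length(lengths) < 5) stop("need at least 5 samples")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("lengths must be finite and positive")
  lx <- log(lengths)
  n <- length(lx)
  sig_ln <- sqrt(sum((lx - mean(lx))^2) / n)
  list(l_fil = exp(mean(lx)), sigma = sig_ln / log(log_base), n = n)
}

#' Estimate the longitudinal assembly rate from length samples
#'
#' Least squares of the per-time-point geometric mean length against
#' time, the analysis applied to AFM length measurements. The slope is
#' the longitudinal assembly rate.
#'
#' Because the length distribution broadens as filaments grow, the
#' geometric-mean uncertainty differs by an order of magnitude between
#' early and late time points. The fit therefore uses inverse-variance
#' weights estimated from each time point's own sample
#' (`var(gm) ~ gm^2 * var(log l) / n`); when any per-point variance is
#' zero (degenerate or noise-free data) it falls back to equal weights.
#'
#' @param table `data.frame(time_s, length_ulf)` (e.g. from
#'   [generate_length_samples()] or a measurement file).
#' @return List with `rate` (ULFs/min), `intercept` (ULFs), and the
#'   per-time-point geometric means (`points`).
#' @export
fit_growth_rate <- function(table) {
  stopifnot(all(c("time_s", "length_ulf") %in% names(table)))
  times <- sort(unique(table$time_s))
  if (length(times) < 3) stop("need at least 3 time points")
  stats_at <- vapply(times, function(tt) {
    lx <- log(table$length_ulf[table$time_s == tt])
    m <- mean(lx)
    c(gm = exp(m), var_gm = exp(2 * m) * mean((lx - m)^2) / length(lx))
  }, numeric(2))
  gm <- stats_at["gm", ]
  var_gm <- stats_at["var_gm", ]
  w <- if (any(var_gm <= 0)) rep(1, length(gm)) else 1 / var_gm
  t_min <- times / 60
  fit <- stats::lm(gm ~ t_min, weights = w)
  list(rate = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       points = data.frame(time_s = times, geom_mean_ulf = gm))
}

#' Fit the width law sigma(l_fil)
#'
#' Unweighted least squares of the log-SD against the geometric mean
#' length across populations, recovering the slope and intercept of the
#' empirical width law.
#'
#' @param pairs `data.frame(l_fil, sigma)`, at least 3 rows.
#' @return List with `slope` and `intercept`.
#' @export
fit_sigma_relation <- function(pairs) {
  stopifnot(all(c("l_fil", "sigma") %in% names(pairs)))
  if (nrow(pairs) < 3) stop("need at least 3 (l_fil, sigma) pairs")
  fit <- stats::lm(sigma ~ l_fil, data = pairs)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

#' Summarize filament diameters over time
#'
#' Per-time-point mean, SD and n of measured diameters, plus the
#' transient-compaction summary: the peak-time mean and its percent
#' excess over the final (mature) mean.
#'
#' @param records `data.frame(time_s, diameter_nm)`.
#' @return List of class `diameter_summary`: `by_time` (data.frame
#'   time_s, mean_nm, sd_nm, n), `peak_time_s`, `peak_mean_nm`,
#'   `final_mean_nm`, `percent_excess`.
#' @export
summarize_diameters <- function(records) {
  stopifnot(all(c("time_s", "diameter_nm") %in% names(records)))
  if (any(!is.finite(records$diameter_nm))) stop("diameters must be finite")
  times <- sort(unique(records$time_s))
  by_time <- do.call(rbind, lapply(times, function(tt) {
    d <- records$diameter_nm[records$time_s == tt]
    data.frame(time_s = tt, mean_nm = mean(d),
               sd_nm = if (length(d) > 1) stats::sd(d) else 0, n = length(d))
  }))
  i_peak <- which.max(by_time$mean_nm)
  final <- by_time$mean_nm[nrow(by_time)]
  structure(list(by_time = by_time,
                 peak_time_s = by_time$time_s[i_peak],
                 peak_mean_nm = by_time$mean_nm[i_peak],
                 final_mean_nm = final,
                 percent_excess = 100 * (by_time$mean_nm[i_peak] / final - 1)),
            class = "diameter_summary")
}

#' @export
print.diameter_summary <- function(x, ...) {
  cat(sprintf("diameters: peak %.3g nm at %.4g s, final %.3g nm (%.1f%% excess)\n",
              x$peak_mean_nm, x$peak_time_s, x$final_mean_nm, x$percent_excess))
  invisible(x)
}
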