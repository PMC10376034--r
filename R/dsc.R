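# DSC curve analysis: reference subtraction, endpoint-anchored linear
# baseline correction inside the 30-52 degC window, and transition readout
# from the curve maxima (pretransition T_p,m and main transition T_m,m).

#' Subtract a reference DSC curve from a sample curve
#'
#' The reference is linearly interpolated onto the sample grid; the result is
#' restricted to the overlapping temperature range.
#'
#' @param sample,reference `dsc_curve` tibbles.
#' @return A `dsc_curve` on the overlapping part of the sample grid.
#' @export
subtract_reference <- function(sample, reference) {
  lo <- max(min(sample$temperature), min(reference$temperature))
  hi <- min(max(sample$temperature), max(reference$temperature))
  if (lo > hi) abort("sample and reference temperature ranges do not overlap")
  keep <- sample$temperature >= lo & sample$temperature <= hi
  Tg <- sample$temperature[keep]
  ref <- approx(reference$temperature, reference$cp_excess, xout = Tg)$y
  dsc_curve(Tg, sample$cp_excess[keep] - ref)
}

#' Baseline-correct a DSC curve inside an analysis window
#'
#' Subtracts the straight line through the mean signal of the first and last
#' 1 degC of the window and restricts the output to the window, so the
#' window endpoints average to zero.
#'
#' @param curve A `dsc_curve` tibble.
#' @param window Length-2 numeric analysis window in degC (default
#'   `c(30, 52)`).
#' @param edge Width of the endpoint averaging region, degC (default 1).
#' @return A baseline-corrected `dsc_curve` restricted to `window`.
#' @export
baseline_correct <- function(curve, window = c(30, 52), edge = 1) {
  assert_that(window[1] < window[2], "window must be increasing")
  if (window[1] < min(curve$temperature) || window[2] > max(curve$temperature)) {
    abort("analysis window lies outside the data range")
  }
  keep <- curve$temperature >= window[1] & curve$temperature <= window[2]
  Tg <- curve$temperature[keep]
  y <- curve$cp_excess[keep]
  lo_idx <- Tg <= window[1] + edge
  hi_idx <- Tg >= window[2] - edge
  x_lo <- mean(Tg[lo_idx]); y_lo <- mean(y[lo_idx])
  x_hi <- mean(Tg[hi_idx]); y_hi <- mean(y[hi_idx])
  slope <- (y_hi - y_lo) / (x_hi - x_lo)
  dsc_curve(Tg, y - (y_lo + slope * (Tg - x_lo)))
}

#' Read transition temperatures off a baseline-corrected DSC curve
#'
#' The main transition `T_m_m` is the temperature of the global maximum. The
#' pretransition `T_p_m` is the most prominent local maximum at least
#' `min_separation` degC below `T_m_m` whose prominence reaches
#' `min_prominence_frac` of the global maximum; it is `NA` when none
#' qualifies (e.g. peptides in buffer show no thermotropic event at all,
#' which raises "no transition detected").
#'
#' @param curve A baseline-corrected `dsc_curve`.
#' @param min_prominence_frac Prominence threshold as a fraction of the
#'   global maximum (default 0.05).
#' @param min_separation Minimum pretransition-to-main separation, degC
#'   (default 2).
#' @return A tibble of class `transition_temps` with columns `T_p_m`,
#'   `T_m_m`, `prominence_p`, `prominence_m`.
#' @export
find_transitions <- function(curve, min_prominence_frac = 0.05,
                             min_separation = 2) {
  y <- curve$cp_excess
  Tg <- curve$temperature
  # flat or noise-only curves: the global max must clear the noise floor
  if (max(y) <= 0 || max(y) < 5 * stats::mad(y, center = 0)) {
    abort("no transition detected")
  }
  pk <- find_peaks(y, min_prominence = 0)
  if (!nrow(pk)) abort("no transition detected")
  main <- pk[1, ]
  T_m_m <- Tg[main$idx]
  cand <- pk[Tg[pk$idx] <= T_m_m - min_separation &
               pk$prominence >= min_prominence_frac * max(y), , drop = FALSE]
  if (nrow(cand)) {
    pre <- cand[which.max(cand$prominence), ]
    T_p_m <- Tg[pre$idx]
    prom_p <- pre$prominence
  } else {
    T_p_m <- NA_real_
    prom_p <- NA_real_
  }
  out <- tibble::tibble(T_p_m = T_p_m, T_m_m = T_m_m,
                        prominence_p = prom_p, prominence_m = main$prominence)
  class(out) <- c("transition_temps", class(out))
  out
}
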