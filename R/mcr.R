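# Rank-1 multivariate curve resolution of temperature-dependent spectra and
# double-Boltzmann readout of the phase-transition temperatures.
#
# The measured absorbance matrix is modelled bilinearly, D = c s' + E, with a
# single component whose concentration profile c(T) carries all temperature
# dependence. Fitting c(T) with a sum of two logistic sigmoids puts the
# pretransition and main-transition temperatures at the inflection points.

#' Savitzky-Golay smoothing of a spectra series along the wavelength axis
#'
#' Each temperature's spectrum is smoothed independently. A cubic through an
#' 11-point window is the default (an odd window is required, so a nominal
#' 10-point window is widened to 11).
#'
#' @param series A [spectra_series()] tibble.
#' @param window Odd window length in samples.
#' @param degree Polynomial degree.
#' @return A smoothed [spectra_series()].
#' @export
smooth_sg <- function(series, window = 11L, degree = 3L) {
  sm <- spectra_matrix(series)
  Ds <- t(apply(sm$D, 1, savitzky_golay, window = window, degree = degree))
  spectra_series(sm$temperatures, sm$wavelengths, Ds)
}

#' Rank-1 multivariate curve resolution by alternating least squares
#'
#' Factorizes the absorbance matrix as `D = c s' + E` under nonnegativity of
#' both profiles, with the bilinear scale fixed by max-normalizing the
#' spectral profile (`max(s) = 1`). Alternation stops when the relative
#' change of the residual Frobenius norm drops below `tol`.
#'
#' @param series A [spectra_series()] tibble.
#' @param tol Relative convergence tolerance on `||E||_F` (default 1e-10).
#' @param max_iter Iteration cap (default 500).
#' @return An object of class `bilinear_model`: list with `c` (concentration
#'   profile over temperature), `s` (spectral profile over wavelength,
#'   max-normalized), `E` (residual matrix), `explained_variance`,
#'   `iterations`, `temperatures`, `wavelengths`.
#' @export
rank1_mcr <- function(series, tol = 1e-10, max_iter = 500L) {
  sm <- spectra_matrix(series)
  D <- sm$D
  assert_that(nrow(D) >= 2 && ncol(D) >= 2, "D must be at least 2 x 2")
  normD <- sqrt(sum(D^2))
  if (normD == 0) abort("degenerate input: all-zero absorbance matrix")

  # init s from the dominant right singular vector, sign-fixed nonnegative
  s <- svd(D, nu = 0, nv = 1)$v[, 1]
  if (sum(s) < 0) s <- -s
  s <- pmax(s, 0)
  if (max(s) == 0) s <- rep(1, ncol(D))
  s <- s / max(s)

  prev <- Inf
  it <- 0L
  repeat {
    it <- it + 1L
    cvec <- pmax(as.vector(D %*% s) / sum(s^2), 0)
    if (all(cvec == 0)) abort("degenerate input: concentration profile collapsed")
    s <- pmax(as.vector(crossprod(D, cvec)) / sum(cvec^2), 0)
    smax <- max(s)
    if (smax == 0) abort("degenerate input: spectral profile collapsed")
    cvec <- cvec * smax
    s <- s / smax
    resid <- sqrt(sum((D - tcrossprod(cvec, s))^2))
    if (it >= max_iter || abs(prev - resid) <= tol * max(resid, normD * 1e-16)) {
      break
    }
    prev <- resid
  }
  E <- D - tcrossprod(cvec, s)
  structure(list(
    c = cvec, s = s, E = E,
    explained_variance = 1 - sum(E^2) / sum(D^2),
    iterations = it,
    temperatures = sm$temperatures,
    wavelengths = sm$wavelengths
  ), class = "bilinear_model")
}

#' @export
print.bilinear_model <- function(x, ...) {
  cat(sprintf("<bilinear_model> rank-1 MCR, %d iterations, explained variance %.6f\n",
              x$iterations, x$explained_variance))
  invisible(x)
}

# peaks of |dc/dT| used to initialise the two sigmoid midpoints; the profile
# is smoothed fairly hard first since only rough peak locations are needed,
# and peaks are kept by height (a weak pretransition shoulder can have low
# topographic prominence under noise yet still be a clear derivative peak)
derivative_peaks <- function(temperatures, c_profile, min_height_frac = 0.1) {
  w <- min(15L, length(c_profile) - (1 - length(c_profile) %% 2L))
  w <- w - (1L - w %% 2L) # force odd
  csm <- if (w >= 5) savitzky_golay(c_profile, window = w, degree = 3L)
         else c_profile
  g <- abs(c(diff(csm)[1], diff(csm, lag = 2) / 2, diff(csm)[length(csm) - 1]) /
             c(diff(temperatures)[1], diff(temperatures, lag = 2) / 2,
               diff(temperatures)[length(temperatures) - 1]))
  pk <- find_peaks(g, min_prominence = 0)
  pk[pk$value >= min_height_frac * max(g), , drop = FALSE]
}

#' Fit a double-Boltzmann sigmoid to a concentration profile
#'
#' Nonlinear least squares of
#' `a0 + a1 / (1 + exp((T_p - T) / w_p)) + a2 / (1 + exp((T_m - T) / w_m))`,
#' initialised from the two most prominent peaks of the smoothed numerical
#' derivative. Standard errors come from the fit covariance; fit quality is
#' `R^2 = 1 - SS_res / SS_tot`.
#'
#' @param c_profile Concentration profile values (length >= 8).
#' @param temperatures Matching strictly increasing temperatures, degC.
#' @return An object of class `double_boltzmann_fit` with elements `a0`,
#'   `a1`, `a2`, `T_p`, `T_m`, `w_p`, `w_m`, `se_Tp`, `se_Tm`, `r_squared`,
#'   `fitted`, `temperatures`, `c_profile`.
#' @export
fit_double_boltzmann <- function(c_profile, temperatures) {
  assert_that(length(c_profile) >= 8, "need at least 8 profile points")
  check_strictly_increasing(temperatures, "temperatures")
  assert_that(length(c_profile) == length(temperatures),
              "profile and temperature lengths differ")

  pk <- derivative_peaks(temperatures, c_profile)
  pk <- pk[order(-pk$value), , drop = FALSE]
  # drop peaks closer than 2 degC to an already-kept stronger peak
  keep <- integer()
  for (i in pk$idx) {
    if (!length(keep) ||
        all(abs(temperatures[i] - temperatures[keep]) >= 2)) {
      keep <- c(keep, i)
    }
  }
  if (length(keep) < 2) abort("transitions not separable")
  keep <- sort(keep[1:2])
  Tp0 <- temperatures[keep[1]]
  Tm0 <- temperatures[keep[2]]

  mid <- which.min(abs(temperatures - (Tp0 + Tm0) / 2))
  a0_0 <- c_profile[1]
  a1_0 <- c_profile[mid] - c_profile[1]
  a2_0 <- c_profile[length(c_profile)] - c_profile[mid]
  df <- data.frame(T = temperatures, y = c_profile)
  rngT <- range(temperatures)
  fit <- tryCatch(
    nls(y ~ a0 + a1 / (1 + exp((Tp - T) / wp)) + a2 / (1 + exp((Tm - T) / wm)),
        data = df,
        start = list(a0 = a0_0, a1 = a1_0, a2 = a2_0,
                     Tp = Tp0, Tm = Tm0, wp = 1, wm = 0.5),
        algorithm = "port",
        lower = c(a0 = -Inf, a1 = -Inf, a2 = -Inf,
                  Tp = rngT[1], Tm = rngT[1], wp = 0.05, wm = 0.05),
        upper = c(a0 = Inf, a1 = Inf, a2 = Inf,
                  Tp = rngT[2], Tm = rngT[2], wp = 10, wm = 10),
        control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) {
      abort(sprintf("double-Boltzmann fit did not converge: %s",
                    conditionMessage(e)))
    })
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  # order the two sigmoids so T_p < T_m
  if (est["Tp"] > est["Tm"]) {
    est[c("Tp", "Tm", "wp", "wm", "a1", "a2")] <-
      est[c("Tm", "Tp", "wm", "wp", "a2", "a1")]
    se[c("Tp", "Tm")] <- se[c("Tm", "Tp")]
  }
  fitted_vals <- double_boltzmann(temperatures, est["a0"], est["a1"],
                                  est["a2"], est["Tp"], est["Tm"],
                                  est["wp"], est["wm"])
  ss_res <- sum((c_profile - fitted_vals)^2)
  ss_tot <- sum((c_profile - mean(c_profile))^2)
  structure(list(
    a0 = unname(est["a0"]), a1 = unname(est["a1"]), a2 = unname(est["a2"]),
    T_p = unname(est["Tp"]), T_m = unname(est["Tm"]),
    w_p = unname(est["wp"]), w_m = unname(est["wm"]),
    se_Tp = unname(se["Tp"]), se_Tm = unname(se["Tm"]),
    r_squared = 1 - ss_res / ss_tot,
    fitted = unname(fitted_vals),
    temperatures = temperatures,
    c_profile = c_profile
  ), class = "double_boltzmann_fit")
}

#' @export
print.double_boltzmann_fit <- function(x, ...) {
  cat(sprintf(
    "<double_boltzmann_fit> T_p = %.2f +/- %.2f degC, T_m = %.2f +/- %.2f degC, R^2 = %.5f\n",
    x$T_p, x$se_Tp, x$T_m, x$se_Tm, x$r_squared))
  invisible(x)
}

#' Extract phase-transition temperatures from a spectra series
#'
#' Composition of the full pipeline: Savitzky-Golay smoothing along the
#' wavelength axis, rank-1 multivariate curve resolution, and a
#' double-Boltzmann fit of the resulting concentration profile.
#'
#' @param series A [spectra_series()] tibble.
#' @param window,degree Smoothing parameters; `window = NULL` skips
#'   smoothing.
#' @param tol,max_iter Passed to [rank1_mcr()].
#' @return A `double_boltzmann_fit` whose `explained_variance` element
#'   additionally records the MCR explained variance.
#' @export
extract_transitions <- function(series, window = 11L, degree = 3L,
                                tol = 1e-10, max_iter = 500L) {
  if (!is.null(window)) {
    series <- smooth_sg(series, window = window, degree = degree)
  }
  model <- rank1_mcr(series, tol = tol, max_iter = max_iter)
  fit <- fit_double_boltzmann(model$c, model$temperatures)
  fit$explained_variance <- model$explained_variance
  fit
}
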