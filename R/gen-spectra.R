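# Seeded generators for the three spectroscopic measurements. Each generator
# inverts the matching analysis model so that parameter recovery is testable.
# Draw order is documented per generator and is part of the contract: a given
# seed always produces bit-identical output.

#' Double-Boltzmann sigmoid
#'
#' Sum of two logistic steps,
#' `a0 + a1 / (1 + exp((T_p - T) / w_p)) + a2 / (1 + exp((T_m - T) / w_m))`.
#' Its inflection points sit exactly at `T_p` and `T_m`, which is how the
#' pretransition and main phase-transition temperatures are read off a
#' fitted concentration profile.
#'
#' @param T Temperatures, degC.
#' @param a0,a1,a2 Offset and step amplitudes.
#' @param T_p,T_m Transition midpoints, degC.
#' @param w_p,w_m Transition widths, degC (> 0).
#' @return Numeric vector of profile values.
#' @export
double_boltzmann <- function(T, a0, a1, a2, T_p, T_m, w_p, w_m) {
  a0 + a1 / (1 + exp((T_p - T) / w_p)) + a2 / (1 + exp((T_m - T) / w_m))
}

# Fixed turbidity-like spectral shape: smooth positive monotone decay over
# the wavelength axis, max-normalized at the blue end.
turbidity_shape <- function(lambda) {
  exp(-(lambda - min(lambda)) / 40)
}

#' Generate a synthetic temperature-dependent turbidity spectra series
#'
#' Builds `D[i, j] = c(T_i) * s(lambda_j) + eps` with `c` the
#' double-Boltzmann profile of `params` and `s` a fixed smooth positive
#' monotone-decaying spectral shape; `eps` is iid Gaussian with sd
#' `params$noise_sd`. With zero noise the matrix is exactly rank 1.
#'
#' Draw order: the m x n noise matrix is drawn column-major in one
#' `rnorm(m * n)` call.
#'
#' @param params A [thermo_params()] object.
#' @param seed Integer seed; the generator is deterministic given it.
#' @return A [spectra_series()] tibble.
#' @export
gen_uvvis <- function(params = thermo_params(), seed = 1) {
  validate_thermo_params(params)
  Tg <- params$T_grid
  lg <- params$lambda_grid
  cT <- double_boltzmann(Tg, params$a0, params$a1, params$a2,
                         params$T_p, params$T_m, params$w_p, params$w_m)
  s <- turbidity_shape(lg)
  D <- outer(cT, s)
  if (params$noise_sd > 0) {
    withr::local_seed(seed)
    D <- D + matrix(rnorm(length(D), sd = params$noise_sd),
                    nrow = nrow(D))
  }
  spectra_series(Tg, lg, D)
}

#' Generate a synthetic DSC excess heat capacity curve
#'
#' Two Gaussian peaks (pretransition and main transition) on a linear
#' baseline plus iid Gaussian noise, sampled on a 20-60 degC grid at
#' 0.1 degC steps. Draw order: one `rnorm(n_grid)` call.
#'
#' @param shape A [dsc_shape()] object.
#' @param seed Integer seed.
#' @return A tibble of class `dsc_curve` with columns `temperature` (degC)
#'   and `cp_excess`.
#' @export
gen_dsc <- function(shape = dsc_shape(), seed = 1) {
  Tg <- seq(20, 60, by = 0.1)
  gauss <- function(h, mu, w) h * exp(-0.5 * ((Tg - mu) / w)^2)
  cp <- gauss(shape$height_p, shape$T_p_m, shape$width_p) +
    gauss(shape$height_m, shape$T_m_m, shape$width_m) +
    shape$baseline_offset + shape$baseline_slope * (Tg - min(Tg))
  if (shape$noise_sd > 0) {
    withr::local_seed(seed)
    cp <- cp + rnorm(length(Tg), sd = shape$noise_sd)
  }
  dsc_curve(Tg, cp)
}

#' Construct a DSC curve tibble
#'
#' @param temperatures Strictly increasing temperatures, degC.
#' @param cp_excess Excess heat capacity values (consistent arbitrary units).
#' @return A tibble of class `dsc_curve`.
#' @export
dsc_curve <- function(temperatures, cp_excess) {
  check_strictly_increasing(temperatures, "temperatures")
  assert_that(length(temperatures) == length(cp_excess),
              "temperature and cp_excess lengths differ")
  out <- tibble::tibble(temperature = temperatures, cp_excess = cp_excess)
  class(out) <- c("dsc_curve", class(out))
  out
}

pseudo_voigt <- function(x, center, height, fwhm, eta) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  gamma <- fwhm / 2
  g <- exp(-0.5 * ((x - center) / sigma)^2)
  l <- gamma^2 / ((x - center)^2 + gamma^2)
  height * ((1 - eta) * g + eta * l)
}

#' Generate a synthetic infrared spectrum from pseudo-Voigt bands
#'
#' Sum of pseudo-Voigt profiles plus a linear baseline plus iid Gaussian
#' noise, sampled on a uniform wavenumber grid. Draw order: one
#' `rnorm(n_grid)` call.
#'
#' @param bands List of [band_spec()] objects; every centre must fall inside
#'   the grid.
#' @param baseline_slope Baseline slope per cm^-1 (intercept anchored at the
#'   low-wavenumber end).
#' @param noise_sd Noise standard deviation, absorbance units.
#' @param grid Numeric length-2 range `c(lo, hi)` in cm^-1.
#' @param step Grid spacing, cm^-1 (default 1).
#' @param seed Integer seed.
#' @param system,temperature Labels recorded on the output.
#' @return A tibble of class `ftir_spectrum` with columns `wavenumber`,
#'   `absorbance`, `system`, `temperature`.
#' @export
gen_ftir <- function(bands, baseline_slope = -1e-4, noise_sd = 0.003,
                     grid = c(2820, 3000), step = 1, seed = 1,
                     system = "dppc", temperature = 30) {
  x <- seq(grid[1], grid[2], by = step)
  for (b in bands) {
    if (b$center < grid[1] || b$center > grid[2]) {
      abort(sprintf("band at %g cm^-1 lies outside the grid [%g, %g]",
                    b$center, grid[1], grid[2]))
    }
  }
  y <- baseline_slope * (x - grid[1])
  for (b in bands) {
    y <- y + pseudo_voigt(x, b$center, b$height, b$fwhm, b$lorentz_fraction)
  }
  if (noise_sd > 0) {
    withr::local_seed(seed)
    y <- y + rnorm(length(x), sd = noise_sd)
  }
  ftir_spectrum(x, y, system = system, temperature = temperature)
}

#' Construct an infrared spectrum tibble
#'
#' @param wavenumbers Strictly increasing, uniformly spaced grid, cm^-1.
#' @param absorbance Absorbance values.
#' @param system,temperature Sample labels (system id and acquisition
#'   temperature in degC).
#' @return A tibble of class `ftir_spectrum`.
#' @export
ftir_spectrum <- function(wavenumbers, absorbance, system = "dppc",
                          temperature = 30) {
  check_strictly_increasing(wavenumbers, "wavenumbers")
  assert_that(length(wavenumbers) == length(absorbance),
              "wavenumber and absorbance lengths differ")
  sp <- diff(wavenumbers)
  assert_that(max(abs(sp - sp[1])) < 1e-8 * max(sp),
              "wavenumber grid must be uniform")
  out <- tibble::tibble(wavenumber = wavenumbers, absorbance = absorbance,
                        system = system, temperature = temperature)
  class(out) <- c("ftir_spectrum", class(out))
  out
}
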