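# Tidy containers for the spectroscopic data types. A spectra series is a
# long tibble (temperature, wavelength, absorbance) representing the
# temperature-by-wavelength absorbance matrix D; helpers convert to/from the
# matrix form the factorization works on.

#' Build a temperature-by-wavelength spectra series
#'
#' @param temperatures Strictly increasing temperature axis, degC (length m).
#' @param wavelengths Strictly increasing wavelength axis, nm (length n).
#' @param D m x n absorbance matrix (rows = temperatures).
#' @return A tibble of class `spectra_series` with columns `temperature`,
#'   `wavelength`, `absorbance` in row-major (temperature-blocked) order.
#' @export
spectra_series <- function(temperatures, wavelengths, D) {
  check_strictly_increasing(temperatures, "temperatures")
  check_strictly_increasing(wavelengths, "wavelengths")
  D <- as.matrix(D)
  assert_that(nrow(D) == length(temperatures) && ncol(D) == length(wavelengths),
              "D must be length(temperatures) x length(wavelengths)")
  assert_that(all(is.finite(D)), "D must be finite")
  out <- tibble::tibble(
    temperature = rep(temperatures, each = length(wavelengths)),
    wavelength = rep(wavelengths, times = length(temperatures)),
    absorbance = as.vector(t(D))
  )
  class(out) <- c("spectra_series", class(out))
  out
}

#' @export
print.spectra_series <- function(x, ...) {
  ax <- spectra_axes(x)
  cat(sprintf("<spectra_series> %d temperatures (%.1f-%.1f degC) x %d wavelengths (%g-%g nm)\n",
              length(ax$temperatures), min(ax$temperatures), max(ax$temperatures),
              length(ax$wavelengths), min(ax$wavelengths), max(ax$wavelengths)))
  NextMethod()
}

spectra_axes <- function(series) {
  list(temperatures = sort(unique(series$temperature)),
       wavelengths = sort(unique(series$wavelength)))
}

# long tibble -> m x n matrix with rows ordered by temperature
spectra_matrix <- function(series) {
  assert_that(all(c("temperature", "wavelength", "absorbance") %in%
                    names(series)),
              "a spectra series needs temperature, wavelength, absorbance columns")
  ax <- spectra_axes(series)
  m <- length(ax$temperatures)
  n <- length(ax$wavelengths)
  assert_that(nrow(series) == m * n,
              "spectra series is not a complete temperature x wavelength grid")
  ord <- order(series$temperature, series$wavelength)
  D <- matrix(series$absorbance[ord], nrow = m, ncol = n, byrow = TRUE)
  list(D = D, temperatures = ax$temperatures, wavelengths = ax$wavelengths)
}
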