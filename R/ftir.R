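# Region-wise infrared band analysis: buffer subtraction, crop + smooth +
# two-point baseline + max-normalization, prominence-based peak picking with
# parabolic refinement, and gel->fluid band-shift bookkeeping.

FTIR_REGION_IDS <- c("i", "ii", "iii", "iv", "v", "vi")

#' The six infrared analysis regions
#'
#' (i) 3000-2820 cm^-1 methylene/methyl stretches; (ii) 1780-1695 cm^-1
#' carbonyl stretch; (iii) 1515-1360 cm^-1 methylene scissoring,
#' carboxylate stretch and protonated-amine bending; (iv) 1275-1190 cm^-1
#' antisymmetric phosphate stretch; (v) 1130-1020 cm^-1 symmetric phosphate
#' and C-O stretches; (vi) 990-940 cm^-1 choline modes.
#'
#' @return A tibble with columns `region`, `lo`, `hi`, `description`.
#' @export
ftir_regions <- function() {
  tibble::tibble(
    region = FTIR_REGION_IDS,
    lo = c(2820, 1695, 1360, 1190, 1020, 940),
    hi = c(3000, 1780, 1515, 1275, 1130, 990),
    description = c(
      "(anti)symmetric CH2 and antisymmetric CH3 stretches",
      "glycerol-backbone C=O stretch",
      "CH2 scissoring, COO- symmetric stretch, NH3+ bending",
      "antisymmetric PO2- and C-O stretches",
      "symmetric PO2- and C-O stretches",
      "choline N(CH3)3+ antisymmetric stretch/bend"
    )
  )
}

region_bounds <- function(region) {
  region <- match.arg(region, FTIR_REGION_IDS)
  r <- ftir_regions()
  r[r$region == region, , drop = FALSE]
}

#' Subtract a buffer spectrum from a sample spectrum
#'
#' Both spectra must carry the same acquisition temperature label; the buffer
#' is linearly interpolated onto the sample grid if the grids differ.
#'
#' @param sample,buffer `ftir_spectrum` tibbles.
#' @return The pointwise difference as an `ftir_spectrum` with the sample's
#'   labels.
#' @export
subtract_buffer <- function(sample, buffer) {
  st <- unique(sample$temperature)
  bt <- unique(buffer$temperature)
  if (!identical(st, bt)) {
    abort(sprintf(
      "temperature mismatch: sample at %g degC, buffer at %g degC",
      st[1], bt[1]))
  }
  b <- if (isTRUE(all.equal(sample$wavenumber, buffer$wavenumber))) {
    buffer$absorbance
  } else {
    approx(buffer$wavenumber, buffer$absorbance,
           xout = sample$wavenumber, rule = 2)$y
  }
  ftir_spectrum(sample$wavenumber, sample$absorbance - b,
                system = unique(sample$system)[1], temperature = st[1])
}

#' Preprocess a spectrum within one analysis region
#'
#' Crop to the region, Savitzky-Golay smooth (cubic, 21-point window by
#' default; `window = NULL` skips smoothing, as done for the C-H stretching
#' region), subtract the straight line through the two region endpoint
#' samples, and divide by the region maximum so the tallest point is 1.
#'
#' @param spectrum An `ftir_spectrum` tibble.
#' @param region Region id (`"i"` ... `"vi"`).
#' @param window Odd SG window or `NULL` to skip smoothing.
#' @param degree SG polynomial degree.
#' @return A preprocessed `ftir_spectrum` restricted to the region.
#' @export
preprocess_region <- function(spectrum, region = "i", window = 21L,
                              degree = 3L) {
  rb <- region_bounds(region)
  assert_that(rb$lo >= min(spectrum$wavenumber) &&
                rb$hi <= max(spectrum$wavenumber),
              sprintf("region (%s) [%g, %g] lies outside the spectrum grid",
                      region, rb$lo, rb$hi))
  keep <- spectrum$wavenumber >= rb$lo & spectrum$wavenumber <= rb$hi
  x <- spectrum$wavenumber[keep]
  y <- spectrum$absorbance[keep]
  if (!is.null(window)) {
    y <- savitzky_golay(y, window = window, degree = degree)
  }
  n <- length(y)
  base <- y[1] + (y[n] - y[1]) * (x - x[1]) / (x[n] - x[1])
  y <- y - base
  top <- max(y)
  if (top <= .Machine$double.eps * 100) abort("no signal in region")
  ftir_spectrum(x, y / top, system = unique(spectrum$system)[1],
                temperature = unique(spectrum$temperature)[1])
}

#' Locate band maxima in a preprocessed region spectrum
#'
#' All local maxima with prominence at or above `min_prominence` (in the
#' region's normalized units), refined with a 3-point parabola and sorted by
#' height descending.
#'
#' @param spectrum A preprocessed `ftir_spectrum`.
#' @param min_prominence Prominence threshold (default 0.05).
#' @return A tibble with columns `position` (cm^-1, refined), `height`,
#'   `prominence`, sorted by decreasing height. May be empty.
#' @export
find_band_peaks <- function(spectrum, min_prominence = 0.05) {
  x <- spectrum$wavenumber
  y <- spectrum$absorbance
  pk <- find_peaks(y, min_prominence = min_prominence)
  tibble::tibble(
    position = vapply(pk$idx, function(i) parabolic_refine(x, y, i),
                      numeric(1)),
    height = pk$value,
    prominence = pk$prominence
  )
}

#' Gel-to-fluid band shift for one expected band
#'
#' Matches, in each peak list, the peak nearest to `expected` (within
#' `match_window` cm^-1) and reports the displacement
#' `delta = fluid - gel`; positive values are high-frequency shifts.
#'
#' @param gel,fluid Peak tibbles from [find_band_peaks()].
#' @param expected Expected band position, cm^-1.
#' @param match_window Maximum |position - expected| for a match (default 8).
#' @return A one-row tibble with `expected`, `gel_position`,
#'   `fluid_position`, `delta` (cm^-1, reported to 1 cm^-1 resolution via
#'   rounding of the positions).
#' @export
band_shift <- function(gel, fluid, expected, match_window = 8) {
  match_one <- function(peaks, label) {
    d <- abs(peaks$position - expected)
    ok <- which(d <= match_window)
    if (!length(ok)) {
      abort(sprintf("band not found near %g cm^-1 in the %s spectrum",
                    expected, label))
    }
    peaks$position[ok[which.min(d[ok])]]
  }
  g <- match_one(gel, "gel")
  f <- match_one(fluid, "fluid")
  tibble::tibble(
    expected = expected,
    gel_position = round(g),
    fluid_position = round(f),
    delta = round(f) - round(g)
  )
}
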