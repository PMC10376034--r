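#' Savitzky-Golay smoothing of a uniformly sampled signal
#'
#' Least-squares local polynomial smoothing: each interior sample is replaced
#' by the value at the window centre of the degree-`degree` polynomial fitted
#' to the surrounding `window` samples. Near the edges the window shrinks
#' symmetrically (down to the identity for the outermost samples), which
#' avoids the endpoint swing of polynomial extrapolation; polynomial signals
#' of degree at most `degree` still pass through unchanged everywhere.
#'
#' @param y Numeric vector sampled on a uniform grid.
#' @param window Odd window length, must exceed `degree` and not exceed
#'   `length(y)`.
#' @param degree Polynomial degree (default 3).
#' @return Smoothed numeric vector, same length as `y`.
#' @export
savitzky_golay <- function(y, window = 11L, degree = 3L) {
  window <- as.integer(window)
  degree <- as.integer(degree)
  assert_that(window %% 2L == 1L, "`window` must be odd")
  assert_that(window > degree, "`window` must exceed `degree`")
  n <- length(y)
  assert_that(window <= n, "`window` larger than the signal length")
  h <- (window - 1L) %/% 2L
  centre_weights <- function(hw) {
    t <- seq(-hw, hw)
    A <- outer(t, 0:degree, `^`)
    solve(crossprod(A), t(A))[1, ] # value at the window centre (t = 0)
  }
  w_full <- centre_weights(h)

  out <- y
  idx <- (h + 1L):(n - h)
  out[idx] <- vapply(idx, function(i) sum(w_full * y[(i - h):(i + h)]),
                     numeric(1))
  # edges: symmetric windows shrink until the fit degenerates to identity
  for (i in seq_len(h)) {
    hw <- i - 1L
    if (2L * hw + 1L > degree) {
      w <- centre_weights(hw)
      out[i] <- sum(w * y[(i - hw):(i + hw)])
      out[n - i + 1L] <- sum(w * y[(n - i + 1L - hw):(n - i + 1L + hw)])
    }
  }
  out
}
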