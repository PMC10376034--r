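# Shared numerical helpers: peak finding with topographic prominence and
# 3-point parabolic refinement of a discrete maximum.

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

#' Locate local maxima with topographic prominence
#'
#' A local maximum is a sample strictly greater than its left neighbour and
#' at least as large as its right neighbour (plateaus yield their leftmost
#' sample). Prominence is the height of the peak above the higher of the two
#' minima that separate it from higher terrain (or the series ends).
#'
#' @param y Numeric vector.
#' @param min_prominence Keep peaks with prominence at or above this value.
#' @return A tibble with columns `idx`, `value`, `prominence`, sorted by
#'   decreasing `value`.
#' @export
find_peaks <- function(y, min_prominence = 0) {
  n <- length(y)
  if (n < 3) {
    return(tibble::tibble(idx = integer(), value = numeric(),
                          prominence = numeric()))
  }
  cand <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  prom <- vapply(cand, function(i) peak_prominence(y, i), numeric(1))
  out <- tibble::tibble(idx = cand, value = y[cand], prominence = prom)
  out <- out[out$prominence >= min_prominence, , drop = FALSE]
  out[order(-out$value), , drop = FALSE]
}

peak_prominence <- function(y, i) {
  h <- y[i]
  left <- if (i > 1) y[1:(i - 1)] else numeric()
  right <- if (i < length(y)) y[(i + 1):length(y)] else numeric()
  side_min <- function(v) {
    # v runs away from the peak; stop at the first sample higher than the peak
    higher <- which(v > h)
    if (length(higher)) v <- v[seq_len(higher[1] - 1)]
    if (length(v)) min(v) else h
  }
  lmin <- side_min(rev(left))
  rmin <- side_min(right)
  h - max(lmin, rmin)
}

# Sub-grid refinement of a maximum at index i via the parabola through
# (i-1, i, i+1); returns the x position (grid assumed uniform).
parabolic_refine <- function(x, y, i) {
  n <- length(y)
  if (i <= 1 || i >= n) return(x[i])
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (denom >= 0 || abs(denom) < .Machine$double.eps) return(x[i])
  delta <- 0.5 * (y[i - 1] - y[i + 1]) / denom
  delta <- max(-0.5, min(0.5, delta))
  x[i] + delta * (x[i + 1] - x[i])
}

check_strictly_increasing <- function(x, name) {
  assert_that(length(x) >= 2 && all(diff(x) > 0),
              sprintf("`%s` must be strictly increasing", name))
}
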