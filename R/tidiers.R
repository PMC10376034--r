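# broom-style accessors and ggplot2 autoplot methods for the fitted objects.

#' Tidy a double-Boltzmann fit
#'
#' @param x A `double_boltzmann_fit`.
#' @param ... Unused.
#' @return One row per parameter with `term`, `estimate`, `std.error`
#'   (standard errors are reported for the two transition temperatures).
#' @export
tidy.double_boltzmann_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a0", "a1", "a2", "T_p", "T_m", "w_p", "w_m"),
    estimate = c(x$a0, x$a1, x$a2, x$T_p, x$T_m, x$w_p, x$w_m),
    std.error = c(NA, NA, NA, x$se_Tp, x$se_Tm, NA, NA)
  )
}

#' @rdname tidy.double_boltzmann_fit
#' @export
glance.double_boltzmann_fit <- function(x, ...) {
  tibble::tibble(T_p = x$T_p, T_m = x$T_m, se_Tp = x$se_Tp, se_Tm = x$se_Tm,
                 r.squared = x$r_squared,
                 explained_variance = x$explained_variance %||% NA_real_,
                 nobs = length(x$temperatures))
}

#' Tidy a rank-1 bilinear model
#'
#' @param x A `bilinear_model`.
#' @param profile `"concentration"` (over temperature) or `"spectral"`
#'   (over wavelength).
#' @param ... Unused.
#' @return A two-column tibble of the requested profile.
#' @export
tidy.bilinear_model <- function(x, profile = c("concentration", "spectral"),
                                ...) {
  profile <- match.arg(profile)
  if (profile == "concentration") {
    tibble::tibble(temperature = x$temperatures, c = x$c)
  } else {
    tibble::tibble(wavelength = x$wavelengths, s = x$s)
  }
}

#' @rdname tidy.bilinear_model
#' @export
glance.bilinear_model <- function(x, ...) {
  tibble::tibble(explained_variance = x$explained_variance,
                 iterations = x$iterations,
                 rmse = sqrt(mean(x$E^2)))
}

#' Plot a double-Boltzmann fit over its concentration profile
#'
#' @param object A `double_boltzmann_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.double_boltzmann_fit <- function(object, ...) {
  df <- tibble::tibble(temperature = object$temperatures,
                       c = object$c_profile, fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$temperature)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$c), alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::geom_vline(xintercept = c(object$T_p, object$T_m),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "temperature (°C)", y = "concentration profile",
                  title = sprintf("T_p = %.1f °C, T_m = %.1f °C",
                                  object$T_p, object$T_m))
}

#' Plot a spectra series as temperature-coloured spectra
#'
#' @param object A `spectra_series`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spectra_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$wavelength,
                                       y = .data$absorbance,
                                       group = .data$temperature,
                                       colour = .data$temperature)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::scale_colour_viridis_c(name = "T (°C)") +
    ggplot2::labs(x = "wavelength (nm)", y = "absorbance")
}

#' Plot a DSC curve
#'
#' @param object A `dsc_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dsc_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$temperature,
                                       y = .data$cp_excess)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "temperature (°C)", y = "excess heat capacity")
}

#' Plot an infrared spectrum
#'
#' @param object An `ftir_spectrum`.
#' @param ... Unused.
#' @return A ggplot object (wavenumber axis reversed, as conventional).
#' @export
autoplot.ftir_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$wavenumber,
                                       y = .data$absorbance)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "wavenumber (cm⁻¹)", y = "absorbance")
}
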