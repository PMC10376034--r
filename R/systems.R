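# Default parameter sets per studied system. Three liposome systems are
# modelled: DPPC' (DPPC + 5% DPPG) alone and with either the arginine-rich
# R5F2 or the lysine-rich K5F2 peptide adsorbed. Transition temperatures come
# from the replicate means reported for each technique; amplitudes, widths
# and noise levels are stated conventions of the synthetic world (see the
# methods vignette).

SYSTEMS <- c("dppc", "dppc-r5f2", "dppc-k5f2")

match_system <- function(system) {
  match.arg(system, SYSTEMS)
}

#' Parameters of the synthetic temperature-dependent turbidity experiment
#'
#' Describes the double-Boltzmann concentration profile (pretransition at
#' `T_p`, main transition at `T_m`, widths `w_p`/`w_m`), the three amplitudes
#' of the profile, the additive noise level, and the acquisition grids.
#' Defaults per system use the UV-Vis-derived transition temperatures:
#' DPPC' 34.4/42.2 degC, +R5F2 33.6/42.0 degC, +K5F2 36.1/44.2 degC.
#' Turbidity decreases through both transitions, so `a1` and `a2` are
#' negative; the profile stays positive as nonnegative curve resolution
#' assumes.
#'
#' @param system One of `"dppc"`, `"dppc-r5f2"`, `"dppc-k5f2"`.
#' @param ... Named overrides of any field.
#' @return A list of class `thermo_params`.
#' @export
thermo_params <- function(system = "dppc", ...) {
  system <- match_system(system)
  tt <- switch(system,
    "dppc"      = c(T_p = 34.4, T_m = 42.2),
    "dppc-r5f2" = c(T_p = 33.6, T_m = 42.0),
    "dppc-k5f2" = c(T_p = 36.1, T_m = 44.2))
  p <- list(
    system = system,
    T_p = unname(tt["T_p"]), T_m = unname(tt["T_m"]),
    w_p = 1.2, w_m = 0.5,
    a0 = 1.0, a1 = -0.12, a2 = -0.45,
    noise_sd = 0.005 * (abs(-0.12) + abs(-0.45)),
    T_grid = seq(30, 52, by = 0.5),
    lambda_grid = seq(250, 300, by = 1)
  )
  p <- utils::modifyList(p, list(...))
  validate_thermo_params(p)
  structure(p, class = "thermo_params")
}

validate_thermo_params <- function(p) {
  assert_that(p$T_p < p$T_m, "T_p must be below T_m")
  assert_that(p$w_p > 0 && p$w_m > 0, "transition widths must be positive")
  check_strictly_increasing(p$T_grid, "T_grid")
  check_strictly_increasing(p$lambda_grid, "lambda_grid")
  assert_that(min(p$T_grid) >= 30 && max(p$T_grid) <= 52,
              "T_grid must lie within [30, 52] degC")
  assert_that(min(p$lambda_grid) >= 250 && max(p$lambda_grid) <= 300,
              "lambda_grid must lie within [250, 300] nm")
  assert_that(p$noise_sd >= 0, "noise_sd must be nonnegative")
  invisible(p)
}

#' Shape of the synthetic DSC excess heat capacity curve
#'
#' Sum of two Gaussian peaks (pretransition and main transition) on a linear
#' baseline plus white noise. Defaults per system centre the peaks at the
#' DSC curve maxima: DPPC' 33.2/41.4 degC, +R5F2 34/41.6 degC,
#' +K5F2 32/40.5 degC; the main peak is 10x the pretransition height.
#'
#' @inheritParams thermo_params
#' @return A list of class `dsc_shape`.
#' @export
dsc_shape <- function(system = "dppc", ...) {
  system <- match_system(system)
  ctr <- switch(system,
    "dppc"      = c(T_p_m = 33.2, T_m_m = 41.4),
    "dppc-r5f2" = c(T_p_m = 34.0, T_m_m = 41.6),
    "dppc-k5f2" = c(T_p_m = 32.0, T_m_m = 40.5))
  p <- list(
    system = system,
    T_p_m = unname(ctr["T_p_m"]), T_m_m = unname(ctr["T_m_m"]),
    height_p = 1, height_m = 10,
    width_p = 1.5, width_m = 0.8,
    baseline_slope = 0.01, baseline_offset = 0.2,
    noise_sd = 0.05
  )
  p <- utils::modifyList(p, list(...))
  assert_that(p$width_p > 0 && p$width_m > 0, "peak widths must be positive")
  assert_that(p$height_m >= p$height_p,
              "main-transition height must exceed the pretransition height")
  structure(p, class = "dsc_shape")
}

#' Pseudo-Voigt band description for synthetic infrared spectra
#'
#' @param center Band centre, cm^-1.
#' @param height Peak height (> 0), arbitrary absorbance units.
#' @param fwhm Full width at half maximum, cm^-1 (> 0).
#' @param lorentz_fraction Mixing fraction in \[0, 1\] (0 = Gaussian,
#'   1 = Lorentzian).
#' @return A list of class `band_spec`.
#' @export
band_spec <- function(center, height = 1, fwhm = 12, lorentz_fraction = 0.5) {
  assert_that(height > 0, "band height must be positive")
  assert_that(fwhm > 0, "band fwhm must be positive")
  assert_that(lorentz_fraction >= 0 && lorentz_fraction <= 1,
              "lorentz_fraction must be in [0, 1]")
  structure(list(center = center, height = height, fwhm = fwhm,
                 lorentz_fraction = lorentz_fraction),
            class = "band_spec")
}

#' Default band tables for the six infrared analysis regions
#'
#' Band centres follow the reported gel-phase (30 degC) and fluid-phase
#' (50 degC) maxima per system: e.g. the antisymmetric methylene stretch at
#' 2919/2923 cm^-1, the carbonyl stretch at 1737/1732 cm^-1 in DPPC', the
#' methylene scissoring at 1468/1470 cm^-1, the K5F2-specific amino/
#' carboxylate features at 1455, 1417 and 1379 cm^-1, and the phosphate and
#' choline region maxima. Region (iv) has no published positions; a single
#' synthetic antisymmetric-phosphate stand-in band at 1230 cm^-1 is used.
#' Heights and widths are synthetic-world conventions.
#'
#' @param system One of `"dppc"`, `"dppc-r5f2"`, `"dppc-k5f2"`.
#' @param temperature 30 (gel) or 50 (fluid), degC.
#' @param region Region id, one of `"i"` ... `"vi"`.
#' @return A list of [band_spec()] objects.
#' @export
default_ftir_bands <- function(system = "dppc", temperature = 30,
                               region = "i") {
  system <- match_system(system)
  assert_that(temperature %in% c(30, 50),
              "temperature must be 30 (gel) or 50 (fluid) degC")
  region <- match.arg(region, FTIR_REGION_IDS)
  gel <- temperature == 30
  pick <- function(g, f) if (gel) g else f
  b <- band_spec
  bands <- switch(region,
    i = {
      out <- switch(system,
        "dppc" = list(
          b(pick(2919, 2922), 1.00, 14), b(pick(2850, 2852), 0.80, 11),
          b(pick(2957, 2959), 0.35, 12)),
        "dppc-r5f2" = list(
          b(pick(2919, 2923), 1.00, 14), b(pick(2850, 2852), 0.80, 11),
          b(pick(2957, 2959), 0.35, 12)),
        "dppc-k5f2" = list(
          b(pick(2919, 2923), 1.00, 14), b(pick(2851, 2853), 0.80, 11),
          b(pick(2957, 2959), 0.35, 12), b(2982, 0.15, 14)))
      out
    },
    ii = switch(system,
      "dppc"      = list(b(pick(1737, 1732), 1.00, 25)),
      "dppc-r5f2" = list(b(pick(1738, 1737), 1.00, 25)),
      "dppc-k5f2" = list(b(1737, 1.00, 25))),
    # scissoring/bending bands are narrow and near-Gaussian; they must stay
    # resolvable at 11-13 cm^-1 separations after the 21-point smoothing
    iii = switch(system,
      "dppc"      = list(b(pick(1468, 1470), 1.00, 7, 0)),
      "dppc-r5f2" = list(b(pick(1468, 1466), 1.00, 7, 0)),
      "dppc-k5f2" = list(
        b(pick(1468, 1467), 1.00, 7, 0), b(pick(1455, 1456), 0.60, 7, 0),
        b(pick(1417, 1420), 0.35, 9, 0), b(1379, 0.30, 8, 0))),
    iv = list(b(1230, 1.00, 30)),
    v = switch(system,
      "dppc"      = list(b(pick(1094, 1092), 1.00, 20),
                         b(pick(1058, 1059), 0.80, 20)),
      "dppc-r5f2" = list(b(pick(1090, 1089), 1.00, 20),
                         b(pick(1061, 1055), 0.80, 20)),
      "dppc-k5f2" = list(b(pick(1088, 1086), 0.50, 20),
                         b(1046, 1.00, 20))),
    vi = switch(system,
      "dppc"      = list(b(pick(969, 968), 1.00, 6, 0)),
      "dppc-r5f2" = list(b(pick(976, 969), 1.00, 6, 0)),
      "dppc-k5f2" = {
        out <- list(b(pick(971, 973), 1.00, 6, 0), b(953, 0.50, 5, 0),
                    b(pick(946, 944), 0.40, 5, 0))
        if (!gel) out <- c(out, list(b(980, 0.35, 5, 0)))
        out
      })
  )
  bands
}
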