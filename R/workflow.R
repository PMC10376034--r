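# End-to-end runner chaining generators and analyses into the three-system
# comparison (DPPC', +R5F2, +K5F2) with a consolidated report.

#' Configuration for a full synthetic-study run
#'
#' All ledgered analysis parameters in one place, with explicit seeds so a
#' rerun is byte-identical.
#'
#' @param systems Systems to process.
#' @param stages Character subset of `c("uvvis", "dsc", "ftir", "traj")`.
#' @param uvvis_seeds Seeds of the turbidity ensemble per system.
#' @param dsc_seed Seed for the DSC curve.
#' @param ftir_seed Seed for the infrared spectra.
#' @param traj_seed Seed for the trajectories.
#' @param traj_frames Frames per trajectory scenario (default 200; episode
#'   scenarios always use their scripted full length).
#' @param sg_window,sg_degree Savitzky-Golay settings for the turbidity
#'   pipeline.
#' @param ftir_window SG window for infrared regions (region (i) is never
#'   smoothed).
#' @param dsc_window DSC analysis window, degC.
#' @param contact_cutoff Adsorption cutoff on the minimum peptide-P
#'   distance, nm.
#' @param hb_crit An [hbond_criterion()].
#' @param thickness_bin Phosphorus-histogram bin width, nm.
#' @param ftir_regions Region ids to analyse.
#' @return A list of class `run_config`.
#' @export
run_config <- function(systems = SYSTEMS,
                       stages = c("uvvis", "dsc", "ftir", "traj"),
                       uvvis_seeds = 1:20,
                       dsc_seed = 7,
                       ftir_seed = 2,
                       traj_seed = 11,
                       traj_frames = 200L,
                       sg_window = 11L, sg_degree = 3L,
                       ftir_window = 21L,
                       dsc_window = c(30, 52),
                       contact_cutoff = 0.5,
                       hb_crit = hbond_criterion(),
                       thickness_bin = 0.02,
                       ftir_regions = c("i", "ii", "iii", "iv", "v", "vi")) {
  stages <- match.arg(stages, c("uvvis", "dsc", "ftir", "traj"),
                      several.ok = TRUE)
  structure(list(
    systems = vapply(systems, match_system, character(1)),
    stages = stages, uvvis_seeds = uvvis_seeds, dsc_seed = dsc_seed,
    ftir_seed = ftir_seed, traj_seed = traj_seed,
    traj_frames = as.integer(traj_frames),
    sg_window = sg_window, sg_degree = sg_degree,
    ftir_window = ftir_window, dsc_window = dsc_window,
    contact_cutoff = contact_cutoff, hb_crit = hb_crit,
    thickness_bin = thickness_bin, ftir_regions = ftir_regions
  ), class = "run_config")
}

with_stage <- function(stage, system, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s' (system %s) failed: %s", stage, system,
                  conditionMessage(e)))
  })
}

#' Run the full synthetic three-system study
#'
#' For every requested system: the turbidity ensemble pipeline (generator,
#' smoothing, rank-1 curve resolution, double-Boltzmann fit, averaged over
#' seeds), the DSC transition readout, the region-wise infrared band table
#' with gel-to-fluid shifts, and trajectory metrics (area per lipid,
#' thickness, H-bond counts over bound frames, contact episodes). Fully
#' deterministic given the config seeds.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, `report.json` is written
#'   there.
#' @return The consolidated report as a nested list (also written as JSON
#'   when `out_dir` is given).
#' @export
run_full <- function(config = run_config(), out_dir = NULL) {
  report <- list(config = config_echo(config), systems = list())
  for (sys in config$systems) {
    entry <- list()
    if ("uvvis" %in% config$stages) {
      entry$uvvis <- with_stage("uvvis", sys, uvvis_stage(sys, config))
    }
    if ("dsc" %in% config$stages) {
      entry$dsc <- with_stage("dsc", sys, dsc_stage(sys, config))
    }
    if ("ftir" %in% config$stages) {
      entry$ftir <- with_stage("ftir", sys, ftir_stage(sys, config))
    }
    if ("traj" %in% config$stages && sys != "dppc") {
      entry$traj <- with_stage("traj", sys, traj_stage(sys, config))
    }
    if ("traj" %in% config$stages && sys == "dppc") {
      entry$traj <- with_stage("traj", sys, traj_stage_no_peptide(config))
    }
    report$systems[[sys]] <- entry
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  report
}

config_echo <- function(config) {
  out <- unclass(config)
  out$hb_crit <- unclass(out$hb_crit)
  out
}

uvvis_stage <- function(sys, config) {
  params <- thermo_params(sys)
  fits <- purrr::map(config$uvvis_seeds, function(s) {
    extract_transitions(gen_uvvis(params, seed = s),
                        window = config$sg_window, degree = config$sg_degree)
  })
  tp <- vapply(fits, `[[`, numeric(1), "T_p")
  tm <- vapply(fits, `[[`, numeric(1), "T_m")
  r2 <- vapply(fits, `[[`, numeric(1), "r_squared")
  list(
    T_p = mean(tp), T_m = mean(tm),
    sd_Tp = sd(tp), sd_Tm = sd(tm),
    r_squared = mean(r2),
    explained_variance = mean(vapply(fits, `[[`, numeric(1),
                                     "explained_variance")),
    n_seeds = length(fits),
    injected = list(T_p = params$T_p, T_m = params$T_m)
  )
}

dsc_stage <- function(sys, config) {
  shape <- dsc_shape(sys)
  curve <- gen_dsc(shape, seed = config$dsc_seed)
  tt <- find_transitions(baseline_correct(curve, window = config$dsc_window))
  list(T_p_m = tt$T_p_m, T_m_m = tt$T_m_m,
       injected = list(T_p_m = shape$T_p_m, T_m_m = shape$T_m_m))
}

ftir_stage <- function(sys, config) {
  out <- list()
  regions <- ftir_regions()
  for (rid in config$ftir_regions) {
    rb <- regions[regions$region == rid, ]
    window <- if (rid == "i") NULL else config$ftir_window
    spec <- purrr::map(c(30, 50), function(temp) {
      bands <- default_ftir_bands(sys, temp, rid)
      raw <- gen_ftir(bands, grid = c(rb$lo, rb$hi),
                      seed = config$ftir_seed, system = sys,
                      temperature = temp)
      preprocess_region(raw, region = rid, window = window)
    })
    peaks <- purrr::map(spec, find_band_peaks)
    main_gel <- default_ftir_bands(sys, 30, rid)[[1]]$center
    shift <- tryCatch(
      band_shift(peaks[[1]], peaks[[2]], expected = main_gel),
      error = function(e) NULL)
    out[[rid]] <- list(
      gel_peaks = round(peaks[[1]]$position),
      fluid_peaks = round(peaks[[2]]$position),
      main_band = if (!is.null(shift)) as.list(shift) else NULL
    )
  }
  out
}

traj_stage <- function(sys, config) {
  temps <- c(30, 50)
  out <- list()
  for (temp in temps) {
    script <- traj_script(sys, temp, n_frames = config$traj_frames,
                          seed = config$traj_seed)
    gen <- gen_bilayer_traj(script)
    trace <- min_peptide_P_distance(gen$trajectory, gen$topology)
    eps <- contact_episodes(trace, cutoff = config$contact_cutoff)
    hb <- count_hbonds(gen$trajectory, gen$topology, crit = config$hb_crit,
                       adsorbed_only = TRUE, cutoff = config$contact_cutoff)
    apl <- area_per_lipid(gen$trajectory, n_leaflet = script$n_lipids / 2)
    th <- tryCatch(
      membrane_thickness(gen$trajectory, gen$topology,
                         bin = config$thickness_bin),
      error = function(e) tibble::tibble(thickness = NA_real_))
    out[[as.character(temp)]] <- list(
      apl_mean = mean(apl$apl), apl_sd = sd(apl$apl),
      thickness = th$thickness[1],
      hbond_mean = if (nrow(hb)) mean(hb$n_total) else NA_real_,
      hbond_sd = if (nrow(hb) > 1) sd(hb$n_total) else NA_real_,
      episodes = purrr::map(seq_len(nrow(eps)),
                            function(i) as.list(eps[i, ])),
      injected = list(apl_mean = script$apl_mean,
                      leaflet_sep = script$leaflet_sep,
                      hbond_mean = script$hbond_mean)
    )
  }
  out
}

traj_stage_no_peptide <- function(config) {
  out <- list()
  for (temp in c(30, 50)) {
    script <- traj_script("dppc", temp, n_frames = config$traj_frames,
                          seed = config$traj_seed)
    gen <- gen_bilayer_traj(script)
    apl <- area_per_lipid(gen$trajectory, n_leaflet = script$n_lipids / 2)
    th <- membrane_thickness(gen$trajectory, gen$topology,
                             bin = config$thickness_bin)
    out[[as.character(temp)]] <- list(
      apl_mean = mean(apl$apl), apl_sd = sd(apl$apl),
      thickness = th$thickness[1],
      injected = list(apl_mean = script$apl_mean,
                      leaflet_sep = script$leaflet_sep)
    )
  }
  out
}
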