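# Plain-text I/O: the spectra-series CSV dialect (first row = wavelengths,
# first column = temperatures), two-column CSV curves, concatenated GRO
# frames with times in the title line, and the JSON role map.

#' Write / read a spectra series as CSV
#'
#' Dialect: first row holds the wavelength axis (nm) with an empty leading
#' cell, first column the temperatures (degC), body the absorbance matrix.
#'
#' @param series A [spectra_series()] tibble.
#' @param path File path.
#' @return `write_spectra_csv` returns `path` invisibly; `read_spectra_csv`
#'   returns a [spectra_series()].
#' @export
write_spectra_csv <- function(series, path) {
  sm <- spectra_matrix(series)
  M <- rbind(c(NA, sm$wavelengths), cbind(sm$temperatures, sm$D))
  utils::write.table(M, path, sep = ",", row.names = FALSE, col.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  M <- as.matrix(read.csv(path, header = FALSE))
  spectra_series(temperatures = as.numeric(M[-1, 1]),
                 wavelengths = as.numeric(M[1, -1]),
                 D = unname(M[-1, -1, drop = FALSE]))
}

#' Write / read two-column curves (DSC, FTIR) as CSV
#'
#' One header line naming the two columns, then numeric rows.
#'
#' @param curve A `dsc_curve` or `ftir_spectrum` tibble.
#' @param path File path.
#' @param system,temperature Labels applied on read (FTIR only).
#' @return Writers return `path` invisibly; readers return the tibble.
#' @export
write_dsc_csv <- function(curve, path) {
  write.csv(curve[, c("temperature", "cp_excess")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dsc_csv
#' @export
read_dsc_csv <- function(path) {
  d <- read.csv(path)
  dsc_curve(d$temperature, d$cp_excess)
}

#' @rdname write_dsc_csv
#' @export
write_ftir_csv <- function(curve, path) {
  write.csv(curve[, c("wavenumber", "absorbance")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dsc_csv
#' @export
read_ftir_csv <- function(path, system = "dppc", temperature = 30) {
  d <- read.csv(path)
  ftir_spectrum(d$wavenumber, d$absorbance, system = system,
                temperature = temperature)
}

#' Write / read a trajectory as concatenated GRO-format frames
#'
#' Fixed-width GRO records; each frame's title line carries `t= <ns>`. Units
#' are nm as native to the format. The role map (atom index to role, plus
#' the donor-to-hydrogen pairing) goes to a separate JSON file via
#' [write_role_map()].
#'
#' @param traj An [md_trajectory()].
#' @param topo An [md_topology()].
#' @param path Output file.
#' @return `write_traj_gro` returns `path` invisibly; `read_traj_gro`
#'   returns an [md_trajectory()].
#' @export
write_traj_gro <- function(traj, topo, path) {
  atoms <- topo$atoms
  resname <- ifelse(atoms$mol_type == "lipid", "LIP", "PEP")
  aname <- role_atom_names(atoms)
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(atoms)
  for (f in seq_along(traj$times)) {
    pos <- traj$frames[[f]]
    writeLines(sprintf("synthetic bilayer t= %.4f", traj$times[f]), con)
    writeLines(sprintf("%5d", n), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       atoms$mol_id %% 100000L, resname, aname,
                       atoms$index %% 100000L,
                       pos[, 1], pos[, 2], pos[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", traj$boxes[f, 1],
                       traj$boxes[f, 2], traj$boxes[f, 3]), con)
  }
  invisible(path)
}

role_atom_names <- function(atoms) {
  nm <- c("P" = "P", "N" = "N", "C=O" = "OC", "chainC" = "CC",
          "chainH" = "HC", "pep_donor" = "DON", "pep_H" = "HD",
          "pep_acceptor" = "ACC", "pep_other" = "X")
  unname(nm[atoms$role])
}

#' @rdname write_traj_gro
#' @export
read_traj_gro <- function(path) {
  lines <- readLines(path)
  times <- numeric()
  boxes <- NULL
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    title <- lines[i]
    t <- as.numeric(sub(".*t=\\s*([0-9.eE+-]+).*", "\\1", title))
    n <- as.integer(lines[i + 1L])
    atom_lines <- lines[(i + 2L):(i + 1L + n)]
    x <- as.numeric(substr(atom_lines, 21, 28))
    y <- as.numeric(substr(atom_lines, 29, 36))
    z <- as.numeric(substr(atom_lines, 37, 44))
    box <- scan(text = lines[i + 2L + n], quiet = TRUE)[1:3]
    times <- c(times, t)
    boxes <- rbind(boxes, box)
    frames[[length(frames) + 1L]] <- cbind(x, y, z)
    i <- i + 3L + n
  }
  md_trajectory(times, unname(boxes), frames)
}

#' Write / read the JSON role map of a topology
#'
#' Object with a `roles` map (1-based atom index to role string), the
#' `mol_id` vector, and a `donor_h` pairing map so the topology is fully
#' reconstructable.
#'
#' @param topo An [md_topology()].
#' @param path JSON file path.
#' @return `write_role_map` returns `path` invisibly; `read_role_map`
#'   returns an [md_topology()].
#' @export
write_role_map <- function(topo, path) {
  obj <- list(
    roles = setNames(as.list(topo$atoms$role),
                     as.character(topo$atoms$index)),
    mol_id = topo$atoms$mol_id,
    leaflet = topo$atoms$leaflet,
    carbon = topo$atoms$carbon,
    donor_h = setNames(as.list(topo$donor_h$h),
                       as.character(topo$donor_h$donor))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_role_map
#' @export
read_role_map <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  idx <- as.integer(names(obj$roles))
  ord <- order(idx)
  roles <- unlist(obj$roles)[ord]
  atoms <- tibble::tibble(
    index = idx[ord],
    role = unname(roles),
    mol_id = as.integer(obj$mol_id),
    mol_type = ifelse(startsWith(unname(roles), "pep_"), "peptide", "lipid"),
    leaflet = as.numeric(obj$leaflet),
    carbon = as.numeric(obj$carbon)
  )
  dh <- obj$donor_h
  donor_h <- tibble::tibble(donor = as.integer(names(dh)),
                            h = as.integer(unlist(dh)))
  md_topology(atoms, donor_h)
}
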