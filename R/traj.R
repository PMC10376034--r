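# Membrane/peptide observables on role-labelled trajectories. All distance
# operations use the minimum-image convention in an orthorhombic box: each
# Cartesian separation component is wrapped into [-L/2, L/2).

wrap_min_image <- function(d, L) {
  d - L * floor(d / L + 0.5)
}

# pairwise min-image distance matrix between coordinate sets A (na x 3) and
# B (nb x 3) in box (Lx, Ly, Lz)
pairwise_min_image <- function(A, B, box) {
  d2 <- matrix(0, nrow(A), nrow(B))
  for (k in 1:3) {
    dk <- wrap_min_image(outer(A[, k], B[, k], `-`), box[k])
    d2 <- d2 + dk^2
  }
  sqrt(d2)
}

#' Minimum-image distance between two atoms of a frame
#'
#' @param frame List with elements `box` (length-3, nm) and `positions`
#'   (n x 3 matrix, nm).
#' @param i,j Atom indices.
#' @return Distance in nm.
#' @export
min_image_dist <- function(frame, i, j) {
  d <- wrap_min_image(frame$positions[i, ] - frame$positions[j, ], frame$box)
  sqrt(sum(d^2))
}

get_frame <- function(traj, f) {
  list(box = traj$boxes[f, ], positions = traj$frames[[f]])
}

role_rows <- function(topo, roles, what = roles[1]) {
  idx <- topo$atoms$index[topo$atoms$role %in% roles]
  if (!length(idx)) abort(sprintf("no atoms with role '%s' in topology", what))
  idx
}

#' Minimum peptide-phosphorus distance trace
#'
#' Per frame, the minimum over all peptide-atom x P-atom pairs of the
#' minimum-image distance: the standard adsorption coordinate.
#'
#' @param traj An [md_trajectory()].
#' @param topo An [md_topology()] with peptide atoms and P atoms.
#' @return A tibble with columns `time` (ns) and `min_dist` (nm).
#' @export
min_peptide_P_distance <- function(traj, topo) {
  pep <- topo$atoms$index[topo$atoms$mol_type == "peptide"]
  if (!length(pep)) abort("no atoms with role 'pep_*' in topology")
  p <- role_rows(topo, "P")
  md <- vapply(seq_along(traj$times), function(f) {
    fr <- get_frame(traj, f)
    min(pairwise_min_image(fr$positions[pep, , drop = FALSE],
                           fr$positions[p, , drop = FALSE], fr$box))
  }, numeric(1))
  tibble::tibble(time = traj$times, min_dist = md)
}

#' Detect membrane-contact episodes from a distance trace
#'
#' Maximal runs of consecutive frames with `min_dist < cutoff`; an episode
#' runs from the time of its first to its last below-cutoff frame. Episodes
#' shorter than `min_duration` are dropped.
#'
#' @param trace A tibble with columns `time` and `min_dist` (from
#'   [min_peptide_P_distance()]).
#' @param cutoff Contact cutoff, nm (default 0.5).
#' @param min_duration Minimum episode duration, ns (default 0).
#' @return A tibble with columns `start`, `end`, `duration` (ns); zero rows
#'   when the peptide never binds.
#' @export
contact_episodes <- function(trace, cutoff = 0.5, min_duration = 0) {
  if (!nrow(trace)) abort("empty distance trace")
  check_strictly_increasing(trace$time, "time")
  below <- trace$min_dist < cutoff
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  out <- tibble::tibble(
    start = trace$time[starts[keep]],
    end = trace$time[ends[keep]]
  )
  out$duration <- out$end - out$start
  out[out$duration >= min_duration, , drop = FALSE]
}

#' Area per lipid from the lateral box dimensions
#'
#' `APL = Lx * Ly / n_leaflet` per frame.
#'
#' @param traj An [md_trajectory()].
#' @param n_leaflet Lipids per leaflet (default 96).
#' @param t_equil Drop frames before this time, ns (default 0).
#' @return A tibble with columns `time` and `apl` (nm^2).
#' @export
area_per_lipid <- function(traj, n_leaflet = 96, t_equil = 0) {
  assert_that(n_leaflet > 0, "n_leaflet must be positive")
  keep <- traj$times >= t_equil
  tibble::tibble(
    time = traj$times[keep],
    apl = traj$boxes[keep, 1] * traj$boxes[keep, 2] / n_leaflet
  )
}

#' Membrane thickness from the phosphorus density profile
#'
#' Histograms the z-coordinates of all P atoms (relative to the per-frame
#' membrane centre of geometry) over all frames and reports the distance
#' between the parabolically refined maxima of the lower- and upper-leaflet
#' peaks.
#'
#' @param traj An [md_trajectory()].
#' @param topo An [md_topology()].
#' @param bin Histogram bin width, nm (default 0.02).
#' @param t_equil Drop frames before this time, ns (default 0).
#' @return A one-row tibble with `thickness`, `z_lower`, `z_upper` (nm).
#' @export
membrane_thickness <- function(traj, topo, bin = 0.02, t_equil = 0) {
  p <- role_rows(topo, "P")
  keep <- which(traj$times >= t_equil)
  z <- unlist(lapply(keep, function(f) {
    zp <- traj$frames[[f]][p, 3]
    zp - mean(zp)
  }))
  breaks <- seq(floor(min(z) / bin) * bin - bin,
                ceiling(max(z) / bin) * bin + bin, by = bin)
  h <- graphics::hist(z, breaks = breaks, plot = FALSE)
  mids <- h$mids
  counts <- h$counts
  lower <- which(mids < 0)
  upper <- which(mids > 0)
  if (!length(lower) || !length(upper) ||
      max(counts[lower]) == 0 || max(counts[upper]) == 0) {
    abort("leaflets not resolved")
  }
  i_lo <- lower[which.max(counts[lower])]
  i_up <- upper[which.max(counts[upper])]
  # a genuine bimodal profile has a deep valley between the leaflet peaks
  valley <- min(counts[i_lo:i_up])
  if (valley > 0.5 * min(counts[i_lo], counts[i_up])) {
    abort("leaflets not resolved")
  }
  z_lo <- parabolic_refine(mids, counts, i_lo)
  z_up <- parabolic_refine(mids, counts, i_up)
  tibble::tibble(thickness = z_up - z_lo, z_lower = z_lo, z_upper = z_up)
}

#' Geometric hydrogen-bond criterion
#'
#' @param d_max Maximum donor-acceptor distance, nm (default 0.35).
#' @param angle_max Maximum deviation of the donor-H...acceptor angle from
#'   linear, degrees (default 30).
#' @return A list of class `hbond_criterion`.
#' @export
hbond_criterion <- function(d_max = 0.35, angle_max = 30) {
  assert_that(d_max > 0, "d_max must be positive")
  assert_that(angle_max > 0 && angle_max < 90,
              "angle_max must lie in (0, 90) degrees")
  structure(list(d_max = d_max, angle_max = angle_max),
            class = "hbond_criterion")
}

hbond_count_frame <- function(fr, don, hyd, acc_idx, acc_role, crit) {
  D <- fr$positions[don, , drop = FALSE]
  H <- fr$positions[hyd, , drop = FALSE]
  A <- fr$positions[acc_idx, , drop = FALSE]
  dm <- pairwise_min_image(D, A, fr$box)
  hits <- which(dm <= crit$d_max, arr.ind = TRUE)
  if (!nrow(hits)) {
    return(c(total = 0, phosphate = 0, carbonyl = 0))
  }
  dev <- vapply(seq_len(nrow(hits)), function(r) {
    i <- hits[r, 1]; j <- hits[r, 2]
    hd <- wrap_min_image(D[i, ] - H[i, ], fr$box)
    ha <- wrap_min_image(A[j, ] - H[i, ], fr$box)
    cosang <- sum(hd * ha) / sqrt(sum(hd^2) * sum(ha^2))
    180 - acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  }, numeric(1))
  ok <- dev <= crit$angle_max
  roles <- acc_role[hits[ok, 2]]
  c(total = as.numeric(sum(ok)),
    phosphate = as.numeric(sum(roles == "P")),
    carbonyl = as.numeric(sum(roles == "C=O")))
}

#' Count peptide-lipid hydrogen bonds per frame
#'
#' A bond is counted when the donor-acceptor minimum-image distance is at
#' most `crit$d_max` and the donor-H...acceptor deviation from linearity is
#' at most `crit$angle_max`. Donors are the peptide donor atoms (with their
#' covalent hydrogens from the topology pairing); acceptors are the lipid
#' phosphate group (P atom of the pseudo-lipid) and the carbonyl O atoms.
#' With `adsorbed_only`, frames outside the contact episodes of the minimum
#' peptide-P distance trace are flagged unbound and excluded from averaging.
#'
#' @param traj An [md_trajectory()].
#' @param topo An [md_topology()] with donor-hydrogen pairing.
#' @param crit An [hbond_criterion()].
#' @param adsorbed_only Restrict to bound frames (default `TRUE`).
#' @param cutoff Contact cutoff used to define bound frames, nm.
#' @return A tibble with columns `time`, `bound`, `n_total`, `n_phosphate`,
#'   `n_carbonyl`; when `adsorbed_only` only bound frames are returned.
#' @export
count_hbonds <- function(traj, topo, crit = hbond_criterion(),
                         adsorbed_only = TRUE, cutoff = 0.5) {
  if (!nrow(topo$donor_h)) abort("no donor-hydrogen pairs in topology")
  don <- topo$donor_h$donor
  hyd <- topo$donor_h$h
  acc <- topo$atoms[topo$atoms$role %in% c("P", "C=O"), ]
  if (!nrow(acc)) abort("no acceptor atoms (roles P, C=O) in topology")
  counts <- t(vapply(seq_along(traj$times), function(f) {
    hbond_count_frame(get_frame(traj, f), don, hyd, acc$index, acc$role, crit)
  }, c(total = 0, phosphate = 0, carbonyl = 0)))
  trace <- min_peptide_P_distance(traj, topo)
  out <- tibble::tibble(
    time = traj$times,
    bound = trace$min_dist < cutoff,
    n_total = unname(counts[, "total"]),
    n_phosphate = unname(counts[, "phosphate"]),
    n_carbonyl = unname(counts[, "carbonyl"])
  )
  if (adsorbed_only) out <- out[out$bound, , drop = FALSE]
  out
}

#' Radial distribution function between two atom groups
#'
#' Standard pair-distance histogram, normalized per frame by the spherical
#' shell volume and the mean partner density, averaged over frames.
#'
#' @param traj An [md_trajectory()].
#' @param topo An [md_topology()].
#' @param group_a,group_b Role names (e.g. `"pep_donor"`, `"P"`); a
#'   character vector selects several roles.
#' @param r_max Maximum radius, nm; must not exceed half the smallest box
#'   edge of any frame.
#' @param dr Bin width, nm (default 0.02).
#' @return A tibble with columns `r` (bin centre, nm) and `g`.
#' @export
rdf <- function(traj, topo, group_a, group_b, r_max = 1.5, dr = 0.02) {
  if (r_max > min(traj$boxes) / 2) {
    abort("r_max exceeds half the smallest box dimension")
  }
  ia <- role_rows(topo, group_a)
  ib <- role_rows(topo, group_b)
  breaks <- seq(0, r_max, by = dr)
  nb <- length(breaks) - 1L
  acc <- numeric(nb)
  for (f in seq_along(traj$times)) {
    fr <- get_frame(traj, f)
    dm <- pairwise_min_image(fr$positions[ia, , drop = FALSE],
                             fr$positions[ib, , drop = FALSE], fr$box)
    same <- identical(ia, ib)
    d <- as.vector(dm)
    if (same) d <- d[as.vector(upper.tri(dm))]
    d <- d[d > 0 & d < r_max]
    counts <- graphics::hist(d, breaks = breaks, plot = FALSE)$counts
    if (same) counts <- 2 * counts
    V <- prod(fr$box)
    rho_b <- length(ib) / V
    shell <- 4 / 3 * pi * (breaks[-1]^3 - breaks[-(nb + 1)]^3)
    acc <- acc + counts / (length(ia) * shell * rho_b)
  }
  tibble::tibble(r = breaks[-(nb + 1)] + dr / 2,
                 g = acc / length(traj$times))
}

#' Acyl-chain order parameters per carbon
#'
#' `S_CD = <3 cos^2(theta) - 1> / 2` with `theta` the angle between each
#' C-H bond vector and the bilayer normal (z), averaged over frames and
#' lipids for each chain carbon.
#'
#' @param traj An [md_trajectory()].
#' @param topo An [md_topology()] with `chainC`/`chainH` atoms.
#' @return A tibble with columns `carbon` and `s_cd`.
#' @export
order_parameters <- function(traj, topo) {
  ch <- topo$atoms[topo$atoms$role == "chainH", ]
  if (!nrow(ch)) abort("no atoms with role 'chainH' in topology")
  # each chain H directly follows its carbon in the atom table
  cidx <- ch$index - 1L
  carbon <- topo$atoms$carbon[cidx]
  vals <- lapply(seq_along(traj$times), function(f) {
    pos <- traj$frames[[f]]
    v <- pos[ch$index, , drop = FALSE] - pos[cidx, , drop = FALSE]
    cos2 <- v[, 3]^2 / rowSums(v^2)
    (3 * cos2 - 1) / 2
  })
  s <- Reduce(`+`, vals) / length(vals)
  tibble::tibble(carbon = carbon, s_cd = s) |>
    dplyr::group_by(.data$carbon) |>
    dplyr::summarise(s_cd = mean(.data$s_cd)) |>
    dplyr::arrange(.data$carbon)
}

#' Number density profile of a role along the membrane normal
#'
#' Per-bin atom counts divided by the bin volume (lateral box area x bin
#' width), averaged over frames, with z measured from the membrane centre
#' (mean P z-coordinate) of each frame.
#'
#' @param traj An [md_trajectory()].
#' @param topo An [md_topology()].
#' @param role Role name(s) to profile.
#' @param bin Bin width, nm (default 0.1).
#' @param t_equil Drop frames before this time, ns.
#' @return A tibble with columns `z` (bin centre, nm) and `density`
#'   (nm^-3).
#' @export
number_density_profile <- function(traj, topo, role, bin = 0.1, t_equil = 0) {
  idx <- role_rows(topo, role)
  p <- role_rows(topo, "P")
  keep <- which(traj$times >= t_equil)
  zs <- lapply(keep, function(f) {
    pos <- traj$frames[[f]]
    pos[idx, 3] - mean(pos[p, 3])
  })
  zall <- unlist(zs)
  breaks <- seq(floor(min(zall) / bin) * bin - bin,
                ceiling(max(zall) / bin) * bin + bin, by = bin)
  dens <- numeric(length(breaks) - 1L)
  for (i in seq_along(keep)) {
    f <- keep[i]
    area <- traj$boxes[f, 1] * traj$boxes[f, 2]
    counts <- graphics::hist(zs[[i]], breaks = breaks, plot = FALSE)$counts
    dens <- dens + counts / (area * bin)
  }
  tibble::tibble(z = breaks[-length(breaks)] + bin / 2,
                 density = dens / length(keep))
}
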