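# Synthetic bilayer + peptide trajectory generator. The geometry is minimal
# but supports every downstream observable: 8-atom pseudo-lipids (P, choline
# N, two carbonyl O, two chain C each with one H) on leaflet lattices inside
# an orthorhombic box with the bilayer normal along z, and one peptide whose
# contact with the membrane follows a scripted episode list. During bound
# frames a Poisson number of criterion-satisfying donor-H...acceptor triplets
# is planted (donor-acceptor distance 0.285-0.315 nm, near-linear geometry),
# safely inside the default detection criterion (0.35 nm, 30 deg).

LIPID_ATOM_ROLES <- c("P", "N", "C=O", "C=O", "chainC", "chainH",
                      "chainC", "chainH")
CH_BOND <- 0.109 # nm

#' Script describing a synthetic bilayer + peptide trajectory
#'
#' Scenario defaults follow the simulated systems: area per lipid and leaflet
#' separation per system/temperature (e.g. fluid peptide-free APL
#' 0.615 nm^2, gel R5F2 thickness 5.150 nm), adsorption episodes (R5F2
#' adsorbs at 33 ns at 30 degC and stays; K5F2 at 50 degC stays bound for
#' 113 ns then desorbs; K5F2 at 30 degC makes only sub-2-ns contacts), and
#' mean planted hydrogen-bond counts per bound frame (R5F2: 8 at 30 degC,
#' 11 at 50 degC; K5F2: 5 at 50 degC). 192 lipids, 0.1 ns between frames,
#' a 200 ns analysis window by default.
#'
#' @param system `"dppc"` (no peptide), `"dppc-r5f2"` or `"dppc-k5f2"`.
#' @param temperature 30 (gel) or 50 (fluid) degC.
#' @param ... Named overrides of any field (`n_lipids`, `apl_mean`,
#'   `apl_sd`, `leaflet_sep`, `p_jitter_sd`, `scd_target`, `episodes`,
#'   `hbond_mean`, `frame_dt`, `n_frames`, `seed`).
#' @return A list of class `traj_script`.
#' @export
traj_script <- function(system = "dppc", temperature = 50, ...) {
  system <- match_system(system)
  assert_that(temperature %in% c(30, 50),
              "temperature must be 30 (gel) or 50 (fluid) degC")
  gel <- temperature == 30
  key <- paste(system, temperature)
  tab <- list(
    # apl_mean, apl_sd, leaflet_sep per Table of structural parameters
    "dppc 30"      = list(apl = c(0.518, 0.005), sep = 4.924),
    "dppc 50"      = list(apl = c(0.615, 0.013), sep = 3.905),
    "dppc-r5f2 30" = list(apl = c(0.498, 0.005), sep = 5.150),
    "dppc-r5f2 50" = list(apl = c(0.613, 0.012), sep = 4.018),
    "dppc-k5f2 30" = list(apl = c(0.517, 0.006), sep = 4.940),
    "dppc-k5f2 50" = list(apl = c(0.614, 0.013), sep = 3.905)
  )[[key]]
  episodes <- switch(key,
    "dppc-r5f2 30" = list(c(33, 200)),
    "dppc-r5f2 50" = list(c(0, 200)),
    "dppc-k5f2 30" = list(c(40, 41.5), c(90, 91.2), c(150, 151.8)),
    "dppc-k5f2 50" = list(c(0, 113)),
    list())
  hbond_mean <- switch(key,
    "dppc-r5f2 30" = 8, "dppc-r5f2 50" = 11,
    "dppc-k5f2 30" = 5, "dppc-k5f2 50" = 5,
    0)
  p <- list(
    system = system, temperature = temperature,
    n_lipids = 192L,
    apl_mean = tab$apl[1], apl_sd = tab$apl[2],
    leaflet_sep = tab$sep,
    p_jitter_sd = 0.05,
    scd_target = if (gel) -0.42 else -0.2,
    episodes = episodes,
    hbond_mean = hbond_mean,
    frame_dt = 0.1,
    n_frames = 2001L,
    seed = 1L,
    peptide = system != "dppc"
  )
  dots <- list(...)
  for (nm in names(dots)) p[[nm]] <- dots[[nm]]
  if (!("episodes" %in% names(dots))) {
    # scenario-default episodes are clipped to a shortened time window
    t_end <- (p$n_frames - 1L) * p$frame_dt
    p$episodes <- purrr::keep(
      purrr::map(p$episodes, function(ep) c(ep[1], min(ep[2], t_end))),
      function(ep) ep[1] < ep[2])
  }
  validate_traj_script(p)
  structure(p, class = "traj_script")
}

validate_traj_script <- function(p) {
  assert_that(p$n_lipids %% 2L == 0L, "n_lipids must be even")
  assert_that(p$apl_mean > 0, "apl_mean must be positive")
  assert_that(p$leaflet_sep > 0, "leaflet_sep must be positive")
  assert_that(p$scd_target >= -0.5 && p$scd_target <= 1,
              "scd_target must lie in [-0.5, 1]")
  t_end <- (p$n_frames - 1L) * p$frame_dt
  if (length(p$episodes)) {
    ep <- do.call(rbind, p$episodes)
    assert_that(all(ep[, 1] < ep[, 2]), "episodes must have start < end")
    assert_that(all(ep[, 1] >= 0) && all(ep[, 2] <= t_end + 1e-9),
                "episodes must lie within the trajectory time range")
    if (nrow(ep) > 1) {
      assert_that(all(diff(ep[, 1]) > 0) &&
                    all(ep[-1, 1] > ep[-nrow(ep), 2]),
                  "episodes must be ordered and non-overlapping")
    }
  }
  invisible(p)
}

#' Topology container for role-labelled trajectories
#'
#' @param atoms Tibble with columns `index`, `role`, `mol_id`, `mol_type`,
#'   `leaflet` (+1/-1/NA) and `carbon` (acyl-chain carbon number or NA).
#'   Roles follow the role-map dialect: `P`, `N`, `C=O`, `chainC`, `chainH`,
#'   `pep_donor`, `pep_H`, `pep_acceptor`, `pep_other`. In the pseudo-lipid
#'   the P atom stands in for the phosphate group as H-bond acceptor and the
#'   carbonyl O atoms for the C=O group.
#' @param donor_h Tibble pairing every peptide donor with its covalent
#'   hydrogen (`donor`, `h` atom indices).
#' @return A list of class `md_topology`.
#' @export
md_topology <- function(atoms, donor_h) {
  n_h <- sum(atoms$role == "pep_H")
  assert_that(nrow(donor_h) == n_h &&
                !anyDuplicated(donor_h$h) && !anyDuplicated(donor_h$donor),
              "every pep_H must be paired to exactly one pep_donor")
  p_per_lipid <- atoms |>
    dplyr::filter(.data$mol_type == "lipid") |>
    dplyr::group_by(.data$mol_id) |>
    dplyr::summarise(n_p = sum(.data$role == "P"))
  assert_that(all(p_per_lipid$n_p == 1L), "each lipid must have exactly one P")
  structure(list(atoms = atoms, donor_h = donor_h), class = "md_topology")
}

#' Trajectory container: timestamped orthorhombic-box coordinate frames
#'
#' @param times Strictly increasing frame times, ns.
#' @param boxes n_frames x 3 matrix of box lengths (Lx, Ly, Lz), nm.
#' @param frames List of n_atoms x 3 coordinate matrices, nm.
#' @return A list of class `md_trajectory`.
#' @export
md_trajectory <- function(times, boxes, frames) {
  assert_that(length(times) >= 1 && all(diff(times) > 0),
              "`times` must be strictly increasing")
  boxes <- as.matrix(boxes)
  assert_that(nrow(boxes) == length(times) && ncol(boxes) == 3,
              "boxes must be n_frames x 3")
  assert_that(all(boxes > 0), "box lengths must be positive")
  assert_that(length(frames) == length(times),
              "frames and times lengths differ")
  structure(list(times = times, boxes = boxes, frames = frames),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory> %d frames, %d atoms, t = %g..%g ns\n",
              length(x$times), nrow(x$frames[[1]]), min(x$times),
              max(x$times)))
  invisible(x)
}

time_in_episodes <- function(t, episodes, tol = 1e-9) {
  if (!length(episodes)) return(rep(FALSE, length(t)))
  bound <- rep(FALSE, length(t))
  for (ep in episodes) {
    bound <- bound | (t >= ep[1] - tol & t <= ep[2] + tol)
  }
  bound
}

build_topology <- function(script) {
  n_lip <- script$n_lipids
  lip <- tibble::tibble(
    role = rep(LIPID_ATOM_ROLES, n_lip),
    mol_id = rep(seq_len(n_lip), each = 8L),
    mol_type = "lipid",
    leaflet = rep(rep(c(1, -1), each = n_lip / 2), each = 8L),
    carbon = rep(c(NA, NA, NA, NA, 1, NA, 2, NA), n_lip)
  )
  atoms <- lip
  donor_h <- tibble::tibble(donor = integer(), h = integer())
  if (script$peptide) {
    n_don <- 24L
    pep_roles <- c(rep(c("pep_donor", "pep_H"), n_don),
                   rep("pep_acceptor", 4L), rep("pep_other", 6L))
    pep <- tibble::tibble(
      role = pep_roles,
      mol_id = n_lip + 1L,
      mol_type = "peptide",
      leaflet = NA_real_,
      carbon = NA_real_
    )
    atoms <- dplyr::bind_rows(lip, pep)
    base <- nrow(lip)
    donor_h <- tibble::tibble(
      donor = base + seq(1L, by = 2L, length.out = n_don),
      h = base + seq(2L, by = 2L, length.out = n_don)
    )
  }
  atoms$index <- seq_len(nrow(atoms))
  atoms <- atoms[, c("index", "role", "mol_id", "mol_type", "leaflet",
                     "carbon")]
  md_topology(atoms, donor_h)
}

# fixed peptide cluster template (n x 3 offsets, nm) used when no bonds are
# planted for an atom; deterministic, compact (~0.6 nm across)
pep_template <- function(n) {
  g <- ceiling(sqrt(n))
  i <- seq_len(n) - 1L
  cbind(0.15 * (i %% g) - 0.075 * (g - 1),
        0.15 * (i %/% g) - 0.075 * (g - 1),
        0.05 * (i %% 3L))
}

#' Generate a synthetic bilayer (+ optional peptide) trajectory
#'
#' Per frame, in draw order: (1) one Gaussian area-per-lipid value setting
#' the lateral box, (2) Gaussian z-jitter for every P atom, (3) one uniform
#' azimuth per chain C-H (the polar angle is fixed so the order parameter
#' equals `scd_target` exactly), and, on bound frames of a peptide system,
#' (4) a Poisson count of planted hydrogen bonds followed by per-bond
#' uniform draws (donor-acceptor distance, angular deviation, azimuth).
#' The peptide's minimum distance to any P atom is below the 0.5 nm contact
#' cutoff exactly during scripted episodes and at least twice the cutoff
#' otherwise.
#'
#' @param script A [traj_script()] object.
#' @param seed Integer seed (defaults to `script$seed`).
#' @return A list with elements `topology` ([md_topology()]) and
#'   `trajectory` ([md_trajectory()]).
#' @export
gen_bilayer_traj <- function(script = traj_script(), seed = script$seed) {
  validate_traj_script(script)
  topo <- build_topology(script)
  n_lip <- script$n_lipids
  n_leaf <- n_lip %/% 2L
  Lz <- script$leaflet_sep + 6
  zc <- Lz / 2
  times <- (seq_len(script$n_frames) - 1L) * script$frame_dt
  bound <- time_in_episodes(times, if (script$peptide) script$episodes else list())

  # fractional leaflet lattice, shared by both leaflets
  g <- ceiling(sqrt(n_leaf))
  i <- seq_len(n_leaf) - 1L
  frac <- cbind((i %% g + 0.5) / g, (i %/% g + 0.5) / g)

  # fixed polar angle reproducing the target order parameter exactly
  cos_a <- sqrt((2 * script$scd_target + 1) / 3)
  sin_a <- sqrt(1 - cos_a^2)

  n_atoms <- nrow(topo$atoms)
  p_rows <- which(topo$atoms$role == "P")
  pep_rows <- which(topo$atoms$mol_type == "peptide")
  n_don <- nrow(topo$donor_h)

  withr::local_seed(seed)
  frames <- vector("list", script$n_frames)
  boxes <- matrix(0, script$n_frames, 3)
  for (f in seq_len(script$n_frames)) {
    apl <- rnorm(1, script$apl_mean, script$apl_sd)
    L <- sqrt(max(apl, 0.1) * n_leaf)
    jit <- rnorm(n_lip, 0, script$p_jitter_sd)
    azi <- runif(2L * n_lip, 0, 2 * pi)

    pos <- matrix(0, n_atoms, 3)
    for (leaf in c(1, -1)) {
      lip_ids <- if (leaf == 1) seq_len(n_leaf) else n_leaf + seq_len(n_leaf)
      zP <- zc + leaf * script$leaflet_sep / 2 + jit[lip_ids]
      xy <- frac * L
      base <- (lip_ids - 1L) * 8L
      inw <- -leaf  # unit step toward the membrane centre
      pos[base + 1L, ] <- cbind(xy, zP)                              # P
      pos[base + 2L, ] <- cbind(xy[, 1] + 0.1, xy[, 2], zP - inw * 0.35) # N
      pos[base + 3L, ] <- cbind(xy[, 1] + 0.12, xy[, 2], zP + inw * 0.45) # C=O
      pos[base + 4L, ] <- cbind(xy[, 1] - 0.12, xy[, 2], zP + inw * 0.45) # C=O
      c1 <- cbind(xy, zP + inw * 0.9)
      c2 <- cbind(xy, zP + inw * 1.3)
      a1 <- azi[2L * (lip_ids - 1L) + 1L]
      a2 <- azi[2L * (lip_ids - 1L) + 2L]
      pos[base + 5L, ] <- c1
      pos[base + 6L, ] <- c1 + CH_BOND * cbind(sin_a * cos(a1),
                                               sin_a * sin(a1),
                                               rep(cos_a, n_leaf))
      pos[base + 7L, ] <- c2
      pos[base + 8L, ] <- c2 + CH_BOND * cbind(sin_a * cos(a2),
                                               sin_a * sin(a2),
                                               rep(cos_a, n_leaf))
    }

    if (script$peptide) {
      anchor_xy <- frac[1, ] * L
      z_plane <- zc + script$leaflet_sep / 2
      pep_pos <- place_peptide(
        topo, pos, bound[f], script$hbond_mean, n_don,
        anchor_xy, z_plane, frac, L)
      pos[pep_rows, ] <- pep_pos
    }
    frames[[f]] <- pos
    boxes[f, ] <- c(L, L, Lz)
  }
  list(topology = topo, trajectory = md_trajectory(times, boxes, frames))
}

# Peptide placement for one frame. Returns coordinates for the peptide atoms
# in topology order (donor/H interleaved, then acceptors, then others).
place_peptide <- function(topo, pos, is_bound, hbond_mean, n_don,
                          anchor_xy, z_plane, frac, L) {
  pep_rows <- which(topo$atoms$mol_type == "peptide")
  n_pep <- length(pep_rows)
  tmpl <- pep_template(n_pep)
  if (!is_bound) {
    centre <- c(anchor_xy, z_plane + 2.0)
    return(sweep(tmpl, 2, centre, `+`))
  }
  # bound: compact cluster hovering 0.65 nm above the upper P plane ...
  centre <- c(anchor_xy, z_plane + 0.65)
  out <- sweep(tmpl, 2, centre, `+`)
  # ... one pep_other pinned 0.35 nm above the anchor P keeps the minimum
  # peptide-P distance below the contact cutoff even with zero planted bonds
  other_rows <- which(topo$atoms$role[pep_rows] == "pep_other")
  out[other_rows[1], ] <- c(anchor_xy, z_plane + 0.35)

  k <- if (hbond_mean > 0) min(rpois(1, hbond_mean), n_don) else 0L
  if (k > 0) {
    don_local <- match(topo$donor_h$donor, topo$atoms$index[pep_rows])
    h_local <- match(topo$donor_h$h, topo$atoms$index[pep_rows])
    for (j in seq_len(k)) {
      # bond j targets lipid j of the upper leaflet; 3 of 4 bonds go to the
      # phosphate (P atom), every 4th to a carbonyl O
      lip <- j
      base <- (lip - 1L) * 8L
      to_phosphate <- (j %% 4L) != 0L
      acc <- if (to_phosphate) pos[base + 1L, ] else pos[base + 3L, ]
      d <- runif(1, 0.285, 0.315)
      dev <- runif(1, 0, 8) * pi / 180
      psi <- runif(1, 0, 2 * pi)
      u <- if (to_phosphate) {
        # approach the phosphate from above, tilted 20 deg off z
        tilt <- 20 * pi / 180
        c(sin(tilt) * cos(psi), sin(tilt) * sin(psi), cos(tilt))
      } else {
        # approach the carbonyl laterally, pointing away from its partner O
        psi_c <- (psi %% (pi / 2)) - pi / 4  # within +/-45 deg of +x
        c(cos(psi_c), sin(psi_c), 0)
      }
      donor <- acc + d * u
      # hydrogen close to the donor->acceptor axis: deviation < 15 deg at
      # the donor guarantees a near-linear triplet
      u_da <- -u
      e_perp <- perpendicular_unit(u_da, psi)
      v <- cos(dev) * u_da + sin(dev) * e_perp
      out[don_local[j], ] <- donor
      out[h_local[j], ] <- donor + 0.101 * v
    }
  }
  out
}

perpendicular_unit <- function(u, psi) {
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  cos(psi) * e1 + sin(psi) * e2
}
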