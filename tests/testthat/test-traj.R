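# Trajectory generator geometry and the PBC-aware observables.

test_that("minimum-image distances match the 27-image oracle", {
  withr::with_seed(21, {
    box <- c(6.5, 7.2, 9.1)
    A <- cbind(runif(1000, -3, 10), runif(1000, -3, 10), runif(1000, -3, 10))
    B <- cbind(runif(1000, -3, 10), runif(1000, -3, 10), runif(1000, -3, 10))
    fr <- list(box = box, positions = rbind(A[1:10, ], B[1:10, ]))
    expect_identical(min_image_dist(fr, 3, 3), 0)
    d_fast <- memthermo:::pairwise_min_image(A, B, box)
    idx <- cbind(sample(1000, 60), sample(1000, 60))
    d_oracle <- apply(idx, 1, function(k) dist_27(A[k[1], ], B[k[2], ], box))
    expect_equal(d_fast[idx], d_oracle, tolerance = 1e-12)
  })
  # wrap across the boundary
  fr <- list(box = c(5, 5, 5), positions = rbind(c(0, 1, 1), c(4.9, 1, 1)))
  expect_equal(min_image_dist(fr, 1, 2), 0.1, tolerance = 1e-12)
})

test_that("scripted episodes reappear exactly in the distance trace", {
  g <- gen_bilayer_traj(traj_script(
    "dppc-k5f2", 50, n_frames = 501L, frame_dt = 0.1,
    episodes = list(c(0, 20), c(30, 35.5)), seed = 2))
  tr <- min_peptide_P_distance(g$trajectory, g$topology)
  expect_identical(nrow(tr), 501L)
  expect_true(all(diff(tr$time) > 0))
  below <- tr$min_dist < 0.5
  scripted <- (tr$time <= 20 + 1e-9) |
    (tr$time >= 30 - 1e-9 & tr$time <= 35.5 + 1e-9)
  expect_identical(below, scripted)
  # unbound frames sit beyond twice the cutoff
  expect_gte(min(tr$min_dist[!below]), 1.0)
  ep <- contact_episodes(tr)
  expect_equal(ep$start, c(0, 30))
  expect_equal(ep$duration, c(20, 5.5), tolerance = 1e-9)
})

test_that("episode bookkeeping partitions the time axis", {
  g <- gen_bilayer_traj(traj_script("dppc-k5f2", 30, n_frames = 1601L,
                                    seed = 3))
  tr <- min_peptide_P_distance(g$trajectory, g$topology)
  ep <- contact_episodes(tr)
  bound_frames <- sum(tr$min_dist < 0.5)
  dt <- 0.1
  expect_equal(sum(ep$duration) + nrow(ep) * dt, bound_frames * dt,
               tolerance = 1e-9)
  # all episodes in this scenario are sub-2-ns transient contacts
  expect_lt(max(ep$duration), 2)
  # min_duration drops short episodes
  expect_identical(nrow(contact_episodes(tr, min_duration = 5)), 0L)
  expect_error(contact_episodes(tr[0, ]), "empty")
})

test_that("area per lipid is plain box arithmetic", {
  traj <- md_trajectory(times = 0:1, boxes = rbind(c(7.06, 7.04, 10),
                                                   c(14.12, 7.04, 10)),
                        frames = list(matrix(0, 1, 3), matrix(0, 1, 3)))
  apl <- area_per_lipid(traj, n_leaflet = 96)
  expect_equal(apl$apl[1], 7.06 * 7.04 / 96, tolerance = 1e-12)
  expect_equal(apl$apl[2], 2 * apl$apl[1], tolerance = 1e-12)
})

test_that("generator APL and thickness recover the scripted targets", {
  sc <- traj_script("dppc", 50, n_frames = 200L, seed = 11)
  g <- gen_bilayer_traj(sc)
  apl <- area_per_lipid(g$trajectory, n_leaflet = sc$n_lipids / 2)
  se <- sd(apl$apl) / sqrt(nrow(apl))
  expect_lt(abs(mean(apl$apl) - sc$apl_mean), 2 * se + 2 * sc$apl_sd / sqrt(200))
  th <- membrane_thickness(g$trajectory, g$topology, bin = 0.02)
  expect_lt(abs(th$thickness - sc$leaflet_sep), 0.05)
})

test_that("thickness is invariant under rigid z translation", {
  g <- small_bound_traj(n_frames = 50L)
  th1 <- membrane_thickness(g$trajectory, g$topology)
  shifted <- g$trajectory
  shifted$frames <- lapply(shifted$frames, function(p) {
    p[, 3] <- p[, 3] + 1.7
    p
  })
  th2 <- membrane_thickness(shifted, g$topology)
  expect_equal(th2$thickness, th1$thickness, tolerance = 1e-12)
})

test_that("a unimodal phosphorus profile is reported as unresolved", {
  g <- gen_bilayer_traj(traj_script("dppc", 50, n_frames = 20L,
                                    leaflet_sep = 0.05, p_jitter_sd = 0.3,
                                    seed = 1))
  expect_error(membrane_thickness(g$trajectory, g$topology),
               "leaflets not resolved")
})

test_that("hydrogen-bond criterion thresholds behave as constructed", {
  # one donor-H-acceptor triplet, planted at controlled geometry
  mk_frame <- function(d_da, dev_deg) {
    dev <- dev_deg * pi / 180
    donor <- c(2, 2, 2)
    acc <- donor + c(d_da, 0, 0)
    h <- donor + 0.101 * c(cos(dev), sin(dev), 0)
    rbind(acc, donor, h)  # order: lipid P, pep donor, pep H
  }
  atoms <- tibble::tibble(
    index = 1:3, role = c("P", "pep_donor", "pep_H"), mol_id = c(1L, 2L, 2L),
    mol_type = c("lipid", "peptide", "peptide"), leaflet = c(1, NA, NA),
    carbon = NA_real_)
  topo <- md_topology(atoms, tibble::tibble(donor = 2L, h = 3L))
  count1 <- function(d, ang) {
    traj <- md_trajectory(0, matrix(c(10, 10, 10), 1), list(mk_frame(d, ang)))
    unname(count_hbonds(traj, topo, adsorbed_only = FALSE)$n_total)
  }
  expect_identical(count1(0.29, 10), 1)
  expect_identical(count1(0.36, 10), 0)  # too far
  expect_identical(count1(0.29, 40), 0)  # too bent
})

test_that("planted bond counts match the scripted mean and the oracle", {
  g <- small_bound_traj(n_frames = 120L, seed = 9)
  hb <- count_hbonds(g$trajectory, g$topology, adsorbed_only = TRUE)
  se <- sd(hb$n_total) / sqrt(nrow(hb))
  expect_lt(abs(mean(hb$n_total) - 11), 2 * se + 3 * sqrt(11 / 120))
  # majority of planted bonds go to the phosphate group
  expect_gt(mean(hb$n_phosphate), mean(hb$n_carbonyl))
  # all-pairs brute-force oracle on a subset of frames
  for (f in seq(1, 120, by = 6)) {
    fr <- list(box = g$trajectory$boxes[f, ],
               positions = g$trajectory$frames[[f]])
    expect_identical(hb$n_total[f],
                     as.numeric(hbond_oracle_frame(fr, g$topology,
                                                   hbond_criterion())))
  }
})

test_that("zero planted bonds means zero counted bonds", {
  g <- small_bound_traj(n_frames = 40L, hbond_mean = 0, seed = 2)
  hb <- count_hbonds(g$trajectory, g$topology, adsorbed_only = FALSE)
  expect_true(all(hb$n_total == 0))
  expect_true(all(hb$bound))
})

test_that("order parameters hit the analytic limits and the target", {
  g_perp <- gen_bilayer_traj(traj_script("dppc", 50, n_frames = 3L,
                                         scd_target = -0.5, seed = 1))
  expect_equal(order_parameters(g_perp$trajectory, g_perp$topology)$s_cd,
               c(-0.5, -0.5), tolerance = 1e-10)
  g_par <- gen_bilayer_traj(traj_script("dppc", 50, n_frames = 3L,
                                        scd_target = 1, seed = 1))
  expect_equal(order_parameters(g_par$trajectory, g_par$topology)$s_cd,
               c(1, 1), tolerance = 1e-10)
  g_tgt <- gen_bilayer_traj(traj_script("dppc", 30, n_frames = 5L, seed = 2))
  expect_equal(order_parameters(g_tgt$trajectory, g_tgt$topology)$s_cd,
               c(-0.42, -0.42), tolerance = 1e-10)
})

test_that("isotropic C-H orientations average to zero order", {
  withr::with_seed(5, {
    u <- matrix(rnorm(3e5), ncol = 3)
    cos2 <- u[, 3]^2 / rowSums(u^2)
    s <- mean((3 * cos2 - 1) / 2)
    se <- sd((3 * cos2 - 1) / 2) / sqrt(nrow(u))
    expect_lt(abs(s), 3 * se)
  })
})

test_that("rdf is flat for an ideal gas and matches brute force", {
  withr::with_seed(8, {
    box <- c(6, 6, 6)
    n <- 350
    frames <- lapply(1:5, function(i) {
      cbind(runif(n, 0, 6), runif(n, 0, 6), runif(n, 0, 6))
    })
    atoms <- tibble::tibble(
      index = 1:n, role = "P", mol_id = 1:n, mol_type = "lipid",
      leaflet = 1, carbon = NA_real_)
    topo <- md_topology(atoms, tibble::tibble(donor = integer(),
                                              h = integer()))
    traj <- md_trajectory(0:4, matrix(rep(box, 5), ncol = 3, byrow = TRUE),
                          frames)
    g <- rdf(traj, topo, "P", "P", r_max = 2.5, dr = 0.1)
    expect_lt(max(abs(g$g[g$r > 0.3] - 1)), 0.25)
    expect_equal(mean(g$g[g$r > 0.3]), 1, tolerance = 0.05)
    # brute-force histogram oracle on the same frames
    breaks <- seq(0, 2.5, 0.1)
    acc <- numeric(length(breaks) - 1)
    for (f in 1:5) {
      M <- memthermo:::pairwise_min_image(frames[[f]], frames[[f]], box)
      d <- M[upper.tri(M)]
      counts <- 2 * hist(d[d < 2.5], breaks = breaks, plot = FALSE)$counts
      shell <- 4 / 3 * pi * diff(breaks^3)
      acc <- acc + counts / (n * shell * (n / prod(box)))
    }
    expect_equal(g$g, acc / 5, tolerance = 1e-10)
    expect_error(rdf(traj, topo, "P", "P", r_max = 4), "half")
  })
})

test_that("two fixed atoms give a single occupied rdf bin", {
  atoms <- tibble::tibble(index = 1:2, role = c("P", "N"), mol_id = 1L,
                          mol_type = "lipid", leaflet = 1, carbon = NA_real_)
  topo <- md_topology(atoms, tibble::tibble(donor = integer(), h = integer()))
  traj <- md_trajectory(0, matrix(c(8, 8, 8), 1),
                        list(rbind(c(1, 1, 1), c(1, 1, 1.73))))
  g <- rdf(traj, topo, "P", "N", r_max = 3, dr = 0.1)
  expect_identical(sum(g$g > 0), 1L)
  expect_true(g$g[g$r > 0.7 & g$r < 0.8] > 0)
})

test_that("density profiles conserve counts and match a direct histogram", {
  g <- small_bound_traj(n_frames = 10L)
  prof <- number_density_profile(g$trajectory, g$topology, "P", bin = 0.1)
  area <- mean(g$trajectory$boxes[, 1] * g$trajectory$boxes[, 2])
  expect_equal(sum(prof$density) * 0.1 * area, 192, tolerance = 0.5)
  # one-frame oracle
  traj1 <- md_trajectory(g$trajectory$times[1],
                         g$trajectory$boxes[1, , drop = FALSE],
                         g$trajectory$frames[1])
  prof1 <- number_density_profile(traj1, g$topology, "P", bin = 0.1)
  p_idx <- g$topology$atoms$index[g$topology$atoms$role == "P"]
  z <- g$trajectory$frames[[1]][p_idx, 3]
  z <- z - mean(z)
  a1 <- g$trajectory$boxes[1, 1] * g$trajectory$boxes[1, 2]
  for (i in which(prof1$density > 0)) {
    n_in <- sum(z >= prof1$z[i] - 0.05 & z < prof1$z[i] + 0.05)
    expect_equal(prof1$density[i], n_in / (a1 * 0.1), tolerance = 1e-9)
  }
})

test_that("observables are invariant under rigid translation with wrapping", {
  g <- small_bound_traj(n_frames = 15L)
  tr1 <- min_peptide_P_distance(g$trajectory, g$topology)
  hb1 <- count_hbonds(g$trajectory, g$topology, adsorbed_only = FALSE)
  moved <- g$trajectory
  moved$frames <- lapply(seq_along(moved$frames), function(f) {
    sweep(moved$frames[[f]], 2, c(2.3, -1.1, 4.0), `+`)
  })
  tr2 <- min_peptide_P_distance(moved, g$topology)
  hb2 <- count_hbonds(moved, g$topology, adsorbed_only = FALSE)
  expect_equal(tr2$min_dist, tr1$min_dist, tolerance = 1e-9)
  expect_identical(hb2$n_total, hb1$n_total)
})

test_that("topology invariants are enforced", {
  atoms <- tibble::tibble(index = 1:2, role = c("pep_donor", "pep_H"),
                          mol_id = 1L, mol_type = "peptide", leaflet = NA,
                          carbon = NA_real_)
  expect_error(md_topology(atoms, tibble::tibble(donor = integer(),
                                                 h = integer())),
               "pep_H")
  lip <- tibble::tibble(index = 1:2, role = c("P", "P"), mol_id = 1L,
                        mol_type = "lipid", leaflet = 1, carbon = NA_real_)
  expect_error(md_topology(lip, tibble::tibble(donor = integer(),
                                               h = integer())),
               "exactly one P")
})

test_that("missing roles raise errors naming the role", {
  g <- gen_bilayer_traj(traj_script("dppc", 50, n_frames = 2L, seed = 1))
  expect_error(min_peptide_P_distance(g$trajectory, g$topology), "pep")
  expect_error(count_hbonds(g$trajectory, g$topology), "donor")
})
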