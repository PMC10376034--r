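# Small fixtures shared across test files; everything is generated in code.

tiny_thermo <- function(...) {
  thermo_params("dppc", T_grid = seq(30, 52, by = 1),
                lambda_grid = seq(250, 300, by = 2), ...)
}

# one small bound bilayer+peptide system for observable tests
small_bound_traj <- function(n_frames = 30L, seed = 4, system = "dppc-r5f2",
                             temperature = 50, ...) {
  gen_bilayer_traj(traj_script(system, temperature, n_frames = n_frames,
                               seed = seed, ...))
}

# brute-force min distance over all 27 periodic images (oracle); points are
# first folded into the primary box so +/-1 images suffice
dist_27 <- function(a, b, box) {
  a <- a - box * floor(a / box)
  b <- b - box * floor(b / box)
  img <- expand.grid(x = -1:1, y = -1:1, z = -1:1)
  min(apply(img, 1, function(s) sqrt(sum((a - b + unlist(s) * box)^2))))
}

# brute-force H-bond count on one frame (O(N^2) oracle)
hbond_oracle_frame <- function(fr, topo, crit) {
  don <- topo$donor_h$donor
  hyd <- topo$donor_h$h
  acc <- topo$atoms$index[topo$atoms$role %in% c("P", "C=O")]
  n <- 0L
  for (k in seq_along(don)) {
    for (a in acc) {
      dv <- fr$positions[don[k], ] - fr$positions[a, ]
      dv <- dv - fr$box * floor(dv / fr$box + 0.5)
      if (sqrt(sum(dv^2)) > crit$d_max) next
      hd <- fr$positions[don[k], ] - fr$positions[hyd[k], ]
      hd <- hd - fr$box * floor(hd / fr$box + 0.5)
      ha <- fr$positions[a, ] - fr$positions[hyd[k], ]
      ha <- ha - fr$box * floor(ha / fr$box + 0.5)
      ang <- acos(sum(hd * ha) / sqrt(sum(hd^2) * sum(ha^2))) * 180 / pi
      if (180 - ang <= crit$angle_max) n <- n + 1L
    }
  }
  n
}
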