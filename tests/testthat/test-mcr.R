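# Rank-1 curve resolution and double-Boltzmann transition extraction.

test_that("noiseless rank-1 input is factorized exactly", {
  Tg <- seq(30, 52, 1)
  lg <- seq(250, 300, 2)
  cT <- double_boltzmann(Tg, 1, -0.1, -0.4, 34.4, 42.2, 1.2, 0.5)
  s <- exp(-(lg - 250) / 40)
  series <- spectra_series(Tg, lg, outer(cT, s))
  m <- rank1_mcr(series)
  expect_gt(m$explained_variance, 1 - 1e-12)
  # recovered profiles match ground truth up to the ||s||_inf = 1 scale
  expect_equal(m$s, s / max(s), tolerance = 1e-8)
  expect_equal(m$c, cT * max(s), tolerance = 1e-8)
  # oracle equivalence with the truncated singular decomposition
  sv <- svd(outer(cT, s), nu = 1, nv = 1)
  recon_svd <- sv$d[1] * tcrossprod(sv$u[, 1], sv$v[, 1])
  expect_equal(tcrossprod(m$c, m$s), recon_svd, tolerance = 1e-10)
})

test_that("all-zero matrices are rejected as degenerate", {
  series <- spectra_series(1:10, 1:5, matrix(0, 10, 5))
  expect_error(rank1_mcr(series), "degenerate input")
})

test_that("default-noise synthetic series is explained almost fully", {
  s <- gen_uvvis(thermo_params("dppc"), seed = 2)
  m <- rank1_mcr(smooth_sg(s))
  expect_gt(m$explained_variance, 0.99)
})

test_that("a planted second component shows up in the residuals", {
  p <- thermo_params("dppc", noise_sd = 0)
  s <- gen_uvvis(p, seed = 1)
  sm <- memthermo:::spectra_matrix(s)
  # second component: localized spectral bump growing linearly with T
  bump <- dnorm(sm$wavelengths, 275, 5)
  bump <- bump / max(bump)
  w <- seq(0, 1, length.out = length(sm$temperatures))
  amp <- 0.05 * max(sm$D)
  series2 <- spectra_series(sm$temperatures, sm$wavelengths,
                            sm$D + amp * outer(w, bump))
  m <- rank1_mcr(series2)
  expect_lt(m$explained_variance, 1)
  cors <- apply(m$E, 1, function(r) suppressWarnings(cor(r, bump)))
  expect_gt(max(abs(cors), na.rm = TRUE), 0.9)
})

test_that("exact double-Boltzmann profiles are recovered to 1e-6 degC", {
  Tg <- seq(30, 52, 0.5)
  cases <- list(
    c(a0 = 1, a1 = -0.12, a2 = -0.45, Tp = 34.4, Tm = 42.2, wp = 1.2, wm = 0.5),
    c(a0 = 0.5, a1 = 0.3, a2 = 0.8, Tp = 33, Tm = 44, wp = 0.8, wm = 0.7),
    c(a0 = 2, a1 = -0.2, a2 = -0.3, Tp = 36.1, Tm = 44.2, wp = 1.5, wm = 0.4))
  for (cs in cases) {
    y <- double_boltzmann(Tg, cs["a0"], cs["a1"], cs["a2"], cs["Tp"],
                          cs["Tm"], cs["wp"], cs["wm"])
    fit <- fit_double_boltzmann(y, Tg)
    expect_equal(fit$T_p, unname(cs["Tp"]), tolerance = 1e-6)
    expect_equal(fit$T_m, unname(cs["Tm"]), tolerance = 1e-6)
    expect_gt(fit$r_squared, 1 - 1e-10)
  }
})

test_that("single-sigmoid profiles are flagged as not separable", {
  Tg <- seq(30, 52, 0.5)
  y <- 1 - 0.5 / (1 + exp((41 - Tg) / 0.5))
  expect_error(fit_double_boltzmann(y, Tg), "transitions not separable")
})

test_that("scale invariance: scaling D scales c but not the transitions", {
  s <- gen_uvvis(thermo_params("dppc"), seed = 6)
  f1 <- extract_transitions(s)
  s10 <- s
  s10$absorbance <- s10$absorbance * 10
  f10 <- extract_transitions(s10)
  expect_equal(f10$T_p, f1$T_p, tolerance = 1e-6)
  expect_equal(f10$T_m, f1$T_m, tolerance = 1e-6)
  expect_equal(f10$r_squared, f1$r_squared, tolerance = 1e-8)
  m1 <- rank1_mcr(s)
  m10 <- rank1_mcr(s10)
  expect_equal(m10$c, 10 * m1$c, tolerance = 1e-6)
})

test_that("smoothing is a no-op on noiseless input", {
  s <- gen_uvvis(thermo_params("dppc", noise_sd = 0), seed = 1)
  f_raw <- extract_transitions(s, window = NULL)
  f_sm <- extract_transitions(s)
  expect_equal(f_sm$T_m, f_raw$T_m, tolerance = 1e-6)
  expect_equal(f_sm$T_p, f_raw$T_p, tolerance = 1e-6)
})

test_that("parameter recovery over seeds: small bias, honest intervals", {
  p <- thermo_params("dppc")
  fits <- lapply(1:50, function(s) extract_transitions(gen_uvvis(p, seed = s)))
  tp <- vapply(fits, `[[`, numeric(1), "T_p")
  tm <- vapply(fits, `[[`, numeric(1), "T_m")
  expect_lt(abs(mean(tp) - p$T_p), 0.1)
  expect_lt(abs(mean(tm) - p$T_m), 0.1)
  # coverage of the +/-2 se intervals, pooled over both transition
  # temperatures (the fit covariance cannot see the factorization's shared
  # spectral-profile error, so per-parameter coverage runs a few percent
  # below nominal; see the methods vignette)
  cover_p <- mapply(function(f) abs(f$T_p - p$T_p) <= 2 * f$se_Tp, fits)
  cover_m <- mapply(function(f) abs(f$T_m - p$T_m) <= 2 * f$se_Tm, fits)
  expect_gte(mean(c(cover_p, cover_m)), 0.9)
})

test_that("main-transition error grows (weakly) with noise", {
  base <- 0.005 * 0.57
  errs <- vapply(c(1, 4, 16), function(mult) {
    p <- thermo_params("dppc", noise_sd = base * mult)
    mean(vapply(1:50, function(s) {
      abs(extract_transitions(gen_uvvis(p, seed = s))$T_m - p$T_m)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(errs) >= 0))
})
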