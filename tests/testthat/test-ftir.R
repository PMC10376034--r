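# Infrared preprocessing, peak picking and band-shift bookkeeping.

region_grid <- function(rid) {
  r <- ftir_regions()
  r <- r[r$region == rid, ]
  c(r$lo, r$hi)
}

test_that("buffer subtraction removes a shared band", {
  shared <- band_spec(2880, 0.5, 15)
  buf <- gen_ftir(list(shared), baseline_slope = 0, noise_sd = 0.002,
                  grid = c(2820, 3000), seed = 3)
  smp <- gen_ftir(list(band_spec(2919), shared), baseline_slope = 0,
                  noise_sd = 0.002, grid = c(2820, 3000), seed = 4)
  diff <- subtract_buffer(smp, buf)
  at_2880 <- diff$absorbance[diff$wavenumber == 2880]
  # residual at the buffer-band centre is noise-level, plus the tail of the
  # 2919 band (< 0.06 here), not the 0.5-high band itself
  expect_lt(abs(at_2880 - memthermo:::pseudo_voigt(2880, 2919, 1, 14, 0.5)),
            5 * 0.002 * sqrt(2))
  expect_identical(subtract_buffer(smp, smp)$absorbance,
                   rep(0, nrow(smp)))
})

test_that("temperature mismatch between sample and buffer errors", {
  smp <- gen_ftir(list(band_spec(2919)), temperature = 30)
  buf <- gen_ftir(list(), temperature = 50)
  expect_error(subtract_buffer(smp, buf), "temperature mismatch")
})

test_that("gel-phase methylene stretch is found at 2919", {
  sp <- gen_ftir(default_ftir_bands("dppc", 30, "i"), grid = region_grid("i"),
                 seed = 2)
  pp <- preprocess_region(sp, "i", window = NULL)
  pk <- find_band_peaks(pp)
  expect_equal(round(pk$position[1]), 2919)
  expect_equal(pk$height[1], 1)
})

test_that("straight lines leave no signal in a region", {
  x <- seq(2820, 3000)
  sp <- ftir_spectrum(x, 0.2 + 1e-4 * x)
  expect_error(preprocess_region(sp, "i", window = NULL),
               "no signal in region")
})

test_that("preprocessing is scale invariant and idempotent", {
  sp <- gen_ftir(default_ftir_bands("dppc-k5f2", 30, "iii"),
                 grid = region_grid("iii"), seed = 7, system = "dppc-k5f2")
  p1 <- preprocess_region(sp, "iii")
  sp10 <- ftir_spectrum(sp$wavenumber, 10 * sp$absorbance,
                        system = "dppc-k5f2")
  p10 <- preprocess_region(sp10, "iii")
  expect_equal(p10$absorbance, p1$absorbance, tolerance = 1e-9)
  # second pass: already cropped/baselined/normalized, smoothing aside
  p2 <- preprocess_region(p1, "iii", window = NULL)
  expect_equal(p2$absorbance, p1$absorbance, tolerance = 1e-9)
})

test_that("the K5F2 scissoring region resolves all four reported bands", {
  sp <- gen_ftir(default_ftir_bands("dppc-k5f2", 30, "iii"),
                 grid = region_grid("iii"), seed = 3, system = "dppc-k5f2")
  pk <- find_band_peaks(preprocess_region(sp, "iii"))
  expect_identical(nrow(pk), 4L)
  for (pos in c(1468, 1455, 1417, 1379)) {
    expect_lte(min(abs(pk$position - pos)), 1)
  }
})

test_that("monotone spectra yield an empty peak list", {
  x <- seq(1020, 1130)
  sp <- ftir_spectrum(x, exp(-(x - 1020) / 30))
  expect_identical(nrow(find_band_peaks(sp)), 0L)
})

test_that("refined positions match a dense brute-force profile oracle", {
  bands <- default_ftir_bands("dppc", 30, "v")
  sp <- gen_ftir(bands, baseline_slope = 0, noise_sd = 0,
                 grid = region_grid("v"))
  pk <- find_band_peaks(preprocess_region(sp, "v", window = NULL))
  xd <- seq(1020, 1130, by = 0.01)
  yd <- Reduce(`+`, lapply(bands, function(b) {
    memthermo:::pseudo_voigt(xd, b$center, b$height, b$fwhm,
                             b$lorentz_fraction)
  }))
  for (i in seq_len(nrow(pk))) {
    win <- abs(xd - pk$position[i]) < 5
    expect_lt(abs(pk$position[i] - xd[win][which.max(yd[win])]), 0.5)
  }
})

test_that("noiseless planted bands are each detected exactly once", {
  for (case in list(list("dppc", "i"), list("dppc-k5f2", "iii"),
                    list("dppc", "v"))) {
    bands <- default_ftir_bands(case[[1]], 30, case[[2]])
    sp <- gen_ftir(bands, baseline_slope = 0, noise_sd = 0,
                   grid = region_grid(case[[2]]), system = case[[1]])
    pk <- find_band_peaks(preprocess_region(sp, case[[2]],
                                            window = NULL))
    expect_identical(nrow(pk), length(bands))
    for (b in bands) expect_lte(min(abs(pk$position - b$center)), 1)
  }
})

test_that("band shifts carry the reported sign convention", {
  mk <- function(sys, temp, rid) {
    sp <- gen_ftir(default_ftir_bands(sys, temp, rid),
                   grid = region_grid(rid), seed = 5, system = sys,
                   temperature = temp)
    find_band_peaks(preprocess_region(sp, rid))
  }
  # carbonyl stretch moves down 5 wavenumbers on melting
  co <- band_shift(mk("dppc", 30, "ii"), mk("dppc", 50, "ii"), 1737)
  expect_identical(co$delta, -5)
  # methylene scissoring moves up 2
  ch2 <- band_shift(mk("dppc", 30, "iii"), mk("dppc", 50, "iii"), 1468)
  expect_identical(ch2$delta, 2)
  same <- band_shift(mk("dppc", 30, "ii"), mk("dppc", 30, "ii"), 1737)
  expect_identical(same$delta, 0)
  expect_error(band_shift(mk("dppc", 30, "ii"), mk("dppc", 50, "ii"), 1600),
               "band not found")
})
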