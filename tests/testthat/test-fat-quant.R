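# Voxelwise water-fat separation: PDFF arithmetic, single-voxel fits,
# field-map initialisation and QC.

test_that("PDFF ratio arithmetic is exact and symmetric", {
  expect_equal(compute_pdff(20, 80), 80)
  expect_equal(compute_pdff(1, 0), 0)
  expect_equal(compute_pdff(5, 5), 50)
  expect_true(is.na(compute_pdff(0, 0)))
  expect_error(compute_pdff(-1, 2), "non-negative")
  withr::with_seed(3, {
    w <- runif(50, 0, 10); f <- runif(50, 0, 10)
    expect_equal(compute_pdff(w, f) + compute_pdff(f, w), rep(100, 50))
  })
})

test_that("noiseless single-voxel fits recover the generating parameters", {
  acq <- acq6(); sp <- default_fat_spectrum()
  v <- voxel_params(70, 30, common_phase_rad = 0.4, fieldmap_Hz = 25,
                    r2star_per_ms = 0.04)
  f <- fit_voxel(forward_signal(v, acq, sp), acq, sp)
  expect_true(f$converged)
  expect_equal(f$water_amp, 70, tolerance = 1e-6)
  expect_equal(f$fat_amp, 30, tolerance = 1e-6)
  expect_equal(f$fieldmap_Hz, 25, tolerance = 1e-6)
  expect_equal(f$r2star_per_ms, 0.04, tolerance = 1e-6)
  expect_equal(f$pdff_percent, 30, tolerance = 1e-6)
  expect_equal(f$common_phase_rad, 0.4, tolerance = 1e-6)
})

test_that("pure-water voxel yields zero fat and PDFF 0", {
  acq <- acq6(); sp <- default_fat_spectrum()
  s <- forward_signal(voxel_params(100, 0, fieldmap_Hz = 10,
                                   r2star_per_ms = 0.02), acq, sp)
  f <- fit_voxel(s, acq, sp)
  expect_lt(f$fat_amp, 1e-5)
  expect_lt(f$pdff_percent, 1e-5)
})

test_that("initialising on the aliased branch reproduces the water-fat swap", {
  acq <- acq6(); sp <- default_fat_spectrum()
  truth <- 30
  v <- voxel_params(100 - truth, truth, fieldmap_Hz = 25, r2star_per_ms = 0.04)
  s <- forward_signal(v, acq, sp)
  # the dominant fat peak sits ~ -434 Hz from water at 3 T; seeding the local
  # fit one fat-water shift away lands in the swapped basin
  swap_shift <- -3.4 * 42.577 * 3
  f <- fit_voxel(s, acq, sp, psi_init = 25 + swap_shift)
  expect_equal(f$pdff_percent, 100 - truth, tolerance = 15)
  expect_gt(abs(f$fieldmap_Hz - 25), 100)
})

test_that("degenerate signals are flagged", {
  acq <- acq6(); sp <- default_fat_spectrum()
  f <- fit_voxel(rep(0 + 0i, 6), acq, sp)
  expect_true(f$flagged)
  expect_equal(f$water_amp + f$fat_amp, 0)
  expect_error(fit_voxel(c(1 + 0i, NA, 1, 1, 1, 1), acq, sp), "finite")
})

test_that("round trip holds over a parameter subgrid", {
  acq <- acq6(); sp <- default_fat_spectrum()
  for (pdff in c(0, 30, 50, 80, 100)) {
    for (psi in c(-100, 0, 100)) {
      v <- voxel_params(100 - pdff, pdff, fieldmap_Hz = psi,
                        r2star_per_ms = 0.05)
      f <- fit_voxel(forward_signal(v, acq, sp), acq, sp)
      expect_equal(f$pdff_percent, pdff, tolerance = 1e-4)
      expect_equal(f$fieldmap_Hz, psi, tolerance = 1e-3)
    }
  }
})

test_that("fit residual at the estimate is locally optimal", {
  acq <- acq6(); sp <- default_fat_spectrum()
  withr::with_seed(21, {
    for (rep in 1:5) {
      v <- voxel_params(runif(1, 0, 100), runif(1, 0, 100),
                        common_phase_rad = runif(1, -pi, pi),
                        fieldmap_Hz = runif(1, -100, 100),
                        r2star_per_ms = runif(1, 0.01, 0.1))
      s <- forward_signal(v, acq, sp)
      sn <- s + complex(real = rnorm(6, sd = 0.02 * max(Mod(s))),
                        imaginary = rnorm(6, sd = 0.02 * max(Mod(s))))
      f <- fit_voxel(sn, acq, sp)
      # residual at the estimate must not exceed residual at the truth
      fw <- forward_signal(voxel_params(f$water_amp, f$fat_amp,
                                        f$common_phase_rad, f$fieldmap_Hz,
                                        f$r2star_per_ms), acq, sp)
      expect_lte(sum(Mod(sn - fw)^2), sum(Mod(sn - s)^2) + 1e-8)
    }
  })
})

test_that("field-map grid search finds constant offsets within one grid step", {
  sp <- default_fat_spectrum()
  # uniform zero-field phantom
  p0 <- make_two_compartment(n = 10, fieldmap_Hz = 0)
  fm <- fieldmap_init(p0$series, sp)
  expect_equal(max(abs(fm)), 0)
  # constant 40 Hz on a 2 Hz grid
  p40 <- make_two_compartment(n = 10, fieldmap_Hz = 40)
  fm40 <- fieldmap_init(p40$series, sp, psi_grid = seq(-460, 460, by = 2))
  expect_lte(max(abs(fm40 - 40)), 2)
})

test_that("field-map follows a smooth ramp without water-fat swaps", {
  sp <- default_fat_spectrum()
  d <- c(12, 12, 16)
  ramp <- array(rep(seq(-100, 100, length.out = d[3]), each = d[1] * d[2]), d)
  ph <- make_two_compartment(n = 12, fieldmap_Hz = 1)   # placeholder sizes
  # rebuild with the ramp on a 12x12x16 grid
  rl <- slice.index(array(0L, d), 3)
  lab <- ifelse(rl <= d[3] / 2, 1L, 2L)
  pdff <- array(c(90, 5)[lab], d); r2 <- array(c(1 / 30, 1 / 25)[lab], d)
  acq <- acq6(); cn <- fat_phasor(sp, acq)
  t_s <- acq$echo_times_ms / 1000
  sig <- array(0i, c(d, 6))
  for (k in 1:6) {
    sig[, , , k] <- ((1 - pdff / 100) + (pdff / 100) * cn[k]) *
      exp(1i * 2 * pi * ramp * t_s[k]) * exp(-r2 * acq$echo_times_ms[k])
  }
  series <- echo_series(sig, acq)
  fm <- fieldmap_init(series, sp)
  step <- attr(fm, "grid_step")
  expect_lte(max(abs(fm - ramp)), step)
  expect_error(fieldmap_init(echo_series(array(0i, c(4, 4, 4, 6)), acq), sp),
               "no signal")
})

test_that("volume fitting recovers a noiseless two-compartment phantom", {
  sp <- default_fat_spectrum()
  ph <- make_two_compartment(n = 12, fieldmap_Hz = 30)
  maps <- fit_volume(ph$series, sp)
  expect_true(all(maps$qc_flags == 0L))
  err <- abs(maps$pdff_percent - ph$truth$pdff)
  expect_lt(max(err), 0.5)
  expect_equal(max(abs(maps$fieldmap_Hz - 30)), 0, tolerance = 0.1)
  # T2* is reported in ms as 1/r2*
  expect_equal(median(maps$t2star_ms[ph$truth$labels == 1L]), 30,
               tolerance = 0.1)
})

test_that("all-air volumes come back fully flagged and fail QC", {
  acq <- acq6(); sp <- default_fat_spectrum()
  series <- echo_series(array(0i, c(8, 8, 8, 6)), acq)
  maps <- fit_volume(series, sp)
  expect_true(all(maps$qc_flags == 2L))
  expect_true(all(is.na(maps$pdff_percent)))
  expect_false(qc_report(maps)$pass)
})

test_that("QC report thresholds behave at the boundaries", {
  sp <- default_fat_spectrum()
  ph <- make_two_compartment(n = 8)
  maps <- fit_volume(ph$series, sp)
  r <- qc_report(maps)
  expect_true(r$pass)
  expect_lt(r$fraction_flagged, 0.01)
  # threshold 0: a single flagged voxel fails the dataset
  maps$qc_flags[1] <- 1L
  expect_false(qc_report(maps, threshold = 0)$pass)
  expect_true(qc_report(maps, threshold = 0.5)$pass)
})
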