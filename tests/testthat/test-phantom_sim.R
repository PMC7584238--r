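# Point-scatterer simulator: determinism, Poisson statistics, spectral
# support and the size -> spectral-slope monotonicity it must provide as
# ground truth.

test_that("scatterer fields follow the stated Poisson/uniform model", {
  ext <- c(0.01, 0.01)  # 10 x 10 mm
  expect_length(generate_scatterer_field(ext, 0, 30e-6, seed = 1)$axial, 0)

  counts <- vapply(1:20, function(s)
    length(generate_scatterer_field(ext, 12, 30e-6, seed = s)$axial), 0)
  # mean count of 20 Poisson(1200) draws within 3 standard errors
  expect_close(mean(counts), 1200, 3 * sqrt(1200 / 20))

  f1 <- generate_scatterer_field(ext, 12, 30e-6, seed = 42)
  f2 <- generate_scatterer_field(ext, 12, 30e-6, seed = 42)
  expect_identical(f1$axial, f2$axial)
  expect_identical(f1$amplitudes, f2$amplitudes)
  expect_true(all(f1$axial >= 0 & f1$axial <= ext[1]))
  expect_true(all(f1$lateral >= 0 & f1$lateral <= ext[2]))
  expect_true(all(f1$amplitudes > 0))

  expect_error(generate_scatterer_field(ext, -1, 30e-6), "number_density")
  expect_error(generate_scatterer_field(c(-1, 1), 5, 30e-6), "extent")
})

test_that("pulse model invariants are enforced", {
  expect_error(pulse_model(fractional_bandwidth = 2.5), "fractional_bandwidth")
  expect_error(pulse_model(center_frequency = 7e6, sampling_frequency = 20e6),
               "sampling_frequency")
  expect_silent(pulse_model())
})

test_that("synthesized RF has the correct spectral signature", {
  p <- fix_pulse()
  lam <- p$speed_of_sound / p$center_frequency
  ext <- c(0.006, 31 * 2e-4 + 14 * lam)

  # empty field -> silence
  empty <- generate_scatterer_field(ext, 0, 30e-6, seed = 1)
  rf0 <- synthesize_rf(empty, p, 32, 2e-4)
  expect_true(all(rf0$frames[[1]] == 0))

  # dense, vanishingly small scatterers: mean power spectrum peaks near fc
  # (periodograms Welch-averaged over lines and axial segments so speckle
  # noise cannot move the argmax across the flat Gaussian top)
  fld <- generate_scatterer_field(ext, 40, 1e-6, seed = 3)
  rf <- synthesize_rf(fld, p, 64, 1e-4)
  fr <- rf$frames[[1]]
  segs <- seq(1, nrow(fr) - 127, by = 64)
  lin <- Reduce(`+`, lapply(segs, function(s) {
    10^(window_power_spectrum(fr[s:(s + 127), ],
                              p$sampling_frequency)$power_db / 10)
  })) / length(segs)
  ps <- power_spectrum((0:64) * p$sampling_frequency / 128, 10 * log10(lin))
  pk <- ps$frequencies[which.max(ps$power_db)]
  expect_close(pk, p$center_frequency, 0.15 * p$center_frequency)

  # spectral support confined to the transducer band to -40 dB; for the
  # Gaussian system response the -40 dB (power) half-width is
  # sigma_f * sqrt(2 ln 1e4) ~ 6.5 MHz
  lin <- 10^(ps$power_db / 10)
  inband <- abs(ps$frequencies - p$center_frequency) <= 6.6e6
  expect_lt(max(lin[!inband]) / max(lin), 1e-4)

  expect_error(synthesize_rf(fld, list(center_frequency = 7e6), 32, 2e-4),
               "pulse")
})

test_that("larger scatterers give steeper negative spectral slopes", {
  ref <- fix_reference()
  radii <- c(20, 35, 50, 65, 80) * 1e-6
  slopes <- vapply(radii, function(a) {
    ph <- homogeneous_phantom(a, seed = 7)
    volume_mean(phantom_maps(ph, ref), "SS")
  }, 0)
  expect_equal(cor(slopes, seq_along(radii), method = "spearman"), -1)
  # the 20 um vs 80 um contrast of the spec example, on fitted SS
  expect_gt(slopes[1], slopes[5])
  assign("slope_sweep", list(radii = radii, slopes = slopes),
         envir = .fixtures)
})

test_that("reference phantom is homogeneous, deterministic, with positive BSC", {
  p <- fix_pulse()
  r1 <- generate_reference(p, n_lines = 32, seed = 9, extent_axial = 0.008)
  r2 <- generate_reference(p, n_lines = 32, seed = 9, extent_axial = 0.008)
  expect_identical(r1$rf$frames, r2$rf$frames)

  grid <- r1$known_bsc$frequency
  expect_true(all(r1$known_bsc$bsc[grid >= 4e6 & grid <= 9e6] > 0))

  # per-window in-band spectra vary < 2 dB (std) across windows
  fr <- r1$rf$frames[[1]]
  n <- nrow(fr)
  starts <- seq(1, n - 115, by = 57)
  mids <- vapply(starts, function(s) {
    ps <- window_power_spectrum(fr[s:(s + 114), ], p$sampling_frequency)
    mean(ps$power_db[ps$frequencies >= 4e6 & ps$frequencies <= 9e6])
  }, 0)
  expect_lt(sd(mids), 2)
})

test_that("cohort generator yields labelled volumes and flags degenerate setups", {
  p <- fix_pulse()
  coh <- generate_cohort(n_per_class = 2, seed = 11, pulse = p,
                         n_lines = 32, extent_axial = 0.006)
  expect_length(coh, 4)
  expect_setequal(unique(vapply(coh, `[[`, "", "label")), c("R", "NR"))
  expect_true(all(vapply(coh, function(x)
    inherits(x$rf, "rf_volume") && is.logical(x$mask[[1]]), TRUE)))
  # mask aligned to frame lattice, non-empty
  expect_true(all(vapply(coh, function(x)
    sum(x$mask[[1]]) > 0 && all(dim(x$mask[[1]]) == dim(x$rf$frames[[1]])), TRUE)))

  coh2 <- generate_cohort(n_per_class = 2, seed = 11, pulse = p,
                          n_lines = 32, extent_axial = 0.006)
  expect_identical(coh[[1]]$rf$frames, coh2[[1]]$rf$frames)
  expect_identical(coh[[4]]$truth, coh2[[4]]$truth)

  same <- list(radius_range = c(3e-5, 4e-5), density_range = c(10, 12),
               amplitude_cv = 0.3)
  expect_warning(generate_cohort(2, class_params = list(R = same, NR = same),
                                 noise = 0, seed = 1, pulse = p,
                                 n_lines = 32, extent_axial = 0.006),
                 "inseparable")
})
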