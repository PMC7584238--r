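# Shared fixtures (memoized: expensive simulations are built once per run)
# and independent oracles used across test files.

.fixtures <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, expr, envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

fix_pulse <- function() pulse_model()

fix_reference <- function() {
  fixture("reference", generate_reference(fix_pulse(), n_lines = 64, seed = 2))
}

# one synthetic patient from the default two-class cohort generator
fix_patient <- function() {
  fixture("patient", generate_cohort(n_per_class = 2, seed = 5,
                                     pulse = fix_pulse())[[1]])
}

fix_extract <- function() {
  fixture("extract", {
    pat <- fix_patient()
    run_extract(pat$rf, pat$mask, fix_reference(), qus_config(), keep_maps = TRUE)
  })
}

# homogeneous full-mask phantom with known microstructure
homogeneous_phantom <- function(effective_radius, number_density = 12,
                                seed = 7, n_lines = 48,
                                extent_axial = 0.008, mean_amplitude = 1,
                                pulse = fix_pulse()) {
  lam <- pulse$speed_of_sound / pulse$center_frequency
  ext <- c(extent_axial, (n_lines - 1) * 2e-4 + 14 * lam)
  fld <- generate_scatterer_field(ext, number_density, effective_radius,
                                  seed = seed, mean_amplitude = mean_amplitude)
  rf <- synthesize_rf(fld, pulse, n_lines, 2e-4)
  mask <- list(matrix(TRUE, nrow(rf$frames[[1]]), ncol(rf$frames[[1]])))
  list(rf = rf, mask = mask, field = fld)
}

phantom_maps <- function(ph, reference = fix_reference(),
                         pulse = fix_pulse()) {
  grid <- plan_subrois(ph$mask, pulse, ph$rf$line_spacing)
  build_parametric_maps(ph$rf, grid, reference)
}

# brute-force GLCM oracle: explicit double loop over all pixel pairs
glcm_oracle <- function(grid, levels, config) {
  counts <- matrix(0, levels, levels)
  nr <- nrow(grid); nc <- ncol(grid)
  for (off in qustex:::glcm_offsets(config)) {
    for (r in seq_len(nr)) {
      for (cc in seq_len(nc)) {
        r2 <- r + off[1]; c2 <- cc + off[2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        a <- grid[r, cc]; b <- grid[r2, c2]
        if (is.na(a) || is.na(b)) next
        counts[a + 1, b + 1] <- counts[a + 1, b + 1] + 1
      }
    }
  }
  if (config$symmetric) counts <- counts + t(counts)
  counts / sum(counts)
}

# synthetic Gaussian feature cohort for classifier tests: `shift` is the
# class separation (in SDs) applied to the first n_informative features
make_feature_cohort <- function(n_per_class = 17, p = 10, shift = 0,
                                n_informative = 1, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  X <- matrix(rnorm(n * p), n, p)
  labs <- rep(c("R", "NR"), each = n_per_class)
  if (shift != 0 && n_informative > 0) {
    X[labs == "NR", seq_len(n_informative)] <-
      X[labs == "NR", seq_len(n_informative)] + shift
  }
  colnames(X) <- sprintf("F%02d", seq_len(p))
  cohort_table(sprintf("p%02d", seq_len(n)), labs, X)
}

expect_close <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("|%g - %g| <= %g", object, expected, tol))
}
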