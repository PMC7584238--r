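# Per-window spectral estimation and the five QUS parameters:
# mid-band fit (MBF), spectral slope (SS), 0-MHz intercept (SI) from a
# straight-line fit to the normalized dB spectrum over the analysis band,
# and average scatterer diameter (ASD) / average acoustic concentration
# (AAC) from a Gaussian form-factor linearization of the backscatter
# coefficient.

power_spectrum <- function(frequencies, power_db, window_origin = c(NA, NA),
                           degenerate = FALSE, units = "dB") {
  structure(list(frequencies = frequencies, power_db = power_db,
                 window_origin = window_origin, degenerate = degenerate,
                 units = units),
            class = "power_spectrum")
}

#' Averaged periodogram of one RF analysis window
#'
#' Applies a taper (Hann by default) to each scan line in the window,
#' computes per-line periodograms and averages them in linear power before
#' conversion to dB (Welch-style averaging across lines).
#'
#' @param rf_window real matrix, axial samples x scan lines (>= 16 x 2)
#' @param sampling_frequency Hz
#' @param taper "hann" or "rect"
#' @return a `power_spectrum` on the one-sided FFT frequency grid; an
#'   all-zero window yields -Inf dB flagged `degenerate`, not an error
#' @export
window_power_spectrum <- function(rf_window, sampling_frequency,
                                  taper = c("hann", "rect")) {
  taper <- match.arg(taper)
  assert(is.matrix(rf_window), "rf_window must be a matrix (samples x lines)")
  n <- nrow(rf_window)
  assert(n >= 16, "window must have >= 16 axial samples")
  assert(ncol(rf_window) >= 2, "window must have >= 2 scan lines")
  w <- if (taper == "hann") hann_taper(n) else rep(1, n)
  sp <- Mod(stats::mvfft(rf_window * w))^2 / (n * sum(w^2))
  p <- rowMeans(sp)
  half <- seq_len(floor(n / 2) + 1)
  freqs <- (half - 1) * sampling_frequency / n
  pd <- to_db(p[half])
  power_spectrum(freqs, pd, degenerate = all(rf_window == 0))
}

#' Average window spectrum of a reference phantom
#'
#' Tiles the reference RF into axial windows of the requested length (50%
#' overlap, all lines, all frames) and averages the per-window periodograms
#' in linear power — the system-response estimate used for normalization.
#'
#' @param reference a `reference_phantom`
#' @param window_samples axial window length in samples
#' @param taper passed to [window_power_spectrum()]
#' @return a `power_spectrum`
#' @export
reference_spectrum <- function(reference, window_samples,
                               taper = c("hann", "rect")) {
  taper <- match.arg(taper)
  assert(inherits(reference, "reference_phantom"),
         "reference must be a reference_phantom")
  rf <- reference$rf
  n <- nrow(rf$frames[[1]])
  assert(window_samples <= n, "window longer than the reference frames")
  starts <- unique(pmin(seq(1, n - window_samples + 1,
                            by = max(1, floor(window_samples / 2))),
                        n - window_samples + 1))
  acc <- NULL
  count <- 0
  for (fr in rf$frames) {
    for (s in starts) {
      ps <- window_power_spectrum(fr[s:(s + window_samples - 1), , drop = FALSE],
                                  rf$sampling_frequency, taper)
      lin <- 10^(ps$power_db / 10)
      acc <- if (is.null(acc)) lin else acc + lin
      count <- count + 1
    }
  }
  ps$power_db <- to_db(acc / count)
  ps$window_origin <- c(NA, NA)
  ps
}

#' Reference-phantom normalization of a sample spectrum
#'
#' `normalized_dB = sample_dB - reference_dB + 10*log10(known_bsc)`; any
#' multiplicative system response common to sample and reference cancels
#' exactly, leaving an estimate of the sample backscatter coefficient in dB
#' relative units (dBr).
#'
#' @param sample,reference `power_spectrum` objects on the same frequency
#'   grid
#' @param known_bsc data.frame with columns `frequency`, `bsc` (tabulated
#'   reference backscatter coefficient, interpolated on log scale), or NULL
#'   for a unit BSC
#' @return a `power_spectrum` in dBr
#' @export
normalize_to_reference <- function(sample, reference, known_bsc = NULL) {
  assert(inherits(sample, "power_spectrum") &&
           inherits(reference, "power_spectrum"),
         "sample and reference must be power_spectrum objects")
  assert(length(sample$frequencies) == length(reference$frequencies) &&
           isTRUE(all.equal(sample$frequencies, reference$frequencies)),
         "sample and reference must share the same frequency grid")
  bsc_db <- if (is.null(known_bsc)) 0 else
    to_db(interp_bsc(known_bsc, sample$frequencies))
  out <- sample
  out$power_db <- sample$power_db - reference$power_db + bsc_db
  out$degenerate <- sample$degenerate || reference$degenerate
  out$units <- "dBr"
  out
}

#' Straight-line fit to a normalized spectrum over the analysis band
#'
#' Least-squares line of dBr against frequency in MHz restricted to the
#' band; spectral slope SS is the slope (dBr/MHz), SI the 0-MHz intercept
#' (dBr) and MBF the fitted value at the centre frequency, so
#' `MBF = SI + SS * fc_MHz` holds exactly.
#'
#' @param norm a `power_spectrum` in dBr
#' @param band length-2 Hz, analysis band (default 4--9 MHz)
#' @param center_frequency Hz (default 7 MHz)
#' @return object of class `spectral_fit` with MBF, SS, SI, band,
#'   center_frequency, valid
#' @export
fit_spectral_band <- function(norm, band = c(4e6, 9e6),
                              center_frequency = 7e6) {
  assert(inherits(norm, "power_spectrum"), "norm must be a power_spectrum")
  sel <- norm$frequencies >= band[1] & norm$frequencies <= band[2]
  assert(sum(sel) >= 4, "need >= 4 frequency bins in the analysis band")
  f <- norm$frequencies[sel] / 1e6
  y <- norm$power_db[sel]
  valid <- !norm$degenerate && all(is.finite(y))
  if (!valid) {
    fit <- list(MBF = NA_real_, SS = NA_real_, SI = NA_real_)
  } else {
    fm <- mean(f); ym <- mean(y)
    ss <- sum((f - fm) * (y - ym)) / sum((f - fm)^2)
    si <- ym - ss * fm
    fit <- list(MBF = si + ss * center_frequency / 1e6, SS = ss, SI = si)
  }
  structure(c(fit, list(band = band, center_frequency = center_frequency,
                        valid = valid)),
            class = "spectral_fit")
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat(sprintf("<spectral_fit> MBF = %.2f dBr, SS = %.2f dBr/MHz, SI = %.2f dBr (band %.1f-%.1f MHz)%s\n",
              x$MBF, x$SS, x$SI, x$band[1] / 1e6, x$band[2] / 1e6,
              if (x$valid) "" else " [invalid]"))
  invisible(x)
}

#' Scatterer size and acoustic concentration from a normalized spectrum
#'
#' Gaussian form-factor linearization: with
#' `BSC(f) = C * f^4 * exp(-G (2 pi f / c)^2 a_eff^2)` (G = 0.827, the
#' spherical-Gaussian form-factor constant), the quantity
#' `ln(BSC) - 4 ln(f)` is linear in `f^2` with slope
#' `-G (2 pi / c)^2 a_eff^2`. The regression slope therefore maps to the
#' effective radius, reported as a diameter `ASD = 2 a_eff` in micrometres;
#' the intercept maps to the log concentration `AAC = 10 log10(C)` in
#' dB/cm^3 convention (relative units; a 10x concentration step is exactly
#' +10 dB).
#'
#' @param norm a `power_spectrum` in dBr
#' @param band length-2 Hz analysis band
#' @param speed_of_sound m/s
#' @param min_asd minimum resolvable diameter in micrometres; a
#'   non-negative slope (nonphysical size) clamps ASD here and flags the
#'   estimate
#' @return object of class `scatterer_estimate` with ASD (um), AAC (dB),
#'   valid, clamped
#' @export
estimate_scatterer_properties <- function(norm, band = c(4e6, 9e6),
                                          speed_of_sound = 1540,
                                          min_asd = 1) {
  assert(inherits(norm, "power_spectrum"), "norm must be a power_spectrum")
  sel <- norm$frequencies >= band[1] & norm$frequencies <= band[2] &
    norm$frequencies > 0
  assert(sum(sel) >= 4, "need >= 4 frequency bins in the analysis band")
  f <- norm$frequencies[sel]
  db <- norm$power_db[sel]
  if (norm$degenerate || !all(is.finite(db))) {
    return(structure(list(ASD = NA_real_, AAC = NA_real_, valid = FALSE,
                          clamped = FALSE),
                     class = "scatterer_estimate"))
  }
  bsc <- 10^(db / 10)
  y <- log(bsc) - 4 * log(f)
  x <- f^2
  xm <- mean(x); ym <- mean(y)
  slope <- sum((x - xm) * (y - ym)) / sum((x - xm)^2)
  intercept <- ym - slope * xm
  aac <- 10 * intercept / log(10)
  clamped <- FALSE
  if (slope >= 0) {
    asd <- min_asd
    clamped <- TRUE
  } else {
    a_eff <- (speed_of_sound / (2 * pi)) *
      sqrt(-slope / GAUSS_FORM_FACTOR_CONSTANT)
    asd <- 2 * a_eff * 1e6
  }
  structure(list(ASD = asd, AAC = aac, valid = TRUE, clamped = clamped),
            class = "scatterer_estimate")
}

#' Dump per-window spectra to CSV for inspection
#'
#' @param spectra list of `power_spectrum` objects
#' @param path output CSV path
#' @return path, invisibly
#' @export
write_spectra_csv <- function(spectra, path) {
  rows <- do.call(rbind, lapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    data.frame(window = i, frequency = s$frequencies, power_db = s$power_db)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
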