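# Sub-ROI tiling of the tumour mask and assembly of the five QUS parametric
# maps (MBF, SS, SI, ASD, AAC) on the sliding-window lattice.

QUS_PARAMS <- c("MBF", "SS", "SI", "ASD", "AAC")
QUS_UNITS <- c(MBF = "dBr", SS = "dBr/MHz", SI = "dBr", ASD = "um",
               AAC = "dB/cm^3")

#' Plan overlapping sub-ROI analysis windows over a tumour mask
#'
#' Windows are `window_wavelengths` x `window_wavelengths` ultrasound
#' wavelengths square (10 lambda by default, about 2.2 mm at 7 MHz in soft
#' tissue), converted to samples (axial pitch `c / (2 fs)`) and lines
#' (lateral pitch = line spacing) and rounded to odd pixel counts so window
#' centres are well defined. The step per axis is
#' `max(1, round((1 - overlap) * window))`, giving the nominal 94% overlap.
#'
#' @param mask logical matrix (one frame) or list of logical matrices on the
#'   RF sample x line lattice
#' @param pulse a [pulse_model()]
#' @param line_spacing metres
#' @param overlap fractional overlap between neighbouring windows
#'   (default 0.94)
#' @param window_wavelengths physical window side in wavelengths
#'   (default 10)
#' @param inclusion "center" keeps windows whose centre pixel is inside the
#'   mask (default); "inside" requires the whole window inside the mask
#' @return object of class `subroi_grid`: window/step sizes, physical window
#'   side (`side_m`), per-frame origin tables (window top-left corner plus
#'   lattice indices), lattice dimensions and map pixel pitch in mm
#' @export
plan_subrois <- function(mask, pulse, line_spacing, overlap = 0.94,
                         window_wavelengths = 10,
                         inclusion = c("center", "inside")) {
  inclusion <- match.arg(inclusion)
  if (is.matrix(mask)) mask <- list(mask)
  assert(length(mask) >= 1 && all(vapply(mask, is.logical, TRUE)),
         "mask must be one or more logical matrices")
  assert(overlap >= 0 && overlap < 1, "overlap must lie in [0, 1)")
  c0 <- pulse$speed_of_sound
  lambda <- c0 / pulse$center_frequency
  side <- window_wavelengths * lambda
  axial_pitch <- c0 / (2 * pulse$sampling_frequency)
  ws <- round_odd(side / axial_pitch)
  wl <- round_odd(side / line_spacing)
  step_s <- max(1L, as.integer(round((1 - overlap) * ws)))
  step_l <- max(1L, as.integer(round((1 - overlap) * wl)))

  n <- nrow(mask[[1]]); m <- ncol(mask[[1]])
  row_starts <- seq(1L, max(1L, n - ws + 1L), by = step_s)
  col_starts <- seq(1L, max(1L, m - wl + 1L), by = step_l)
  row_starts <- row_starts[row_starts + ws - 1L <= n]
  col_starts <- col_starts[col_starts + wl - 1L <= m]

  origins <- lapply(mask, function(msk) {
    assert(nrow(msk) == n && ncol(msk) == m, "mask shapes must match")
    if (length(row_starts) == 0 || length(col_starts) == 0) {
      return(matrix(integer(0), 0, 4,
                    dimnames = list(NULL, c("row", "col", "ir", "ic"))))
    }
    grid <- expand.grid(i = seq_along(row_starts), j = seq_along(col_starts))
    r <- row_starts[grid$i]; cc <- col_starts[grid$j]
    keep <- if (inclusion == "center") {
      msk[cbind(r + (ws - 1L) %/% 2L, cc + (wl - 1L) %/% 2L)]
    } else {
      vapply(seq_along(r), function(k)
        all(msk[r[k]:(r[k] + ws - 1L), cc[k]:(cc[k] + wl - 1L)]), TRUE)
    }
    cbind(row = r[keep], col = cc[keep], ir = grid$i[keep], ic = grid$j[keep])
  })
  empty <- all(vapply(origins, nrow, 1L) == 0)
  structure(list(window_samples = ws, window_lines = wl,
                 step_samples = step_s, step_lines = step_l,
                 side_m = side,
                 lattice_dim = c(length(row_starts), length(col_starts)),
                 pixel_mm = c(step_s * axial_pitch, step_l * line_spacing) * 1e3,
                 origins = origins, empty = empty,
                 inclusion = inclusion),
            class = "subroi_grid")
}

#' @export
print.subroi_grid <- function(x, ...) {
  cat(sprintf("<subroi_grid> window %d samples x %d lines (%.2f mm side), step (%d, %d), lattice %d x %d, %d origin(s)\n",
              x$window_samples, x$window_lines, x$side_m * 1e3,
              x$step_samples, x$step_lines, x$lattice_dim[1], x$lattice_dim[2],
              sum(vapply(x$origins, nrow, 1L))))
  invisible(x)
}

parametric_map <- function(name, values, pixel_mm,
                           units = QUS_UNITS[[name]]) {
  structure(list(name = name, values = values, pixel_mm = pixel_mm,
                 units = units),
            class = "parametric_map")
}

#' @export
print.parametric_map <- function(x, ...) {
  v <- x$values
  cat(sprintf("<parametric_map> %s [%s], %d x %d, %d valid, mean %.3g\n",
              x$name, x$units, nrow(v), ncol(v), sum(is.finite(v)),
              mean(v[is.finite(v)])))
  invisible(x)
}

#' Build the five QUS parametric maps for every frame
#'
#' Runs the spectral pipeline (window periodogram, reference-phantom
#' normalization, band-limited line fit, Gaussian form-factor estimation)
#' once per planned sub-ROI and places each parameter at the window's
#' lattice position. Invalid fits become missing values.
#'
#' @param rf an [rf_volume()]
#' @param grid a `subroi_grid` from [plan_subrois()]
#' @param reference a `reference_phantom`
#' @param band analysis band in Hz
#' @param center_frequency Hz
#' @param taper periodogram taper
#' @return list (one element per frame) of named lists of `parametric_map`
#'   objects (MBF, SS, SI, ASD, AAC)
#' @export
build_parametric_maps <- function(rf, grid, reference,
                                  band = c(4e6, 9e6),
                                  center_frequency = 7e6,
                                  taper = "hann") {
  assert(inherits(rf, "rf_volume"), "rf must be an rf_volume")
  assert(inherits(grid, "subroi_grid"), "grid must come from plan_subrois()")
  assert(!grid$empty, "sub-ROI grid is empty (ROI smaller than one window)")
  assert(length(grid$origins) == length(rf$frames),
         "grid and rf must have the same number of frames")
  assert(isTRUE(all.equal(rf$sampling_frequency,
                          reference$rf$sampling_frequency)),
         "reference sampling frequency incompatible with sample")

  ref_spec <- reference_spectrum(reference, grid$window_samples, taper)
  kbsc <- reference$known_bsc
  fs <- rf$sampling_frequency
  ws <- grid$window_samples; wl <- grid$window_lines

  lapply(seq_along(rf$frames), function(fi) {
    fr <- rf$frames[[fi]]
    org <- grid$origins[[fi]]
    maps <- lapply(QUS_PARAMS, function(p)
      matrix(NA_real_, grid$lattice_dim[1], grid$lattice_dim[2]))
    names(maps) <- QUS_PARAMS
    for (k in seq_len(nrow(org))) {
      win <- fr[org[k, "row"]:(org[k, "row"] + ws - 1L),
                org[k, "col"]:(org[k, "col"] + wl - 1L), drop = FALSE]
      ps <- window_power_spectrum(win, fs, taper)
      norm <- normalize_to_reference(ps, ref_spec, kbsc)
      fit <- fit_spectral_band(norm, band, center_frequency)
      est <- estimate_scatterer_properties(norm, band, rf$speed_of_sound)
      ir <- org[k, "ir"]; ic <- org[k, "ic"]
      if (fit$valid) {
        maps$MBF[ir, ic] <- fit$MBF
        maps$SS[ir, ic] <- fit$SS
        maps$SI[ir, ic] <- fit$SI
      }
      if (est$valid) {
        maps$ASD[ir, ic] <- est$ASD
        maps$AAC[ir, ic] <- est$AAC
      }
    }
    lapply(stats::setNames(QUS_PARAMS, QUS_PARAMS), function(p)
      parametric_map(p, maps[[p]], grid$pixel_mm))
  })
}

#' Pooled mean of one parameter over all frames
#'
#' Unweighted mean over every valid sub-ROI value pooled across frames (no
#' per-frame reweighting): the per-tumour "volume mean" of a parameter.
#'
#' @param frame_maps output of [build_parametric_maps()] (or any list of
#'   per-frame named map lists)
#' @param name parameter name
#' @return scalar mean; NA (with a warning) if no valid pixels
#' @export
volume_mean <- function(frame_maps, name) {
  vals <- unlist(lapply(frame_maps, function(m) {
    v <- m[[name]]$values
    v[is.finite(v)]
  }))
  if (length(vals) == 0) {
    warning(sprintf("no valid sub-ROI values for %s", name))
    return(NA_real_)
  }
  mean(vals)
}

#' Export per-frame parametric maps as CSV matrices with a JSON sidecar
#'
#' @param frame_maps output of [build_parametric_maps()]
#' @param dir output directory (created if needed)
#' @return dir, invisibly
#' @export
write_parametric_maps <- function(frame_maps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list()
  for (fi in seq_along(frame_maps)) {
    for (p in names(frame_maps[[fi]])) {
      m <- frame_maps[[fi]][[p]]
      fn <- sprintf("frame%02d_%s.csv", fi, p)
      utils::write.table(m$values, file.path(dir, fn), sep = ",",
                         row.names = FALSE, col.names = FALSE)
      meta[[fn]] <- list(frame = fi, name = p, units = m$units,
                         pixel_mm = m$pixel_mm)
    }
  }
  jsonlite::write_json(meta, file.path(dir, "maps.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
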