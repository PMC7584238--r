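# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

assert <- function(cond, ...) {
  if (!isTRUE(cond)) stop_input(...)
}

#' Round a positive length to the nearest odd integer (>= 1)
#'
#' Window sizes are kept odd so every analysis window has a well-defined
#' centre pixel.
#' @param x positive numeric
#' @return odd integer
#' @keywords internal
round_odd <- function(x) {
  k <- max(1, round(x))
  if (k %% 2 == 0) {
    # pick the nearer odd neighbour
    k <- if (x >= k) k + 1 else k - 1
    k <- max(1L, k)
  }
  as.integer(k)
}

#' Convert linear power to decibels
#' @param p linear power (>= 0)
#' @return 10*log10(p); -Inf for zero power
#' @keywords internal
to_db <- function(p) 10 * log10(p)

# Hann taper of length n (periodic-symmetric form used for periodograms)
hann_taper <- function(n) {
  assert(n >= 2, "taper length must be >= 2")
  0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
}

# deterministic derived seed streams, kept below 2^31
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k) * 9176L + 17L
}

# short stable hash of an R object (for provenance stamps), via tools::md5sum
config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), tf)
  unname(tools::md5sum(tf))
}

# linear interpolation of a tabulated positive function on log scale
interp_bsc <- function(table, frequencies) {
  assert(is.data.frame(table) && all(c("frequency", "bsc") %in% names(table)),
         "known_bsc must be a data.frame with columns 'frequency' and 'bsc'")
  assert(all(table$bsc > 0), "known_bsc must be strictly positive")
  exp(stats::approx(table$frequency, log(table$bsc), xout = frequencies,
                    rule = 2)$y)
}
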