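# Grey-level co-occurrence matrix (GLCM) texture analysis of QUS parametric
# maps, and the second-pass "texture derivative" (texture-of-texture)
# features. The second pass is literally the first-pass operator re-applied
# to first-pass texture maps: same quantization, same GLCM, same four
# Haralick features (contrast, energy, correlation, homogeneity).

TEX_FEATURES <- c("CON", "ENE", "COR", "HOM")

#' GLCM configuration
#'
#' @param levels number of grey levels after quantization (default 16)
#' @param distances pixel offsets (default 1)
#' @param angles offset directions in degrees, any of 0, 45, 90, 135
#' @param symmetric count each pair in both directions (default TRUE)
#' @param hom homogeneity definition: "inverse_difference"
#'   (sum p / (1 + |i-j|), default) or "idm" (inverse difference moment,
#'   sum p / (1 + (i-j)^2))
#' @param neighborhood sliding-window side (in map pixels) for texture maps
#'   (default 15, mirroring the 15-pixel sub-ROI construction)
#' @param step sliding-window step for texture maps
#' @param min_valid_fraction minimum fraction of realizable pixel pairs that
#'   must be valid (non-missing) for a sliding-window position to produce a
#'   value
#' @return object of class `glcm_config`
#' @export
glcm_config <- function(levels = 16, distances = 1,
                        angles = c(0, 45, 90, 135), symmetric = TRUE,
                        hom = c("inverse_difference", "idm"),
                        neighborhood = 15, step = 1,
                        min_valid_fraction = 0.5) {
  hom <- match.arg(hom)
  assert(levels >= 2, "levels must be >= 2")
  assert(all(distances >= 1), "distances must be >= 1")
  assert(all(angles %in% c(0, 45, 90, 135)),
         "angles must be among 0, 45, 90, 135 degrees")
  assert(neighborhood >= 3, "neighborhood must be >= 3 map pixels")
  assert(step >= 1, "step must be >= 1")
  structure(list(levels = as.integer(levels), distances = as.integer(distances),
                 angles = angles, symmetric = symmetric, hom = hom,
                 neighborhood = as.integer(neighborhood),
                 step = as.integer(step),
                 min_valid_fraction = min_valid_fraction),
            class = "glcm_config")
}

# (row, col) lattice offsets for each (distance, angle); 0 deg is the
# positive-column (lateral) direction, 90 deg the negative-row direction.
glcm_offsets <- function(config) {
  out <- list()
  for (d in config$distances) {
    for (a in config$angles) {
      off <- switch(as.character(a),
                    "0" = c(0L, d), "45" = c(-d, d),
                    "90" = c(-d, 0L), "135" = c(-d, -d))
      out[[length(out) + 1L]] <- off
    }
  }
  out
}

#' Quantize a map to integer grey levels
#'
#' Equal-width bins over the `[min, max]` range of valid (finite) pixels —
#' the per-map min-max policy, which makes every GLCM feature invariant to
#' strictly increasing affine transforms of the map values. Missing pixels
#' stay missing and are skipped by co-occurrence counting.
#'
#' @param values numeric matrix (NA/NaN/Inf treated as missing)
#' @param levels number of grey levels
#' @param range optional fixed c(min, max) quantization range
#' @return list with `grid` (integer matrix of levels 0..levels-1, NA for
#'   missing) and `degenerate` (TRUE when fewer than 2 distinct valid
#'   values)
#' @export
quantize_map <- function(values, levels = 16, range = NULL) {
  assert(is.matrix(values), "values must be a matrix")
  v <- values
  v[!is.finite(v)] <- NA_real_
  ok <- is.finite(v)
  assert(any(ok), "all-missing map cannot be quantized")
  if (is.null(range)) range <- c(min(v[ok]), max(v[ok]))
  degenerate <- length(unique(v[ok])) < 2 || diff(range) == 0
  grid <- matrix(NA_integer_, nrow(v), ncol(v))
  if (degenerate) {
    grid[ok] <- 0L
  } else {
    grid[ok] <- pmin(levels - 1L,
                     as.integer(floor((v[ok] - range[1]) / diff(range) * levels)))
    grid[ok] <- pmax(0L, grid[ok])
  }
  list(grid = grid, degenerate = degenerate, levels = as.integer(levels))
}

#' Compute a normalized GLCM over a whole quantized grid
#'
#' Co-occurrence counts are accumulated over every configured
#' (distance, angle) offset; pairs touching a missing pixel are skipped;
#' the matrix is symmetrized (when configured) and normalized to sum 1.
#'
#' @param grid integer matrix of grey levels 0..levels-1 (NA = missing), as
#'   produced by [quantize_map()]
#' @param config a [glcm_config()]
#' @param levels number of grey levels (defaults to `config$levels`)
#' @return object of class `glcm`: `matrix` (levels x levels, sums to 1),
#'   `n_pairs`, `config`
#' @export
compute_glcm <- function(grid, config = glcm_config(), levels = config$levels) {
  assert(is.matrix(grid), "grid must be a matrix")
  L <- as.integer(levels)
  counts <- matrix(0, L, L)
  nr <- nrow(grid); nc <- ncol(grid)
  for (off in glcm_offsets(config)) {
    dr <- off[1]; dc <- off[2]
    if (max(1L, 1L - dr) > min(nr, nr - dr) ||
        max(1L, 1L - dc) > min(nc, nc - dc)) next
    r1 <- max(1L, 1L - dr):min(nr, nr - dr)
    c1 <- max(1L, 1L - dc):min(nc, nc - dc)
    a <- grid[r1, c1, drop = FALSE]
    b <- grid[r1 + dr, c1 + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    tab <- tabulate(a[ok] * L + b[ok] + 1L, nbins = L * L)
    counts <- counts + matrix(tab, L, L, byrow = TRUE)
  }
  if (config$symmetric) counts <- counts + t(counts)
  n_pairs <- sum(counts)
  if (n_pairs == 0) stop_input("degenerate ROI: no valid co-occurrence pairs")
  structure(list(matrix = counts / n_pairs, n_pairs = n_pairs,
                 config = config),
            class = "glcm")
}

#' Haralick features of a GLCM
#'
#' Contrast `sum p (i-j)^2`, energy `sum p^2`, correlation
#' `sum (i - mu_i)(j - mu_j) p / (sigma_i sigma_j)` and homogeneity
#' `sum p / (1 + |i-j|)` (or the inverse-difference-moment variant). A
#' zero-variance GLCM (single occupied level) has correlation defined as 1
#' by convention — the limit of a perfectly correlated constant field — and
#' carries a `degenerate_correlation` attribute.
#'
#' @param g a `glcm` (or a plain normalized levels x levels matrix)
#' @param hom homogeneity variant when `g` is a plain matrix
#' @return named numeric c(CON, ENE, COR, HOM)
#' @export
glcm_features <- function(g, hom = "inverse_difference") {
  if (inherits(g, "glcm")) {
    p <- g$matrix
    hom <- g$config$hom
  } else {
    p <- g
  }
  L <- nrow(p)
  i <- matrix(seq_len(L) - 1, L, L)
  j <- t(i)
  con <- sum(p * (i - j)^2)
  ene <- sum(p^2)
  homv <- if (hom == "inverse_difference") sum(p / (1 + abs(i - j))) else
    sum(p / (1 + (i - j)^2))
  mu_i <- sum(p * i); mu_j <- sum(p * j)
  var_i <- sum(p * i^2) - mu_i^2
  var_j <- sum(p * j^2) - mu_j^2
  degen <- var_i <= 0 || var_j <= 0
  cor <- if (degen) 1 else
    (sum(p * i * j) - mu_i * mu_j) / sqrt(var_i * var_j)
  out <- c(CON = con, ENE = ene, COR = min(1, max(-1, cor)), HOM = homv)
  attr(out, "degenerate_correlation") <- degen
  out
}

map_values <- function(map) {
  if (inherits(map, c("parametric_map", "texture_map"))) map$values
  else if (is.matrix(map)) map
  else stop_input("expected a parametric_map, texture_map or matrix")
}

map_name <- function(map) {
  if (inherits(map, "parametric_map")) map$name
  else if (inherits(map, "texture_map")) paste(map$parent, map$feature, sep = "-")
  else "map"
}

#' Whole-ROI GLCM texture features of a map
#'
#' Quantize, build one GLCM over the entire valid extent of the map, and
#' return the four Haralick features. Works identically on parametric maps
#' (first pass) and texture maps (second pass).
#'
#' @param map a `parametric_map`, `texture_map` or numeric matrix
#' @param config a [glcm_config()]
#' @return named numeric c(CON, ENE, COR, HOM); all NA for a map with no
#'   valid pixels or no valid pairs
#' @export
texture_scalar <- function(map, config = glcm_config()) {
  v <- map_values(map)
  if (!any(is.finite(v))) {
    return(stats::setNames(rep(NA_real_, 4), TEX_FEATURES))
  }
  q <- quantize_map(v, config$levels)
  g <- tryCatch(compute_glcm(q$grid, config),
                error = function(e) NULL)
  if (is.null(g)) return(stats::setNames(rep(NA_real_, 4), TEX_FEATURES))
  glcm_features(g)
}

texture_map_obj <- function(parent, feature, values, pixel_mm = c(NA, NA)) {
  structure(list(parent = parent, feature = feature, values = values,
                 pixel_mm = pixel_mm),
            class = "texture_map")
}

#' @export
print.texture_map <- function(x, ...) {
  v <- x$values
  cat(sprintf("<texture_map> %s-%s, %d x %d, %d valid\n", x$parent,
              x$feature, nrow(v), ncol(v), sum(is.finite(v))))
  invisible(x)
}

# summed-area table with a zero first row/column, so that
# sat[i+1, j+1] - sat[i0, j+1] - sat[i+1, j0] + sat[i0, j0]
# is the sum over rows i0..i, cols j0..j
sat2d <- function(m) {
  s <- apply(m, 2, cumsum)
  s <- t(apply(s, 1, cumsum))
  rbind(0, cbind(0, s))
}

#' Sliding-neighbourhood GLCM texture maps
#'
#' Slides a square neighbourhood over the map lattice; at each position the
#' four Haralick features of the local GLCM form the four output texture
#' maps. Pairs touching missing pixels are skipped; positions where fewer
#' than `min_valid_fraction` of realizable pairs are valid become missing.
#'
#' Implemented with per-grey-level-pair summed-area tables so the local
#' co-occurrence counts for every window position are computed in one
#' vectorized pass per (offset, level-pair) channel.
#'
#' @param map a `parametric_map`, `texture_map` or numeric matrix
#' @param config a [glcm_config()]; `neighborhood` and `step` are taken from
#'   it unless overridden
#' @param neighborhood square window side in map pixels
#' @param step window step in map pixels
#' @return named list of four `texture_map` objects (CON, ENE, COR, HOM)
#'   with dimensions `(dim - neighborhood) / step + 1`
#' @export
texture_map_sliding <- function(map, config = glcm_config(),
                                neighborhood = config$neighborhood,
                                step = config$step) {
  v <- map_values(map)
  parent <- map_name(map)
  nh <- as.integer(neighborhood); s <- as.integer(step)
  assert(nh >= 3, "neighborhood must be >= 3 map pixels")
  assert(max(config$distances) < nh,
         "GLCM distance must be smaller than the neighborhood")
  nr <- nrow(v); nc <- ncol(v)
  if (nh > nr || nh > nc) {
    warning("neighborhood larger than map: empty texture maps")
    empty <- matrix(NA_real_, 0, 0)
    return(lapply(stats::setNames(TEX_FEATURES, TEX_FEATURES), function(f)
      texture_map_obj(parent, f, empty)))
  }
  L <- config$levels
  q <- quantize_map(v, L)$grid

  rows <- seq(1L, nr - nh + 1L, by = s)
  cols <- seq(1L, nc - nh + 1L, by = s)
  npos <- length(rows) * length(cols)
  counts <- matrix(0, npos, L * L)  # column = code L*i + j + 1
  max_pairs <- 0
  for (off in glcm_offsets(config)) {
    dr <- off[1]; dc <- off[2]
    max_pairs <- max_pairs + (nh - abs(dr)) * (nh - abs(dc))
    # code matrix anchored at the first pixel of each pair
    K <- matrix(NA_integer_, nr, nc)
    r1 <- max(1L, 1L - dr):min(nr, nr - dr)
    c1 <- max(1L, 1L - dc):min(nc, nc - dc)
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + dr, c1 + dc, drop = FALSE]
    K[r1, c1] <- ifelse(is.na(a) | is.na(b), NA_integer_, a * L + b + 1L)
    # anchor sub-rectangle of each window for this offset
    a0 <- rows + max(0L, -dr); a1 <- rows + nh - 1L - max(0L, dr)
    b0 <- cols + max(0L, -dc); b1 <- cols + nh - 1L - max(0L, dc)
    present <- sort(unique(K[!is.na(K)]))
    for (code in present) {
      sat <- sat2d((!is.na(K)) & (K == code))
      wsum <- sat[a1 + 1L, b1 + 1L, drop = FALSE] -
        sat[a0, b1 + 1L, drop = FALSE] -
        sat[a1 + 1L, b0, drop = FALSE] + sat[a0, b0, drop = FALSE]
      counts[, code] <- counts[, code] + as.vector(wsum)
    }
  }
  if (config$symmetric) {
    ij <- expand.grid(j = 0:(L - 1), i = 0:(L - 1))  # column order of codes
    swap <- ij$j * L + ij$i + 1L
    counts <- counts + counts[, swap, drop = FALSE]
    max_pairs <- 2 * max_pairs
  }

  tot <- rowSums(counts)
  valid <- tot >= config$min_valid_fraction * max_pairs & tot > 0
  p <- counts / ifelse(tot > 0, tot, 1)
  iL <- rep(0:(L - 1), each = L)   # code = L*i + j + 1 (i varies slowly)
  jL <- rep(0:(L - 1), times = L)
  con <- as.vector(p %*% (iL - jL)^2)
  ene <- rowSums(p^2)
  homw <- if (config$hom == "inverse_difference") 1 / (1 + abs(iL - jL)) else
    1 / (1 + (iL - jL)^2)
  homv <- as.vector(p %*% homw)
  mu_i <- as.vector(p %*% iL); mu_j <- as.vector(p %*% jL)
  var_i <- as.vector(p %*% iL^2) - mu_i^2
  var_j <- as.vector(p %*% jL^2) - mu_j^2
  eij <- as.vector(p %*% (iL * jL))
  corv <- ifelse(var_i <= 1e-12 | var_j <= 1e-12, 1,
                 (eij - mu_i * mu_j) / sqrt(pmax(var_i * var_j, 1e-300)))
  corv <- pmin(1, pmax(-1, corv))

  shape <- function(x) {
    x[!valid] <- NA_real_
    matrix(x, length(rows), length(cols))
  }
  vals <- list(CON = shape(con), ENE = shape(ene), COR = shape(corv),
               HOM = shape(homv))
  pix <- if (inherits(map, c("parametric_map", "texture_map")))
    map$pixel_mm * s else c(NA, NA)
  lapply(stats::setNames(TEX_FEATURES, TEX_FEATURES), function(f)
    texture_map_obj(parent, f, vals[[f]], pix))
}

#' Second-pass texture-derivative features
#'
#' Applies the whole-ROI texture operator ([texture_scalar()]) to each
#' first-pass texture map, producing the 4 x 20 = 80 texture-of-texture
#' scalars (e.g. `MBF-COR-ENE`). Name-keyed: permuting the input order
#' permutes nothing in the named output.
#'
#' @param texture_maps named list of 20 `texture_map` objects (names like
#'   "MBF-CON")
#' @param config a [glcm_config()]
#' @return named numeric vector of 80 values
#' @export
texture_derivatives <- function(texture_maps, config = glcm_config()) {
  assert(length(texture_maps) >= 1 && !is.null(names(texture_maps)),
         "texture_maps must be a named list")
  out <- numeric(0)
  for (nm in names(texture_maps)) {
    ts <- texture_scalar(texture_maps[[nm]], config)
    if (all(is.na(ts))) {
      message(sprintf("degenerate texture map %s: derivatives missing", nm))
    }
    names(ts) <- paste(nm, TEX_FEATURES, sep = "-")
    out <- c(out, ts)
  }
  out
}

#' Canonical feature names
#'
#' @param set "qus" (5), "tex1" (20), "tex2" (80) or "all" (105)
#' @return character vector in canonical order (bases MBF, SS, SI, ASD, AAC;
#'   texture features CON, ENE, COR, HOM)
#' @export
qus_feature_names <- function(set = c("all", "qus", "tex1", "tex2")) {
  set <- match.arg(set)
  qus <- QUS_PARAMS
  tex1 <- as.vector(t(outer(qus, TEX_FEATURES, paste, sep = "-")))
  tex2 <- as.vector(t(outer(tex1, TEX_FEATURES, paste, sep = "-")))
  switch(set, qus = qus, tex1 = tex1, tex2 = tex2,
         all = c(qus, tex1, tex2))
}

#' Parse and validate a feature name
#'
#' Grammar: `BASE`, `BASE-TEX1` or `BASE-TEX1-TEX2` with BASE one of MBF,
#' SS, SI, ASD, AAC and TEX one of CON, ENE, COR, HOM.
#'
#' @param name feature name string
#' @return list(base, tex1, tex2) with NULLs for absent parts
#' @export
parse_feature_name <- function(name) {
  parts <- strsplit(name, "-", fixed = TRUE)[[1]]
  assert(length(parts) >= 1 && length(parts) <= 3 &&
           parts[1] %in% QUS_PARAMS &&
           all(parts[-1] %in% TEX_FEATURES),
         sprintf("invalid feature name '%s'", name))
  list(base = parts[1],
       tex1 = if (length(parts) >= 2) parts[2] else NULL,
       tex2 = if (length(parts) >= 3) parts[3] else NULL)
}

#' Assemble the canonical 105-entry feature vector
#'
#' @param qus_means named numeric, the 5 QUS volume means
#' @param tex1 named numeric, the 20 first-pass texture scalars
#' @param tex2 named numeric, the 80 texture-derivative scalars
#' @return object of class `qus_features`: named numeric length 105 in
#'   canonical order (missing values allowed, flagged via attribute)
#' @export
assemble_feature_vector <- function(qus_means, tex1, tex2) {
  all_names <- c(names(qus_means), names(tex1), names(tex2))
  assert(!anyDuplicated(all_names), "duplicate feature names")
  for (nm in all_names) parse_feature_name(nm)
  assert(length(qus_means) == 5, "expected 5 QUS means")
  assert(length(tex1) == 20, "expected 20 first-pass texture features")
  assert(length(tex2) == 80, "expected 80 texture-derivative features")
  v <- c(qus_means, tex1, tex2)[qus_feature_names("all")]
  names(v) <- qus_feature_names("all")
  structure(v, class = c("qus_features", "numeric"),
            n_missing = sum(!is.finite(v)))
}

#' @export
print.qus_features <- function(x, ...) {
  cat(sprintf("<qus_features> 105 features (5 QUS + 20 Tex1 + 80 Tex1-Tex2), %d missing\n",
              attr(x, "n_missing")))
  utils::str(unclass(x))
  invisible(x)
}
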