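# Configuration, I/O and orchestration: simulate -> extract -> classify ->
# report as one reproducible pipeline.

#' Pipeline configuration
#'
#' Nested configuration reproducing the protocol constants: 40 MHz sampling,
#' 7 MHz centre frequency with a 4--9 MHz analysis band, 10-wavelength
#' sub-ROIs at 94% overlap, 16-level symmetric GLCM at distance 1 over four
#' angles with a 15-pixel second-pass neighbourhood, seven balanced subsets,
#' at most 3 selected features, LOOCV.
#'
#' @param acquisition,subroi,glcm,classify optional lists overriding
#'   individual defaults
#' @param seed integer seed recorded in outputs
#' @return object of class `qus_config`
#' @export
qus_config <- function(acquisition = list(), subroi = list(), glcm = list(),
                       classify = list(), seed = 1) {
  cfg <- list(
    acquisition = utils::modifyList(list(
      sampling_frequency = 40e6, center_frequency = 7e6,
      band = c(4e6, 9e6), fractional_bandwidth = 5 / 7,
      speed_of_sound = 1540, line_spacing = 2e-4, frame_spacing = 0.01),
      acquisition),
    subroi = utils::modifyList(list(
      window_wavelengths = 10, overlap = 0.94, inclusion = "center"),
      subroi),
    glcm = utils::modifyList(list(
      levels = 16, distances = 1, angles = c(0, 45, 90, 135),
      symmetric = TRUE, hom = "inverse_difference", neighborhood = 15,
      step = 1, min_valid_fraction = 0.5),
      glcm),
    classify = utils::modifyList(list(
      classifiers = c("fld", "knn", "svm"), k = 5, C = 1, gamma = NULL,
      n_subsets = 7, max_features = 3, selection = "nested",
      positive = "NR"),
      classify),
    seed = as.integer(seed))
  acq <- cfg$acquisition
  assert(acq$sampling_frequency > 4 * acq$center_frequency,
         "sampling frequency must exceed 4 x centre frequency")
  assert(acq$band[1] < acq$band[2], "analysis band must be increasing")
  assert(cfg$subroi$overlap >= 0 && cfg$subroi$overlap < 1,
         "overlap must lie in [0, 1)")
  assert(cfg$classify$max_features >= 1, "max_features must be >= 1")
  structure(cfg, class = "qus_config")
}

config_pulse <- function(config) {
  a <- config$acquisition
  pulse_model(a$center_frequency, a$fractional_bandwidth,
              a$sampling_frequency, a$speed_of_sound)
}

config_glcm <- function(config) {
  g <- config$glcm
  glcm_config(g$levels, g$distances, g$angles, g$symmetric, g$hom,
              g$neighborhood, g$step, g$min_valid_fraction)
}

#' Read a pipeline configuration from JSON
#' @param path JSON file
#' @return a [qus_config()]
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  qus_config(acquisition = raw$acquisition %||% list(),
             subroi = raw$subroi %||% list(),
             glcm = raw$glcm %||% list(),
             classify = raw$classify %||% list(),
             seed = raw$seed %||% 1)
}

#' Write a pipeline configuration to JSON
#' @param config a [qus_config()]
#' @param path output path
#' @return path, invisibly
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

# ---- RF container ----------------------------------------------------------
# Directory-based hierarchical container (text-only stand-in for an HDF5
# file): frame_NN.tsv matrices, mask_NN.tsv 0/1 matrices, meta.json with
# the acquisition attributes.

#' Write an RF volume (and optional masks) to a directory container
#'
#' @param rf an [rf_volume()]
#' @param dir target directory (created)
#' @param mask optional list of logical matrices, one per frame
#' @param extra named list merged into the JSON attributes
#' @return dir, invisibly
#' @export
write_rf_container <- function(rf, dir, mask = NULL, extra = list()) {
  assert(inherits(rf, "rf_volume"), "rf must be an rf_volume")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(rf$frames)) {
    utils::write.table(rf$frames[[i]],
                       file.path(dir, sprintf("frame_%02d.tsv", i)),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    if (!is.null(mask)) {
      utils::write.table(mask[[i]] * 1L,
                         file.path(dir, sprintf("mask_%02d.tsv", i)),
                         sep = "\t", row.names = FALSE, col.names = FALSE)
    }
  }
  meta <- c(list(n_frames = length(rf$frames),
                 sampling_frequency = rf$sampling_frequency,
                 line_spacing = rf$line_spacing,
                 speed_of_sound = rf$speed_of_sound,
                 frame_spacing = rf$frame_spacing,
                 has_mask = !is.null(mask)),
            extra)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read an RF volume container written by [write_rf_container()]
#'
#' @param dir container directory
#' @return list with `rf` ([rf_volume()]), `mask` (list of logical matrices
#'   or NULL), `meta` (attribute list)
#' @export
read_rf_container <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  assert(file.exists(meta_path),
         sprintf("not an RF container (missing meta.json): %s", dir))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  frames <- lapply(seq_len(meta$n_frames), function(i) {
    f <- file.path(dir, sprintf("frame_%02d.tsv", i))
    assert(file.exists(f), sprintf("corrupted container: missing %s", f))
    as.matrix(utils::read.table(f, sep = "\t"))
  })
  frames <- lapply(frames, unname)
  mask <- NULL
  if (isTRUE(meta$has_mask)) {
    mask <- lapply(seq_len(meta$n_frames), function(i) {
      m <- file.path(dir, sprintf("mask_%02d.tsv", i))
      assert(file.exists(m), sprintf("corrupted container: missing %s", m))
      unname(as.matrix(utils::read.table(m, sep = "\t"))) > 0
    })
  }
  list(rf = rf_volume(frames, meta$sampling_frequency, meta$line_spacing,
                      meta$speed_of_sound, meta$frame_spacing),
       mask = mask, meta = meta)
}

# ---- feature tables --------------------------------------------------------

#' Write a cohort feature table to CSV
#' @param cohort a [cohort_table()]
#' @param path CSV path
#' @return path, invisibly
#' @export
write_feature_table <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Read a cohort feature table CSV
#' @param path CSV with patient_id, label and feature columns
#' @return a [cohort_table()]
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  assert(all(c("patient_id", "label") %in% names(df)),
         "feature table must have patient_id and label columns")
  meta <- intersect(c("rfs_months", "event"), names(df))
  fcols <- setdiff(names(df), c("patient_id", "label", meta))
  cohort_table(df$patient_id, df$label, df[, fcols, drop = FALSE],
               rfs_months = if ("rfs_months" %in% meta) df$rfs_months,
               event = if ("event" %in% meta) df$event)
}

# ---- extraction ------------------------------------------------------------

#' End-to-end feature extraction for one tumour
#'
#' Plans sub-ROIs over the mask, builds the five parametric maps per frame,
#' computes the 5 QUS volume means, the 20 first-pass texture scalars and
#' first-pass texture maps, and the 80 second-pass texture derivatives
#' (per-frame values averaged across frames with equal weight), assembling
#' the canonical 105-entry feature vector.
#'
#' @param rf an [rf_volume()]
#' @param mask list of logical matrices, one per frame
#' @param reference a `reference_phantom`
#' @param config a [qus_config()]
#' @param keep_maps return the parametric and texture maps alongside the
#'   features
#' @return list with `features` (`qus_features`), `provenance` (config
#'   hash, seed), and optionally `maps`, `texture_maps`
#' @export
run_extract <- function(rf, mask, reference, config = qus_config(),
                        keep_maps = FALSE) {
  assert(inherits(rf, "rf_volume"), "rf must be an rf_volume")
  if (is.matrix(mask)) mask <- list(mask)
  assert(length(mask) == length(rf$frames),
         "need one mask per frame")
  d <- dim(rf$frames[[1]])
  assert(all(vapply(mask, function(m) all(dim(m) == d), TRUE)),
         "mask shape must equal frame shape")
  pulse <- config_pulse(config)
  gcfg <- config_glcm(config)
  acq <- config$acquisition

  grid <- plan_subrois(mask, pulse, rf$line_spacing,
                       overlap = config$subroi$overlap,
                       window_wavelengths = config$subroi$window_wavelengths,
                       inclusion = config$subroi$inclusion)
  frame_maps <- build_parametric_maps(rf, grid, reference, band = acq$band,
                                      center_frequency = acq$center_frequency)

  qus_means <- vapply(QUS_PARAMS, function(p) volume_mean(frame_maps, p), 0)

  # first pass: per-frame whole-ROI texture scalars and sliding texture maps
  tex1_sum <- NULL
  tex1_n <- NULL
  tex2_sum <- NULL
  tex2_n <- NULL
  all_tex_maps <- list()
  for (fi in seq_along(frame_maps)) {
    t1 <- unlist(lapply(QUS_PARAMS, function(p) {
      ts <- texture_scalar(frame_maps[[fi]][[p]], gcfg)
      names(ts) <- paste(p, TEX_FEATURES, sep = "-")
      ts
    }))
    tmaps <- list()
    for (p in QUS_PARAMS) {
      tm <- texture_map_sliding(frame_maps[[fi]][[p]], gcfg)
      for (f in TEX_FEATURES) tmaps[[paste(p, f, sep = "-")]] <- tm[[f]]
    }
    t2 <- texture_derivatives(tmaps, gcfg)
    if (is.null(tex1_sum)) {
      tex1_sum <- ifelse(is.na(t1), 0, t1); tex1_n <- !is.na(t1)
      tex2_sum <- ifelse(is.na(t2), 0, t2); tex2_n <- !is.na(t2)
    } else {
      tex1_sum <- tex1_sum + ifelse(is.na(t1), 0, t1)
      tex1_n <- tex1_n + !is.na(t1)
      tex2_sum <- tex2_sum + ifelse(is.na(t2), 0, t2)
      tex2_n <- tex2_n + !is.na(t2)
    }
    if (keep_maps) all_tex_maps[[fi]] <- tmaps
  }
  tex1 <- tex1_sum / ifelse(tex1_n > 0, tex1_n, NA)
  tex2 <- tex2_sum / ifelse(tex2_n > 0, tex2_n, NA)

  features <- assemble_feature_vector(qus_means, tex1, tex2)
  out <- list(features = features,
              provenance = list(config_hash = config_hash(unclass(config)),
                                seed = config$seed,
                                package_version =
                                  as.character(utils::packageVersion("qustex"))))
  if (keep_maps) {
    out$maps <- frame_maps
    out$texture_maps <- all_tex_maps
    out$grid <- grid
  }
  out
}

#' Extract features for a whole cohort and evaluate the classifiers
#'
#' Runs [run_extract()] for every patient (failures are logged and skipped),
#' assembles the cohort feature table, then evaluates each configured
#' classifier on both feature sets — QUS + first-pass textures (25
#' features) and the full 105 — over balanced subsets with LOOCV.
#'
#' @param patients list of patients as produced by [generate_cohort()]
#'   (elements with `id`, `label`, `rf`, `mask`), or a directory of RF
#'   containers with `label` fields in their meta.json
#' @param reference a `reference_phantom`
#' @param config a [qus_config()]
#' @param classify run the classification stage (requires both labels)
#' @return list with `table` ([cohort_table()]), `panels` (nested list
#'   panels[[classifier]][[feature_set]] of `subset_summary`), `failures`
#' @export
run_cohort <- function(patients, reference, config = qus_config(),
                       classify = TRUE) {
  if (is.character(patients)) patients <- load_cohort_dir(patients)
  assert(length(patients) >= 4, "need >= 4 patients")
  rows <- list(); ids <- character(0); labels <- character(0)
  failures <- list()
  for (p in patients) {
    res <- tryCatch(run_extract(p$rf, p$mask, reference, config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("extraction failed for patient %s: %s", p$id,
                      conditionMessage(res)))
      failures[[p$id]] <- conditionMessage(res)
      next
    }
    rows[[length(rows) + 1L]] <- as.numeric(res$features)
    ids <- c(ids, p$id); labels <- c(labels, p$label)
  }
  assert(length(rows) >= 4, "fewer than 4 patients extracted successfully")
  X <- do.call(rbind, rows)
  colnames(X) <- qus_feature_names("all")
  tab <- cohort_table(ids, labels, X)

  panels <- NULL
  if (classify) {
    assert(length(unique(labels)) == 2,
           "classification refused: cohort has a single class")
    cl <- config$classify
    feature_sets <- list(tex1 = c(qus_feature_names("qus"),
                                  qus_feature_names("tex1")),
                         tex2 = qus_feature_names("all"))
    panels <- lapply(stats::setNames(cl$classifiers, cl$classifiers),
                     function(type) {
      spec <- classifier_spec(type, k = cl$k, C = cl$C, gamma = cl$gamma,
                              positive = cl$positive)
      lapply(feature_sets, function(fs) {
        # drop features that failed to extract anywhere
        fs <- fs[colSums(!is.finite(X[, fs, drop = FALSE])) == 0]
        subs <- balanced_subsets(tab, cl$n_subsets, config$seed)
        res <- lapply(subs, function(s)
          loocv_evaluate(s, spec, cl$selection, cl$max_features, fs))
        aggregate_subsets(res)
      })
    })
  }
  list(table = tab, panels = panels, failures = failures,
       provenance = list(config_hash = config_hash(unclass(config)),
                         seed = config$seed))
}

load_cohort_dir <- function(dir) {
  subdirs <- list.dirs(dir, recursive = FALSE)
  assert(length(subdirs) >= 1, sprintf("no patient containers in %s", dir))
  lapply(subdirs, function(d) {
    cont <- read_rf_container(d)
    assert(!is.null(cont$meta$label),
           sprintf("container %s has no label", d))
    list(id = cont$meta$id %||% basename(d), label = cont$meta$label,
         rf = cont$rf, mask = cont$mask)
  })
}

#' Write classification panels as a JSON + CSV report
#'
#' @param panels the `panels` element of [run_cohort()]
#' @param dir output directory
#' @param provenance optional provenance list embedded in the JSON
#' @return dir, invisibly
#' @export
write_report <- function(panels, dir, provenance = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  js <- list()
  for (clf in names(panels)) {
    for (fs in names(panels[[clf]])) {
      s <- panels[[clf]][[fs]]
      p <- s$panel
      rows[[length(rows) + 1L]] <- data.frame(
        classifier = clf, feature_set = fs,
        sensitivity = p$sensitivity, specificity = p$specificity,
        PPV = p$PPV, NPV = p$NPV, accuracy = p$accuracy, AUC = p$AUC,
        selected = paste(utils::head(s$selected_features, 3),
                         collapse = ";"))
      js[[clf]][[fs]] <- list(
        panel = p[c("sensitivity", "specificity", "PPV", "NPV", "accuracy",
                    "AUC")],
        selected_features = s$selected_features,
        roc = if (!is.null(s$roc)) list(fpr = s$roc$fpr, tpr = s$roc$tpr))
    }
  }
  utils::write.csv(do.call(rbind, rows), file.path(dir, "panels.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(panels = js, provenance = provenance),
                       file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}
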