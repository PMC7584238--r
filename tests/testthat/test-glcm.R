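# GLCM construction against a brute-force oracle, Haralick feature
# formulas, sliding texture maps and the texture-derivative composition.

test_that("quantization bins valid pixels and flags degenerate maps", {
  const <- quantize_map(matrix(7, 4, 4), 16)
  expect_true(const$degenerate)
  expect_true(all(const$grid == 0))

  ident <- quantize_map(matrix(0:15, 4, 4), 16)
  expect_false(ident$degenerate)
  expect_equal(as.vector(ident$grid), 0:15)

  set.seed(2)
  m <- matrix(rnorm(100), 10)
  m[sample(100, 10)] <- NA
  q <- quantize_map(m, 8)
  expect_true(all(q$grid[!is.na(q$grid)] %in% 0:7))
  expect_equal(is.na(q$grid), is.na(m))

  expect_error(quantize_map(matrix(NA_real_, 3, 3)), "all-missing")
})

test_that("GLCM matches hand counts and normalizes to 1", {
  cb <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  cfg0 <- glcm_config(levels = 2, angles = 0)
  g <- compute_glcm(cb, cfg0)
  expect_equal(g$matrix, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  expect_equal(sum(g$matrix), 1)

  # zero valid pairs -> degenerate-ROI error
  lone <- matrix(NA_integer_, 3, 3); lone[2, 2] <- 1L
  expect_error(compute_glcm(lone, glcm_config(levels = 2)), "degenerate ROI")
})

test_that("GLCM equals the brute-force pair-counting oracle on random grids", {
  set.seed(33)
  for (i in 1:40) {
    L <- sample(2:8, 1)
    nr <- sample(4:12, 1); nc <- sample(4:12, 1)
    g <- matrix(sample(0:(L - 1), nr * nc, TRUE), nr, nc)
    if (i %% 2 == 0) g[sample(nr * nc, ceiling(nr * nc / 6))] <- NA
    cfg <- glcm_config(levels = L,
                       distances = sample(1:2, 1),
                       angles = sample(c(0, 45, 90, 135),
                                       sample(1:4, 1)),
                       symmetric = sample(c(TRUE, FALSE), 1))
    got <- compute_glcm(g, cfg)$matrix
    expect_equal(got, glcm_oracle(g, L, cfg), tolerance = 1e-12)
  }
})

test_that("Haralick formulas give the hand-derived values and bounds", {
  # constant image: single occupied diagonal cell
  cfg <- glcm_config(levels = 4, angles = 0)
  const <- compute_glcm(matrix(2L, 3, 3), cfg, levels = 4)
  f <- glcm_features(const)
  expect_equal(unname(f[c("CON", "ENE", "HOM", "COR")]), c(0, 1, 1, 1))
  expect_true(attr(f, "degenerate_correlation"))

  # 2x2 checkerboard, distance 1, angle 0, symmetric
  cb <- compute_glcm(matrix(c(0L, 1L, 1L, 0L), 2, 2),
                     glcm_config(levels = 2, angles = 0))
  f2 <- glcm_features(cb)
  expect_equal(unname(f2[c("CON", "ENE", "HOM", "COR")]),
               c(1, 0.5, 0.5, -1))

  # bounds on random GLCMs
  set.seed(5)
  for (i in 1:30) {
    p <- matrix(rexp(36), 6); p <- (p + t(p)); p <- p / sum(p)
    f <- glcm_features(p)
    expect_gte(f[["ENE"]], 0); expect_lte(f[["ENE"]], 1)
    expect_gte(f[["HOM"]], 0); expect_lte(f[["HOM"]], 1)
    expect_gte(f[["COR"]], -1); expect_lte(f[["COR"]], 1)
    expect_gte(f[["CON"]], 0); expect_lte(f[["CON"]], 25)
  }
})

test_that("whole-ROI texture scalars behave in the homogeneous limit", {
  res <- fix_extract()
  mbf <- res$maps[[1]]$MBF
  ts <- texture_scalar(mbf)
  expect_named(ts, c("CON", "ENE", "COR", "HOM"))
  expect_identical(ts, texture_scalar(mbf))  # deterministic

  # constant (homogeneous-limit) map: ENE = 1, CON = 0 exactly; note that
  # under per-map min-max quantization a speckled-but-homogeneous map still
  # spans all grey levels, so the limit is only reached at zero variance
  tsc <- texture_scalar(matrix(1, 20, 20))
  expect_equal(tsc[["ENE"]], 1)
  expect_equal(tsc[["CON"]], 0)
  expect_equal(tsc[["HOM"]], 1)

  # 5 parametric maps -> 20 named first-pass scalars
  t1 <- unlist(lapply(c("MBF", "SS", "SI", "ASD", "AAC"), function(p) {
    x <- texture_scalar(res$maps[[1]][[p]])
    names(x) <- paste(p, names(x), sep = "-")
    x
  }))
  expect_length(t1, 20)
  expect_setequal(names(t1), qus_feature_names("tex1"))
})

test_that("sliding texture maps match a per-window GLCM oracle", {
  set.seed(44)
  m <- matrix(rnorm(26 * 22), 26, 22)
  m[sample(length(m), 30)] <- NA
  cfg <- glcm_config(levels = 6, neighborhood = 7,
                     min_valid_fraction = 0.3)
  tm <- texture_map_sliding(m, cfg)
  expect_equal(dim(tm$CON$values), c(26 - 7 + 1, 22 - 7 + 1))

  # oracle: quantize whole map once, then independent whole-window GLCMs
  q <- quantize_map(m, cfg$levels)$grid
  for (k in 1:12) {
    r <- sample(nrow(tm$CON$values), 1); cc <- sample(ncol(tm$CON$values), 1)
    sub <- q[r:(r + 6), cc:(cc + 6), drop = FALSE]
    ref <- tryCatch(glcm_features(compute_glcm(sub, cfg)),
                    error = function(e) NULL)
    got <- c(CON = tm$CON$values[r, cc], ENE = tm$ENE$values[r, cc],
             COR = tm$COR$values[r, cc], HOM = tm$HOM$values[r, cc])
    if (any(is.na(got)) || is.null(ref)) next
    expect_equal(unname(got), unname(ref[c("CON", "ENE", "COR", "HOM")]),
                 tolerance = 1e-10)
  }

  # constant parametric map -> CON texture map identically 0, ENE 1
  cm <- texture_map_sliding(matrix(3, 20, 20), glcm_config(neighborhood = 7))
  expect_true(all(cm$CON$values == 0))
  expect_true(all(cm$ENE$values == 1))

  # step reduces output dims accordingly
  t2 <- texture_map_sliding(m, cfg, step = 2)
  expect_equal(dim(t2$CON$values),
               c(length(seq(1, 26 - 7 + 1, 2)), length(seq(1, 22 - 7 + 1, 2))))

  expect_warning(te <- texture_map_sliding(matrix(1, 4, 4),
                                           glcm_config(neighborhood = 15)),
                 "larger than map")
  expect_equal(dim(te$CON$values), c(0, 0))
})

test_that("texture features are invariant to increasing affine rescaling", {
  set.seed(55)
  m <- matrix(rnorm(400), 20)
  f1 <- texture_scalar(m)
  f2 <- texture_scalar(3.7 * m + 11)
  expect_equal(f1, f2, tolerance = 1e-12)
  t1 <- texture_map_sliding(m, glcm_config(neighborhood = 9))
  t2 <- texture_map_sliding(0.2 * m - 4, glcm_config(neighborhood = 9))
  expect_equal(t1$COR$values, t2$COR$values, tolerance = 1e-12)
})

test_that("texture derivatives are the first-pass operator re-applied", {
  res <- fix_extract()
  tmaps <- res$texture_maps[[1]]
  expect_length(tmaps, 20)
  cfg <- glcm_config()
  t2 <- texture_derivatives(tmaps, cfg)
  expect_length(t2, 80)
  expect_setequal(names(t2), qus_feature_names("tex2"))

  # operator-composition identity: same code path as texture_scalar
  nm <- "MBF-CON"
  manual <- texture_scalar(tmaps[[nm]], cfg)
  expect_equal(as.numeric(t2[paste(nm, names(manual), sep = "-")]),
               as.numeric(manual))

  # permuting map order changes nothing (name-keyed)
  t2p <- texture_derivatives(rev(tmaps), cfg)
  expect_equal(t2p[names(t2)], t2)

  # constant texture map: CON derivative 0, ENE derivative 1
  ctm <- list("SS-HOM" = matrix(0.5, 18, 18))
  suppressMessages(td <- texture_derivatives(ctm, cfg))
  expect_equal(unname(td["SS-HOM-CON"]), 0)
  expect_equal(unname(td["SS-HOM-ENE"]), 1)
})

test_that("feature-vector assembly enforces the 5/20/80 grammar", {
  res <- fix_extract()
  fv <- res$features
  expect_s3_class(fv, "qus_features")
  expect_length(fv, 105)
  expect_identical(names(fv), qus_feature_names("all"))

  expect_equal(parse_feature_name("SI-COR"),
               list(base = "SI", tex1 = "COR", tex2 = NULL))
  expect_equal(parse_feature_name("AAC-CON-ENE")$tex2, "ENE")
  expect_error(parse_feature_name("MBF-FOO"), "invalid feature name")

  q <- setNames(rnorm(5), qus_feature_names("qus"))
  t1 <- setNames(rnorm(20), qus_feature_names("tex1"))
  t2 <- setNames(rnorm(80), qus_feature_names("tex2"))
  v <- assemble_feature_vector(q, t1, t2)
  expect_length(v, 105)
  dup <- t1; names(dup)[1] <- "MBF"
  expect_error(assemble_feature_vector(q, dup, t2), "duplicate")
  bad <- t1; names(bad)[2] <- "MBF-XYZ"
  expect_error(assemble_feature_vector(q, bad, t2), "invalid feature name")
})
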