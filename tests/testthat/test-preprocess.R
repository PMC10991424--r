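test_that("8-bit rescale maps the percentile window linearly onto [0, 255]", {
  ramp <- matrix(seq(0, 65535, length.out = 256), 16, 16)
  out <- rescale_to_8bit(ramp, lo = 0, hi = 100)
  expect_equal(range(out), c(0L, 255L))
  expect_equal(as.vector(out), round(seq(0, 255, length.out = 256)))

  expect_true(all(rescale_to_8bit(matrix(0, 8, 8)) == 0L))

  # 100 pixels valued 0..99: the top pixel must land at (almost) full scale
  img <- matrix(0:99, 10, 10)
  out <- rescale_to_8bit(img, lo = 0, hi = 99)
  expect_gte(out[img == 99], 254)

  expect_error(rescale_to_8bit(matrix(numeric(0), 0, 0)), "empty")
  expect_error(rescale_to_8bit(ramp, lo = 50, hi = 10), "percentile")
})

test_that("core QC drops exactly the cores deviating beyond the SD threshold", {
  set.seed(1)
  cm <- matrix(rnorm(10 * 3, mean = 100, sd = 1), 10, 3,
               dimnames = list(sprintf("core%02d", 1:10), c("A", "B", "C")))
  # push one core's channel B out by 5 contaminated SDs
  s0 <- sd(c(cm[, "B"][-4], 100))
  cm[4, "B"] <- mean(cm[-4, "B"]) + 12 * s0
  rep <- qc_filter_cores(cm, n_sd = 2)
  # oracle: recompute the rule directly
  keep <- apply(cm, 1, function(r)
    all(abs(r - colMeans(cm)) <= 2 * apply(cm, 2, sd)))
  expect_identical(sort(rep$kept), sort(rownames(cm)[keep]))
  expect_identical(names(rep$dropped), "core04")
  expect_identical(rep$dropped$core04, "B")

  none <- qc_filter_cores(matrix(5, 4, 2,
                                 dimnames = list(paste0("c", 1:4), NULL)))
  expect_length(none$dropped, 0)

  expect_error(qc_filter_cores(cm[1:2, ]), "3 cores")
})

test_that("QC report stores the original TMA statistics it filtered against", {
  set.seed(2)
  cm <- matrix(rnorm(8 * 2, 50, 5), 8, 2,
               dimnames = list(paste0("c", 1:8), c("A", "B")))
  rep <- qc_filter_cores(cm)
  expect_equal(rep$tma_mean, colMeans(cm))
  expect_equal(rep$tma_sd, apply(cm, 2, sd))
  expect_identical(rep$core_means, cm)
})

test_that("crop_cells centres, aligns and separates labelled cells", {
  sc <- ellipse_scene(angles_deg = c(0, 37))
  st <- crop_cells(sc$channels, sc$labels, sc$markers, core_id = "coreA")
  expect_equal(n_cells(st), 2L)
  expect_false(anyDuplicated(st$cell_id) > 0)
  for (i in 1:2) {
    m <- st$mask[, , i]
    expect_lt(max(abs(mask_com(m) - 16.5)), 1)
    expect_lt(abs(mask_orientation_deg(m)), 5)
    for (c in 1:2) expect_true(all(st$data[, , c, i][!m] == 0L))
  }
})

test_that("translation-only alignment preserves the within-mask pixel multiset; rotation nearly", {
  sc <- ellipse_scene(angles_deg = c(0, 37))
  st <- crop_cells(sc$channels, sc$labels, sc$markers)
  # cell 1 is axis-aligned: exact multiset preservation per channel
  src_mask <- sc$labels == 1L
  for (c in 1:2) {
    src_pixels <- sort(sc$channels[, , c][src_mask])
    out_pixels <- sort(st$data[, , c, 1][st$mask[, , 1]])
    expect_identical(as.integer(src_pixels), as.integer(out_pixels))
  }
  # cell 2 is rotated 37 degrees: bilinear resampling, mean drift < 2%
  src_mask2 <- sc$labels == 2L
  for (c in 1:2) {
    m_src <- mean(sc$channels[, , c][src_mask2])
    m_out <- mean(st$data[, , c, 2][st$mask[, , 2]])
    expect_lt(abs(m_out - m_src) / m_src, 0.02)
  }
})

test_that("crop_cells warns on absent labels and errors on empty masks", {
  sc <- ellipse_scene(angles_deg = 0)
  expect_warning(st <- crop_cells(sc$channels, sc$labels, sc$markers,
                                  which_labels = c(1L, 9L)), "absent")
  expect_equal(n_cells(st), 1L)
  expect_error(crop_cells(sc$channels, matrix(0L, 96, 96), sc$markers),
               "empty")
})

test_that("histogram matching pulls a shifted distribution toward the reference", {
  set.seed(3)
  ref <- pmin(pmax(round(rnorm(5000, 80, 25)), 0), 255)
  src <- matrix(pmin(ref[1:1024] + 50, 255), 32, 32)
  out <- histogram_match(src, ref)
  ks <- function(a, b) {
    cdf <- function(v) cumsum(tabulate(as.integer(v) + 1L, 256L)) / length(v)
    max(abs(cdf(a) - cdf(b)))
  }
  expect_lt(ks(out, ref), ks(src, ref))
  expect_true(all(out >= 0 & out <= 255))
  # matching a distribution to itself is (near) identity
  same <- histogram_match(matrix(ref[1:1024], 32, 32), ref)
  expect_lt(mean(abs(as.numeric(same) - ref[1:1024])), 1.5)
  expect_warning(cst <- histogram_match(src, rep(7L, 100)), "constant")
  expect_true(all(cst == 7L))
})

test_that("matching a gain-distorted batch to reference cores restores mean-intensity ranks", {
  # loadings scaled down so the 1.5x gain stays below 8-bit saturation;
  # mild pixel noise spreads the per-cell distributions so the 256-bin
  # quantile mapping does not collapse discrete levels into ties
  L <- default_loading(c("DAPI", "CD45", "PanCK", "CD3", "Ki67", "ECad")) * 0.6
  base <- generate_stack(synthetic_spec(n_cells = 300, seed = 6, noise_sd = 3,
                                        loading_matrix = L))
  dist <- generate_stack(synthetic_spec(n_cells = 300, seed = 6, noise_sd = 3,
                                        loading_matrix = L,
                                        batch_gain = c(1, 1.5)))
  b2 <- which(dist$stack$batch_id == "batch02")
  ref_cells <- which(base$stack$batch_id == "batch01")
  matched <- dist$stack$data
  for (c in seq_along(base$stack$markers)) {
    refpix <- as.vector(base$stack$data[, , c, ref_cells])
    # batch-level operation: one quantile mapping per channel over the
    # pooled batch pixels, applied to every cell of the batch
    pooled <- dist$stack$data[, , c, b2]
    matched[, , c, b2] <- histogram_match(pooled, refpix)
  }
  m_ref <- mean_intensities(base$stack)[b2, ]
  m_mat <- mean_intensities(base$stack, data = matched)[b2, ]
  for (c in seq_along(base$stack$markers))
    expect_gte(cor(m_ref[, c], m_mat[, c], method = "spearman"), 0.95)
})

test_that("cell-level splits have the stated sizes and are seed-deterministic", {
  sim <- generate_stack(synthetic_spec(n_cells = 1000, seed = 9))
  sp <- split_dataset(sim$stack, c(0.9, 0.05, 0.05), seed = 4)
  expect_equal(vapply(sp, n_cells, 1L), c(train = 900L, val = 50L, test = 50L))
  ids <- c(sp$train$cell_id, sp$val$cell_id, sp$test$cell_id)
  expect_setequal(ids, sim$stack$cell_id)
  expect_equal(length(ids), 1000L)

  sp2 <- split_dataset(sim$stack, c(0.9, 0.05, 0.05), seed = 4)
  expect_identical(attr(sp, "indices"), attr(sp2, "indices"))
  sp3 <- split_dataset(sim$stack, c(0.9, 0.05, 0.05), seed = 5)
  expect_false(identical(attr(sp, "indices"), attr(sp3, "indices")))

  all_train <- split_dataset(sim$stack[1:20], c(1, 0, 0), seed = 1)
  expect_equal(n_cells(all_train$train), 20L)
  expect_null(all_train$test)

  expect_error(split_dataset(sim$stack[1:5], c(0.9, 0.05, 0.05), seed = 1),
               "few cells")
  expect_error(split_dataset(sim$stack, c(0.5, 0.2), seed = 1), "sum to 1")
})

test_that("splits depend on ids and seed only, never on pixel content", {
  sim <- generate_stack(synthetic_spec(n_cells = 100, seed = 9))
  st2 <- sim$stack
  st2$data[st2$mask] <- pmin(st2$data[st2$mask] + 1L, 255L)
  sp1 <- split_dataset(sim$stack, c(0.8, 0.1, 0.1), seed = 7)
  sp2 <- split_dataset(st2, c(0.8, 0.1, 0.1), seed = 7)
  expect_identical(attr(sp1, "indices"), attr(sp2, "indices"))
})

test_that("core-level folds partition the cores into near-equal test sets", {
  cores <- sprintf("core%03d", 1:320)
  folds <- kfold_core_split(cores, k = 5, seed = 1)
  expect_length(folds, 5)
  sizes <- vapply(folds, function(f) length(f$test), 1L)
  expect_true(all(sizes == 64L))
  tests <- lapply(folds, `[[`, "test")
  expect_setequal(unlist(tests), cores)
  for (i in 1:4) for (j in (i + 1):5)
    expect_length(intersect(tests[[i]], tests[[j]]), 0)
  for (f in folds) expect_length(intersect(f$train, f$test), 0)

  f7 <- kfold_core_split(paste0("c", 1:7), k = 3, seed = 2)
  expect_setequal(vapply(f7, function(f) length(f$test), 1L), c(3L, 2L, 2L))

  expect_error(kfold_core_split(cores, k = 1), ">= 2")
  expect_error(kfold_core_split(paste0("c", 1:3), k = 5), "exceeds")
})
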