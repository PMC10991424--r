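gaussian_kernel <- function(size = 7L, sigma = 1.5) {
  r <- (size - 1L) %/% 2L
  d <- (-r):r
  k1 <- exp(-d^2 / (2 * sigma^2))
  k <- outer(k1, k1)
  k / sum(k)
}

# 'valid' 2-D convolution with a small kernel, via shifted submatrices
conv2_valid <- function(img, kern) {
  kh <- nrow(kern); kw <- ncol(kern)
  oh <- nrow(img) - kh + 1L; ow <- ncol(img) - kw + 1L
  out <- matrix(0, oh, ow)
  for (i in seq_len(kh)) for (j in seq_len(kw)) {
    if (kern[i, j] != 0)
      out <- out + kern[i, j] * img[i:(i + oh - 1L), j:(j + ow - 1L)]
  }
  out
}

#' Structural similarity index (SSIM) between two images
#'
#' Windowed luminance/contrast/structure similarity with a Gaussian
#' window (side `win`, sigma 1.5) and the standard stabilising constants
#' `C1 = (K1 * L)^2`, `C2 = (K2 * L)^2` with `K1 = 0.01`, `K2 = 0.03` and
#' dynamic range `L = data_range`.  Local statistics are weighted
#' (population) moments; the score is the mean of the SSIM map over all
#' windows fully inside the image.  Symmetric in its arguments;
#' identical images score exactly 1.
#'
#' @param x,y numeric matrices of identical shape (for 8-bit crops,
#'   values in `0..255`).
#' @param data_range dynamic range `L` (255 for 8-bit).
#' @param win odd window side in pixels; @param sigma Gaussian SD.
#' @param K1,K2 stabilising constants.
#' @return scalar SSIM in `[-1, 1]`.
#' @export
ssim <- function(x, y, data_range = 255, win = 7L, sigma = 1.5,
                 K1 = 0.01, K2 = 0.03) {
  if (!identical(dim(x), dim(y))) stop("images must have identical shape")
  if (min(dim(x)) < win) stop("image smaller than the SSIM window")
  x <- matrix(as.numeric(x), nrow(x)); y <- matrix(as.numeric(y), nrow(y))
  k <- gaussian_kernel(win, sigma)
  mu_x <- conv2_valid(x, k); mu_y <- conv2_valid(y, k)
  sxx <- conv2_valid(x * x, k) - mu_x^2
  syy <- conv2_valid(y * y, k) - mu_y^2
  sxy <- conv2_valid(x * y, k) - mu_x * mu_y
  C1 <- (K1 * data_range)^2; C2 <- (K2 * data_range)^2
  map <- ((2 * mu_x * mu_y + C1) * (2 * sxy + C2)) /
    ((mu_x^2 + mu_y^2 + C1) * (sxx + syy + C2))
  mean(map)
}

#' Evaluate an imputer on a test stack
#'
#' Imputes the complement of `panel` once for every cell, then reports —
#' per held-out marker — the Spearman and Pearson correlations of actual
#' versus predicted within-mask mean intensities across cells, and the
#' mean [ssim()] between actual and predicted 32x32 channel images;
#' aggregates are the mean Spearman rho, the variance of rho across
#' markers (prediction consistency across stains), and the mean SSIM.
#' The per-cell actual/predicted table is kept for plotting and for
#' regenerating the aggregates.
#'
#' @param imputer any [impute()]-capable object.
#' @param stack the held-out evaluation `cell_stack`.
#' @param panel measured-marker names.
#' @param split_id optional label recorded in the report.
#' @return an object of class `"eval_report"`.
#' @export
evaluate_panel <- function(imputer, stack, panel, split_id = "test") {
  if (n_cells(stack) < 3) stop("need at least 3 cells to correlate")
  mask <- panel_to_mask(panel, stack$markers)
  pred <- impute(imputer, stack, mask = mask)
  actual <- mean_intensities(stack)
  predicted <- mean_intensities(stack, data = pred)
  held <- stack$markers[mask$masked]
  n <- n_cells(stack)

  rho <- pear <- ssim_mean <- stats::setNames(numeric(length(held)), held)
  for (mk in held) {
    a <- actual[, mk]; p <- predicted[, mk]
    rho[mk] <- if (stats::sd(a) == 0 || stats::sd(p) == 0) NA_real_
               else stats::cor(a, p, method = "spearman")
    pear[mk] <- if (stats::sd(a) == 0 || stats::sd(p) == 0) NA_real_
                else stats::cor(a, p)
    ch <- which(stack$markers == mk)
    ssim_mean[mk] <- mean(vapply(seq_len(n), function(i)
      ssim(stack$data[, , ch, i], pred[, , ch, i]), numeric(1)))
  }
  cells <- data.frame(
    cell_id = rep(stack$cell_id, length(held)),
    marker = rep(held, each = n),
    actual_mean = as.vector(actual[, held]),
    predicted_mean = as.vector(predicted[, held])
  )
  structure(list(
    panel = panel, held_out = held, split_id = split_id, n_cells = n,
    spearman = rho, pearson = pear, ssim = ssim_mean,
    mean_rho = mean(rho, na.rm = TRUE),
    var_rho = stats::var(rho[!is.na(rho)]),
    mean_ssim = mean(ssim_mean),
    per_cell = cells
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> split '%s': panel of %d markers, %d held out, %d cells\n",
              x$split_id, length(x$panel), length(x$held_out), x$n_cells))
  cat(sprintf("  mean Spearman rho %.4f (variance across stains %.4f), mean SSIM %.4f\n",
              x$mean_rho, x$var_rho, x$mean_ssim))
  df <- data.frame(marker = x$held_out, spearman = round(x$spearman, 3),
                   pearson = round(x$pearson, 3), ssim = round(x$ssim, 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Assert that two stacks share no cores or cells
#'
#' Guard used by [crossvalidate()] (and available to callers assembling
#' their own folds): errors if any core or cell id appears in both the
#' training and the test stack.
#'
#' @param train_stack,test_stack `cell_stack`s.
#' @return `TRUE`, invisibly.
#' @export
assert_no_leakage <- function(train_stack, test_stack) {
  shared_cores <- intersect(unique(train_stack$core_id),
                            unique(test_stack$core_id))
  if (length(shared_cores))
    stop("core leakage between train and test: ",
         paste(shared_cores, collapse = ", "))
  shared_cells <- intersect(train_stack$cell_id, test_stack$cell_id)
  if (length(shared_cells))
    stop("cell leakage between train and test: ",
         paste(utils::head(shared_cells, 5), collapse = ", "))
  invisible(TRUE)
}

#' Core-level k-fold cross-validation
#'
#' Splits the TMA cores into `k` folds ([kfold_core_split()]), trains one
#' autoencoder per fold on the training cores' cells and evaluates it on
#' the test cores' cells with [evaluate_panel()].  No core — and so no
#' cell — appears on both sides of any fold.
#'
#' @param stack the full `cell_stack`.
#' @param k number of folds.
#' @param config a [mae_config()] used for every fold's model.
#' @param panel measured-marker names for evaluation.
#' @param seed seed for the core partition.
#' @return list of `k` `eval_report`s (with a `fold` element each).
#' @export
crossvalidate <- function(stack, k, config, panel, seed = 1L) {
  folds <- kfold_core_split(stack$core_id, k, seed)
  lapply(seq_len(k), function(f) {
    tr_cores <- folds[[f]]$train; te_cores <- folds[[f]]$test
    stopifnot(length(intersect(tr_cores, te_cores)) == 0)
    tr <- stack[stack$core_id %in% tr_cores]
    te <- stack[stack$core_id %in% te_cores]
    assert_no_leakage(tr, te)
    model <- channel_mae(tr, config)
    rep <- evaluate_panel(model, te, panel, split_id = sprintf("fold%d", f))
    rep$fold <- f
    rep$test_cores <- te_cores
    rep
  })
}
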