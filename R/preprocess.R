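#' Rescale a 16-bit channel to 8-bit
#'
#' Linear percentile stretch: intensities between the `lo` and `hi`
#' percentiles of the channel are mapped linearly onto `[0, 255]` and
#' clipped.  The default 0/99.9 window is robust to hot pixels.  A
#' constant channel maps to all zeros.
#'
#' @param image numeric matrix (one channel, any bit depth).
#' @param lo,hi percentile bounds in `[0, 100]`, `hi > lo`.
#' @return integer matrix of the same shape with values in `0..255`.
#' @export
rescale_to_8bit <- function(image, lo = 0, hi = 99.9) {
  if (length(image) == 0) stop("empty image")
  if (hi <= lo) stop("hi percentile must exceed lo percentile")
  q <- stats::quantile(image, c(lo, hi) / 100, names = FALSE, type = 7)
  out <- if (q[2] > q[1]) (image - q[1]) / (q[2] - q[1]) * 255 else image * 0
  out <- round(pmin(pmax(out, 0), 255))
  storage.mode(out) <- "integer"
  out
}

#' Core-level quality control by channel mean intensity
#'
#' Flags every TMA core that contains at least one channel whose mean
#' intensity deviates from the across-core mean of that channel by more
#' than `n_sd` standard deviations, and drops it.  The statistics are
#' computed once, over all cores of the original TMA, and stored in the
#' report; the filter is defined against those original statistics, not
#' re-derived from its own output.
#'
#' @param core_means numeric matrix, cores x channels, with core ids as
#'   rownames and channel names as colnames.
#' @param n_sd deviation threshold in SD units (default 2).
#' @return an object of class `"core_qc_report"`: `core_means`, `tma_mean`,
#'   `tma_sd` (per channel), `dropped` (named list core -> offending
#'   channels), `kept` (character vector of retained core ids), `n_sd`.
#' @export
qc_filter_cores <- function(core_means, n_sd = 2) {
  core_means <- as.matrix(core_means)
  if (nrow(core_means) < 3)
    stop("need at least 3 cores to estimate across-core dispersion")
  if (is.null(rownames(core_means)))
    rownames(core_means) <- sprintf("core%03d", seq_len(nrow(core_means)))
  m <- colMeans(core_means)
  s <- apply(core_means, 2, stats::sd)
  dev <- abs(sweep(core_means, 2, m)) > sweep(matrix(n_sd, nrow(core_means),
                                                     ncol(core_means)), 2, s, `*`)
  bad <- which(rowSums(dev) > 0)
  dropped <- lapply(bad, function(i) colnames(core_means)[dev[i, ]])
  names(dropped) <- rownames(core_means)[bad]
  structure(list(
    core_means = core_means, tma_mean = m, tma_sd = s,
    dropped = dropped,
    kept = setdiff(rownames(core_means), names(dropped)),
    n_sd = n_sd
  ), class = "core_qc_report")
}

#' @export
print.core_qc_report <- function(x, ...) {
  cat(sprintf("<core_qc_report> %d cores, %d dropped (> %g SD), %d kept\n",
              nrow(x$core_means), length(x$dropped), x$n_sd, length(x$kept)))
  if (length(x$dropped))
    for (nm in names(x$dropped))
      cat("  ", nm, ": ", paste(x$dropped[[nm]], collapse = ", "), "\n", sep = "")
  invisible(x)
}

mask_moments <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  ybar <- mean(idx[, 1]); xbar <- mean(idx[, 2])
  dy <- idx[, 1] - ybar; dx <- idx[, 2] - xbar
  mu20 <- mean(dx^2); mu02 <- mean(dy^2); mu11 <- mean(dx * dy)
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  list(cx = xbar, cy = ybar, theta = theta, mu20 = mu20, mu02 = mu02,
       mu11 = mu11)
}

bilinear_sample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  gv <- function(yy, xx) {
    ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
    v <- numeric(length(xx))
    v[ok] <- img[cbind(yy[ok], xx[ok])]
    v
  }
  gv(y0, x0) * (1 - fx) * (1 - fy) + gv(y0, x0 + 1) * fx * (1 - fy) +
    gv(y0 + 1, x0) * (1 - fx) * fy + gv(y0 + 1, x0 + 1) * fx * fy
}

nearest_sample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  xi <- round(x); yi <- round(y)
  ok <- yi >= 1 & yi <= h & xi >= 1 & xi <= w
  v <- numeric(length(xi))
  v[ok] <- img[cbind(yi[ok], xi[ok])]
  v
}

#' Crop, centre and pose-align single cells from a labelled image
#'
#' For every label in the segmentation mask, extracts a 32x32 crop in a
#' canonical pose: the mask's centre of mass is translated to the crop
#' centre and its major principal axis (from second-order image moments)
#' is rotated to horizontal.  The 180-degree ambiguity of the axis is
#' resolved by flipping the crop so the DAPI centre of mass falls in the
#' left half.  Intensities are resampled bilinearly, the mask with
#' nearest-neighbour; out-of-mask pixels are re-zeroed after resampling.
#' When the measured orientation is already (numerically) horizontal the
#' cell is moved by an integer translation only, which preserves the
#' within-mask pixel multiset exactly.  Cells larger than the 32x32 window
#' are centre-cropped.
#'
#' @param channels numeric array `H x W x C` of 8-bit channel images.
#' @param labels integer matrix `H x W`; 0 = background, `k` = cell `k`.
#' @param markers channel names (first should be DAPI for flip resolution).
#' @param which_labels labels to extract (default: all present).
#' @param core_id,batch_id identifiers stamped on every extracted cell.
#' @return a [cell_image_stack()].
#' @export
crop_cells <- function(channels, labels, markers,
                       which_labels = NULL,
                       core_id = "core1", batch_id = "batch1") {
  if (length(dim(channels)) == 2L) channels <- array(channels, c(dim(channels), 1L))
  stopifnot(identical(dim(channels)[1:2], dim(labels)))
  C <- dim(channels)[3]
  stopifnot(length(markers) == C)
  present <- sort(unique(labels[labels > 0]))
  if (is.null(which_labels)) which_labels <- present
  missing <- setdiff(which_labels, present)
  if (length(missing)) {
    warning("labels absent from mask, skipped: ", paste(missing, collapse = ", "))
    which_labels <- intersect(which_labels, present)
  }
  if (!length(which_labels)) stop("no cells to extract (empty mask)")
  p <- crop_size()
  n <- length(which_labels)
  dapi_ch <- if ("DAPI" %in% markers) which(markers == "DAPI")[1] else 1L
  data <- array(0L, dim = c(p, p, C, n))
  mask <- array(FALSE, dim = c(p, p, n))
  ctr <- (p + 1) / 2
  grid_x <- matrix(rep(seq_len(p), each = p), p, p) - ctr
  grid_y <- matrix(rep(seq_len(p), times = p), p, p) - ctr
  for (i in seq_len(n)) {
    lab <- which_labels[i]
    mo <- mask_moments(labels == lab)
    th <- mo$theta
    if (abs(th) < 1e-3) {
      # translation-only path: pure integer shift, pixel multiset preserved
      x0 <- round(mo$cx) - p %/% 2L; y0 <- round(mo$cy) - p %/% 2L
      sx <- as.vector(matrix(rep(seq_len(p), each = p), p, p)) + x0 - 1L
      sy <- as.vector(matrix(rep(seq_len(p), times = p), p, p)) + y0 - 1L
      mi <- nearest_sample(labels, sx, sy) == lab
      for (c in seq_len(C)) {
        v <- nearest_sample(channels[, , c], sx, sy)
        v[!mi] <- 0
        data[, , c, i] <- as.integer(round(matrix(v, p, p)))
      }
    } else {
      # rotate by -theta about the centroid (inverse map: rotate grid by +theta)
      sx <- mo$cx + cos(th) * grid_x - sin(th) * grid_y
      sy <- mo$cy + sin(th) * grid_x + cos(th) * grid_y
      mi <- nearest_sample(labels, as.vector(sx), as.vector(sy)) == lab
      # normalised masked interpolation: boundary pixels average only
      # in-cell contributions, avoiding dilution by the zero background
      inmask <- (labels == lab) * 1
      wgt <- bilinear_sample(inmask, as.vector(sx), as.vector(sy))
      for (c in seq_len(C)) {
        v <- bilinear_sample(channels[, , c] * inmask, as.vector(sx),
                             as.vector(sy))
        v <- ifelse(wgt > 1e-6, v / pmax(wgt, 1e-6), 0)
        v[!mi] <- 0
        data[, , c, i] <- as.integer(round(pmin(pmax(matrix(v, p, p), 0), 255)))
      }
    }
    mm <- matrix(mi, p, p)
    # resolve the 180-degree axis ambiguity: DAPI centre of mass left of centre
    dch <- data[, , dapi_ch, i]
    wsum <- sum(dch)
    comx <- if (wsum > 0) sum(dch * (matrix(rep(seq_len(p), each = p), p, p))) / wsum else ctr
    if (comx > ctr + 1e-9) {
      data[, , , i] <- data[p:1, p:1, , i, drop = FALSE]
      mm <- mm[p:1, p:1]
    }
    mask[, , i] <- mm
  }
  cell_image_stack(data, mask, markers,
                   cell_id = sprintf("%s_c%04d", core_id, which_labels),
                   core_id = rep(core_id, n), batch_id = rep(batch_id, n))
}

#' Histogram matching against a reference pixel distribution
#'
#' Monotone quantile mapping of 8-bit intensities: each grey level of the
#' source image is sent to the reference grey level with the same (or
#' next-larger) cumulative frequency, using 256-bin empirical CDFs.  Used
#' to normalise a batch against designated reference cores.
#'
#' @param image integer matrix/array of 8-bit intensities.
#' @param reference integer vector (or matrix) of 8-bit reference pixels.
#' @return matched image, same shape, values in `0..255`.
#' @export
histogram_match <- function(image, reference) {
  if (length(reference) == 0) stop("reference distribution is empty")
  ref <- as.integer(reference)
  if (length(unique(ref)) == 1L) {
    warning("constant reference distribution; all pixels map to it")
    out <- image; out[] <- ref[1]; return(out)
  }
  src <- as.integer(image)
  cdf_src <- cumsum(tabulate(src + 1L, 256L)) / length(src)
  cdf_ref <- cumsum(tabulate(ref + 1L, 256L)) / length(ref)
  # map grey level v -> smallest reference level whose CDF >= CDF_src(v)
  lut <- vapply(0:255, function(v) {
    which(cdf_ref >= cdf_src[v + 1L] - 1e-12)[1] - 1L
  }, integer(1))
  out <- image
  out[] <- lut[src + 1L]
  out
}

largest_remainder_sizes <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Random cell-level train/validation/test split
#'
#' Splits cells (by id, never by pixel content) into disjoint, exhaustive
#' subsets with the given fractions, reproducibly in `seed`.  The default
#' fractions reserve 90% for training, 5% for validation / panel
#' selection and 5% for testing.
#'
#' @param stack a `cell_stack`.
#' @param fractions numeric vector summing to 1 (train, validation, test).
#' @param seed integer seed.
#' @return named list of `cell_stack`s (`train`, `val`, `test`; zero-
#'   fraction entries are dropped) with an `"indices"` attribute.
#' @export
split_dataset <- function(stack, fractions = c(0.9, 0.05, 0.05), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  n <- n_cells(stack)
  sizes <- largest_remainder_sizes(n, fractions)
  if (any(sizes == 0 & fractions > 0))
    stop("too few cells: a split with a positive fraction would be empty")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  perm <- sample.int(n)
  nm <- c("train", "val", "test")[seq_along(fractions)]
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  idx <- lapply(seq_along(sizes), function(j)
    if (sizes[j] > 0) sort(perm[starts[j]:ends[j]]) else integer(0))
  names(idx) <- nm
  out <- lapply(idx[sizes > 0], function(i) stack[i])
  attr(out, "indices") <- idx
  out
}

#' Core-level k-fold split
#'
#' Partitions TMA cores into `k` test sets of near-equal size (differing
#' by at most one core); the training cores of each fold are the
#' complement, so no core — and hence no cell — ever appears on both
#' sides of a fold.
#'
#' @param core_ids character vector of core ids (duplicates allowed; the
#'   unique set is partitioned).
#' @param k number of folds (>= 2, <= number of distinct cores).
#' @param seed integer seed.
#' @return list of `k` lists with elements `train` and `test` (core ids).
#' @export
kfold_core_split <- function(core_ids, k, seed = 1L) {
  cores <- unique(core_ids)
  if (k < 2) stop("k must be >= 2")
  if (k > length(cores)) stop("k exceeds the number of distinct cores")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  perm <- sample(cores)
  fold <- rep(seq_len(k), length.out = length(cores))
  lapply(seq_len(k), function(f) {
    test <- sort(perm[fold == f])
    list(train = sort(setdiff(cores, test)), test = test)
  })
}
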