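#' Single-cell image stack
#'
#' The universal data container of the package: `N` single-cell crops of a
#' multiplexed image, each `32 x 32` pixels with `C` marker channels, plus
#' the binary cell mask of every crop and per-cell identifiers (cell, TMA
#' core, staining batch). Intensities are 8-bit (`0..255`); every pixel
#' outside the cell mask is exactly zero.
#'
#' @param data integer array `c(32, 32, C, N)` of intensities in `[0, 255]`
#'   (rows, columns, channels, cells).
#' @param mask logical array `c(32, 32, N)`; `TRUE` inside the cell.
#' @param markers character vector of `C` unique marker names.
#' @param cell_id,core_id,batch_id per-cell identifier vectors of length `N`.
#'
#' @return An object of class `"cell_stack"`.
#' @seealso [generate_stack()], [crop_cells()], [mean_intensities()]
#' @export
cell_image_stack <- function(data, mask, markers,
                             cell_id = seq_len(dim(data)[4]),
                             core_id = rep("core1", dim(data)[4]),
                             batch_id = rep("batch1", dim(data)[4])) {
  if (length(dim(data)) != 4L)
    stop("`data` must be a 4-d array (rows, cols, channels, cells)")
  d <- dim(data)
  if (d[1] != crop_size() || d[2] != crop_size())
    stop("crops must be ", crop_size(), "x", crop_size(), " pixels")
  if (d[4] < 1L) stop("stack must contain at least one cell")
  if (length(markers) != d[3]) stop("length(markers) must equal channel count")
  if (anyDuplicated(markers)) stop("marker names must be unique")
  if (!identical(dim(mask), d[c(1, 2, 4)]))
    stop("`mask` dimensions must be (rows, cols, cells)")
  if (min(data) < 0 || max(data) > 255) stop("intensities must lie in [0, 255]")
  storage.mode(data) <- "integer"
  n <- d[4]
  stopifnot(length(cell_id) == n, length(core_id) == n, length(batch_id) == n)
  if (anyDuplicated(cell_id)) stop("cell ids must be unique")
  bg <- sweep_background_check(data, mask)
  if (!bg) stop("out-of-mask pixels must be exactly 0")
  structure(list(
    data = data, mask = array(as.logical(mask), d[c(1, 2, 4)]),
    markers = as.character(markers),
    cell_id = cell_id, core_id = core_id, batch_id = batch_id
  ), class = "cell_stack")
}

crop_size <- function() 32L

sweep_background_check <- function(data, mask) {
  n <- dim(data)[4]; C <- dim(data)[3]
  mm <- matrix(mask, ncol = n)
  dm3 <- array(data, dim = c(crop_size()^2, C, n))
  for (c in seq_len(C)) {
    ch <- matrix(dm3[, c, ], ncol = n)
    if (any(ch[!mm] != 0L)) return(FALSE)
  }
  TRUE
}

#' @export
print.cell_stack <- function(x, ...) {
  cat(sprintf("<cell_stack> %d cells x %d channels (%dx%d px)\n",
              n_cells(x), length(x$markers), crop_size(), crop_size()))
  cat("  markers:", paste(x$markers, collapse = ", "), "\n")
  cat(sprintf("  cores: %d   batches: %d\n",
              length(unique(x$core_id)), length(unique(x$batch_id))))
  invisible(x)
}

#' Number of cells in a stack
#' @param stack a [cell_image_stack()] object.
#' @return integer cell count.
#' @export
n_cells <- function(stack) dim(stack$data)[4]

#' Subset a stack by cell index
#'
#' @param x a `cell_stack`.
#' @param i integer or logical index over cells.
#' @param ... ignored.
#' @return a `cell_stack` with the selected cells.
#' @export
`[.cell_stack` <- function(x, i, ...) {
  i <- seq_len(n_cells(x))[i]
  structure(list(
    data = x$data[, , , i, drop = FALSE],
    mask = x$mask[, , i, drop = FALSE],
    markers = x$markers,
    cell_id = x$cell_id[i], core_id = x$core_id[i], batch_id = x$batch_id[i]
  ), class = "cell_stack")
}

#' Combine stacks cell-wise
#' @param ... `cell_stack` objects sharing the same marker panel.
#' @return a single `cell_stack`.
#' @export
stack_rbind <- function(...) {
  xs <- list(...)
  mk <- xs[[1]]$markers
  for (s in xs) if (!identical(s$markers, mk)) stop("marker panels differ")
  structure(list(
    data = array(unlist(lapply(xs, function(s) s$data), use.names = FALSE),
                 dim = c(crop_size(), crop_size(), length(mk),
                         sum(vapply(xs, n_cells, 1L)))),
    mask = array(unlist(lapply(xs, function(s) s$mask), use.names = FALSE),
                 dim = c(crop_size(), crop_size(),
                         sum(vapply(xs, n_cells, 1L)))),
    markers = mk,
    cell_id = unlist(lapply(xs, `[[`, "cell_id")),
    core_id = unlist(lapply(xs, `[[`, "core_id")),
    batch_id = unlist(lapply(xs, `[[`, "batch_id"))
  ), class = "cell_stack")
}

#' Within-mask mean intensity of one channel of one crop
#'
#' The single-cell summary statistic the whole framework optimises and
#' evaluates: the arithmetic mean of a marker channel over the pixels
#' inside the cell mask.
#'
#' @param crop numeric matrix (one channel of one cell crop).
#' @param mask logical matrix of the same shape; must contain at least one
#'   `TRUE` pixel.
#' @return scalar in `[0, 255]`.
#' @export
mean_intensity <- function(crop, mask) {
  if (!any(mask)) stop("empty cell mask")
  if (!identical(dim(crop), dim(mask))) stop("crop/mask shape mismatch")
  mean(crop[mask])
}

#' Per-cell, per-marker within-mask mean intensities
#'
#' @param stack a `cell_stack`.
#' @param data optional replacement intensity array (e.g. model predictions)
#'   with the same dimensions as `stack$data`; the stack's own masks are
#'   always used.
#' @return numeric matrix `N x C` with marker names as column names.
#' @export
mean_intensities <- function(stack, data = stack$data) {
  C <- length(stack$markers); n <- n_cells(stack)
  d3 <- array(as.numeric(data), dim = c(crop_size()^2, C, n))
  mm <- matrix(stack$mask, ncol = n)
  npix <- colSums(mm)
  if (any(npix == 0)) stop("empty cell mask")
  out <- matrix(NA_real_, n, C, dimnames = list(NULL, stack$markers))
  for (c in seq_len(C)) out[, c] <- colSums(matrix(d3[, c, ], ncol = n) * mm) / npix
  out
}
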