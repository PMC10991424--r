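#' Write / read a cell stack store
#'
#' On-disk interchange format for single-cell image stacks: a directory
#' holding `images.tif` (one 32x32 page per cell x channel, cell-major),
#' `masks.tif` (one page per cell), `cells.csv` (cell_id, core_id,
#' batch_id and, when supplied, per-marker true means) and `meta.json`
#' (markers, dimensions).
#'
#' @param stack a [cell_image_stack()].
#' @param dir target directory (created if needed).
#' @param true_means optional N x C matrix written into `cells.csv`.
#' @return `stack_write` the directory, invisibly; `stack_read` a
#'   `cell_stack`.
#' @export
stack_write <- function(stack, dir, true_means = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- n_cells(stack); C <- length(stack$markers)
  pages <- lapply(seq_len(n * C), function(k) {
    i <- (k - 1L) %/% C + 1L; c <- (k - 1L) %% C + 1L
    stack$data[, , c, i] / 255
  })
  tiff::writeTIFF(pages, file.path(dir, "images.tif"), bits.per.sample = 8L)
  mpages <- lapply(seq_len(n), function(i) stack$mask[, , i] * 1)
  tiff::writeTIFF(mpages, file.path(dir, "masks.tif"), bits.per.sample = 8L)
  cells <- data.frame(cell_id = stack$cell_id, core_id = stack$core_id,
                      batch_id = stack$batch_id)
  if (!is.null(true_means))
    cells <- cbind(cells, stats::setNames(as.data.frame(true_means),
                                          paste0("true_", stack$markers)))
  utils::write.csv(cells, file.path(dir, "cells.csv"), row.names = FALSE)
  jsonlite::write_json(list(markers = stack$markers, n_cells = n,
                            crop = crop_size()),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname stack_write
#' @export
stack_read <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  C <- length(meta$markers); n <- meta$n_cells; p <- crop_size()
  pages <- tiff::readTIFF(file.path(dir, "images.tif"), all = TRUE)
  mpages <- tiff::readTIFF(file.path(dir, "masks.tif"), all = TRUE)
  data <- array(0L, dim = c(p, p, C, n))
  for (k in seq_along(pages)) {
    i <- (k - 1L) %/% C + 1L; c <- (k - 1L) %% C + 1L
    data[, , c, i] <- as.integer(round(pages[[k]] * 255))
  }
  mask <- array(FALSE, dim = c(p, p, n))
  for (i in seq_len(n)) mask[, , i] <- mpages[[i]] > 0.5
  cells <- utils::read.csv(file.path(dir, "cells.csv"),
                           colClasses = c(cell_id = "character",
                                          core_id = "character",
                                          batch_id = "character"))
  cell_image_stack(data, mask, meta$markers, cell_id = cells$cell_id,
                   core_id = cells$core_id, batch_id = cells$batch_id)
}

#' Read a multichannel image and its marker panel
#'
#' Reads a multi-page TIFF (one page per marker channel, 8- or 16-bit)
#' into an `H x W x C` array scaled back to raw integer intensities, and
#' a marker-panel CSV with columns `marker` (required) and optionally
#' `cycle`, `channel_index`.
#'
#' @param image_path multi-page TIFF path.
#' @param panel_path CSV path.
#' @return list with `channels` (array) and `panel` (data.frame).
#' @export
read_multichannel <- function(image_path, panel_path = NULL) {
  pages <- tiff::readTIFF(image_path, all = TRUE, as.is = TRUE)
  channels <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (i in seq_along(pages)) channels[, , i] <- pages[[i]]
  panel <- NULL
  if (!is.null(panel_path)) {
    panel <- utils::read.csv(panel_path)
    if (!"marker" %in% names(panel)) stop("panel CSV needs a 'marker' column")
    if ("channel_index" %in% names(panel))
      panel <- panel[order(panel$channel_index), , drop = FALSE]
    if (nrow(panel) != length(pages))
      stop("panel rows do not match image pages")
  }
  list(channels = channels, panel = panel)
}

#' Read an integer-label segmentation mask TIFF
#' @param path TIFF path (single page, integer labels).
#' @return integer matrix.
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  m
}
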