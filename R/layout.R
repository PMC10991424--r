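#' Channel-to-grid layout
#'
#' The bijection between the `C` marker channels of a cell crop and the
#' tiles of a `g x g` single-channel mosaic, where `g = ceiling(sqrt(C))`.
#' Channels fill the grid row-major; the `g^2 - C` leftover slots are
#' zero-padding and are excluded from masking, loss and metrics.  A
#' 25-channel, 32-px crop therefore becomes a 160 x 160 mosaic.
#'
#' @param markers marker names (defines `C` and the channel order, which
#'   is part of the trained model's contract).
#' @param patch_size tile side in pixels (default 32).
#' @return object of class `"grid_layout"` with fields `markers`,
#'   `n_channels`, `patch_size`, `grid_side`, `slot_row`/`slot_col`
#'   (0-based tile coordinates per channel) and `pad_slots`.
#' @export
grid_layout <- function(markers, patch_size = crop_size()) {
  C <- length(markers)
  stopifnot(C >= 1)
  g <- ceiling(sqrt(C))
  i <- seq_len(C) - 1L
  structure(list(
    markers = markers, n_channels = C, patch_size = as.integer(patch_size),
    grid_side = as.integer(g),
    slot_row = as.integer(i %/% g), slot_col = as.integer(i %% g),
    pad_slots = as.integer(g^2 - C)
  ), class = "grid_layout")
}

#' @export
print.grid_layout <- function(x, ...) {
  cat(sprintf("<grid_layout> %d channels -> %dx%d grid of %d-px tiles (%d pad slots)\n",
              x$n_channels, x$grid_side, x$grid_side, x$patch_size, x$pad_slots))
  invisible(x)
}

#' Fold a multichannel crop into a single-channel tile mosaic
#'
#' @param crop numeric array `p x p x C`.
#' @param layout a [grid_layout()].
#' @return numeric matrix `(g*p) x (g*p)`; channel `i` occupies its tile,
#'   pad slots are zero.  Lossless (see [grid_to_channels()]).
#' @export
channels_to_grid <- function(crop, layout) {
  p <- layout$patch_size
  if (length(dim(crop)) != 3L || dim(crop)[1] != p || dim(crop)[2] != p ||
      dim(crop)[3] != layout$n_channels)
    stop("crop shape does not match the layout")
  g <- layout$grid_side
  out <- matrix(0, g * p, g * p)
  for (i in seq_len(layout$n_channels)) {
    r <- layout$slot_row[i] * p; c <- layout$slot_col[i] * p
    out[r + seq_len(p), c + seq_len(p)] <- crop[, , i]
  }
  out
}

#' Unfold a tile mosaic back into a multichannel crop
#'
#' Exact inverse of [channels_to_grid()] on its image; any non-zero
#' content in pad slots is discarded with a warning.
#'
#' @param grid numeric matrix `(g*p) x (g*p)`.
#' @param layout a [grid_layout()].
#' @return numeric array `p x p x C`.
#' @export
grid_to_channels <- function(grid, layout) {
  p <- layout$patch_size; g <- layout$grid_side
  if (!identical(dim(grid), c(g * p, g * p)))
    stop("grid shape does not match the layout")
  crop <- array(0, dim = c(p, p, layout$n_channels))
  used <- matrix(FALSE, g, g)
  for (i in seq_len(layout$n_channels)) {
    r <- layout$slot_row[i] * p; c <- layout$slot_col[i] * p
    crop[, , i] <- grid[r + seq_len(p), c + seq_len(p)]
    used[layout$slot_row[i] + 1L, layout$slot_col[i] + 1L] <- TRUE
  }
  if (layout$pad_slots > 0) {
    for (rr in seq_len(g)) for (cc in seq_len(g)) {
      if (!used[rr, cc] &&
          any(grid[(rr - 1) * p + seq_len(p), (cc - 1) * p + seq_len(p)] != 0)) {
        warning("non-zero content in pad slot discarded")
      }
    }
  }
  crop
}

new_mask_spec <- function(masked, C) {
  masked <- sort(unique(as.integer(masked)))
  if (length(masked) < 1 || length(masked) > C - 1)
    stop("between 1 and C-1 channels must be masked")
  if (any(masked < 1) || any(masked > C)) stop("channel index out of range")
  structure(list(
    masked = masked, unmasked = setdiff(seq_len(C), masked),
    n_channels = as.integer(C), ratio = length(masked) / C
  ), class = "mask_spec")
}

#' @export
print.mask_spec <- function(x, ...) {
  cat(sprintf("<mask_spec> %d of %d channels masked (ratio %.2f)\n",
              length(x$masked), x$n_channels, x$ratio))
  invisible(x)
}

round_half_up <- function(x) floor(x + 0.5)

#' Number of channels masked at a training ratio
#'
#' `clamp(round(ratio * C), 1, C - 1)` with round-half-up, so a 50% ratio
#' on 25 channels masks 13.
#'
#' @param C channel count; @param ratio masking ratio in (0, 1).
#' @return integer count.
#' @export
mask_count <- function(C, ratio) {
  if (ratio <= 0 || ratio >= 1) stop("ratio must lie in (0, 1)")
  as.integer(min(max(round_half_up(ratio * C), 1), C - 1))
}

#' Sample a random channel mask
#'
#' Draws a uniformly random subset of [mask_count()] channels to hide.
#' Every channel, DAPI included, is maskable during training.  Uses the
#' session RNG (seed it for reproducibility).
#'
#' @param C channel count; @param ratio masking ratio in (0, 1).
#' @return a `mask_spec`.
#' @export
sample_mask <- function(C, ratio) {
  m <- mask_count(C, ratio)
  new_mask_spec(sample.int(C, m), C)
}

#' Mask specification from a reduced marker panel
#'
#' The panel lists the markers that remain measured (unmasked); every
#' other marker is masked for imputation.  A 3-marker panel of 25 gives a
#' masking ratio of 0.88.
#'
#' @param panel character vector of measured marker names (a strict,
#'   non-empty subset of `markers`).
#' @param markers the full ordered marker panel.
#' @return a `mask_spec`.
#' @export
panel_to_mask <- function(panel, markers) {
  unknown <- setdiff(panel, markers)
  if (length(unknown))
    stop("unknown marker(s): ", paste(unknown, collapse = ", "))
  if (length(panel) < 1) stop("panel must contain at least one marker")
  if (length(unique(panel)) >= length(markers))
    stop("panel covers every marker; nothing to impute")
  new_mask_spec(which(!(markers %in% panel)), length(markers))
}
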