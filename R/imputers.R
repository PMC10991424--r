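#' Imputer interface
#'
#' Anything that can predict the masked channels of a cell stack from the
#' unmasked ones can drive panel selection and evaluation.  The fitted
#' [channel_mae()] is the primary implementation; [oracle_imputer()] and
#' [knn_imputer()] provide ground-truth and baseline implementations for
#' testing and comparison.  All imputers honour two contracts: unmasked
#' channels are returned bit-identical (pass-through) and predictions lie
#' in `[0, 255]`.
#'
#' @param imputer an imputer object.
#' @param stack a [cell_image_stack()].
#' @param mask a `mask_spec` (or supply `panel`).
#' @param panel measured-marker names, converted via [panel_to_mask()].
#' @param ... method-specific arguments.
#' @return integer array shaped like `stack$data` with a `"provenance"`
#'   attribute (`"measured"`/`"imputed"` per channel).
#' @export
impute <- function(imputer, stack, mask = NULL, panel = NULL, ...) {
  UseMethod("impute")
}

#' @export
impute.channel_mae <- function(imputer, stack, mask = NULL, panel = NULL, ...) {
  predict(imputer, stack, mask = mask, panel = panel, ...)
}

finalize_imputation <- function(raw, stack, mask) {
  C <- length(stack$markers)
  out <- stack$data
  for (ch in mask$masked) {
    v <- round(pmin(pmax(as.numeric(raw[, , ch, , drop = FALSE]), 0), 255))
    out[, , ch, ] <- as.integer(array(v, dim(out)[c(1, 2, 4)]))
  }
  prov <- rep("measured", C)
  prov[mask$masked] <- "imputed"
  names(prov) <- stack$markers
  attr(out, "provenance") <- prov
  out
}

#' Wrap a prediction function as an imputer
#'
#' @param markers marker panel the imputer understands.
#' @param predict_fn `function(stack, mask)` returning an array shaped
#'   like `stack$data` holding predictions for the masked channels
#'   (unmasked entries are ignored; the wrapper enforces pass-through and
#'   range clipping).
#' @return an object of classes `"fn_imputer"`, `"imputer"`.
#' @export
new_imputer <- function(markers, predict_fn) {
  structure(list(markers = markers, predict_fn = predict_fn),
            class = c("fn_imputer", "imputer"))
}

#' @export
impute.fn_imputer <- function(imputer, stack, mask = NULL, panel = NULL, ...) {
  if (!identical(stack$markers, imputer$markers))
    stop("stack markers do not match the imputer")
  if (!is.null(panel)) mask <- panel_to_mask(panel, stack$markers)
  if (!inherits(mask, "mask_spec") || mask$n_channels != length(stack$markers))
    stop("need a mask_spec over the imputer's channels")
  raw <- imputer$predict_fn(stack, mask)
  finalize_imputation(raw, stack, mask)
}

#' Perfect-oracle imputer
#'
#' Returns the held-out channels' true pixel content (from a reference
#' stack indexed by cell id).  With it, every imputation is exact — the
#' degenerate upper bound used to validate selection and evaluation
#' machinery.
#'
#' @param truth_stack the reference `cell_stack` holding the true images.
#' @return an imputer.
#' @export
oracle_imputer <- function(truth_stack) {
  new_imputer(truth_stack$markers, function(stack, mask) {
    idx <- match(stack$cell_id, truth_stack$cell_id)
    if (anyNA(idx)) stop("oracle has no truth for some cells")
    truth_stack$data[, , , idx, drop = FALSE]
  })
}

#' k-nearest-neighbour baseline imputer
#'
#' Non-parametric reference implementation of the imputer contract: a
#' query cell's masked channels are predicted as the pixelwise average of
#' the corresponding channels of its `k` nearest training cells, where
#' proximity is Euclidean distance between the unmasked within-mask mean-
#' intensity profiles.  Slow and crude, but assumption-free — useful as an
#' independent competent imputer in tests of the selection algorithm.
#'
#' @param train_stack training `cell_stack`.
#' @param k neighbours to average.
#' @return an imputer.
#' @export
knn_imputer <- function(train_stack, k = 5) {
  tr_means <- mean_intensities(train_stack)
  new_imputer(train_stack$markers, function(stack, mask) {
    q <- mean_intensities(stack)[, mask$unmasked, drop = FALSE]
    r <- tr_means[, mask$unmasked, drop = FALSE]
    n <- nrow(q)
    kk <- min(k, nrow(r))
    out <- array(0, dim = dim(stack$data))
    d2 <- outer(rowSums(q^2), rep(1, nrow(r))) - 2 * q %*% t(r) +
      outer(rep(1, n), rowSums(r^2))
    for (i in seq_len(n)) {
      nb <- order(d2[i, ])[seq_len(kk)]
      out[, , , i] <- rowMeans(train_stack$data[, , , nb, drop = FALSE],
                               dims = 3)
    }
    out
  })
}
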