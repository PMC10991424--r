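#' Configuration of the channel-wise masked autoencoder
#'
#' Hyperparameters of the ViT encoder/decoder pair.  The defaults are the
#' full-scale settings (1024/512 embedding dimensions, 8 heads, 6 layers,
#' 2048-unit MLP, 50% training masking ratio, Adam at 1e-3, 300 epochs at
#' batch 4096) used for real tissue-microarray data; tests and examples
#' shrink them to desk scale.
#'
#' @param enc_embed_dim,dec_embed_dim token embedding dimensions of the
#'   encoder and decoder (must be divisible by `heads` and by 4, for the
#'   two-dimensional sin/cos positional code).
#' @param heads attention heads; @param layers transformer blocks in each
#'   of encoder and decoder; @param mlp_dim hidden width of the block MLPs.
#' @param patch_size tile side in pixels (one channel = one 32x32 tile).
#' @param train_mask_ratio fraction of channels hidden per sample during
#'   training (strictly between 0 and 1).
#' @param epochs,batch_size,learning_rate Adam training schedule.
#' @param schedule `"constant"` (default) or `"cosine"` learning-rate decay.
#' @param warmup_epochs epochs of linear learning-rate warmup from 0
#'   before the schedule takes over (0 disables).
#' @param clip_norm global gradient-norm clipping threshold (`Inf`
#'   disables); stabilises short high-learning-rate runs.
#' @param seed integer seed controlling initialization, masking and
#'   shuffling; training is bit-reproducible in it.
#' @return an object of class `"mae_config"`.
#' @export
mae_config <- function(enc_embed_dim = 1024, dec_embed_dim = 512,
                       heads = 8, layers = 6, mlp_dim = 2048,
                       patch_size = crop_size(), train_mask_ratio = 0.5,
                       epochs = 300, batch_size = 4096,
                       learning_rate = 1e-3, schedule = c("constant", "cosine"),
                       warmup_epochs = 0, clip_norm = 1,
                       seed = 1L) {
  schedule <- match.arg(schedule)
  if (enc_embed_dim %% heads != 0 || dec_embed_dim %% heads != 0)
    stop("embedding dimensions must be divisible by the number of heads")
  if (enc_embed_dim %% 4 != 0 || dec_embed_dim %% 4 != 0)
    stop("embedding dimensions must be divisible by 4")
  if (train_mask_ratio <= 0 || train_mask_ratio >= 1)
    stop("train_mask_ratio must lie strictly between 0 and 1")
  structure(list(
    enc_embed_dim = as.integer(enc_embed_dim),
    dec_embed_dim = as.integer(dec_embed_dim),
    heads = as.integer(heads), layers = as.integer(layers),
    mlp_dim = as.integer(mlp_dim), patch_size = as.integer(patch_size),
    train_mask_ratio = train_mask_ratio, epochs = as.integer(epochs),
    batch_size = as.integer(batch_size), learning_rate = learning_rate,
    schedule = schedule, warmup_epochs = as.integer(warmup_epochs),
    clip_norm = clip_norm, seed = as.integer(seed)
  ), class = "mae_config")
}

stack_to_pixels <- function(stack) {
  C <- length(stack$markers)
  n <- n_cells(stack)
  t(matrix(as.numeric(stack$data) / 255, crop_size()^2, C * n))
}

sample_batch_masks <- function(B, C, m) {
  M <- do.call(rbind, lapply(seq_len(B), function(i) sort(sample.int(C, m))))
  U <- do.call(rbind, lapply(seq_len(B), function(i) setdiff(seq_len(C), M[i, ])))
  list(U = U, M = M)
}

#' Fit a channel-wise masked autoencoder to a single-cell image stack
#'
#' Self-supervised training: each cell's `C` marker channels become the
#' `C` tiles of a vision-transformer grid; for every sample a random
#' subset of channels (a fixed fraction, round-half-up, clamped to
#' `[1, C-1]`) is hidden; the encoder sees only the surviving tiles, a
#' learned mask token stands in for the hidden ones at the decoder input,
#' and the decoder reconstructs them.  The loss is mean squared error on
#' the masked tiles only, with pixel intensities normalised to `[0, 1]`.
#' Optimisation is plain Adam.
#'
#' Channel identity is carried purely by tile position (fixed 2-D sin/cos
#' positional codes), so the marker order is part of the fitted model and
#' is stored with it.
#'
#' @param stack training [cell_image_stack()].
#' @param config a [mae_config()].
#' @param verbose print the per-epoch masked-tile loss.
#' @return an object of class `"channel_mae"`: parameters, config, the
#'   [grid_layout()], marker names and the per-epoch training `loss` log.
#' @seealso [predict.channel_mae()], [masked_loss()]
#' @export
channel_mae <- function(stack, config = mae_config(), verbose = FALSE) {
  stopifnot(inherits(stack, "cell_stack"), inherits(config, "mae_config"))
  n <- n_cells(stack)
  if (n < 1) stop("empty training stack")
  C <- length(stack$markers)
  if (C < 2) stop("need at least 2 channels to mask")
  layout <- grid_layout(stack$markers, config$patch_size)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  P <- init_mae_params(config, layout)
  pos_e <- sincos_pos_table(layout, config$enc_embed_dim)
  pos_d <- sincos_pos_table(layout, config$dec_embed_dim)
  pix <- stack_to_pixels(stack)
  m <- mask_count(C, config$train_mask_ratio)
  st <- adam_init(P)
  bs <- min(config$batch_size, n)
  loss_log <- numeric(config$epochs)

  wu <- config$warmup_epochs %||% 0L
  clip <- config$clip_norm %||% Inf
  for (ep in seq_len(config$epochs)) {
    lr <- if (config$schedule == "cosine")
      config$learning_rate * 0.5 *
        (1 + cos(pi * max(ep - 1 - wu, 0) / max(config$epochs - wu, 1)))
    else config$learning_rate
    if (wu > 0 && ep <= wu) lr <- config$learning_rate * ep / (wu + 1)
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1, n, by = bs)) {
      cells <- ord[start:min(start + bs - 1, n)]
      B <- length(cells)
      rows <- rep((cells - 1L) * C, each = C) + rep(seq_len(C), B)
      bpix <- pix[rows, , drop = FALSE]
      mk <- sample_batch_masks(B, C, m)
      fw <- mae_forward(P, config, pos_e, pos_d, bpix, mk$U, mk$M)
      bw <- mae_backward(P, config, fw, bpix, mk$M)
      g <- if (is.finite(clip)) clip_grads(bw$grads, clip) else bw$grads
      up <- adam_step(P, g, st, lr)
      P <- up$P; st <- up$state
      losses <- c(losses, bw$loss)
    }
    loss_log[ep] <- mean(losses)
    if (verbose)
      message(sprintf("epoch %3d  masked-tile MSE %.6f", ep, loss_log[ep]))
  }

  structure(list(
    params = P, config = config, layout = layout,
    markers = stack$markers, pos_e = pos_e, pos_d = pos_d,
    loss = loss_log, n_train = n
  ), class = "channel_mae")
}

#' @export
print.channel_mae <- function(x, ...) {
  cat(sprintf("<channel_mae> %d channels, enc %d / dec %d dims, %d heads, %d layers\n",
              x$layout$n_channels, x$config$enc_embed_dim,
              x$config$dec_embed_dim, x$config$heads, x$config$layers))
  cat(sprintf("  trained %d epochs on %d cells; final masked-tile MSE %.5f\n",
              x$config$epochs, x$n_train, utils::tail(x$loss, 1)))
  cat("  markers:", paste(x$markers, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.channel_mae <- function(object, ...) {
  npar <- sum(rapply(object$params, length, how = "unlist"))
  cat("Channel-wise masked autoencoder\n")
  print(object)
  cat(sprintf("  parameters: %d   training mask ratio: %.2f (%d of %d channels)\n",
              npar, object$config$train_mask_ratio,
              mask_count(object$layout$n_channels, object$config$train_mask_ratio),
              object$layout$n_channels))
  invisible(object)
}

#' Plot the training loss curve
#' @param x a fitted `channel_mae`; @param ... passed to [graphics::plot()].
#' @export
plot.channel_mae <- function(x, ...) {
  graphics::plot(seq_along(x$loss), x$loss, type = "l",
                 xlab = "epoch", ylab = "masked-tile MSE", ...)
  invisible(x)
}

resolve_mask <- function(model, mask, panel = NULL) {
  if (!is.null(panel)) mask <- panel_to_mask(panel, model$markers)
  if (!inherits(mask, "mask_spec")) stop("need a mask_spec or a panel")
  if (mask$n_channels != model$layout$n_channels)
    stop("mask channel count does not match the model")
  mask
}

mae_predict_pixels <- function(model, stack, mask, chunk = 512L) {
  C <- model$layout$n_channels
  if (!identical(stack$markers, model$markers))
    stop("stack markers do not match the model (channel order is part of the model)")
  n <- n_cells(stack)
  pix <- stack_to_pixels(stack)
  U <- matrix(mask$unmasked, 1, length(mask$unmasked))
  M <- matrix(mask$masked, 1, length(mask$masked))
  pred <- matrix(0, n * C, crop_size()^2)
  for (start in seq(1, n, by = chunk)) {
    cells <- start:min(start + chunk - 1, n)
    B <- length(cells)
    rows <- rep((cells - 1L) * C, each = C) + rep(seq_len(C), B)
    fw <- mae_forward(model$params, model$config, model$pos_e, model$pos_d,
                      pix[rows, , drop = FALSE],
                      U[rep(1, B), , drop = FALSE], M[rep(1, B), , drop = FALSE])
    pred[rows, ] <- fw$pred
  }
  pred
}

#' Impute masked channels of a stack
#'
#' Runs the fitted autoencoder on every cell: measured (unmasked) channels
#' are passed through bit-identically; masked channels are replaced by the
#' model's reconstruction, clipped to `[0, 255]`.
#'
#' @param object a fitted `channel_mae`.
#' @param stack a `cell_stack` over the same marker panel (channel order
#'   must match).
#' @param mask a `mask_spec`, or use `panel` instead.
#' @param panel character vector of measured markers (converted via
#'   [panel_to_mask()]).
#' @param ... unused.
#' @return integer array with the dimensions of `stack$data`; attribute
#'   `"provenance"` marks each channel `"measured"` or `"imputed"`.
#' @export
predict.channel_mae <- function(object, stack, mask = NULL, panel = NULL, ...) {
  mask <- resolve_mask(object, mask, panel)
  C <- object$layout$n_channels
  n <- n_cells(stack)
  pred <- mae_predict_pixels(object, stack, mask)
  out <- stack$data  # pass-through for unmasked channels
  p <- crop_size()
  for (ch in mask$masked) {
    rows <- (seq_len(n) - 1L) * C + ch
    vals <- round(pmin(pmax(pred[rows, , drop = FALSE] * 255, 0), 255))
    out[, , ch, ] <- as.integer(t(vals))
  }
  prov <- rep("measured", C)
  prov[mask$masked] <- "imputed"
  names(prov) <- object$markers
  attr(out, "provenance") <- prov
  out
}

#' Masked-tile reconstruction loss of a fitted model
#'
#' Mean squared error, on `[0, 1]`-normalised pixels, between the model's
#' reconstruction and the target — computed over the masked tiles only,
#' which is the training objective.  `target_data` defaults to the stack's
#' own intensities; supplying a modified target shows that unmasked tiles
#' never enter the loss.
#'
#' @param model a fitted `channel_mae`.
#' @param stack a `cell_stack`; @param mask a `mask_spec`.
#' @param target_data optional replacement target array, same shape as
#'   `stack$data`.
#' @return scalar loss.
#' @export
masked_loss <- function(model, stack, mask, target_data = stack$data) {
  mask <- resolve_mask(model, mask)
  C <- model$layout$n_channels
  n <- n_cells(stack)
  pred <- mae_predict_pixels(model, stack, mask)
  tgt <- t(matrix(as.numeric(target_data) / 255, crop_size()^2, C * n))
  rows <- rep((seq_len(n) - 1L) * C, times = length(mask$masked)) +
    rep(mask$masked, each = n)
  mean((pred[rows, ] - tgt[rows, ])^2)
}

#' Save / load a fitted model checkpoint
#'
#' The checkpoint is a single file containing the parameters, the
#' configuration, the channel-grid layout and the marker names, so a
#' reloaded model is usable (and produces identical output) without any
#' other context.
#'
#' @param model a `channel_mae`; @param path checkpoint file path.
#' @return `mae_load` returns the model; `mae_save` the path, invisibly.
#' @export
mae_save <- function(model, path) {
  stopifnot(inherits(model, "channel_mae"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname mae_save
#' @export
mae_load <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "channel_mae"))
  model
}
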