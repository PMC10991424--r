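# Shared fixtures, all generated in code.  Expensive objects (the trained
# tiny autoencoder) are built once per test run and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .cache)) assign(key, builder(), envir = .cache)
  get(key, envir = .cache)
}

# A fast, small synthetic dataset for structural tests.
small_sim <- function() cached("small_sim", function() {
  generate_stack(synthetic_spec(n_cells = 80, seed = 42, noise_sd = 0))
})

tiny_mae_config <- function(epochs = 30, seed = 5, batch_size = 32,
                            train_mask_ratio = 0.5) {
  mae_config(enc_embed_dim = 32, dec_embed_dim = 16, heads = 2, layers = 2,
             mlp_dim = 128, train_mask_ratio = train_mask_ratio,
             epochs = epochs, batch_size = batch_size,
             learning_rate = 2e-3, seed = seed)
}

# Evaluation panel at the trained 50% masking ratio: the informative pair
# plus one redundant marker (3 of 6 channels measured).
study_panel <- function(sim) c(sim$truth$informative, "PanCK")

micro_mae_config <- function(epochs = 3, seed = 9) {
  mae_config(enc_embed_dim = 16, dec_embed_dim = 8, heads = 2, layers = 1,
             mlp_dim = 24, train_mask_ratio = 0.5, epochs = epochs,
             batch_size = 64, learning_rate = 1e-3, seed = seed)
}

# The desk-scale study setup: 2000 noiseless rank-2 cells, 90/5/5 split,
# tiny autoencoder trained 30 epochs.
study_data <- function() cached("study_data", function() {
  sim <- generate_stack(synthetic_spec(n_cells = 2000, seed = 11, noise_sd = 0))
  splits <- split_dataset(sim$stack, c(0.9, 0.05, 0.05), seed = 2)
  list(sim = sim, splits = splits)
})

study_model <- function() cached("study_model", function() {
  channel_mae(study_data()$splits$train, tiny_mae_config())
})

# A quicker, weaker model for contract tests that only need "a fitted model".
quick_model <- function() cached("quick_model", function() {
  sim <- small_sim()
  channel_mae(sim$stack, micro_mae_config(epochs = 4))
})

# A labelled multichannel image containing ellipse "cells" for crop tests.
# Returns list(channels HxWxC, labels HxW, markers).
ellipse_scene <- function(angles_deg = c(0, 37), H = 96, W = 96) {
  C <- 2
  markers <- c("DAPI", "CD45")
  channels <- array(0, dim = c(H, W, C))
  labels <- matrix(0L, H, W)
  centers <- list(c(30, 30), c(30, 66))
  xs <- matrix(rep(seq_len(W), each = H), H, W)
  ys <- matrix(rep(seq_len(H), times = W), H, W)
  for (k in seq_along(angles_deg)) {
    th <- angles_deg[k] * pi / 180
    cy <- centers[[k]][1]; cx <- centers[[k]][2]
    xr <- cos(th) * (xs - cx) + sin(th) * (ys - cy)
    yr <- -sin(th) * (xs - cx) + cos(th) * (ys - cy)
    inside <- (xr / 10)^2 + (yr / 5)^2 <= 1
    labels[inside] <- k
    nuc <- (xr / 6)^2 + (yr / 3.5)^2 <= 1
    channels[, , 1][nuc] <- 200
    channels[, , 2][inside] <- 60 + 20 * k
  }
  list(channels = channels, labels = labels, markers = markers)
}

# Second-moment orientation (degrees in [-90, 90]) of a binary mask.
mask_orientation_deg <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  dy <- idx[, 1] - mean(idx[, 1]); dx <- idx[, 2] - mean(idx[, 2])
  0.5 * atan2(2 * mean(dx * dy), mean(dx^2) - mean(dy^2)) * 180 / pi
}

mask_com <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  c(row = mean(idx[, 1]), col = mean(idx[, 2]))
}

# Hand oracle: Spearman as Pearson of average ranks.
spearman_by_hand <- function(x, y) {
  stats::cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
}

# Loading matrix in which the second latent factor is private to CD45:
# every panel that omits CD45 leaves it unpredictable, so {DAPI, CD45}
# is the uniquely optimal pair, not merely one of several spanning pairs.
recovery_loading <- function() {
  L <- rbind(c(0.20, 0), c(0, 0.20), c(0.16, 0),
             c(0.13, 0), c(0.10, 0), c(0.18, 0))
  rownames(L) <- c("DAPI", "CD45", "M3", "M4", "M5", "M6")
  L
}

recovery_spec <- function(seed) {
  synthetic_spec(n_cells = 1000, markers = rownames(recovery_loading()),
                 loading_matrix = recovery_loading(), noise_sd = 2,
                 seed = seed)
}
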