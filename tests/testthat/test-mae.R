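test_that("configuration invariants are enforced", {
  expect_error(mae_config(enc_embed_dim = 30, heads = 4), "divisible")
  expect_error(mae_config(train_mask_ratio = 0), "between")
  expect_error(mae_config(train_mask_ratio = 1), "between")
  cfg <- mae_config()
  expect_equal(cfg$enc_embed_dim, 1024L)
  expect_equal(cfg$dec_embed_dim, 512L)
  expect_equal(cfg$heads, 8L)
  expect_equal(cfg$layers, 6L)
  expect_equal(cfg$mlp_dim, 2048L)
  expect_equal(cfg$train_mask_ratio, 0.5)
})

test_that("analytic gradients match central finite differences", {
  ns <- asNamespace("panelmae")
  set.seed(42)
  cfg <- mae_config(enc_embed_dim = 8, dec_embed_dim = 8, heads = 2,
                    layers = 1, mlp_dim = 12, train_mask_ratio = 0.5,
                    epochs = 1, batch_size = 4, seed = 1)
  layout <- grid_layout(paste0("M", 1:4))
  P <- ns$init_mae_params(cfg, layout)
  pe <- ns$sincos_pos_table(layout, 8)
  pd <- ns$sincos_pos_table(layout, 8)
  B <- 3; C <- 4
  pix <- matrix(runif(B * C * 1024), B * C, 1024)
  U <- t(vapply(seq_len(B), function(i) sort(sample.int(C, 2)), integer(2)))
  M <- t(vapply(seq_len(B), function(i) setdiff(seq_len(C), U[i, ]), integer(2)))
  flat <- unlist(P)
  lossfn <- function(v) {
    Pp <- utils::relist(v, P)
    ns$mae_backward(Pp, cfg, ns$mae_forward(Pp, cfg, pe, pd, pix, U, M),
                    pix, M)$loss
  }
  align <- function(g, p) {
    if (is.list(p)) {
      if (!is.null(names(p))) g <- g[names(p)]
      Map(align, g, p)
    } else g
  }
  fw <- ns$mae_forward(P, cfg, pe, pd, pix, U, M)
  G <- ns$mae_backward(P, cfg, fw, pix, M)$grads
  gflat <- unlist(align(G[names(P)], P))
  set.seed(7)
  idx <- sample(length(flat), 50)
  eps <- 1e-5
  num <- vapply(idx, function(i) {
    vp <- flat; vp[i] <- vp[i] + eps
    vm <- flat; vm[i] <- vm[i] - eps
    (lossfn(vp) - lossfn(vm)) / (2 * eps)
  }, numeric(1))
  err <- abs(num - gflat[idx]) / pmax(abs(num) + abs(gflat[idx]), 1e-6)
  expect_lt(max(err), 1e-4)
})

test_that("training reduces the masked-tile loss and is seed-reproducible", {
  sim <- small_sim()
  m1 <- channel_mae(sim$stack, micro_mae_config(epochs = 4, seed = 9))
  expect_lt(tail(m1$loss, 1), m1$loss[1])
  m2 <- channel_mae(sim$stack, micro_mae_config(epochs = 4, seed = 9))
  expect_identical(m1$loss, m2$loss)
  expect_identical(m1$params, m2$params)
  m3 <- channel_mae(sim$stack, micro_mae_config(epochs = 4, seed = 10))
  expect_false(identical(tail(m1$loss, 1), tail(m3$loss, 1)))
})

test_that("imputation passes unmasked channels through bit-exact and stays in range", {
  model <- quick_model()
  sim <- small_sim()
  st <- sim$stack[1:10]
  ms <- panel_to_mask(c("DAPI", "CD45", "PanCK", "CD3", "Ki67"), st$markers)
  out <- predict(model, st, mask = ms)
  for (ch in ms$unmasked)
    expect_identical(out[, , ch, ], st$data[, , ch, ])
  expect_true(all(out >= 0L & out <= 255L))
  prov <- attr(out, "provenance")
  expect_equal(unname(prov[ms$masked]), rep("imputed", length(ms$masked)))
  expect_equal(unname(prov[ms$unmasked]), rep("measured", length(ms$unmasked)))

  # all-zero input: outputs finite and in range
  z <- st
  z$data[] <- 0L
  outz <- predict(model, z, mask = ms)
  expect_true(all(is.finite(outz)))
  expect_true(all(outz >= 0L & outz <= 255L))

  wrong <- panel_to_mask("A", c("A", "B"))
  expect_error(predict(model, st, mask = wrong), "channel count")
})

test_that("the loss is computed on masked tiles only", {
  model <- quick_model()
  st <- small_sim()$stack[1:12]
  ms <- panel_to_mask(c("DAPI", "CD45", "PanCK"), st$markers)
  base <- masked_loss(model, st, ms)
  # zero an UNMASKED channel's target: loss identical
  tgt <- st$data
  tgt[, , ms$unmasked[1], ] <- 0L
  expect_identical(masked_loss(model, st, ms, target_data = tgt), base)
  # zero a MASKED channel's target: loss changes
  tgt2 <- st$data
  tgt2[, , ms$masked[1], ] <- 0L
  expect_false(isTRUE(all.equal(masked_loss(model, st, ms, target_data = tgt2),
                                base)))
})

test_that("channel order is part of the model contract", {
  model <- quick_model()
  sim <- small_sim()
  st <- sim$stack
  st$markers <- rev(st$markers)
  expect_error(predict(model, st, panel = c("DAPI", "CD45")), "channel order")
})

test_that("permuting channels of data and layout together trains equivalently", {
  sim <- small_sim()
  st <- sim$stack
  perm <- c(3L, 1L, 6L, 2L, 5L, 4L)
  stp <- st
  stp$data <- st$data[, , perm, , drop = FALSE]
  stp$markers <- st$markers[perm]
  m1 <- channel_mae(st, micro_mae_config(epochs = 4, seed = 9))
  m2 <- channel_mae(stp, micro_mae_config(epochs = 4, seed = 9))
  l1 <- tail(m1$loss, 1); l2 <- tail(m2$loss, 1)
  expect_lt(abs(l1 - l2) / ((l1 + l2) / 2), 0.5)
})

test_that("a checkpoint round-trips and reproduces predictions exactly", {
  model <- quick_model()
  st <- small_sim()$stack[1:5]
  path <- withr::local_tempfile(fileext = ".ckpt")
  mae_save(model, path)
  model2 <- mae_load(path)
  ms <- panel_to_mask(c("DAPI", "CD45"), st$markers)
  expect_identical(predict(model, st, mask = ms), predict(model2, st, mask = ms))
  expect_identical(model2$markers, model$markers)
})

test_that("the trained tiny model imputes held-out markers well on noiseless rank-2 data", {
  sd <- study_data()
  model <- study_model()
  rep <- evaluate_panel(model, sd$splits$test, study_panel(sd$sim))
  expect_gte(mean(rep$spearman >= 0.8), 0.8)
  expect_gte(rep$mean_rho, 0.8)
})
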