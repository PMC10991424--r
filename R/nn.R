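# Compact vision-transformer building blocks (forward + analytic backward)
# used by the channel-wise masked autoencoder.  Token activations are kept
# as plain matrices of shape (batch * tokens, dim), rows ordered
# sample-major, so all dense algebra runs through BLAS; attention loops
# only over the (small) token count, never over the batch.

ln_eps <- 1e-6

add_bias <- function(X, b) X + matrix(b, nrow(X), length(b), byrow = TRUE)

linear_fwd <- function(X, W, b) {
  list(Y = add_bias(X %*% W, b), X = X)
}
linear_bwd <- function(dY, cache, W) {
  list(dX = dY %*% t(W), dW = crossprod(cache$X, dY), db = colSums(dY))
}

layernorm_fwd <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + ln_eps)
  xh <- xc * inv
  list(Y = add_bias(xh * matrix(g, nrow(X), length(g), byrow = TRUE), b),
       xh = xh, inv = inv)
}
layernorm_bwd <- function(dY, cache, g) {
  xh <- cache$xh
  dxh <- dY * matrix(g, nrow(dY), length(g), byrow = TRUE)
  dX <- cache$inv * (dxh - rowMeans(dxh) - xh * rowMeans(dxh * xh))
  list(dX = dX, dg = colSums(dY * xh), db = colSums(dY))
}

gelu_fwd <- function(X) {
  Phi <- stats::pnorm(X)
  list(Y = X * Phi, X = X, Phi = Phi)
}
gelu_bwd <- function(dY, cache) {
  dY * (cache$Phi + cache$X * stats::dnorm(cache$X))
}

# Multi-head self-attention over T tokens per sample.
attn_fwd <- function(X, p, B, T, H) {
  D <- ncol(X)
  dh <- D %/% H
  scale <- 1 / sqrt(dh)
  Q <- add_bias(X %*% p$Wq, p$bq)
  K <- add_bias(X %*% p$Wk, p$bk)
  V <- add_bias(X %*% p$Wv, p$bv)
  rep_g <- rep(seq_len(B), each = T)          # sample of each row
  tok_rows <- function(j) (seq_len(B) - 1L) * T + j
  O <- matrix(0, nrow(X), D)
  Plist <- vector("list", H)
  for (h in seq_len(H)) {
    ch <- (h - 1L) * dh + seq_len(dh)
    Qh <- Q[, ch, drop = FALSE]
    S <- matrix(0, nrow(X), T)
    for (j in seq_len(T)) {
      Kj <- K[tok_rows(j), ch, drop = FALSE][rep_g, , drop = FALSE]
      S[, j] <- rowSums(Qh * Kj) * scale
    }
    S <- S - apply(S, 1, max)
    E <- exp(S)
    Pw <- E / rowSums(E)
    Oh <- matrix(0, nrow(X), dh)
    for (j in seq_len(T)) {
      Vj <- V[tok_rows(j), ch, drop = FALSE][rep_g, , drop = FALSE]
      Oh <- Oh + Pw[, j] * Vj
    }
    O[, ch] <- Oh
    Plist[[h]] <- Pw
  }
  Y <- add_bias(O %*% p$Wo, p$bo)
  list(Y = Y, X = X, Q = Q, K = K, V = V, O = O, Plist = Plist)
}

attn_bwd <- function(dY, cache, p, B, T, H) {
  X <- cache$X
  D <- ncol(X)
  dh <- D %/% H
  scale <- 1 / sqrt(dh)
  rep_g <- rep(seq_len(B), each = T)
  tok_rows <- function(j) (seq_len(B) - 1L) * T + j
  dO <- dY %*% t(p$Wo)
  dWo <- crossprod(cache$O, dY)
  dbo <- colSums(dY)
  dQ <- matrix(0, nrow(X), D); dK <- matrix(0, nrow(X), D)
  dV <- matrix(0, nrow(X), D)
  for (h in seq_len(H)) {
    ch <- (h - 1L) * dh + seq_len(dh)
    Pw <- cache$Plist[[h]]
    dOh <- dO[, ch, drop = FALSE]
    Qh <- cache$Q[, ch, drop = FALSE]
    dP <- matrix(0, nrow(X), T)
    for (j in seq_len(T)) {
      Vj <- cache$V[tok_rows(j), ch, drop = FALSE][rep_g, , drop = FALSE]
      dP[, j] <- rowSums(dOh * Vj)
      dV[tok_rows(j), ch] <- dV[tok_rows(j), ch] +
        rowsum(Pw[, j] * dOh, rep_g, reorder = TRUE)
    }
    dS <- Pw * (dP - rowSums(dP * Pw))
    dQh <- matrix(0, nrow(X), dh)
    for (j in seq_len(T)) {
      Kj <- cache$K[tok_rows(j), ch, drop = FALSE][rep_g, , drop = FALSE]
      dQh <- dQh + dS[, j] * Kj * scale
      dK[tok_rows(j), ch] <- dK[tok_rows(j), ch] +
        rowsum(dS[, j] * Qh * scale, rep_g, reorder = TRUE)
    }
    dQ[, ch] <- dQh
  }
  dX <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  list(dX = dX,
       dWq = crossprod(X, dQ), dbq = colSums(dQ),
       dWk = crossprod(X, dK), dbk = colSums(dK),
       dWv = crossprod(X, dV), dbv = colSums(dV),
       dWo = dWo, dbo = dbo)
}

# Pre-norm transformer block: x + attn(ln1(x)); then x + mlp(ln2(x))
block_fwd <- function(X, p, B, T, H) {
  l1 <- layernorm_fwd(X, p$ln1_g, p$ln1_b)
  at <- attn_fwd(l1$Y, p, B, T, H)
  X1 <- X + at$Y
  l2 <- layernorm_fwd(X1, p$ln2_g, p$ln2_b)
  f1 <- linear_fwd(l2$Y, p$W1, p$b1)
  gl <- gelu_fwd(f1$Y)
  f2 <- linear_fwd(gl$Y, p$W2, p$b2)
  list(Y = X1 + f2$Y, l1 = l1, at = at, X1 = X1, l2 = l2, f1 = f1,
       gl = gl, f2 = f2)
}

block_bwd <- function(dY, cache, p, B, T, H) {
  g <- list()
  b2 <- linear_bwd(dY, cache$f2, p$W2)
  g$W2 <- b2$dW; g$b2 <- b2$db
  dgl <- gelu_bwd(b2$dX, cache$gl)
  b1 <- linear_bwd(dgl, cache$f1, p$W1)
  g$W1 <- b1$dW; g$b1 <- b1$db
  l2 <- layernorm_bwd(b1$dX, cache$l2, p$ln2_g)
  g$ln2_g <- l2$dg; g$ln2_b <- l2$db
  dX1 <- dY + l2$dX
  ab <- attn_bwd(dX1, cache$at, p, B, T, H)
  g$Wq <- ab$dWq; g$bq <- ab$dbq; g$Wk <- ab$dWk; g$bk <- ab$dbk
  g$Wv <- ab$dWv; g$bv <- ab$dbv; g$Wo <- ab$dWo; g$bo <- ab$dbo
  l1 <- layernorm_bwd(ab$dX, cache$l1, p$ln1_g)
  g$ln1_g <- l1$dg; g$ln1_b <- l1$db
  list(dX = dX1 + l1$dX, grads = g)
}

# Xavier-uniform weight init, the ViT/MAE convention for linear maps.
xavier <- function(nr, nc) {
  a <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -a, a), nr, nc)
}

init_block <- function(D, M) {
  rn <- xavier
  list(ln1_g = rep(1, D), ln1_b = rep(0, D),
       Wq = rn(D, D), bq = rep(0, D), Wk = rn(D, D), bk = rep(0, D),
       Wv = rn(D, D), bv = rep(0, D), Wo = rn(D, D), bo = rep(0, D),
       ln2_g = rep(1, D), ln2_b = rep(0, D),
       W1 = rn(D, M), b1 = rep(0, M), W2 = rn(M, D), b2 = rep(0, D))
}

# Fixed 2-D sine/cosine positional embeddings over grid slots.
sincos_pos_table <- function(layout, D) {
  stopifnot(D %% 4 == 0)
  g <- layout$grid_side
  slots <- expand.grid(col = 0:(g - 1), row = 0:(g - 1))  # slot index row-major
  half <- D %/% 2
  emb1d <- function(pos, d) {
    omega <- 1 / 10000^((seq_len(d %/% 2) - 1) / (d %/% 2))
    ang <- outer(pos, omega)
    cbind(sin(ang), cos(ang))
  }
  cbind(emb1d(slots$row, half), emb1d(slots$col, half))
}

# Global-norm gradient clipping over a nested gradient list.
clip_grads <- function(G, max_norm) {
  sq <- function(g) if (is.list(g)) sum(vapply(g, sq, numeric(1))) else sum(g^2)
  nrm <- sqrt(sq(G))
  if (nrm <= max_norm) return(G)
  scale <- max_norm / nrm
  mul <- function(g) if (is.list(g)) lapply(g, mul) else g * scale
  mul(G)
}

# Nested-list SGD with adaptive moments; P, G, and the state share structure.
adam_init <- function(P) {
  zero <- function(x) if (is.list(x)) lapply(x, zero) else x * 0
  list(m = zero(P), v = zero(P), t = 0L)
}

adam_step <- function(P, G, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      if (!is.null(names(p))) g <- g[names(p)]
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mh <- m / (1 - beta1^st$t)
      vh <- v / (1 - beta2^st$t)
      list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
    }
  }
  out <- Map(walk, P, G[names(P)], st$m, st$v)
  list(P = lapply(out, `[[`, "p"),
       state = list(m = lapply(out, `[[`, "m"),
                    v = lapply(out, `[[`, "v"), t = st$t))
}

init_mae_params <- function(cfg, layout) {
  De <- cfg$enc_embed_dim; Dd <- cfg$dec_embed_dim
  npx <- cfg$patch_size^2
  rn <- xavier
  list(
    emb = list(W = rn(npx, De), b = rep(0, De)),
    enc = lapply(seq_len(cfg$layers), function(i) init_block(De, cfg$mlp_dim)),
    enorm = list(g = rep(1, De), b = rep(0, De)),
    proj = list(W = rn(De, Dd), b = rep(0, Dd)),
    mask_token = stats::rnorm(Dd, 0, 0.02),
    dec = lapply(seq_len(cfg$layers), function(i) init_block(Dd, cfg$mlp_dim)),
    dnorm = list(g = rep(1, Dd), b = rep(0, Dd)),
    head = list(W = rn(Dd, npx), b = rep(0, npx))
  )
}

# Full forward pass.  pix: (B*C x npx) normalized pixels, rows cell-major
# (cell 1 channels 1..C, ...).  U/M: B x u / B x m matrices of unmasked /
# masked channel indices per sample.  Returns predictions for all C slots
# plus the caches needed for the backward pass.
mae_forward <- function(P, cfg, pos_e, pos_d, pix, U, M) {
  B <- nrow(U); u <- ncol(U); m <- ncol(M)
  C <- u + m; H <- cfg$heads
  ch_enc <- as.vector(t(U))
  enc_rows <- rep((seq_len(B) - 1L) * C, each = u) + ch_enc
  E <- linear_fwd(pix[enc_rows, , drop = FALSE], P$emb$W, P$emb$b)
  X <- E$Y + pos_e[ch_enc, , drop = FALSE]
  enc_caches <- vector("list", cfg$layers)
  for (l in seq_len(cfg$layers)) {
    enc_caches[[l]] <- block_fwd(X, P$enc[[l]], B, u, H)
    X <- enc_caches[[l]]$Y
  }
  EN <- layernorm_fwd(X, P$enorm$g, P$enorm$b)
  PR <- linear_fwd(EN$Y, P$proj$W, P$proj$b)
  Dd <- cfg$dec_embed_dim
  ch_all <- rep(seq_len(C), B)
  Xd <- matrix(P$mask_token, B * C, Dd, byrow = TRUE) +
    pos_d[ch_all, , drop = FALSE]
  Xd[enc_rows, ] <- PR$Y + pos_d[ch_enc, , drop = FALSE]
  dec_caches <- vector("list", cfg$layers)
  for (l in seq_len(cfg$layers)) {
    dec_caches[[l]] <- block_fwd(Xd, P$dec[[l]], B, C, H)
    Xd <- dec_caches[[l]]$Y
  }
  DN <- layernorm_fwd(Xd, P$dnorm$g, P$dnorm$b)
  HD <- linear_fwd(DN$Y, P$head$W, P$head$b)
  list(pred = HD$Y, enc_rows = enc_rows, ch_enc = ch_enc,
       E = E, enc_caches = enc_caches, EN = EN, PR = PR,
       dec_caches = dec_caches, DN = DN, HD = HD, B = B, u = u, m = m, C = C)
}

# Loss (MSE over masked tiles only) + full gradient.
mae_backward <- function(P, cfg, fw, pix, M, target = pix) {
  B <- fw$B; C <- fw$C; m <- fw$m; H <- cfg$heads
  ch_m <- as.vector(t(M))
  rows_m <- rep((seq_len(B) - 1L) * C, each = m) + ch_m
  diff <- fw$pred[rows_m, , drop = FALSE] - target[rows_m, , drop = FALSE]
  loss <- mean(diff^2)
  dPred <- matrix(0, nrow(fw$pred), ncol(fw$pred))
  dPred[rows_m, ] <- 2 * diff / length(diff)

  G <- list()
  hb <- linear_bwd(dPred, fw$HD, P$head$W)
  G$head <- list(W = hb$dW, b = hb$db)
  dn <- layernorm_bwd(hb$dX, fw$DN, P$dnorm$g)
  G$dnorm <- list(g = dn$dg, b = dn$db)
  dXd <- dn$dX
  G$dec <- vector("list", cfg$layers)
  for (l in rev(seq_len(cfg$layers))) {
    bb <- block_bwd(dXd, fw$dec_caches[[l]], P$dec[[l]], B, C, H)
    G$dec[[l]] <- bb$grads
    dXd <- bb$dX
  }
  G$mask_token <- colSums(dXd[-fw$enc_rows, , drop = FALSE])
  dZ <- dXd[fw$enc_rows, , drop = FALSE]
  pb <- linear_bwd(dZ, fw$PR, P$proj$W)
  G$proj <- list(W = pb$dW, b = pb$db)
  en <- layernorm_bwd(pb$dX, fw$EN, P$enorm$g)
  G$enorm <- list(g = en$dg, b = en$db)
  dX <- en$dX
  G$enc <- vector("list", cfg$layers)
  for (l in rev(seq_len(cfg$layers))) {
    bb <- block_bwd(dX, fw$enc_caches[[l]], P$enc[[l]], B, fw$u, H)
    G$enc[[l]] <- bb$grads
    dX <- bb$dX
  }
  eb <- linear_bwd(dX, fw$E, P$emb$W)
  G$emb <- list(W = eb$dW, b = eb$db)
  list(loss = loss, grads = G)
}
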