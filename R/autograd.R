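# Reverse-mode gradients for the backbone. vit_backward consumes the cache
# produced by vit_forward(keep_cache = TRUE) and supports three gradient
# sources, used alone or together:
#   dscores : B x n_classes        (classification losses)
#   dA      : [[layer]][[head]] n x n x B   (losses on attention maps)
#   dZ      : [[layer]] (B*n) x (H_l*d_k)   (losses on head-output slices,
#             injected before the output projection W_o)
# Correctness is pinned by finite-difference checks in the test suite.

vit_backward <- function(model, fw, dscores = NULL, dA = NULL, dZ = NULL) {
  cfg <- model$config
  p <- model$params
  cache <- fw$cache
  if (is.null(cache)) stop("forward pass was run without keep_cache")
  mask <- cache$mask
  B <- cache$B
  n <- n_tokens(cfg); d <- cfg$embed_dim; dk <- cfg$head_dim
  sc <- 1 / sqrt(dk)
  g <- list()
  row_idx <- function(b) ((b - 1L) * n + 1L):(b * n)
  cls_rows <- (seq_len(B) - 1L) * n + 1L

  dlnf_y <- matrix(0, B * n, d)
  if (!is.null(dscores)) {
    g$head_W <- t(cache$feats) %*% dscores
    g$head_b <- colSums(dscores)
    dfeats <- dscores %*% t(p$head_W)
    if (cfg$use_cls_token) {
      dlnf_y[cls_rows, ] <- dfeats
    } else {
      dlnf_y <- dfeats[rep(seq_len(B), each = n), ] / n
    }
  }
  lb <- layernorm_bwd(dlnf_y, cache$lnf, p$lnf_g)
  g$lnf_g <- lb$dg; g$lnf_b <- lb$db
  dx <- lb$dx

  for (l in rev(seq_len(cfg$depth))) {
    lc <- cache$layers[[l]]
    H <- cfg$heads_per_layer[l]
    nm <- function(s) paste0("L", l, ".", s)
    W1 <- p[[nm("W1")]]; W2 <- p[[nm("W2")]]
    Wq <- p[[nm("Wq")]]; Wk <- p[[nm("Wk")]]; Wv <- p[[nm("Wv")]]
    Wo <- p[[nm("Wo")]]

    dmlp <- dx
    g[[nm("W2")]] <- t(lc$a1) %*% dmlp
    g[[nm("b2")]] <- colSums(dmlp)
    dh1 <- (dmlp %*% t(W2)) * gelu_grad(lc$h1)
    g[[nm("W1")]] <- t(lc$ln2$y) %*% dh1
    g[[nm("b1")]] <- colSums(dh1)
    l2 <- layernorm_bwd(dh1 %*% t(W1), lc$ln2, p[[nm("ln2_g")]])
    g[[nm("ln2_g")]] <- l2$dg; g[[nm("ln2_b")]] <- l2$db
    dx_mid <- dx + l2$dx

    g[[nm("Wo")]] <- t(lc$Zc) %*% dx_mid
    g[[nm("bo")]] <- colSums(dx_mid)
    dZc <- dx_mid %*% t(Wo)
    if (!is.null(dZ) && !is.null(dZ[[l]])) dZc <- dZc + dZ[[l]]
    dQ <- matrix(0, B * n, H * dk)
    dK <- matrix(0, B * n, H * dk)
    dV <- matrix(0, B * n, H * dk)
    for (h in seq_len(H)) {
      if (!mask[[l]][h]) next
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      Ah <- lc$A[[h]]
      dAh <- if (!is.null(dA) && !is.null(dA[[l]]) && !is.null(dA[[l]][[h]]))
        dA[[l]][[h]] else NULL
      for (b in seq_len(B)) {
        ri <- row_idx(b)
        A <- Ah[, , b]
        dZh <- dZc[ri, cols, drop = FALSE]
        dAb <- dZh %*% t(lc$V[ri, cols, drop = FALSE])
        if (!is.null(dAh)) dAb <- dAb + dAh[, , b]
        dV[ri, cols] <- dV[ri, cols, drop = FALSE] + t(A) %*% dZh
        dS <- A * (dAb - rowSums(dAb * A))
        dQ[ri, cols] <- (dS %*% lc$K[ri, cols, drop = FALSE]) * sc
        dK[ri, cols] <- (t(dS) %*% lc$Q[ri, cols, drop = FALSE]) * sc
      }
    }
    g[[nm("Wq")]] <- t(lc$ln1$y) %*% dQ; g[[nm("bq")]] <- colSums(dQ)
    g[[nm("Wk")]] <- t(lc$ln1$y) %*% dK; g[[nm("bk")]] <- colSums(dK)
    g[[nm("Wv")]] <- t(lc$ln1$y) %*% dV; g[[nm("bv")]] <- colSums(dV)
    dln1y <- dQ %*% t(Wq) + dK %*% t(Wk) + dV %*% t(Wv)
    l1 <- layernorm_bwd(dln1y, lc$ln1, p[[nm("ln1_g")]])
    g[[nm("ln1_g")]] <- l1$dg; g[[nm("ln1_b")]] <- l1$db
    dx <- dx_mid + l1$dx
  }

  g$pos <- rowsum(dx, rep(seq_len(n), B))
  dimnames(g$pos) <- NULL
  if (cfg$use_cls_token) {
    g$cls <- matrix(colSums(dx[cls_rows, , drop = FALSE]), 1L, d)
    demb <- dx[-cls_rows, , drop = FALSE]
  } else {
    demb <- dx
  }
  g$patch_W <- t(cache$Pmat) %*% demb
  g$patch_b <- colSums(demb)
  g
}

# Softmax cross-entropy over class scores; labels are 1-based integers.
# Returns mean loss and the gradient already divided by the batch size.
softmax_xent <- function(scores, labels) {
  B <- nrow(scores)
  m <- apply(scores, 1L, max)
  E <- exp(scores - m)
  Z <- rowSums(E)
  P <- E / Z
  picked <- scores[cbind(seq_len(B), labels)]
  loss <- mean(log(Z) + m - picked)
  dP <- P
  dP[cbind(seq_len(B), labels)] <- dP[cbind(seq_len(B), labels)] - 1
  list(loss = loss, dscores = dP / B, probs = P)
}
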