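# Tiny trainable ViT backbone. Parameters live in a flat named list so the
# optimizer, checkpoint IO and surgery can address them uniformly:
#   patch_W, patch_b, pos, cls, L<l>.{ln1_g,ln1_b,Wq,bq,Wk,bk,Wv,bv,Wo,bo,
#   ln2_g,ln2_b,W1,b1,W2,b2}, lnf_g, lnf_b, head_W, head_b
# Blocks are pre-norm with residuals and a GELU MLP. Q/K/V projections are
# stored as d x (H*d_k) matrices whose column blocks are the per-head
# projections; W_o is (H*d_k) x d with per-head row blocks.

LN_EPS <- 1e-6

layer_param_names <- c("ln1_g", "ln1_b", "Wq", "bq", "Wk", "bk", "Wv", "bv",
                       "Wo", "bo", "ln2_g", "ln2_b", "W1", "b1", "W2", "b2")

#' Initialize a ViT model
#'
#' Weights are drawn from N(0, 0.02^2) using the current RNG state, except
#' the query/key projections, which use sd `3 / sqrt(embed_dim)` so the
#' attention logits start at unit scale regardless of width (with layer-
#' normed inputs of norm `sqrt(d)`, logit variance is then O(1); a width-
#' independent sd would leave narrow models with near-uniform attention
#' that never specializes). Layer norm gains start at 1 and all biases at
#' 0. Call `set.seed()` beforehand for reproducible initialization.
#'
#' @param config A [model_config()].
#' @return An object of class `taha_model`: `list(config, params)`.
#' @export
init_model <- function(config) {
  d <- config$embed_dim
  dk <- config$head_dim
  n <- n_tokens(config)
  pd <- config$patch_size^2 * config$channels
  sd0 <- 0.02
  sd_qk <- 3 / sqrt(d)
  rmat <- function(r, c, sd = sd0) matrix(stats::rnorm(r * c, sd = sd), r, c)
  p <- list(
    patch_W = rmat(pd, d),
    patch_b = numeric(d),
    pos = rmat(n, d)
  )
  if (config$use_cls_token) p$cls <- rmat(1, d)
  for (l in seq_len(config$depth)) {
    H <- config$heads_per_layer[l]
    lp <- list(
      ln1_g = rep(1, d), ln1_b = numeric(d),
      Wq = rmat(d, H * dk, sd_qk), bq = numeric(H * dk),
      Wk = rmat(d, H * dk, sd_qk), bk = numeric(H * dk),
      Wv = rmat(d, H * dk), bv = numeric(H * dk),
      Wo = rmat(H * dk, d), bo = numeric(d),
      ln2_g = rep(1, d), ln2_b = numeric(d),
      W1 = rmat(d, config$mlp_dim), b1 = numeric(config$mlp_dim),
      W2 = rmat(config$mlp_dim, d), b2 = numeric(d)
    )
    names(lp) <- paste0("L", l, ".", layer_param_names)
    p <- c(p, lp)
  }
  p$lnf_g <- rep(1, d)
  p$lnf_b <- numeric(d)
  p$head_W <- rmat(d, config$n_classes)
  p$head_b <- numeric(config$n_classes)
  structure(list(config = config, params = p), class = "taha_model")
}

#' @export
print.taha_model <- function(x, ...) {
  cat("taha_model with", length(x$params), "parameter arrays,",
      format(sum(vapply(x$params, length, 1L)), big.mark = ","),
      "parameters\n")
  print(x$config)
  invisible(x)
}

# Linear index table mapping (patch, within-patch element) -> element of an
# S x S x C image array; within-patch order is the native column-major order
# of the ps x ps x C sub-array.
patch_index <- function(config) {
  S <- config$image_size; ps <- config$patch_size; C <- config$channels
  g <- S %/% ps
  P0 <- g * g
  idx <- matrix(0L, P0, ps * ps * C)
  for (pr in seq_len(g)) {
    for (pc in seq_len(g)) {
      p <- (pr - 1L) * g + pc
      rows <- ((pr - 1L) * ps + 1L):(pr * ps)
      cols <- ((pc - 1L) * ps + 1L):(pc * ps)
      k <- 1L
      lin <- integer(ps * ps * C)
      for (ch in seq_len(C)) for (cc in cols) for (rr in rows) {
        lin[k] <- rr + (cc - 1L) * S + (ch - 1L) * S * S
        k <- k + 1L
      }
      idx[p, ] <- lin
    }
  }
  idx
}

add_rowvec <- function(x, v) sweep(x, 2L, v, "+")

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

layernorm_fwd <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + LN_EPS)
  xhat <- xc * inv
  list(y = add_rowvec(sweep(xhat, 2L, g, "*"), b), xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dy, fw, g) {
  dxhat <- sweep(dy, 2L, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * fw$xhat)
  dx <- (dxhat - m1 - fw$xhat * m2) * fw$inv
  list(dx = dx, dg = colSums(dy * fw$xhat), db = colSums(dy))
}

softmax_rows <- function(S) {
  mx <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - mx)
  E / rowSums(E)
}

#' Embed an image into a token sequence
#'
#' Splits the image into non-overlapping patches, projects each flattened
#' patch linearly, adds the learned positional term, and prepends the class
#' token when the configuration enables one.
#'
#' @param image An `image_size x image_size x channels` numeric array.
#' @param model A `taha_model` (its config and embedding parameters are used).
#' @return An `n_tokens x embed_dim` matrix.
#' @export
patch_embed <- function(image, model) {
  cfg <- model$config
  dm <- dim(image)
  if (length(dm) != 3L || dm[1] != cfg$image_size || dm[2] != cfg$image_size ||
      dm[3] != cfg$channels) {
    stop("image shape (", paste(dm, collapse = "x"),
         ") does not match config (", cfg$image_size, "x", cfg$image_size,
         "x", cfg$channels, ")")
  }
  batch <- array(image, c(1L, dm))
  tokens_from_images(batch, model)$tokens
}

# Batch patch embedding: images B x S x S x C -> (B*n) x d token matrix in
# sample-major row blocks; also returns the raw patch matrix for backprop.
tokens_from_images <- function(images, model, idx = NULL) {
  cfg <- model$config
  if (is.null(idx)) idx <- patch_index(cfg)
  B <- dim(images)[1]
  P0 <- nrow(idx); pd <- ncol(idx)
  n <- n_tokens(cfg)
  Pmat <- matrix(0, B * P0, pd)
  for (b in seq_len(B)) {
    v <- as.vector(images[b, , , ])
    stopifnot_finite(v, "input image")
    Pmat[((b - 1L) * P0 + 1L):(b * P0), ] <- matrix(v[idx], P0, pd)
  }
  emb <- add_rowvec(Pmat %*% model$params$patch_W, model$params$patch_b)
  d <- cfg$embed_dim
  tok <- matrix(0, B * n, d)
  if (cfg$use_cls_token) {
    cls_rows <- (seq_len(B) - 1L) * n + 1L
    tok[cls_rows, ] <- matrix(model$params$cls, B, d, byrow = TRUE)
    tok[-cls_rows, ] <- emb
  } else {
    tok <- emb
  }
  tok <- tok + model$params$pos[rep(seq_len(n), B), ]
  list(tokens = tok, Pmat = Pmat)
}

default_mask <- function(config) {
  lapply(config$heads_per_layer, function(H) rep(TRUE, H))
}

check_mask <- function(mask, config) {
  if (is.null(mask)) return(default_mask(config))
  if (length(mask) != config$depth) {
    stop("head mask must have one entry per layer")
  }
  for (l in seq_len(config$depth)) {
    if (length(mask[[l]]) != config$heads_per_layer[l]) {
      stop("mask length for layer ", l, " (", length(mask[[l]]),
           ") does not equal its head count (",
           config$heads_per_layer[l], ")")
    }
    if (!any(mask[[l]])) stop("all heads masked in layer ", l)
  }
  lapply(mask, as.logical)
}

# Core batched forward pass.
#   images : B x S x S x C array
#   mask   : per-layer logical head mask (TRUE = active), NULL = all active
#   keep_cache : retain every intermediate needed by vit_backward
#   keep_records : retain attention maps / head outputs (always on when
#                  keep_cache is on)
# Returns list(scores, records, pooled_z, cache).
vit_forward <- function(model, images, mask = NULL, keep_cache = FALSE,
                        keep_records = TRUE) {
  cfg <- model$config
  p <- model$params
  mask <- check_mask(mask, cfg)
  if (length(dim(images)) == 3L) images <- array(images, c(1L, dim(images)))
  B <- dim(images)[1]
  if (B < 1L) stop("empty image batch")
  n <- n_tokens(cfg); d <- cfg$embed_dim; dk <- cfg$head_dim
  keep_records <- keep_records || keep_cache

  te <- tokens_from_images(images, model)
  x <- te$tokens
  cache <- if (keep_cache) list(Pmat = te$Pmat, mask = mask, B = B) else NULL
  layers_cache <- vector("list", cfg$depth)
  records <- vector("list", cfg$depth)
  pooled <- if (keep_records) vector("list", cfg$depth) else NULL

  row_idx <- function(b) ((b - 1L) * n + 1L):(b * n)
  for (l in seq_len(cfg$depth)) {
    H <- cfg$heads_per_layer[l]
    lp <- function(nm) p[[paste0("L", l, ".", nm)]]
    ln1 <- layernorm_fwd(x, lp("ln1_g"), lp("ln1_b"))
    Q <- add_rowvec(ln1$y %*% lp("Wq"), lp("bq"))
    K <- add_rowvec(ln1$y %*% lp("Wk"), lp("bk"))
    V <- add_rowvec(ln1$y %*% lp("Wv"), lp("bv"))
    Zc <- matrix(0, B * n, H * dk)
    A_store <- if (keep_records) vector("list", H) else NULL
    sc <- 1 / sqrt(dk)
    for (h in seq_len(H)) {
      if (!mask[[l]][h]) next
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      Ah <- if (keep_records) array(0, c(n, n, B)) else NULL
      for (b in seq_len(B)) {
        ri <- row_idx(b)
        A <- softmax_rows(Q[ri, cols, drop = FALSE] %*%
                            t(K[ri, cols, drop = FALSE]) * sc)
        Zc[ri, cols] <- A %*% V[ri, cols, drop = FALSE]
        if (keep_records) Ah[, , b] <- A
      }
      if (keep_records) A_store[[h]] <- Ah
    }
    attn_out <- add_rowvec(Zc %*% lp("Wo"), lp("bo"))
    x_mid <- x + attn_out
    ln2 <- layernorm_fwd(x_mid, lp("ln2_g"), lp("ln2_b"))
    h1 <- add_rowvec(ln2$y %*% lp("W1"), lp("b1"))
    a1 <- gelu(h1)
    x_out <- x_mid + add_rowvec(a1 %*% lp("W2"), lp("b2"))
    if (keep_cache) {
      layers_cache[[l]] <- list(x_in = x, ln1 = ln1, Q = Q, K = K, V = V,
                                A = A_store, Zc = Zc, x_mid = x_mid,
                                ln2 = ln2, h1 = h1, a1 = a1)
    }
    if (keep_records) {
      records[[l]] <- list(maps = A_store, head_outputs = Zc)
      pm <- matrix(0, B, H * dk)
      for (b in seq_len(B)) pm[b, ] <- colMeans(Zc[row_idx(b), , drop = FALSE])
      pooled[[l]] <- pm
    }
    x <- x_out
  }
  lnf <- layernorm_fwd(x, p$lnf_g, p$lnf_b)
  if (cfg$use_cls_token) {
    feats <- lnf$y[(seq_len(B) - 1L) * n + 1L, , drop = FALSE]
  } else {
    feats <- matrix(0, B, d)
    for (b in seq_len(B)) feats[b, ] <- colMeans(lnf$y[row_idx(b), , drop = FALSE])
  }
  scores <- add_rowvec(feats %*% p$head_W, p$head_b)
  if (keep_cache) {
    cache$layers <- layers_cache
    cache$x_top <- x
    cache$lnf <- lnf
    cache$feats <- feats
  }
  rec <- NULL
  if (keep_records) {
    rec <- structure(list(maps = lapply(records, `[[`, "maps"),
                          head_outputs = lapply(records, `[[`, "head_outputs"),
                          pooled = do.call(cbind, pooled),
                          mask = mask, n_tokens = n, batch = B),
                     class = "taha_attention_record")
  }
  list(scores = scores, record = rec, cache = cache)
}

#' Multi-head self-attention forward pass for one token sequence
#'
#' Computes, for every unmasked head, `softmax(Q K' / sqrt(d_k)) V` and the
#' concatenated-head output projection. Pure attention: no residual or layer
#' norm. Masked heads contribute zero columns to the concatenation, so their
#' rows of the output projection are inert.
#'
#' @param x An `n x d` token matrix.
#' @param layer_params Named list with `Wq,bq,Wk,bk,Wv,bv,Wo,bo`.
#' @param head_dim Per-head width `d_k`.
#' @param mask Optional logical vector, one flag per head (`TRUE` = active).
#' @return `list(output, maps, head_outputs)`: `output` is `n x d`; `maps`
#'   and `head_outputs` are per-head lists (`NULL` for masked heads) of the
#'   row-stochastic attention map and the `n x d_k` head output.
#' @export
mhsa_forward <- function(x, layer_params, head_dim, mask = NULL) {
  if (!all(is.finite(x))) stop("NaN or non-finite values in input tokens")
  dk <- head_dim
  H <- ncol(layer_params$Wq) %/% dk
  if (is.null(mask)) mask <- rep(TRUE, H)
  if (length(mask) != H) stop("mask length ", length(mask),
                              " does not equal head count ", H)
  if (!any(mask)) stop("all heads masked")
  n <- nrow(x)
  Q <- add_rowvec(x %*% layer_params$Wq, layer_params$bq)
  K <- add_rowvec(x %*% layer_params$Wk, layer_params$bk)
  V <- add_rowvec(x %*% layer_params$Wv, layer_params$bv)
  Zc <- matrix(0, n, H * dk)
  maps <- vector("list", H)
  outs <- vector("list", H)
  for (h in seq_len(H)) {
    if (!mask[h]) next
    cols <- ((h - 1L) * dk + 1L):(h * dk)
    A <- softmax_rows(Q[, cols, drop = FALSE] %*%
                        t(K[, cols, drop = FALSE]) / sqrt(dk))
    Z <- A %*% V[, cols, drop = FALSE]
    Zc[, cols] <- Z
    maps[[h]] <- A
    outs[[h]] <- Z
  }
  list(output = add_rowvec(Zc %*% layer_params$Wo, layer_params$bo),
       maps = maps, head_outputs = outs)
}

# Extract layer l's parameter sub-list with short names (Wq, bq, ...).
layer_params <- function(model, l) {
  nms <- paste0("L", l, ".", layer_param_names)
  lp <- model$params[nms]
  names(lp) <- layer_param_names
  lp
}

#' Forward pass with attention records
#'
#' Runs a batch of images through the model and returns class scores, the
#' per-layer attention records (row-stochastic maps and head outputs for
#' every unmasked head), and the token-mean pooled head outputs concatenated
#' in fixed (layer, head) order -- the `Z` feeding the phenotypic
#' consistency constraint and the head-label correlation.
#'
#' @param model A `taha_model`.
#' @param images `B x S x S x C` array (or a single `S x S x C` image).
#' @param mask Optional per-layer logical head mask.
#' @return `list(scores, record, pooled_z)` where `pooled_z` is
#'   `B x sum(H_l * d_k)`.
#' @export
forward_with_records <- function(model, images, mask = NULL) {
  fw <- vit_forward(model, images, mask = mask, keep_cache = FALSE,
                    keep_records = TRUE)
  list(scores = fw$scores, record = fw$record, pooled_z = fw$record$pooled)
}

#' Attention maps of one head from a record
#'
#' @param record A `taha_attention_record`.
#' @param layer,head 1-based indices.
#' @return `n x n x B` array, or `NULL` if the head was masked.
#' @export
record_maps <- function(record, layer, head) record$maps[[layer]][[head]]

#' Per-head output slice from a record
#'
#' @param record A `taha_attention_record`.
#' @param layer,head 1-based indices.
#' @param head_dim Per-head width `d_k`.
#' @return `(B*n_tokens) x d_k` matrix of the head's output rows.
#' @export
record_head_output <- function(record, layer, head, head_dim) {
  cols <- ((head - 1L) * head_dim + 1L):(head * head_dim)
  record$head_outputs[[layer]][, cols, drop = FALSE]
}
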