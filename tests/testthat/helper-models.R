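# Shared fixtures, built in code.

# Tiny configs used across test files.
tiny_cfg <- function(depth = 2L, heads = 2L, d = 8L, mlp = 16L,
                     image = 16L, patch = 4L, classes = 2L, cls = TRUE) {
  model_config(image_size = image, patch_size = patch, channels = 3L,
               depth = depth, heads_per_layer = heads, embed_dim = d,
               mlp_dim = mlp, n_classes = classes, use_cls_token = cls)
}

tiny_model <- function(seed = 1L, ...) {
  set.seed(seed)
  init_model(tiny_cfg(...))
}

rand_images <- function(b, cfg, seed = 1L) {
  set.seed(seed)
  array(stats::runif(b * cfg$image_size^2 * cfg$channels),
        c(b, cfg$image_size, cfg$image_size, cfg$channels))
}

# Independent dense-attention oracle: explicit per-head loop written
# directly from softmax(QK'/sqrt(dk))V with no shared code paths.
naive_mhsa <- function(x, lp, dk, mask = NULL) {
  H <- ncol(lp$Wq) / dk
  if (is.null(mask)) mask <- rep(TRUE, H)
  n <- nrow(x)
  concat <- NULL
  for (h in seq_len(H)) {
    cols <- ((h - 1) * dk + 1):(h * dk)
    Q <- x %*% lp$Wq[, cols] + matrix(lp$bq[cols], n, dk, byrow = TRUE)
    K <- x %*% lp$Wk[, cols] + matrix(lp$bk[cols], n, dk, byrow = TRUE)
    V <- x %*% lp$Wv[, cols] + matrix(lp$bv[cols], n, dk, byrow = TRUE)
    Z <- matrix(0, n, dk)
    if (mask[h]) {
      for (i in seq_len(n)) {
        logits <- as.numeric(K %*% Q[i, ]) / sqrt(dk)
        w <- exp(logits - max(logits))
        w <- w / sum(w)
        Z[i, ] <- colSums(V * w)
      }
    }
    concat <- cbind(concat, Z)
  }
  concat %*% lp$Wo + matrix(lp$bo, n, ncol(lp$Wo), byrow = TRUE)
}

# Total parameter array sizes of an instantiated model, classifier
# excluded: the instantiation oracle for count_params.
instantiated_param_total <- function(model) {
  keep <- setdiff(names(model$params), c("head_W", "head_b"))
  sum(vapply(model$params[keep], length, 1L))
}

# MAC oracle that walks an instantiated model's matrix shapes (one
# "instrumented forward"): accumulates m*k products for each matmul the
# forward pass performs, patch embedding included, classifier excluded.
shape_trace_macs <- function(model) {
  cfg <- model$config
  n <- n_tokens(cfg)
  P0 <- (cfg$image_size / cfg$patch_size)^2
  macs <- P0 * nrow(model$params$patch_W) * ncol(model$params$patch_W)
  for (l in seq_len(cfg$depth)) {
    lp <- layer_params_public(model, l)
    dk <- cfg$head_dim
    H <- ncol(lp$Wq) / dk
    macs <- macs + 3 * n * nrow(lp$Wq) * ncol(lp$Wq)       # Q, K, V
    macs <- macs + H * (n * n * dk)                        # Q K'
    macs <- macs + H * (n * n * dk)                        # A V
    macs <- macs + n * nrow(lp$Wo) * ncol(lp$Wo)           # W_o
    macs <- macs + 2 * n * nrow(lp$W1) * ncol(lp$W1)       # MLP (in + out)
  }
  macs
}

layer_params_public <- function(model, l) {
  nms <- c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo", "W1", "W2")
  lp <- model$params[paste0("L", l, ".", nms)]
  names(lp) <- nms
  lp
}
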