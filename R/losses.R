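# Alignment losses: the KL domain alignment loss on attention maps and the
# phenotypic consistency constraint on pooled head outputs.

DAL_EPS <- 1e-8

# Coerce a single map, an n x n x B array, or a list of maps to n x n x B.
as_map_array <- function(x) {
  if (is.list(x)) {
    n <- nrow(x[[1]])
    arr <- array(0, c(n, n, length(x)))
    for (i in seq_along(x)) arr[, , i] <- x[[i]]
    return(arr)
  }
  if (is.matrix(x)) return(array(x, c(dim(x), 1L)))
  if (length(dim(x)) == 3L) return(x)
  stop("attention maps must be a matrix, 3-d array, or list of matrices")
}

#' Domain alignment loss for one attention head
#'
#' Mean over images and query rows of the Kullback-Leibler divergence from
#' each source-attention row to the matching target-attention row,
#' `KL(p || q) = sum_j p_j log((p_j + eps) / (q_j + eps))`, with additive
#' smoothing `eps = 1e-8` inside the logarithm. The direction matters: the
#' source map is the reference distribution (first argument).
#'
#' @param source_maps,target_maps Row-stochastic attention maps: an
#'   `n x n` matrix, an `n x n x B` array, or a list of matrices. Shapes
#'   must match.
#' @param eps Additive smoothing before the logarithm.
#' @return A single non-negative scalar.
#' @export
domain_alignment_loss <- function(source_maps, target_maps, eps = DAL_EPS) {
  P <- as_map_array(source_maps)
  Q <- as_map_array(target_maps)
  if (!identical(dim(P), dim(Q))) {
    stop("source and target attention maps have different shapes (",
         paste(dim(P), collapse = "x"), " vs ",
         paste(dim(Q), collapse = "x"), ")")
  }
  if (any(P < 0) || any(Q < 0)) stop("attention maps must be non-negative")
  rp <- apply(P, 3L, rowSums); rq <- apply(Q, 3L, rowSums)
  if (max(abs(c(rp, rq) - 1)) > 1e-3) {
    stop("attention map rows are not normalized")
  }
  kl_map_mean(P, Q, eps)$value
}

# Shared kernel: value and d(value)/dQ for KL(P || Q) averaged over rows
# and batch entries. Both arguments are smoothed, so at P == Q the value
# AND the gradient through the softmax vanish exactly (an asymmetric
# smoothing leaves an O(eps) residual gradient that adaptive optimizers
# would amplify into full-size steps).
kl_map_mean <- function(P, Q, eps = DAL_EPS) {
  n <- dim(P)[1]; B <- dim(P)[3]
  scale <- 1 / (n * B)
  Pe <- P + eps
  val <- sum(Pe * (log(Pe) - log(Q + eps))) * scale
  list(value = val, dQ = -(Pe / (Q + eps)) * scale)
}

#' Linear warmup schedule for the consistency weight
#'
#' Interpolates linearly from `lambda0` at step 0 to `lambda_max` at
#' `warmup_steps`, constant afterwards; gradually shifts the objective from
#' pure attention alignment towards phenotypic prediction.
#'
#' @param step Current step (0-based), non-negative.
#' @param warmup_steps Positive warmup length.
#' @param lambda0 Initial weight (default 0.1).
#' @param lambda_max Weight after warmup (default 1.0).
#' @return The scheduled weight.
#' @export
lambda_schedule <- function(step, warmup_steps, lambda0 = 0.1,
                            lambda_max = 1.0) {
  if (warmup_steps <= 0) stop("warmup_steps must be positive")
  if (any(step < 0)) stop("step must be non-negative")
  frac <- pmin(step, warmup_steps) / warmup_steps
  lambda0 + (lambda_max - lambda0) * frac
}

# ---- Phenotypic predictor (small tanh MLP) ---------------------------------

mlp_init <- function(d_in, hidden, d_out, sd0 = 0.05) {
  list(W1 = matrix(stats::rnorm(d_in * hidden, sd = sd0), d_in, hidden),
       b1 = numeric(hidden),
       W2 = matrix(stats::rnorm(hidden * d_out, sd = sd0), hidden, d_out),
       b2 = numeric(d_out))
}

mlp_forward <- function(mlp, X) {
  h <- tanh(add_rowvec(X %*% mlp$W1, mlp$b1))
  list(out = add_rowvec(h %*% mlp$W2, mlp$b2), h = h, X = X)
}

mlp_backward <- function(mlp, fw, dout) {
  gW2 <- t(fw$h) %*% dout
  gb2 <- colSums(dout)
  dh <- (dout %*% t(mlp$W2)) * (1 - fw$h^2)
  gW1 <- t(fw$X) %*% dh
  gb1 <- colSums(dh)
  list(grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2),
       dX = dh %*% t(mlp$W1))
}

# One-hot labels, each column z-scored (population sd) over the given rows.
# Columns with zero spread (absent classes) stay at zero after centering.
standardized_onehot <- function(y, n_classes) {
  n <- length(y)
  Y <- matrix(0, n, n_classes)
  Y[cbind(seq_len(n), y)] <- 1
  mu <- colMeans(Y)
  sd_ <- sqrt(colMeans(sweep(Y, 2L, mu)^2))
  Yc <- sweep(Y, 2L, mu)
  ok <- sd_ > 0
  Yc[, ok] <- sweep(Yc[, ok, drop = FALSE], 2L, sd_[ok], "/")
  Yc
}

# Mean over samples of the squared L2 residual norm.
mean_sq_residual <- function(target, pred) {
  target <- as.matrix(target); pred <- as.matrix(pred)
  mean(rowSums((target - pred)^2))
}

#' Phenotypic consistency loss
#'
#' Mean squared L2 distance between standardized one-hot phenotype labels
#' and the MLP prediction from pooled head outputs, evaluated on labeled
#' samples only (the semi-supervised protocol). Pooling is the token mean
#' per head, concatenated in fixed (layer, head) order; pass pooled features
#' directly as a matrix.
#'
#' @param Z `B x D` matrix of pooled concatenated head outputs (e.g.
#'   `forward_with_records(...)$pooled_z`).
#' @param y Integer class labels in `1..n_classes`, length `B`.
#' @param mlp_head Predictor from `mlp_init()` whose output width equals
#'   `n_classes`.
#' @param labeled Optional logical vector marking labeled samples; `NULL`
#'   means all labeled.
#' @param n_classes Label cardinality (default `max(y)`).
#' @return A non-negative scalar.
#' @export
phenotypic_consistency_loss <- function(Z, y, mlp_head, labeled = NULL,
                                        n_classes = max(y)) {
  Z <- as.matrix(Z)
  if (nrow(Z) != length(y)) stop("Z rows and label count differ")
  if (is.null(labeled)) labeled <- rep(TRUE, nrow(Z))
  if (!any(labeled)) {
    stop("no labeled samples in batch: insufficient supervision for the ",
         "phenotypic consistency loss")
  }
  Zl <- Z[labeled, , drop = FALSE]
  Tgt <- standardized_onehot(y[labeled], n_classes)
  fw <- mlp_forward(mlp_head, Zl)
  mean_sq_residual(Tgt, fw$out)
}

# Loss + gradients wrt MLP params and wrt the labeled pooled rows.
pcc_grad <- function(Z, y, mlp_head, labeled, n_classes) {
  Zl <- Z[labeled, , drop = FALSE]
  Tgt <- standardized_onehot(y[labeled], n_classes)
  fw <- mlp_forward(mlp_head, Zl)
  nl <- nrow(Zl)
  loss <- mean(rowSums((Tgt - fw$out)^2))
  dout <- 2 * (fw$out - Tgt) / nl
  bw <- mlp_backward(mlp_head, fw, dout)
  list(loss = loss, mlp_grads = bw$grads, dZ_labeled = bw$dX)
}
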