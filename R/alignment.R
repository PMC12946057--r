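# Cross-species alignment: a frozen source-pretrained snapshot provides the
# reference attention maps; the live model adapts on target images under
# mean per-head DAL + lambda * PCC.

#' Create an alignment state
#'
#' Holds the frozen source snapshot (never updated), the live model being
#' adapted (initialized from the same weights), the phenotypic MLP
#' predictor, the optimizer state, and the lambda schedule position.
#'
#' @param source_model Source-pretrained `taha_model`; copied into both the
#'   frozen snapshot and the live model.
#' @param warmup_steps Linear warmup length for lambda.
#' @param lr Adam learning rate for the alignment updates.
#' @param lambda0,lambda_max Schedule endpoints (defaults 0.1 and 1.0).
#' @param mlp_hidden Hidden width of the phenotypic MLP.
#' @param update_scope Which live parameters move: `"attention"` (default:
#'   per-head Q/K/V/O projections; patch embedding and MLP blocks frozen) or
#'   `"all_but_patch"`.
#' @param mask Optional per-layer logical head mask restricting alignment to
#'   currently retained heads.
#' @return An object of class `taha_alignment_state`.
#' @export
alignment_state <- function(source_model, warmup_steps, lr = 3e-5,
                            lambda0 = 0.1, lambda_max = 1.0,
                            mlp_hidden = 32L,
                            update_scope = c("attention", "all_but_patch"),
                            mask = NULL) {
  update_scope <- match.arg(update_scope)
  cfg <- source_model$config
  mask <- check_mask(mask, cfg)
  D <- sum(cfg$heads_per_layer) * cfg$head_dim
  st <- list(
    frozen = source_model,
    live = source_model,
    mlp = mlp_init(D, mlp_hidden, cfg$n_classes),
    mask = mask,
    opt_model = adam_state(lr = lr),
    opt_mlp = adam_state(lr = lr),
    step = 0L,
    lambda0 = lambda0, lambda_max = lambda_max,
    warmup_steps = warmup_steps,
    update_scope = update_scope
  )
  class(st) <- "taha_alignment_state"
  st
}

# Per-head DAL values (and gradients wrt the live maps) between two
# recorded forward passes restricted to active heads.
dal_per_head <- function(frozen_rec, live_rec, mask, with_grad = FALSE) {
  depth <- length(frozen_rec$maps)
  rows <- list(); k <- 0L
  dA <- if (with_grad) vector("list", depth) else NULL
  for (l in seq_len(depth)) {
    H <- length(mask[[l]])
    if (with_grad) dA[[l]] <- vector("list", H)
    for (h in seq_len(H)) {
      if (!mask[[l]][h]) next
      kl <- kl_map_mean(frozen_rec$maps[[l]][[h]], live_rec$maps[[l]][[h]])
      k <- k + 1L
      rows[[k]] <- data.frame(layer = l, head = h, dal = kl$value)
      if (with_grad) dA[[l]][[h]] <- kl$dQ
    }
  }
  list(table = do.call(rbind, rows), dA = dA)
}

#' One alignment update on a target batch
#'
#' Computes attention maps of the frozen source snapshot and the live model
#' on the same target images, takes one Adam step on
#' `mean_h DAL_h + lambda * PCC`, and advances the lambda schedule. The
#' frozen snapshot is never touched.
#'
#' @param state A [alignment_state()].
#' @param images Target-domain image batch, `B x S x S x C`.
#' @param y Integer labels (only positions with `labeled = TRUE` are used).
#' @param labeled Logical vector marking the labeled target fraction; when
#'   no labeled sample is present the PCC term is skipped (lambda times an
#'   absent term), since alignment itself is unsupervised.
#' @return `list(state, metrics)` where metrics holds `step`, `lambda`,
#'   per-head `dal` table, `mean_dal`, `pcc`, `total`.
#' @export
alignment_step <- function(state, images, y, labeled = NULL) {
  cfg <- state$live$config
  n <- n_tokens(cfg); dk <- cfg$head_dim
  if (length(dim(images)) == 3L) images <- array(images, c(1L, dim(images)))
  B <- dim(images)[1]
  if (is.null(labeled)) labeled <- rep(TRUE, B)

  fwf <- vit_forward(state$frozen, images, mask = state$mask,
                     keep_records = TRUE)
  fwl <- vit_forward(state$live, images, mask = state$mask,
                     keep_cache = TRUE)
  dal <- dal_per_head(fwf$record, fwl$record, state$mask, with_grad = TRUE)
  n_active <- nrow(dal$table)
  mean_dal <- mean(dal$table$dal)
  for (l in seq_along(dal$dA)) {
    for (h in seq_along(dal$dA[[l]])) {
      if (!is.null(dal$dA[[l]][[h]])) {
        dal$dA[[l]][[h]] <- dal$dA[[l]][[h]] / n_active
      }
    }
  }
  lam <- lambda_schedule(state$step, state$warmup_steps,
                         state$lambda0, state$lambda_max)

  pcc <- NA_real_
  dZ <- NULL
  mlp_grads <- NULL
  if (any(labeled)) {
    pooled <- fwl$record$pooled
    pg <- pcc_grad(pooled, y, state$mlp, labeled, cfg$n_classes)
    pcc <- pg$loss
    dpool <- matrix(0, B, ncol(pooled))
    dpool[labeled, ] <- pg$dZ_labeled
    dZ <- vector("list", cfg$depth)
    off <- 0L
    for (l in seq_len(cfg$depth)) {
      w <- cfg$heads_per_layer[l] * dk
      sl <- dpool[, (off + 1L):(off + w), drop = FALSE] * (lam / n)
      dZ[[l]] <- sl[rep(seq_len(B), each = n), , drop = FALSE]
      off <- off + w
    }
    mlp_grads <- lapply(pg$mlp_grads, function(g) lam * g)
  }
  total <- mean_dal + if (is.na(pcc)) 0 else lam * pcc
  if (!is.finite(total)) {
    stop("alignment loss is not finite at step ", state$step,
         " (mean DAL = ", mean_dal, ", PCC = ", pcc, ")")
  }

  grads <- vit_backward(state$live, fwl, dscores = NULL, dA = dal$dA, dZ = dZ)
  state$live$params <- adam_step(
    state$live$params, grads, state$opt_model,
    trainable = param_scope(state$live, state$update_scope))
  if (!is.null(mlp_grads)) {
    state$mlp <- adam_step(state$mlp, mlp_grads, state$opt_mlp)
  }
  state$step <- state$step + 1L
  list(state = state,
       metrics = list(step = state$step, lambda = lam, dal = dal$table,
                      mean_dal = mean_dal, pcc = pcc, total = total))
}
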