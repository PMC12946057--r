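# Physical head removal. Pruned heads' Q/K/V column blocks and the matching
# W_o row blocks are deleted (not zeroed); because the dropped W_o rows
# multiply exactly the dropped concatenation slices, the compact forward
# pass equals the zero-masked full forward pass.

#' Rebuild one attention layer with a subset of heads
#'
#' Copies the retained heads' Q/K/V projection blocks (with their biases)
#' in original order and deletes the output-projection rows belonging to
#' pruned heads, producing the reduced projection `W_o'`. Layer norms and
#' the MLP are untouched by head surgery.
#'
#' @param lp Layer parameter list with short names (`Wq, bq, ..., Wo, bo`),
#'   as returned by [layer_params()].
#' @param retained Ordered integer indices of heads to keep (at least one).
#' @param head_dim Per-head width `d_v = d_k`.
#' @return The rebuilt layer parameter list plus `retained`.
#' @export
rebuild_pruned_layer <- function(lp, retained, head_dim) {
  if (length(retained) < 1L) stop("cannot rebuild a layer with zero heads")
  retained <- sort(as.integer(retained))
  H <- ncol(lp$Wq) %/% head_dim
  if (any(retained < 1L | retained > H)) {
    stop("retained head indices out of range 1..", H)
  }
  keep <- as.vector(vapply(retained, function(h) {
    ((h - 1L) * head_dim + 1L):(h * head_dim)
  }, integer(head_dim)))
  out <- lp
  for (w in c("Wq", "Wk", "Wv")) out[[w]] <- lp[[w]][, keep, drop = FALSE]
  for (b in c("bq", "bk", "bv")) out[[b]] <- lp[[b]][keep]
  out$Wo <- lp$Wo[keep, , drop = FALSE]
  out$retained <- retained
  out
}

#' Physically prune heads from a model
#'
#' Applies a prune mask layer by layer, rebuilding each attention layer
#' with only its retained heads and updating the per-layer head counts in
#' the config. The forward output dimension `d` is preserved.
#'
#' @param model A `taha_model`.
#' @param mask A `taha_prune_mask` from [select_heads()], or a plain list
#'   of retained head index vectors (one per layer).
#' @return `list(model, report, retained)`: the compact model, a
#'   [reduction_report()] comparing full vs pruned costs, and the retained
#'   original head indices per layer.
#' @export
prune_model <- function(model, mask) {
  cfg <- model$config
  retained <- if (inherits(mask, "taha_prune_mask")) {
    mask_retained(mask, cfg$depth)
  } else {
    mask
  }
  if (length(retained) != cfg$depth) {
    stop("mask covers ", length(retained), " layers but model has ",
         cfg$depth)
  }
  p <- model$params
  new_heads <- integer(cfg$depth)
  for (l in seq_len(cfg$depth)) {
    r <- retained[[l]]
    if (length(r) < 1L) stop("layer ", l, " would retain zero heads")
    if (any(r < 1L | r > cfg$heads_per_layer[l])) {
      stop("mask for layer ", l, " does not match its head count (",
           cfg$heads_per_layer[l], ")")
    }
    lp <- rebuild_pruned_layer(layer_params(model, l), r, cfg$head_dim)
    for (s in layer_param_names) p[[paste0("L", l, ".", s)]] <- lp[[s]]
    new_heads[l] <- length(r)
  }
  new_cfg <- cfg
  new_cfg$heads_per_layer <- new_heads
  compact <- structure(list(config = new_cfg, params = p),
                       class = "taha_model")
  list(model = compact,
       report = reduction_report(cfg, new_cfg),
       retained = lapply(retained, sort))
}
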