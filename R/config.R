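#' Vision Transformer architecture configuration
#'
#' Describes a (possibly pruned) ViT backbone. Head counts are stored per
#' layer so that models with unevenly pruned layers are first-class; the
#' per-head width `head_dim` is fixed at construction (`embed_dim / heads`
#' for an unpruned model) and does not change when heads are removed.
#'
#' @param image_size Input image side length in pixels (square images).
#' @param patch_size Patch side length in pixels; must divide `image_size`.
#' @param channels Number of image channels.
#' @param depth Number of transformer blocks.
#' @param heads_per_layer Integer vector of head counts, one per layer, or a
#'   single integer recycled to all layers.
#' @param embed_dim Token embedding width `d`.
#' @param head_dim Per-head query/key/value width; defaults to
#'   `embed_dim / max(heads_per_layer)` and must then divide evenly.
#' @param mlp_dim Hidden width of the per-block MLP.
#' @param n_classes Number of phenotype classes.
#' @param use_cls_token Prepend a learned class token (default `TRUE`).
#'
#' @return An object of class `taha_config`.
#' @export
model_config <- function(image_size, patch_size, channels = 3L, depth,
                         heads_per_layer, embed_dim, head_dim = NULL,
                         mlp_dim, n_classes, use_cls_token = TRUE) {
  if (length(heads_per_layer) == 1L) {
    heads_per_layer <- rep(as.integer(heads_per_layer), depth)
  }
  heads_per_layer <- as.integer(heads_per_layer)
  if (length(heads_per_layer) != depth) {
    stop("heads_per_layer must have one entry per layer (depth = ",
         depth, ")")
  }
  if (any(heads_per_layer < 1L)) stop("every layer needs at least one head")
  if (image_size %% patch_size != 0L) {
    stop("image_size (", image_size, ") is not divisible by patch_size (",
         patch_size, ")")
  }
  if (is.null(head_dim)) {
    H0 <- max(heads_per_layer)
    if (embed_dim %% H0 != 0L) {
      stop("embed_dim (", embed_dim, ") is not divisible by the head count (",
           H0, "); give head_dim explicitly")
    }
    head_dim <- embed_dim %/% H0
  }
  if (n_classes < 2L) stop("n_classes must be at least 2")
  cfg <- list(
    image_size = as.integer(image_size),
    patch_size = as.integer(patch_size),
    channels = as.integer(channels),
    depth = as.integer(depth),
    heads_per_layer = heads_per_layer,
    embed_dim = as.integer(embed_dim),
    head_dim = as.integer(head_dim),
    mlp_dim = as.integer(mlp_dim),
    n_classes = as.integer(n_classes),
    use_cls_token = isTRUE(use_cls_token)
  )
  class(cfg) <- "taha_config"
  cfg
}

#' Number of tokens produced by the patch embedding
#'
#' `(image_size / patch_size)^2` patches, plus one if a class token is used.
#'
#' @param config A [model_config()].
#' @return Integer token count.
#' @export
n_tokens <- function(config) {
  n <- (config$image_size %/% config$patch_size)^2
  if (config$use_cls_token) n <- n + 1L
  as.integer(n)
}

#' The ViT-Base/16 reference configuration
#'
#' 12 layers of 12 heads, embedding width 768, patch 16 at 224 px input --
#' the standard full-size backbone used as the reference point for cost
#' accounting.
#'
#' @param n_classes Classifier width (irrelevant to default cost accounting).
#' @return A `taha_config`.
#' @export
vit_base_config <- function(n_classes = 1000L) {
  model_config(image_size = 224L, patch_size = 16L, channels = 3L,
               depth = 12L, heads_per_layer = 12L, embed_dim = 768L,
               mlp_dim = 3072L, n_classes = n_classes)
}

#' @export
print.taha_config <- function(x, ...) {
  cat("ViT config: ", x$image_size, "px / patch ", x$patch_size,
      ", depth ", x$depth, ", heads ", paste(x$heads_per_layer, collapse = ","),
      ", d=", x$embed_dim, " (d_k=", x$head_dim, "), mlp=", x$mlp_dim,
      ", classes=", x$n_classes,
      if (x$use_cls_token) ", cls token" else "", "\n", sep = "")
  invisible(x)
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop("non-finite values in ", what)
}
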