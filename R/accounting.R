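# Exact parameter and multiply-accumulate (MAC) accounting for any config,
# including unevenly pruned layers, and percent-reduction reports.
#
# MAC convention (the one that reproduces the standard full-size ViT-Base/16
# figure of 17.6 G at 224 x 224): 1 MAC = 1 reported "FLOP"; the patch
# embedding projection is counted, while softmax, layer norms, GELU and the
# classifier are not. Attention cost per layer:
#   QKV projections  n * d * 3 H d_k
#   score products   H * n^2 * d_k
#   value weighting  H * n^2 * d_v
#   output proj      n * (H d_v) * d
#   MLP              2 * n * d * mlp_dim

round_half_up <- function(x, digits = 1L) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' Exact parameter count
#'
#' Sums the sizes of every parameter array the backbone instantiates:
#' patch projection (+bias), positional term, class token, and per layer
#' the two layer norms, per-head Q/K/V blocks with biases, `W_o` (+bias),
#' and the MLP, plus the final norm. The classifier head is excluded by
#' default.
#'
#' @param config A [model_config()].
#' @param include_classifier Count the classifier head too (default
#'   `FALSE`).
#' @return Integer-valued count (as a double, exact).
#' @export
count_params <- function(config, include_classifier = FALSE) {
  d <- config$embed_dim; dk <- config$head_dim
  n <- n_tokens(config)
  pd <- config$patch_size^2 * config$channels
  total <- pd * d + d +                # patch projection + bias
    n * d +                            # positions
    (if (config$use_cls_token) d else 0)
  for (H in config$heads_per_layer) {
    total <- total +
      2 * d +                          # ln1
      3 * (d * H * dk + H * dk) +      # Q/K/V blocks + biases
      (H * dk * d + d) +               # W_o + bias
      2 * d +                          # ln2
      (d * config$mlp_dim + config$mlp_dim) +
      (config$mlp_dim * d + d)
  }
  total <- total + 2 * d               # final norm
  if (include_classifier) total <- total + d * config$n_classes + config$n_classes
  total
}

#' Exact multiply-accumulate count for one forward pass
#'
#' See the file header for the convention. The count scales exactly
#' linearly in each layer's head count for the attention terms, the
#' operational form of the `O(H P^2 d) -> O(|H'| P^2 d)` complexity
#' reduction from pruning.
#'
#' @param config A [model_config()].
#' @param image_size Input side length (defaults to the config's).
#' @return MAC count.
#' @export
count_macs <- function(config, image_size = config$image_size) {
  if (image_size %% config$patch_size != 0L) {
    stop("image_size not divisible by patch_size")
  }
  d <- config$embed_dim; dk <- config$head_dim
  P0 <- (image_size %/% config$patch_size)^2
  n <- P0 + (if (config$use_cls_token) 1L else 0L)
  pd <- config$patch_size^2 * config$channels
  total <- P0 * pd * d
  for (H in config$heads_per_layer) {
    total <- total +
      n * d * (3 * H * dk) +
      H * n^2 * dk +
      H * n^2 * dk +
      n * (H * dk) * d +
      2 * n * d * config$mlp_dim
  }
  total
}

# Normalize reduction_report inputs: a taha_config or a list with fields
# heads (scalar average or per-layer vector), params, macs (alias flops).
cost_summary <- function(x, image_size = NULL) {
  if (inherits(x, "taha_config")) {
    return(list(heads = mean(x$heads_per_layer),
                depth = x$depth,
                params = count_params(x),
                macs = count_macs(x, image_size %||% x$image_size)))
  }
  if (!is.list(x)) stop("expected a taha_config or a cost list")
  macs <- x$macs %||% x$flops
  if (is.null(x$heads) || is.null(x$params) || is.null(macs)) {
    stop("cost list needs fields heads, params, and macs (or flops)")
  }
  list(heads = mean(x$heads), depth = x$depth %||% NA_integer_,
       params = x$params, macs = macs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cost reduction report
#'
#' Compares a full and a pruned model (configs or raw cost summaries) and
#' reports head counts (per-layer average to 1 decimal), parameters, and
#' MACs with percent reductions `100 * (1 - pruned/full)`, rounded half-up
#' to 1 decimal. A pruned cost exceeding its full counterpart marks the
#' report invalid.
#'
#' @param full,pruned `taha_config`s, or lists with `heads`, `params`, and
#'   `macs` (alias `flops`) entries.
#' @return An object of class `taha_cost_report` with fields `heads_full`,
#'   `heads_pruned_avg`, `params_full`, `params_pruned`, `macs_full`,
#'   `macs_pruned`, `reductions` (named percents), `table`, `valid`.
#' @export
reduction_report <- function(full, pruned) {
  a <- cost_summary(full)
  b <- cost_summary(pruned)
  if (!is.na(a$depth) && !is.na(b$depth) && a$depth != b$depth) {
    stop("full and pruned models have different depths (",
         a$depth, " vs ", b$depth, ")")
  }
  red <- function(f, p) round_half_up(100 * (1 - p / f), 1L)
  reductions <- c(heads = red(a$heads, b$heads),
                  params = red(a$params, b$params),
                  macs = red(a$macs, b$macs))
  valid <- b$heads <= a$heads && b$params <= a$params && b$macs <= a$macs
  if (!valid) warning("pruned costs exceed full costs; report flagged invalid")
  tab <- data.frame(
    component = c("attention_heads", "flops", "parameters"),
    full = c(a$heads, a$macs, a$params),
    pruned = c(round_half_up(b$heads, 1L), b$macs, b$params),
    reduction_pct = unname(reductions[c("heads", "macs", "params")])
  )
  structure(list(heads_full = a$heads,
                 heads_pruned_avg = round_half_up(b$heads, 1L),
                 params_full = a$params, params_pruned = b$params,
                 macs_full = a$macs, macs_pruned = b$macs,
                 reductions = reductions, table = tab, valid = valid),
            class = "taha_cost_report")
}

#' @export
print.taha_cost_report <- function(x, ...) {
  fmt <- function(v) ifelse(v >= 1e9, paste0(signif(v / 1e9, 3), "G"),
                            ifelse(v >= 1e6, paste0(signif(v / 1e6, 3), "M"),
                                   format(v)))
  tab <- x$table
  tab$full <- fmt(tab$full)
  tab$pruned <- fmt(tab$pruned)
  tab$reduction_pct <- sprintf("%.1f%%", tab$reduction_pct)
  print(tab, row.names = FALSE)
  if (!x$valid) cat("!! invalid: pruned costs exceed full costs\n")
  invisible(x)
}
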