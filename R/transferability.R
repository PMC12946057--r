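# Head transferability scoring and dynamic-threshold selection.

#' Correlation between a head's outputs and phenotype labels
#'
#' Token-mean pools the head output per sample, then computes the Pearson
#' correlation between every feature dimension and every standardized
#' one-hot label column; the score is the mean over feature dimensions of
#' the maximum absolute correlation over label columns, which lies in
#' `[0, 1]`. Constant feature dimensions (and absent classes) contribute 0.
#'
#' @param Z_h Head outputs: an `n x d_v` matrix of pooled per-sample
#'   features, or an `n x tokens x d_v` array pooled internally.
#' @param y Integer class labels in `1..n_classes`, length `n`; at least 3
#'   samples and 2 distinct classes.
#' @param n_classes Label cardinality (default `max(y)`).
#' @return A scalar in `[0, 1]`.
#' @export
head_label_correlation <- function(Z_h, y, n_classes = max(y)) {
  if (length(dim(Z_h)) == 3L) {
    Z_h <- apply(Z_h, c(1L, 3L), mean)
  }
  Z_h <- as.matrix(Z_h)
  n <- nrow(Z_h)
  if (n != length(y)) stop("feature rows and label count differ")
  if (n < 3L) stop("need at least 3 labeled samples for a correlation")
  if (length(unique(y)) < 2L) {
    stop("need at least 2 classes present to correlate with labels")
  }
  Y <- standardized_onehot(y, n_classes)
  mu <- colMeans(Z_h)
  sd_ <- sqrt(colMeans(sweep(Z_h, 2L, mu)^2))
  Zs <- sweep(Z_h, 2L, mu)
  ok <- sd_ > 0
  Zs[, ok] <- sweep(Zs[, ok, drop = FALSE], 2L, sd_[ok], "/")
  R <- crossprod(Zs, Y) / n          # d_v x n_classes Pearson matrix
  R[!ok, ] <- 0
  val <- mean(apply(abs(R), 1L, max))
  min(max(val, 0), 1)
}

#' Head transferability score
#'
#' `HTS = alpha * exp(-dal) + (1 - alpha) * corr`: an exponentially
#' transformed alignment loss blended with the phenotypic correlation, so
#' well-aligned, label-relevant heads score near 1.
#'
#' @param dal Non-negative per-head domain alignment loss (vectorized).
#' @param corr Correlation score in `[0, 1]` (vectorized).
#' @param alpha Mixing weight in `[0, 1]` (default 0.6).
#' @return Scores in `(0, 1]` (given `corr` in range).
#' @export
head_transferability_score <- function(dal, corr, alpha = 0.6) {
  if (any(dal < 0)) stop("dal must be non-negative")
  if (any(corr < 0 | corr > 1)) stop("corr must lie in [0, 1]")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  alpha * exp(-dal) + (1 - alpha) * corr
}

#' Dynamic pruning threshold
#'
#' `tau = mean(hts) - beta * sd_pop(hts)` with the population (not sample)
#' standard deviation: the scored heads are the entire population being
#' thresholded, not a sample from a larger one.
#'
#' @param hts_values Numeric vector of at least 2 head scores.
#' @param beta Aggressiveness parameter (default 1.5); larger `beta` lowers
#'   `tau` and prunes fewer heads.
#' @return The threshold `tau`.
#' @export
prune_threshold <- function(hts_values, beta = 1.5) {
  if (length(hts_values) < 2L) {
    stop("need at least 2 HTS values to form a threshold")
  }
  mu <- mean(hts_values)
  sigma <- sqrt(mean((hts_values - mu)^2))
  mu - beta * sigma
}

#' Build a head score table
#'
#' One row per retained head with its DAL, correlation, and HTS columns;
#' the HTS column is recomputable from `(dal, corr, alpha)`.
#'
#' @param layer,head Integer index vectors (same length).
#' @param dal,corr Per-head scores.
#' @param alpha Mixing weight passed to [head_transferability_score()].
#' @return A `data.frame` of class `taha_head_scores` with attribute
#'   `alpha`.
#' @export
head_score_table <- function(layer, head, dal, corr, alpha = 0.6) {
  tab <- data.frame(layer = as.integer(layer), head = as.integer(head),
                    dal = dal, corr = corr,
                    hts = head_transferability_score(dal, corr, alpha))
  attr(tab, "alpha") <- alpha
  class(tab) <- c("taha_head_scores", "data.frame")
  tab
}

#' Select heads to retain via the dynamic threshold
#'
#' Pools HTS values (globally by default), computes
#' `tau = mean - beta * sd_pop`, and retains heads with `hts >= tau` (ties
#' retained). Layers that would fall below the per-layer floor get their
#' top-HTS heads force-retained and flagged.
#'
#' @param table A [head_score_table()] covering all currently retained
#'   heads.
#' @param beta Threshold aggressiveness (default 1.5).
#' @param min_heads_per_layer Per-layer retention floor (default 1).
#' @param pooling `"global"` (one tau over all layers, default) or
#'   `"layer"` (per-layer tau).
#' @return An object of class `taha_prune_mask`: `list(decisions, tau,
#'   beta, pooling)` where `decisions` has columns `layer, head, hts,
#'   retain, forced`.
#' @export
select_heads <- function(table, beta = 1.5, min_heads_per_layer = 1L,
                         pooling = c("global", "layer")) {
  pooling <- match.arg(pooling)
  if (is.null(table) || nrow(table) == 0L) stop("empty head score table")
  dec <- data.frame(layer = table$layer, head = table$head, hts = table$hts)
  if (pooling == "global") {
    tau <- prune_threshold(table$hts, beta)
    dec$retain <- dec$hts >= tau
  } else {
    tau <- vapply(split(table$hts, table$layer),
                  prune_threshold, numeric(1), beta = beta)
    dec$retain <- dec$hts >= tau[as.character(dec$layer)]
  }
  dec$forced <- FALSE
  for (l in unique(dec$layer)) {
    li <- which(dec$layer == l)
    kept <- sum(dec$retain[li])
    if (kept < min_heads_per_layer) {
      need <- min_heads_per_layer - kept
      cand <- li[!dec$retain[li]]
      cand <- cand[order(dec$hts[cand], decreasing = TRUE)]
      take <- cand[seq_len(min(need, length(cand)))]
      dec$retain[take] <- TRUE
      dec$forced[take] <- TRUE
    }
  }
  structure(list(decisions = dec, tau = tau, beta = beta, pooling = pooling),
            class = "taha_prune_mask")
}

#' @export
print.taha_prune_mask <- function(x, ...) {
  cat("Prune mask: tau =", format(x$tau, digits = 6),
      "(beta =", x$beta, ",", x$pooling, "pooling);",
      sum(x$decisions$retain), "of", nrow(x$decisions), "heads retained",
      if (any(x$decisions$forced))
        paste0("(", sum(x$decisions$forced), " floor-forced)") else "",
      "\n")
  invisible(x)
}

# Retained original head indices per layer, as a list keyed by layer.
mask_retained <- function(mask, depth = max(mask$decisions$layer)) {
  lapply(seq_len(depth), function(l) {
    d <- mask$decisions
    sort(d$head[d$layer == l & d$retain])
  })
}
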