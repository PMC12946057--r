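# Procedural two-domain plant-image benchmark. Two "species" share the
# morphology channel (class-conditional leaf-blob size and vein-like lines)
# but differ in texture/background statistics; a shift magnitude controls
# the texture divergence. An optional source-only corner glyph plants
# verifiably non-transferable structure: the glyph fills exactly the
# top-left corner patch of the TEXTURE channel and its brightness encodes
# the class. Reading it forces a head onto texture-space value features,
# and texture is class-independent everywhere on the target, so glyph
# heads are verifiably useless there while morphology heads transfer.
#
# Channel layout: 1 = morphology (class signal), 2 = texture (species
# signal), 3 = their mixture. Shape and texture use separate RNG streams so
# texture randomness can be re-drawn without touching labels or morphology.

#' Describe one synthetic image domain
#'
#' @param species_id Tag naming the domain (e.g. `"source"`).
#' @param n_classes Number of phenotype classes (>= 2).
#' @param shape_params Class-conditional shape distributions from
#'   [default_shape_params()]; share this object across a transfer pair to
#'   encode the shared-morphology assumption.
#' @param texture_params Baseline texture statistics
#'   (`list(bg, noise_sd, speckle)`).
#' @param shift_magnitude Non-negative texture divergence from the
#'   reference statistics.
#' @param image_size Image side length in pixels.
#' @param seed Seed for labels and morphology.
#' @param texture_seed Seed for the texture stream (defaults to
#'   `seed + 10007`).
#' @param glyph Add the class-coded corner glyph (source-only planted
#'   structure).
#' @return An object of class `taha_domain_spec`.
#' @export
domain_spec <- function(species_id, n_classes = 3L, shape_params = NULL,
                        texture_params = NULL, shift_magnitude = 0,
                        image_size = 32L, seed = 1L, texture_seed = NULL,
                        glyph = FALSE) {
  if (n_classes < 2L) stop("n_classes must be at least 2")
  if (shift_magnitude < 0) stop("shift_magnitude must be non-negative")
  if (is.null(shape_params)) {
    shape_params <- default_shape_params(n_classes)
  }
  if (length(shape_params) != n_classes) {
    stop("shape_params must have one entry per class")
  }
  if (is.null(texture_params)) texture_params <- default_texture_params()
  structure(list(species_id = species_id, n_classes = as.integer(n_classes),
                 shape_params = shape_params,
                 texture_params = texture_params,
                 shift_magnitude = shift_magnitude,
                 image_size = as.integer(image_size),
                 seed = as.integer(seed),
                 texture_seed = as.integer(texture_seed %||% (seed + 10007L)),
                 glyph = isTRUE(glyph)),
            class = "taha_domain_spec")
}

#' Default class-conditional shape distributions
#'
#' Classes differ in leaf-blob size: the major semi-axis of class `k` is
#' drawn from a narrow band around equally spaced fractions of the image
#' (disjoint across classes, so foreground area separates classes); the
#' minor axis is 0.6-0.9 of the major, orientation uniform, with 2-4
#' vein-like lines per blob in every class.
#'
#' @param n_classes Number of classes.
#' @return List of per-class `list(a_range, b_frac, veins)` entries.
#' @export
default_shape_params <- function(n_classes = 3L) {
  centers <- seq(0.16, 0.44, length.out = n_classes)
  half <- min(0.035, diff(range(centers)) / (4 * max(n_classes - 1, 1)))
  lapply(seq_len(n_classes), function(k) {
    list(a_range = c(centers[k] - half, centers[k] + half),
         b_frac = c(0.6, 0.9),
         veins = c(2L, 4L))
  })
}

#' Default texture statistics
#'
#' Background level 0.35, pixel white-noise sd 0.05, per-patch "blotch"
#' noise sd 0.12 (a low-frequency lighting-patch field, constant over
#' quarter-image cells, present in both domains), no extra speckle. A
#' shift of magnitude m perturbs these to `bg + 0.2 m`,
#' `noise_sd + 0.05 m`, and speckle amplitude `0.25 m` (an added
#' high-frequency noise field), so the band-pass energy of the texture
#' channel grows monotonically with m while the blotch field stays
#' domain-invariant.
#'
#' @return `list(bg, noise_sd, speckle, blotch)`.
#' @export
default_texture_params <- function() {
  list(bg = 0.35, noise_sd = 0.05, speckle = 0, blotch = 0.12)
}

shifted_texture <- function(tp, m) {
  list(bg = min(tp$bg + 0.2 * m, 0.8),
       noise_sd = tp$noise_sd + 0.05 * m,
       speckle = tp$speckle + 0.25 * m,
       blotch = tp$blotch %||% 0)
}

# Class-coded glyph brightness: evenly spaced levels well above/below the
# background so a linear readout of the corner patch separates classes.
glyph_level <- function(label, n_classes) {
  0.25 + 0.7 * (label - 1) / max(n_classes - 1, 1)
}

#' Generate a labeled image set from a domain spec
#'
#' Fully reproducible from the spec's seeds: labels and morphology come
#' from `seed`, texture noise from `texture_seed`. Pixel values are clipped
#' to `[0, 1]`.
#'
#' @param spec A [domain_spec()].
#' @param n Number of images (>= 0).
#' @return An object of class `taha_image_set`: `list(images, labels,
#'   labeled_mask, spec)` with `images` an `n x S x S x 3` array.
#' @export
generate_domain <- function(spec, n) {
  if (n < 0) stop("n must be non-negative")
  S <- spec$image_size
  images <- array(0, c(n, S, S, 3L))
  labels <- integer(n)
  if (n == 0L) {
    return(structure(list(images = images, labels = labels,
                          labeled_mask = logical(0), spec = spec),
                     class = "taha_image_set"))
  }
  xs <- matrix(rep(seq_len(S), each = S), S, S)   # column index
  ys <- matrix(rep(seq_len(S), S), S, S)          # row index
  gs <- max(S %/% 4L, 2L)                          # glyph block size

  set.seed(spec$seed)
  labels <- sample.int(spec$n_classes, n, replace = TRUE)
  shape_ch <- array(0, c(n, S, S))
  for (i in seq_len(n)) {
    sp <- spec$shape_params[[labels[i]]]
    cx <- S / 2 + stats::runif(1, -2, 2)
    cy <- S / 2 + stats::runif(1, -2, 2)
    a <- stats::runif(1, sp$a_range[1], sp$a_range[2]) * S
    b <- a * stats::runif(1, sp$b_frac[1], sp$b_frac[2])
    th <- stats::runif(1, 0, pi)
    dx <- (xs - cx) * cos(th) + (ys - cy) * sin(th)
    dy <- -(xs - cx) * sin(th) + (ys - cy) * cos(th)
    inside <- (dx / a)^2 + (dy / b)^2 <= 1
    ch <- 0.15 + 0.30 * inside
    nv <- sample(seq(sp$veins[1], sp$veins[2]), 1L)
    for (v in seq_len(nv)) {
      phi <- stats::runif(1, 0, pi)
      dist <- abs(-(xs - cx) * sin(phi) + (ys - cy) * cos(phi))
      ch[inside & dist < 0.7] <- ch[inside & dist < 0.7] - 0.2
    }
    ch <- ch + stats::rnorm(S * S, sd = 0.12)
    shape_ch[i, , ] <- pmin(pmax(ch, 0), 1)
  }

  set.seed(spec$texture_seed)
  tp <- shifted_texture(spec$texture_params, spec$shift_magnitude)
  for (i in seq_len(n)) {
    tex <- tp$bg + stats::rnorm(S * S, sd = tp$noise_sd) +
      tp$speckle * stats::rnorm(S * S)
    tex <- matrix(tex, S, S)
    if (tp$blotch > 0) {
      cells <- matrix(stats::rnorm(16, sd = tp$blotch), 4, 4)
      tex <- tex + cells[rep(1:4, each = gs), rep(1:4, each = gs)]
    }
    if (spec$glyph) {
      tex[1:gs, 1:gs] <- glyph_level(labels[i], spec$n_classes)
    }
    tex <- pmin(pmax(tex, 0), 1)
    mix <- pmin(pmax(0.5 * shape_ch[i, , ] + 0.5 * tex +
                       stats::rnorm(S * S, sd = 0.01), 0), 1)
    images[i, , , 1] <- shape_ch[i, , ]
    images[i, , , 2] <- tex
    images[i, , , 3] <- mix
  }
  structure(list(images = images, labels = labels,
                 labeled_mask = rep(TRUE, n), spec = spec),
            class = "taha_image_set")
}

#' @export
print.taha_image_set <- function(x, ...) {
  cat("taha_image_set:", length(x$labels), "images",
      paste0(x$spec$image_size, "px"), "| species", x$spec$species_id,
      "|", sum(x$labeled_mask), "labeled\n")
  invisible(x)
}

#' Build a source/target transfer pair
#'
#' Both domains share the class-conditional shape distributions; the target
#' texture is shifted by `shift_magnitude`. The source is fully labeled;
#' the target exposes labels for `round(labeled_fraction * n_target)`
#' randomly chosen images. When `glyph = TRUE` the class-coded corner
#' glyph appears in source images only.
#'
#' @param shape_params Shared shape distributions (default
#'   [default_shape_params()]).
#' @param shift_magnitude Texture divergence of the target domain.
#' @param labeled_fraction Labeled fraction of the target in `(0, 1]`;
#'   default 0.125, within the 10-15 percent semi-supervised protocol.
#' @param n_source,n_target Set sizes.
#' @param seed Master seed; domain and mask seeds are derived from it.
#' @param n_classes,image_size Passed to both domains.
#' @param glyph Plant the source-only glyph.
#' @return `list(source, target)` of `taha_image_set`s.
#' @export
make_transfer_pair <- function(shape_params = NULL, shift_magnitude = 0.5,
                               labeled_fraction = 0.125, n_source = 240L,
                               n_target = 240L, seed = 1L, n_classes = 3L,
                               image_size = 32L, glyph = FALSE) {
  if (labeled_fraction <= 0 || labeled_fraction > 1) {
    stop("labeled_fraction must lie in (0, 1]")
  }
  if (is.null(shape_params)) shape_params <- default_shape_params(n_classes)
  src <- generate_domain(
    domain_spec("source", n_classes, shape_params,
                shift_magnitude = 0, image_size = image_size,
                seed = derive_seed(seed, 1L), glyph = glyph),
    n_source)
  tgt <- generate_domain(
    domain_spec("target", n_classes, shape_params,
                shift_magnitude = shift_magnitude, image_size = image_size,
                seed = derive_seed(seed, 2L), glyph = FALSE),
    n_target)
  if (n_target > 0L) {
    set.seed(derive_seed(seed, 3L))
    k <- round(labeled_fraction * n_target)
    k <- max(min(k, n_target), 1L)
    mask <- rep(FALSE, n_target)
    mask[sample.int(n_target, k)] <- TRUE
    tgt$labeled_mask <- mask
  }
  list(source = src, target = tgt)
}

# Deterministic sub-seed derivation; stays below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483629)
}

#' Token index of the glyph patch for each image
#'
#' The glyph sits on the top-left corner patch (patch 1) in every source
#' image; the index is offset by one when a class token is prepended.
#'
#' @param labels Integer class labels (one token index is returned per
#'   label, keeping the per-image interface).
#' @param config The model config (for the cls-token offset).
#' @return Integer token indices, one per image.
#' @export
glyph_token_index <- function(labels, config) {
  rep(1L + (if (config$use_cls_token) 1L else 0L), length(labels))
}

# Band-pass (high-frequency) energy of the texture channel: mean squared
# deviation from a 3x3 box blur, averaged over images.
bandpass_energy <- function(set, channel = 2L) {
  n <- dim(set$images)[1]
  if (n == 0L) return(NA_real_)
  e <- numeric(n)
  for (i in seq_len(n)) {
    img <- set$images[i, , , channel]
    e[i] <- mean((img - box_blur3(img))^2)
  }
  mean(e)
}

box_blur3 <- function(m) {
  S <- nrow(m)
  pad <- rbind(m[1, , drop = FALSE], m, m[S, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, S, drop = FALSE])
  out <- matrix(0, S, S)
  for (di in 0:2) for (dj in 0:2) {
    out <- out + pad[(1:S) + di, (1:S) + dj]
  }
  out / 9
}

#' Mean texture discrepancy between two image sets
#'
#' Absolute difference of the band-pass (high-frequency) energy of the
#' texture channel, the fixed statistic used to verify that the shift
#' magnitude monotonically separates the domains.
#'
#' @param a,b `taha_image_set`s.
#' @return Non-negative scalar.
#' @export
texture_discrepancy <- function(a, b) {
  abs(bandpass_energy(a) - bandpass_energy(b))
}
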