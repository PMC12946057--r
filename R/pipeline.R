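# End-to-end loop: pretrain on source -> iterate (align -> score -> prune ->
# fine-tune) until an outer iteration prunes nothing (pruning is the only
# irreversible state change) or the iteration cap is hit. During the loop
# pruned heads are masked, which is provably output-equivalent to removal;
# physical surgery produces the final compact model.

#' Full run configuration
#'
#' Mirrors the pipeline's tunables. Defaults follow the reference
#' adaptation protocol (`alpha = 0.6`, `beta = 1.5`, `lambda0 = 0.1` with
#' linear warmup, Adam at `3e-5`, batch 32); training-rate fields can be
#' overridden per stage for small backbones trained from scratch.
#'
#' @param seed Master seed (mandatory); per-stage seeds derive from it.
#' @param image_size,patch_size,channels,depth,heads,embed_dim,mlp_dim,n_classes,use_cls_token
#'   Backbone architecture (see [model_config()]).
#' @param n_source,n_target,labeled_fraction,shift_magnitude,glyph Synthetic
#'   transfer-pair settings (see [make_transfer_pair()]).
#' @param lr,batch_size Reference optimizer settings (Adam).
#' @param pretrain_lr,align_lr,finetune_lr Stage learning rates; default to
#'   `lr`.
#' @param alpha HTS mixing weight. @param beta Threshold aggressiveness.
#' @param pooling HTS pooling for the threshold (`"global"` or `"layer"`).
#' @param lambda0,lambda_max,warmup_steps Lambda schedule.
#' @param pretrain_steps,steps_per_phase Step budgets.
#' @param max_outer_iters Outer iteration cap (default 5).
#' @param min_heads_per_layer Retention floor (default 1).
#' @param update_scope Live parameters updated during alignment.
#' @param record_every Record the HTS trajectory every this many alignment
#'   steps.
#' @param mlp_hidden Hidden width of the phenotypic MLP.
#' @param output_dir Artifact directory, or `NULL` for in-memory only.
#' @return A list of class `taha_run_config`.
#' @export
run_config <- function(seed,
                       image_size = 32L, patch_size = 8L, channels = 3L,
                       depth = 2L, heads = 4L, embed_dim = 32L,
                       mlp_dim = 64L, n_classes = 3L, use_cls_token = TRUE,
                       n_source = 240L, n_target = 240L,
                       labeled_fraction = 0.125, shift_magnitude = 0.5,
                       glyph = FALSE,
                       lr = 3e-5, batch_size = 32L,
                       pretrain_lr = lr, align_lr = lr, finetune_lr = lr,
                       alpha = 0.6, beta = 1.5,
                       pooling = c("global", "layer"),
                       lambda0 = 0.1, lambda_max = 1.0,
                       warmup_steps = steps_per_phase,
                       pretrain_steps = 300L, steps_per_phase = 60L,
                       max_outer_iters = 5L, min_heads_per_layer = 1L,
                       update_scope = c("attention", "all_but_patch"),
                       record_every = 10L, mlp_hidden = 32L,
                       output_dir = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(alpha >= 0, alpha <= 1, beta >= 0, lambda0 >= 0,
            lambda_max >= lambda0, labeled_fraction > 0,
            labeled_fraction <= 1, max_outer_iters >= 1)
  cfg <- list(seed = as.integer(seed),
              model = model_config(image_size, patch_size, channels, depth,
                                   heads, embed_dim, mlp_dim = mlp_dim,
                                   n_classes = n_classes,
                                   use_cls_token = use_cls_token),
              n_source = n_source, n_target = n_target,
              labeled_fraction = labeled_fraction,
              shift_magnitude = shift_magnitude, glyph = glyph,
              lr = lr, batch_size = as.integer(batch_size),
              pretrain_lr = pretrain_lr, align_lr = align_lr,
              finetune_lr = finetune_lr,
              alpha = alpha, beta = beta, pooling = match.arg(pooling),
              lambda0 = lambda0, lambda_max = lambda_max,
              warmup_steps = warmup_steps,
              pretrain_steps = as.integer(pretrain_steps),
              steps_per_phase = as.integer(steps_per_phase),
              max_outer_iters = as.integer(max_outer_iters),
              min_heads_per_layer = as.integer(min_heads_per_layer),
              update_scope = match.arg(update_scope),
              record_every = as.integer(record_every),
              mlp_hidden = as.integer(mlp_hidden),
              output_dir = output_dir)
  class(cfg) <- "taha_run_config"
  cfg
}

#' Small-backbone demonstration configuration
#'
#' The study conditions used throughout the package's experiments and
#' vignette: a 2-layer, 4-head, width-32 backbone on 32 px images with the
#' planted source-only glyph, 240 source and 400 target images, a 15%
#' labeled target fraction, a width-8 phenotypic MLP, and stage learning
#' rates of 1e-3 (appropriate for a model of this size trained from
#' scratch; the 3e-5 reference rate targets full-size fine-tuning).
#'
#' @param seed Master seed.
#' @param ... Overrides forwarded to [run_config()].
#' @return A `taha_run_config`.
#' @export
demo_run_config <- function(seed, ...) {
  args <- list(seed = seed, glyph = TRUE,
               n_target = 400L, labeled_fraction = 0.15,
               pretrain_lr = 1e-3, align_lr = 1e-3, finetune_lr = 1e-3,
               pretrain_steps = 300L, steps_per_phase = 60L,
               max_outer_iters = 3L, mlp_hidden = 8L)
  over <- list(...)
  args[names(over)] <- over
  do.call(run_config, args)
}

make_pair_from_config <- function(config) {
  make_transfer_pair(shift_magnitude = config$shift_magnitude,
                     labeled_fraction = config$labeled_fraction,
                     n_source = config$n_source, n_target = config$n_target,
                     seed = derive_seed(config$seed, 101L),
                     n_classes = config$model$n_classes,
                     image_size = config$model$image_size,
                     glyph = config$glyph)
}

# Supervised cross-entropy training (used for source pretraining and
# target fine-tuning). Returns the updated model and the per-step loss.
train_supervised <- function(model, images, labels, steps, lr, batch_size,
                             scope = "all", seed = 1L, mask = NULL) {
  if (steps == 0L) return(list(model = model, losses = numeric(0)))
  set.seed(seed)
  st <- adam_state(lr = lr)
  trainable <- param_scope(model, scope)
  n <- dim(images)[1]
  losses <- numeric(steps)
  for (s in seq_len(steps)) {
    idx <- if (n >= batch_size) sample.int(n, batch_size) else
      sample.int(n, batch_size, replace = TRUE)
    fw <- vit_forward(model, images[idx, , , , drop = FALSE], mask = mask,
                      keep_cache = TRUE)
    ce <- softmax_xent(fw$scores, labels[idx])
    if (!is.finite(ce$loss)) {
      stop("training diverged (loss not finite) at step ", s)
    }
    grads <- vit_backward(model, fw, dscores = ce$dscores)
    model$params <- adam_step(model$params, grads, st, trainable)
    losses[s] <- ce$loss
  }
  list(model = model, losses = losses)
}

#' Predict class labels
#'
#' @param model A `taha_model`.
#' @param images `B x S x S x C` array.
#' @param mask Optional per-layer head mask.
#' @param chunk Forward-pass batch size.
#' @return Integer predicted labels.
#' @export
predict_classes <- function(model, images, mask = NULL, chunk = 64L) {
  n <- dim(images)[1]
  out <- integer(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    fw <- vit_forward(model, images[idx, , , , drop = FALSE], mask = mask,
                      keep_records = FALSE)
    out[idx] <- max.col(fw$scores, ties.method = "first")
  }
  out
}

classification_accuracy <- function(model, images, labels, mask = NULL) {
  mean(predict_classes(model, images, mask = mask) == labels)
}

#' Pretrain the backbone on the source domain
#'
#' Initializes a model from the derived init seed and trains it with
#' cross-entropy on the (fully labeled) source set; the checkpoint becomes
#' both the frozen snapshot and the live model's initialization. With
#' `pretrain_steps = 0` the returned model equals its initialization.
#'
#' @param config A [run_config()].
#' @param data Optional transfer pair (generated from the config if
#'   `NULL`).
#' @return `list(model, losses, data)`.
#' @export
pretrain_source <- function(config, data = NULL) {
  if (is.null(data)) data <- make_pair_from_config(config)
  src <- data$source
  if (!any(src$labeled_mask)) stop("source set has no labels")
  set.seed(derive_seed(config$seed, 11L))
  model <- init_model(config$model)
  li <- which(src$labeled_mask)
  tr <- train_supervised(model, src$images[li, , , , drop = FALSE],
                         src$labels[li], config$pretrain_steps,
                         lr = config$pretrain_lr,
                         batch_size = config$batch_size, scope = "all",
                         seed = derive_seed(config$seed, 12L))
  list(model = tr$model, losses = tr$losses, data = data)
}

# Score all active heads on a labeled evaluation batch.
evaluate_head_scores <- function(frozen, live, mask, images, y, alpha) {
  fwf <- vit_forward(frozen, images, mask = mask, keep_records = TRUE)
  fwl <- vit_forward(live, images, mask = mask, keep_records = TRUE)
  dal <- dal_per_head(fwf$record, fwl$record, mask)$table
  cfg <- live$config
  dk <- cfg$head_dim
  pooled <- fwl$record$pooled
  corr <- numeric(nrow(dal))
  off_layer <- c(0L, cumsum(cfg$heads_per_layer * dk))
  for (i in seq_len(nrow(dal))) {
    l <- dal$layer[i]; h <- dal$head[i]
    cols <- off_layer[l] + ((h - 1L) * dk + 1L):(h * dk)
    corr[i] <- head_label_correlation(pooled[, cols, drop = FALSE], y,
                                      n_classes = cfg$n_classes)
  }
  head_score_table(dal$layer, dal$head, dal$dal, corr, alpha)
}

#' Run the full iterative align-score-prune-finetune loop
#'
#' Executes, per outer iteration: (1) compute attention maps on target
#' batches, (2) update head parameters on `mean DAL + lambda * PCC`, (3)
#' evaluate HTS on the labeled target subset, (4) prune heads below the
#' dynamic threshold, (5) fine-tune the remaining heads on labeled target
#' data. Stops when an iteration prunes nothing or `max_outer_iters` is
#' reached. Fully reproducible from the config seed.
#'
#' @param config A [run_config()].
#' @param data Optional pre-built transfer pair.
#' @param pretrained Optional source-pretrained model (skips pretraining).
#' @param prune Set `FALSE` to run the identical alignment/fine-tune
#'   schedule without removing heads (the unpruned baseline); the loop then
#'   always runs `max_outer_iters` iterations.
#' @return An object of class `taha_run`; see [report()].
#' @export
run_taha <- function(config, data = NULL, pretrained = NULL, prune = TRUE) {
  if (is.null(data)) data <- make_pair_from_config(config)
  if (is.null(pretrained)) {
    pretrained <- pretrain_source(config, data)$model
  }
  tgt <- data$target
  n_t <- length(tgt$labels)
  li <- which(tgt$labeled_mask)
  if (length(li) == 0L) stop("target set has no labeled fraction")
  imgs_l <- tgt$images[li, , , , drop = FALSE]
  y_l <- tgt$labels[li]

  astate <- alignment_state(pretrained, warmup_steps = config$warmup_steps,
                            lr = config$align_lr, lambda0 = config$lambda0,
                            lambda_max = config$lambda_max,
                            mlp_hidden = config$mlp_hidden,
                            update_scope = config$update_scope)
  metrics <- list(); traj <- list(); score_tables <- list(); masks <- list()
  mrow <- 0L; trow <- 0L
  iters_done <- 0L
  pruned_any <- FALSE

  for (it in seq_len(config$max_outer_iters)) {
    iters_done <- it
    set.seed(derive_seed(config$seed, 200L + it))
    for (s in seq_len(config$steps_per_phase)) {
      idx <- if (n_t >= config$batch_size)
        sample.int(n_t, config$batch_size) else
          sample.int(n_t, config$batch_size, replace = TRUE)
      res <- alignment_step(astate, tgt$images[idx, , , , drop = FALSE],
                            tgt$labels[idx], tgt$labeled_mask[idx])
      astate <- res$state
      mrow <- mrow + 1L
      metrics[[mrow]] <- data.frame(
        iter = it, phase = "align", step = astate$step,
        lambda = res$metrics$lambda, mean_dal = res$metrics$mean_dal,
        pcc = res$metrics$pcc, loss = res$metrics$total)
      if (s %% config$record_every == 0L) {
        tab <- evaluate_head_scores(astate$frozen, astate$live, astate$mask,
                                    imgs_l, y_l, config$alpha)
        trow <- trow + 1L
        traj[[trow]] <- cbind(iter = it, align_step = astate$step,
                              as.data.frame(tab))
      }
    }

    tab <- evaluate_head_scores(astate$frozen, astate$live, astate$mask,
                                imgs_l, y_l, config$alpha)
    mask_obj <- select_heads(tab, beta = config$beta,
                             min_heads_per_layer = config$min_heads_per_layer,
                             pooling = config$pooling)
    score_tables[[it]] <- tab
    masks[[it]] <- mask_obj

    converged <- FALSE
    if (prune) {
      retained <- mask_retained(mask_obj, config$model$depth)
      newly <- sum(vapply(astate$mask, sum, 1L)) -
        sum(lengths(retained))
      if (newly == 0L) {
        converged <- TRUE
      } else {
        pruned_any <- TRUE
        for (l in seq_len(config$model$depth)) {
          keep <- rep(FALSE, config$model$heads_per_layer[l])
          keep[retained[[l]]] <- TRUE
          astate$mask[[l]] <- astate$mask[[l]] & keep
        }
        # parameter shapes change at the eventual surgery; moment estimates
        # for removed heads are meaningless, so reset the optimizer state
        astate$opt_model <- adam_state(lr = config$align_lr)
        astate$opt_mlp <- adam_state(lr = config$align_lr)
      }
    }

    ft <- train_supervised(astate$live, imgs_l, y_l,
                           config$steps_per_phase,
                           lr = config$finetune_lr,
                           batch_size = min(config$batch_size, length(li)),
                           scope = "heads_classifier",
                           seed = derive_seed(config$seed, 300L + it),
                           mask = astate$mask)
    astate$live <- ft$model
    if (length(ft$losses)) {
      mrow <- mrow + 1L
      metrics[[mrow]] <- data.frame(
        iter = it, phase = "finetune", step = NA_integer_,
        lambda = NA_real_, mean_dal = NA_real_, pcc = NA_real_,
        loss = mean(ft$losses))
    }
    # every outer iteration ends with supervised fine-tuning; convergence
    # (an iteration that pruned nothing) only decides whether another
    # iteration starts
    if (converged) break
  }

  retained_final <- lapply(astate$mask, which)
  surgery <- prune_model(astate$live, retained_final)
  acc <- classification_accuracy(astate$live, imgs_l, y_l,
                                 mask = astate$mask)
  run <- structure(list(
    config = config, data = data,
    source_model = pretrained,
    aligned_model = astate$live,
    final_model = surgery$model,
    mlp = astate$mlp,
    alive = retained_final,
    head_mask = astate$mask,
    masks = masks, score_tables = score_tables,
    metrics = do.call(rbind, metrics),
    trajectory = if (length(traj)) do.call(rbind, traj) else NULL,
    iterations = iters_done,
    pruned_any = pruned_any,
    cost_report = surgery$report,
    target_labeled_accuracy = acc), class = "taha_run")
  if (!is.null(config$output_dir)) write_run_artifacts(run)
  run
}

#' @export
print.taha_run <- function(x, ...) {
  cat("taha run:", x$iterations, "outer iteration(s);",
      sum(lengths(x$alive)), "of",
      sum(x$config$model$heads_per_layer), "heads retained;",
      "labeled-target accuracy", round(x$target_labeled_accuracy, 3), "\n")
  invisible(x)
}

write_run_artifacts <- function(run) {
  dir <- run$config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config_to_list(run$config), file.path(dir, "config.yaml"))
  save_checkpoint(run$source_model, file.path(dir, "source_checkpoint.json"))
  save_checkpoint(run$final_model, file.path(dir, "final_compact.json"))
  for (it in seq_along(run$score_tables)) {
    write_score_table(run$score_tables[[it]],
                      file.path(dir, sprintf("head_scores_iter%02d.csv", it)))
    write_prune_mask(run$masks[[it]],
                     file.path(dir, sprintf("prune_mask_iter%02d.json", it)))
  }
  utils::write.csv(run$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  if (!is.null(run$trajectory)) {
    utils::write.csv(run$trajectory, file.path(dir, "hts_trajectory.csv"),
                     row.names = FALSE)
  }
  write_cost_report(run$cost_report,
                    json_path = file.path(dir, "cost_report.json"),
                    csv_path = file.path(dir, "cost_report.csv"))
  invisible(dir)
}

#' Summarize a finished run
#'
#' Produces the cost accounting (full vs compact), the per-head HTS
#' trajectory, and the alignment-vs-correlation scatter table (one row per
#' initial head with its last recorded scores and retention flag).
#'
#' @param run A `taha_run`.
#' @return `list(cost_report, trajectory, scatter, summary)`.
#' @export
report <- function(run) {
  if (!inherits(run, "taha_run")) stop("report() expects a taha_run")
  if (length(run$score_tables) == 0L) stop("run has no score tables")
  last_seen <- list()
  for (tab in run$score_tables) {
    for (i in seq_len(nrow(tab))) {
      key <- paste(tab$layer[i], tab$head[i])
      last_seen[[key]] <- tab[i, , drop = FALSE]
    }
  }
  scatter <- do.call(rbind, unname(last_seen))
  scatter <- as.data.frame(scatter)
  scatter$retained <- mapply(function(l, h) h %in% run$alive[[l]],
                             scatter$layer, scatter$head)
  scatter <- scatter[order(scatter$layer, scatter$head), ]
  rownames(scatter) <- NULL
  summary <- list(
    iterations = run$iterations,
    heads_initial = sum(run$config$model$heads_per_layer),
    heads_final = sum(lengths(run$alive)),
    target_labeled_accuracy = run$target_labeled_accuracy,
    reductions = as.list(run$cost_report$reductions))
  list(cost_report = run$cost_report, trajectory = run$trajectory,
       scatter = scatter, summary = summary)
}

#' Mean attention mass on glyph tokens per head
#'
#' For images carrying the class-coded corner glyph, measures each head's
#' mean attention (over query rows and images) into the glyph token. Heads
#' exceeding twice the uniform share `1/n_tokens` are glyph-attending.
#'
#' @param model A `taha_model`.
#' @param images Source-domain images with the glyph.
#' @param glyph_tokens Per-image glyph token index
#'   (see [glyph_token_index()]).
#' @param mask Optional head mask.
#' @return Data frame `layer, head, mass`.
#' @export
glyph_attention_mass <- function(model, images, glyph_tokens, mask = NULL) {
  fw <- vit_forward(model, images, mask = mask, keep_records = TRUE)
  cfg <- model$config
  mask <- check_mask(mask, cfg)
  B <- dim(images)[1]
  rows <- list(); k <- 0L
  for (l in seq_len(cfg$depth)) {
    for (h in seq_len(cfg$heads_per_layer[l])) {
      if (!mask[[l]][h]) next
      A <- fw$record$maps[[l]][[h]]
      m <- mean(vapply(seq_len(B), function(b) {
        mean(A[, glyph_tokens[b], b])
      }, numeric(1)))
      k <- k + 1L
      rows[[k]] <- data.frame(layer = l, head = h, mass = m)
    }
  }
  do.call(rbind, rows)
}

config_to_list <- function(config) {
  out <- unclass(config)
  out$model <- unclass(out$model)
  out
}

#' Build a run configuration from a YAML file
#'
#' The YAML mirrors [run_config()] field-for-field (model fields at top
#' level, as in the function signature).
#'
#' @param path YAML file path.
#' @param seed Optional seed override.
#' @return A `taha_run_config`.
#' @export
read_run_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(seed)) y$seed <- seed
  do.call(run_config, y)
}
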