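# Adam over flat named parameter lists. State is an environment so repeated
# steps mutate moment estimates in place; it is discarded (reset) after any
# pruning event because parameter shapes change.

adam_state <- function(lr = 3e-5, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$m <- list()
  st$v <- list()
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st
}

# One Adam update on `params` using `grads`; only names in `trainable` (and
# present in grads) move. Returns the updated parameter list.
adam_step <- function(params, grads, st, trainable = names(params)) {
  st$t <- st$t + 1L
  b1 <- st$beta1; b2 <- st$beta2
  c1 <- 1 - b1^st$t
  c2 <- 1 - b2^st$t
  for (nm in intersect(trainable, names(grads))) {
    gr <- grads[[nm]]
    if (is.null(st$m[[nm]])) {
      st$m[[nm]] <- gr * 0
      st$v[[nm]] <- gr * 0
    }
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * gr
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * gr^2
    params[[nm]] <- params[[nm]] -
      st$lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + st$eps)
  }
  params
}

# Named-parameter selections for the training phases. "attention" is the
# per-head Q/K/V/O projections only; "heads_classifier" adds the readout
# (final norm + classifier) for supervised fine-tuning of retained heads;
# "all_but_patch" frees everything except the patch projection.
param_scope <- function(model, scope = c("attention", "heads_classifier",
                                         "all", "all_but_patch")) {
  scope <- match.arg(scope)
  nms <- names(model$params)
  attn <- grep("^L[0-9]+\\.(Wq|bq|Wk|bk|Wv|bv|Wo|bo)$", nms, value = TRUE)
  switch(scope,
         attention = attn,
         heads_classifier = c(attn, "lnf_g", "lnf_b", "head_W", "head_b"),
         all = nms,
         all_but_patch = setdiff(nms, c("patch_W", "patch_b")))
}

# MD5 over the serialized parameter list; pins frozen-model immutability.
param_checksum <- function(model) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(model$params, f, version = 2L)
  unname(tools::md5sum(f))
}
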