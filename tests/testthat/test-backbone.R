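# Backbone contracts: patch embedding geometry, attention-map structure,
# and equivalence of the vectorized MHSA with an independent dense oracle.

test_that("patch embedding produces the expected token counts", {
  cfg224 <- model_config(224, 16, 3, depth = 1, heads_per_layer = 2,
                         embed_dim = 8, mlp_dim = 8, n_classes = 2)
  expect_equal(n_tokens(cfg224), 197L)
  set.seed(1)
  m <- init_model(cfg224)
  img <- array(stats::runif(224 * 224 * 3), c(224, 224, 3))
  expect_equal(dim(patch_embed(img, m)), c(197L, 8L))

  cfg16 <- tiny_cfg(image = 16L, patch = 4L, cls = FALSE)
  expect_equal(n_tokens(cfg16), 16L)

  expect_error(model_config(30, 16, 3, depth = 1, heads_per_layer = 1,
                            embed_dim = 8, mlp_dim = 8, n_classes = 2),
               "divisible")
  m2 <- tiny_model(seed = 2)
  bad <- array(0.5, c(8, 8, 3))
  expect_error(patch_embed(bad, m2), "shape")
})

test_that("degenerate attention cases produce the exact closed forms", {
  set.seed(3)
  d <- 8L; dk <- 4L; H <- 2L
  lp <- list(Wq = matrix(rnorm(d * H * dk), d), bq = numeric(H * dk),
             Wk = matrix(rnorm(d * H * dk), d), bk = numeric(H * dk),
             Wv = matrix(rnorm(d * H * dk), d), bv = numeric(H * dk),
             Wo = matrix(rnorm(H * dk * d), H * dk), bo = numeric(d))
  # single token: softmax over one key
  one <- mhsa_forward(matrix(rnorm(d), 1, d), lp, dk)
  for (h in 1:H) expect_equal(one$maps[[h]], matrix(1, 1, 1))
  # identical key vectors: equal logits, so every row is uniform
  x2 <- rbind(rep(0.3, d), rep(0.3, d))
  two <- mhsa_forward(x2, lp, dk)
  for (h in 1:H) {
    expect_equal(two$maps[[h]], matrix(0.5, 2, 2), tolerance = 1e-12)
  }
  expect_error(mhsa_forward(x2, lp, dk, mask = c(FALSE, FALSE)), "masked")
  x2[1, 1] <- NaN
  expect_error(mhsa_forward(x2, lp, dk), "NaN|finite")
})

test_that("mhsa_forward matches the naive dense oracle on random instances", {
  set.seed(4)
  for (i in 1:100) {
    n <- sample(2:6, 1)
    dk <- sample(2:4, 1)
    H <- sample(1:3, 1)
    d <- sample(c(4L, 6L, 8L), 1)
    lp <- list(Wq = matrix(rnorm(d * H * dk), d), bq = rnorm(H * dk),
               Wk = matrix(rnorm(d * H * dk), d), bk = rnorm(H * dk),
               Wv = matrix(rnorm(d * H * dk), d), bv = rnorm(H * dk),
               Wo = matrix(rnorm(H * dk * d), H * dk), bo = rnorm(d))
    x <- matrix(rnorm(n * d), n, d)
    mask <- if (H > 1 && i %% 3 == 0) {
      ms <- rep(TRUE, H); ms[sample(H, 1)] <- FALSE; ms
    } else NULL
    got <- mhsa_forward(x, lp, dk, mask = mask)
    want <- naive_mhsa(x, lp, dk, mask = mask)
    expect_lt(max(abs(got$output - want)), 1e-6)
  }
})

test_that("recorded attention rows are stochastic for arbitrary inputs", {
  for (seed in 1:5) {
    m <- tiny_model(seed = seed)
    fw <- forward_with_records(m, rand_images(3, m$config, seed = seed + 50))
    for (l in 1:m$config$depth) {
      for (h in 1:m$config$heads_per_layer[l]) {
        A <- record_maps(fw$record, l, h)
        expect_true(all(A >= 0))
        expect_lt(max(abs(apply(A, 3, rowSums) - 1)), 1e-5)
      }
    }
  }
})

test_that("permuting heads with matching W_o row blocks preserves output", {
  m <- tiny_model(seed = 7, heads = 3L, d = 12L)
  dk <- m$config$head_dim
  imgs <- rand_images(2, m$config, seed = 8)
  base <- vit_forward(m, imgs, keep_records = FALSE)$scores
  perm <- c(3L, 1L, 2L)
  m2 <- m
  idx <- as.vector(vapply(perm, function(h) ((h - 1) * dk + 1):(h * dk),
                          integer(dk)))
  for (l in 1:m$config$depth) {
    nm <- function(s) paste0("L", l, ".", s)
    for (w in c("Wq", "Wk", "Wv")) {
      m2$params[[nm(w)]] <- m$params[[nm(w)]][, idx]
    }
    for (b in c("bq", "bk", "bv")) {
      m2$params[[nm(b)]] <- m$params[[nm(b)]][idx]
    }
    m2$params[[nm("Wo")]] <- m$params[[nm("Wo")]][idx, ]
  }
  permuted <- vit_forward(m2, imgs, keep_records = FALSE)$scores
  expect_lt(max(abs(base - permuted)), 1e-6)
})

test_that("forward_with_records exposes scores, maps, and Z as contracted", {
  m <- tiny_model(seed = 9)
  imgs <- rand_images(1, m$config, seed = 10)
  fw <- forward_with_records(m, imgs)
  expect_equal(dim(fw$scores), c(1L, 2L))
  n_maps <- sum(vapply(seq_len(m$config$depth), function(l) {
    sum(!vapply(fw$record$maps[[l]], is.null, TRUE))
  }, 1L))
  expect_equal(n_maps, 4L)  # 2 layers x 2 heads
  expect_equal(ncol(fw$pooled_z),
               sum(m$config$heads_per_layer) * m$config$head_dim)

  # bitwise determinism
  fw2 <- forward_with_records(m, imgs)
  expect_identical(fw$scores, fw2$scores)

  # masked head absent from the records
  msk <- list(c(TRUE, FALSE), c(TRUE, TRUE))
  fwm <- forward_with_records(m, imgs, mask = msk)
  expect_null(record_maps(fwm$record, 1, 2))
  expect_false(is.null(record_maps(fwm$record, 1, 1)))

  expect_error(vit_forward(m, array(0, c(0, 16, 16, 3))), "empty")
})

test_that("analytic gradients match finite differences for both loss paths", {
  cfg <- tiny_cfg()
  set.seed(11)
  model <- init_model(cfg)
  frozen <- tiny_model(seed = 12)
  imgs <- rand_images(2, cfg, seed = 13)
  y <- c(1L, 2L)
  lam <- 0.5
  set.seed(14)
  mlp <- taha:::mlp_init(sum(cfg$heads_per_layer) * cfg$head_dim, 6, 2)
  msk <- taha:::default_mask(cfg)

  loss_of <- function(m) {
    fwf <- taha:::vit_forward(frozen, imgs, keep_records = TRUE)
    fwl <- taha:::vit_forward(m, imgs, keep_records = TRUE)
    ce <- taha:::softmax_xent(fwl$scores, y)
    d <- taha:::dal_per_head(fwf$record, fwl$record, msk)
    pcc <- phenotypic_consistency_loss(fwl$record$pooled, y, mlp)
    ce$loss + mean(d$table$dal) + lam * pcc
  }

  fwf <- taha:::vit_forward(frozen, imgs, keep_records = TRUE)
  fwl <- taha:::vit_forward(model, imgs, keep_cache = TRUE)
  ce <- taha:::softmax_xent(fwl$scores, y)
  d <- taha:::dal_per_head(fwf$record, fwl$record, msk, with_grad = TRUE)
  na <- nrow(d$table)
  for (l in seq_along(d$dA)) for (h in seq_along(d$dA[[l]])) {
    if (!is.null(d$dA[[l]][[h]])) d$dA[[l]][[h]] <- d$dA[[l]][[h]] / na
  }
  pg <- taha:::pcc_grad(fwl$record$pooled, y, mlp, rep(TRUE, 2), 2)
  n <- n_tokens(cfg); dk <- cfg$head_dim
  dZ <- list(); off <- 0L
  for (l in 1:cfg$depth) {
    w <- cfg$heads_per_layer[l] * dk
    sl <- pg$dZ_labeled[, (off + 1):(off + w), drop = FALSE] * (lam / n)
    dZ[[l]] <- sl[rep(1:2, each = n), , drop = FALSE]
    off <- off + w
  }
  g <- taha:::vit_backward(model, fwl, dscores = ce$dscores,
                           dA = d$dA, dZ = dZ)
  eps <- 1e-5
  for (nm in c("patch_W", "pos", "cls", "L1.Wq", "L1.Wk", "L1.Wv", "L1.Wo",
               "L1.ln1_g", "L2.W1", "L2.W2", "lnf_g", "head_W", "L2.bv")) {
    i <- min(3L, length(model$params[[nm]]))
    up <- model; up$params[[nm]][i] <- up$params[[nm]][i] + eps
    dn <- model; dn$params[[nm]][i] <- dn$params[[nm]][i] - eps
    num <- (loss_of(up) - loss_of(dn)) / (2 * eps)
    expect_lt(abs(num - g[[nm]][i]), 1e-6)
  }
})
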