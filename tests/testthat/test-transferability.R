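# HTS scoring and dynamic-threshold head selection.

test_that("head-label correlation handles indicator, null, and constants", {
  # a feature equal to the class indicator correlates perfectly
  y <- rep(c(1L, 2L), each = 10)
  Z <- cbind(as.numeric(y == 1L))
  expect_equal(head_label_correlation(Z, y), 1.0)

  # features independent of labels concentrate near zero at large n
  vals <- vapply(1:10, function(s) {
    set.seed(s)
    Zr <- matrix(stats::rnorm(2000 * 64), 2000, 64)
    yr <- sample.int(3, 2000, replace = TRUE)
    head_label_correlation(Zr, yr, n_classes = 3L)
  }, numeric(1))
  expect_lt(mean(vals), 0.1)

  # all-constant features contribute zero by convention
  expect_equal(head_label_correlation(matrix(2, 20, 3), y), 0)

  expect_error(head_label_correlation(matrix(1:2, 2, 1), c(1L, 2L)),
               "3 labeled")
  expect_error(head_label_correlation(matrix(rnorm(9), 3), rep(1L, 3)),
               "2 classes")
})

test_that("correlation pools token dimension and stays in [0, 1]", {
  set.seed(4)
  Z3 <- array(stats::rnorm(20 * 5 * 4), c(20, 5, 4))
  y <- rep(1:2, 10)
  v <- head_label_correlation(Z3, y)
  expect_gte(v, 0); expect_lte(v, 1)
  pooled <- apply(Z3, c(1, 3), mean)
  expect_equal(v, head_label_correlation(pooled, y))
})

test_that("HTS arithmetic, bounds, and monotonicity hold", {
  expect_equal(head_transferability_score(0, 1, 0.6), 1.0)
  expect_equal(head_transferability_score(0.5, 0.3, 0.6),
               0.6 * exp(-0.5) + 0.12, tolerance = 1e-5)
  expect_equal(head_transferability_score(0.5, 0.3, 0.6), 0.48392,
               tolerance = 1e-5)
  # degenerate weight ignores corr
  expect_equal(head_transferability_score(0.7, 0.9, 1),
               exp(-0.7))
  expect_error(head_transferability_score(-1, 0.5), "dal")
  expect_error(head_transferability_score(0.1, 1.5), "corr")
  expect_error(head_transferability_score(0.1, 0.5, alpha = 2), "alpha")

  set.seed(5)
  dal <- sort(stats::runif(20, 0, 3))
  hts <- head_transferability_score(dal, 0.5)
  expect_true(all(diff(hts) < 0))           # decreasing in dal
  corr <- sort(stats::runif(20))
  hts2 <- head_transferability_score(0.5, corr)
  expect_true(all(diff(hts2) > 0))          # increasing in corr
  expect_true(all(hts > 0 & hts <= 1))
})

test_that("the dynamic threshold uses the population deviation", {
  expect_equal(prune_threshold(rep(0.7, 5), 1.5), 0.7)
  expect_equal(prune_threshold(c(0.9, 0.7, 0.5, 0.3), 1.5), 0.264590,
               tolerance = 1e-5)
  expect_equal(prune_threshold(c(0.9, 0.7, 0.5, 0.3), 0), 0.6)
  expect_error(prune_threshold(0.5), "at least 2")
  # raising beta never increases the number of pruned heads
  set.seed(6)
  hts <- stats::runif(12)
  taus <- vapply(c(0, 0.5, 1, 1.5, 2), function(b) prune_threshold(hts, b),
                 numeric(1))
  expect_true(all(diff(taus) < 0))
})

test_that("select_heads applies ties, bimodal conservatism, and the floor", {
  tab_eq <- head_score_table(rep(1L, 4), 1:4, rep(0.2, 4), rep(0.5, 4))
  m <- select_heads(tab_eq, beta = 1.5)
  expect_true(all(m$decisions$retain))      # tau = mu, ties retained

  tab_bi <- head_score_table(rep(1:2, each = 6), rep(1:6, 2),
                             dal = rep(0, 12),
                             corr = rep(0, 12))
  tab_bi$hts <- rep(c(0.9, 0.1), each = 6)
  m2 <- select_heads(tab_bi, beta = 1.5)
  expect_equal(m2$tau, -0.1)
  expect_true(all(m2$decisions$retain))     # bimodal scores keep everything

  # floor: layer 2's heads all below tau -> retain exactly the floor, flagged
  tab_fl <- head_score_table(rep(1:2, each = 3), rep(1:3, 2),
                             dal = c(0.01, 0.02, 0.03, 4, 4.2, 4.1),
                             corr = c(0.9, 0.95, 0.92, 0.01, 0.02, 0.0))
  m3 <- select_heads(tab_fl, beta = 0.5, min_heads_per_layer = 1L)
  d2 <- m3$decisions[m3$decisions$layer == 2, ]
  expect_equal(sum(d2$retain), 1L)
  expect_true(all(d2$forced[d2$retain]))
  expect_equal(d2$head[d2$retain], which.max(d2$hts))

  expect_error(select_heads(tab_eq[0, ]), "empty")
})

test_that("stored HTS column is recomputable from dal, corr, and alpha", {
  set.seed(7)
  tab <- head_score_table(rep(1:3, each = 4), rep(1:4, 3),
                          dal = stats::runif(12, 0, 2),
                          corr = stats::runif(12), alpha = 0.6)
  expect_identical(tab$hts,
                   head_transferability_score(tab$dal, tab$corr,
                                              attr(tab, "alpha")))
})

test_that("mask serialization reports tau, retained heads, forced flags", {
  tab <- head_score_table(rep(1:2, each = 2), rep(1:2, 2),
                          dal = c(0.1, 0.2, 3.5, 3.8),
                          corr = c(0.9, 0.8, 0.05, 0.02))
  m <- select_heads(tab, beta = 0.5)
  js <- write_prune_mask(m)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$beta, 0.5)
  expect_equal(parsed$tau, m$tau)
  expect_setequal(parsed$layers[["1"]], c(1L, 2L))
})

test_that("glyph-attending heads score lower mean HTS than shape heads", {
  # each head's mean HTS over every recorded trajectory evaluation of its
  # run; glyph-attending heads (frozen-model attention mass on the glyph
  # token above twice the uniform share) should average lower than the
  # morphology-attending rest
  res <- planted_experiment()
  wins <- vapply(res, function(r) {
    tr <- r$trajectory
    key <- paste(tr$layer, tr$head)
    v <- tapply(tr$hts, key, mean)
    gm <- r$glyph_mass
    gm$key <- paste(gm$layer, gm$head)
    gl <- v[gm$key[gm$glyph]]
    sh <- v[gm$key[!gm$glyph]]
    if (all(is.na(gl)) || all(is.na(sh))) return(NA)
    mean(gl, na.rm = TRUE) < mean(sh, na.rm = TRUE)
  }, logical(1))
  expect_gte(sum(wins, na.rm = TRUE), 8L)
})
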