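# Pixel pooling, AUC against the O(n^2) concordance oracle, pooled
# Dice arithmetic, run aggregation and the MCA weight summary.

concordance_auc <- function(p, y) {
  pos <- p[y == 1]; neg <- p[y == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

test_that("pixel pools concatenate with duplicates preserved", {
  pred <- matrix(runif(224^2), 224, 224)
  mask <- matrix(rbinom(224^2, 1, 0.2), 224, 224)
  pool <- pool_pixels(list(pred, pred), list(mask, mask))
  expect_equal(pool$n_pixels, 100352L)
  expect_equal(sum(pool$labels), 2 * sum(mask))
  expect_error(pool_pixels(list(), list()), "empty")
  expect_error(pool_pixels(list(pred), list(mask[1:10, ])), "mismatch")
})

test_that("pooled AUC equals the pairwise concordance oracle", {
  set.seed(81)
  for (k in 1:5) {
    n <- sample(50:200, 1)
    p <- round(runif(n), 2)              # forces ties
    y <- rbinom(n, 1, 0.4)
    if (sum(y) == 0 || sum(y) == n) next
    pool <- structure(list(probabilities = p, labels = y, n_pixels = n),
                      class = "pixel_pool")
    expect_equal(roc_auc(pool), concordance_auc(p, y), tolerance = 1e-12)
  }
  perfect <- structure(list(probabilities = c(0.9, 0.8, 0.1, 0.2),
                            labels = c(1L, 1L, 0L, 0L), n_pixels = 4L),
                       class = "pixel_pool")
  expect_equal(roc_auc(perfect), 1)
  onec <- structure(list(probabilities = runif(5), labels = rep(1L, 5),
                         n_pixels = 5L), class = "pixel_pool")
  expect_error(roc_auc(onec), "one class")
})

test_that("random predictions score close to chance", {
  set.seed(82)
  n <- 1e4
  pool <- structure(list(probabilities = runif(n),
                         labels = rbinom(n, 1, 0.3), n_pixels = n),
                    class = "pixel_pool")
  expect_lt(abs(roc_auc(pool) - 0.5), 0.02)
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(83)
  p <- runif(300); y <- rbinom(300, 1, 0.5)
  pool <- function(pp) structure(list(probabilities = pp, labels = y,
                                      n_pixels = 300L), class = "pixel_pool")
  a0 <- roc_auc(pool(p))
  expect_equal(roc_auc(pool(plogis(5 * p - 1))), a0, tolerance = 1e-12)
  expect_equal(roc_auc(pool(p^3)), a0, tolerance = 1e-12)
})

test_that("pooled Dice reproduces the confusion-count formula", {
  mk <- function(p, y) structure(list(probabilities = p, labels = y,
                                      n_pixels = length(p)),
                                 class = "pixel_pool")
  expect_equal(cancer_dice(mk(c(1, 1, 0, 0), c(1L, 1L, 0L, 0L))), 1)
  expect_equal(cancer_dice(mk(c(1, 1), c(0L, 0L))), 0)
  # TP=2, FP=1, FN=1 -> 4/6
  expect_equal(cancer_dice(mk(c(0.9, 0.8, 0.7, 0.1), c(1L, 1L, 0L, 1L))),
               2 * 2 / (2 * 2 + 1 + 1))
  expect_message(d <- cancer_dice(mk(c(0.1, 0.2), c(0L, 0L))), "defined as 1")
  expect_equal(d, 1)
  # monotonicity: adding a true positive never lowers Dice, a false
  # positive never raises it
  base <- mk(c(0.9, 0.2, 0.8), c(1L, 0L, 1L))
  d0 <- cancer_dice(base)
  expect_gte(cancer_dice(mk(c(base$probabilities, 0.99), c(base$labels, 1L))), d0)
  expect_lte(cancer_dice(mk(c(base$probabilities, 0.99), c(base$labels, 0L))), d0)
})

test_that("pooled metrics equal a streaming two-pass computation", {
  set.seed(84)
  preds <- lapply(1:6, function(i) matrix(runif(64), 8, 8))
  masks <- lapply(1:6, function(i) matrix(rbinom(64, 1, 0.3), 8, 8))
  pool <- pool_pixels(preds, masks)
  # streaming Dice: accumulate confusion counts patch by patch
  tp <- fp <- fn <- 0
  for (i in 1:6) {
    b <- preds[[i]] >= 0.5
    tp <- tp + sum(b & masks[[i]] == 1)
    fp <- fp + sum(b & masks[[i]] == 0)
    fn <- fn + sum(!b & masks[[i]] == 1)
  }
  expect_equal(cancer_dice(pool), 2 * tp / (2 * tp + fp + fn),
               tolerance = 1e-12)
  expect_equal(roc_auc(pool),
               concordance_auc(pool$probabilities, pool$labels),
               tolerance = 1e-12)
})

test_that("run aggregation reports mean and sample SD", {
  r <- list(list(auc = 0.9, cancer_dice = 0.5),
            list(auc = 1.0, cancer_dice = 0.7))
  agg <- aggregate_runs(r)
  expect_equal(agg$mean[agg$metric == "auc"], 0.95)
  expect_equal(agg$sd[agg$metric == "auc"], sd(c(0.9, 1.0)))
  expect_equal(aggregate_runs(rev(r)), agg[, ])
  same <- aggregate_runs(list(list(auc = 0.8), list(auc = 0.8)))
  expect_equal(same$sd, 0)
  expect_error(aggregate_runs(r[1]), "at least 2")
})

test_that("the MCA weight summary reports entrywise means per stage", {
  d <- build_cgsnet(tiny_cfg("dual"), init = "zeros")
  # identity/zero init regardless of the init argument
  s <- mca_weight_summary(d)
  expect_equal(s$cross, c("Weight init", "First cross", "Second cross",
                          "Third cross", "Fourth cross"))
  dims <- d$config$encoder$stage_dims
  expect_equal(s$queries[-1], rep(0, 4))
  expect_equal(s$keys[-1], 1 / dims)
  expect_equal(s$values[-1], 1 / dims)
  # perturbing one entry by delta shifts the mean by delta/d^2
  delta <- 0.5
  d$params[["mca.s1.wq"]][2, 3] <- delta
  s2 <- mca_weight_summary(d)
  expect_equal(s2$queries[2], delta / dims[1]^2)
  m <- build_single(tiny_cfg("single_detail"), init = "zeros")
  expect_error(mca_weight_summary(m), "dual")
})
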