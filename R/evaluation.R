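# Pixel-pooled evaluation: every pixel of every patch (duplicates and
# all -- oversampled cancer patches contribute each occurrence) enters
# one pool, from which the ROC/AUC and the pooled (micro) cancer Dice
# at threshold 0.5 are computed. Also the per-stage summary of the MCA
# weight matrices in the style of the published weight-analysis table.

#' Pool per-patch predictions and labels into one pixel pool
#'
#' Concatenates flattened probabilities and binary labels, preserving
#' duplicates; nothing is deduplicated by slide coordinate.
#'
#' @param predictions list of numeric arrays (probabilities in \[0,1\]).
#' @param masks list of equal-shaped binary arrays.
#' @return a `pixel_pool`: list with `probabilities`, `labels`,
#'   `n_pixels`.
#' @export
pool_pixels <- function(predictions, masks) {
  if (!length(predictions)) stop("empty prediction list")
  if (length(predictions) != length(masks)) {
    stop("prediction/mask list length mismatch")
  }
  probs <- vector("list", length(predictions))
  labs <- vector("list", length(predictions))
  for (i in seq_along(predictions)) {
    p <- as.numeric(predictions[[i]]); m <- as.numeric(masks[[i]])
    if (length(p) != length(m)) stop("shape mismatch in patch ", i)
    probs[[i]] <- p; labs[[i]] <- m
  }
  structure(list(probabilities = unlist(probs),
                 labels = as.integer(unlist(labs) > 0.5),
                 n_pixels = length(unlist(probs))),
            class = "pixel_pool")
}

#' Pooled ROC AUC (trapezoidal, midrank ties)
#'
#' Equivalent to the probability that a random cancer pixel outranks a
#' random non-cancer pixel, with ties counted half.
#'
#' @param pool a `pixel_pool` (both classes must be present).
#' @export
roc_auc <- function(pool) {
  y <- pool$labels; p <- pool$probabilities
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC undefined: pool contains one class only")
  r <- rank(p)   # midranks
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Pooled (micro) cancer Dice score at a fixed threshold
#'
#' Binarizes at `threshold` and computes `2TP / (2TP + FP + FN)` over
#' the pooled cancer class. An empty pool on both sides (no positive
#' labels, no positive predictions) is defined as 1.
#'
#' @param pool a `pixel_pool`; `threshold` defaults to 0.5.
#' @export
cancer_dice <- function(pool, threshold = 0.5) {
  y <- pool$labels
  pred <- pool$probabilities >= threshold
  tp <- sum(pred & y == 1L)
  fp <- sum(pred & y == 0L)
  fn <- sum(!pred & y == 1L)
  if (tp + fp + fn == 0L) {
    message("no positive labels or predictions; Dice defined as 1")
    return(1)
  }
  2 * tp / (2 * tp + fp + fn)
}

#' Per-patch (macro) Dice, for diagnostics
#' @inheritParams pool_pixels
#' @export
macro_dice <- function(predictions, masks, threshold = 0.5) {
  mean(vapply(seq_along(predictions), function(i) {
    cancer_dice(pool_pixels(predictions[i], masks[i]), threshold)
  }, 1))
}

#' Evaluate a model on a set of patch pairs
#'
#' @param model single or dual model.
#' @param pairs list of `patch_pair`s.
#' @return a metrics report: `auc`, `cancer_dice`, `threshold`,
#'   `n_pixels`.
#' @export
evaluate_pairs <- function(model, pairs, threshold = 0.5) {
  preds <- lapply(pairs, function(pr) predict_patch(model, pr))
  masks <- lapply(pairs, function(pr) pr$detail_mask * 1)
  pool <- pool_pixels(preds, masks)
  list(auc = roc_auc(pool), cancer_dice = cancer_dice(pool, threshold),
       threshold = threshold, n_pixels = pool$n_pixels)
}

#' Aggregate repeated-run reports as mean +/- sample SD
#'
#' @param reports list of metric reports (numeric fields are
#'   aggregated); at least two.
#' @return data frame with metric, mean, sd.
#' @export
aggregate_runs <- function(reports) {
  if (length(reports) < 2L) stop("need at least 2 reports to aggregate")
  metrics <- names(reports[[1]])[vapply(reports[[1]], is.numeric, TRUE)]
  do.call(rbind, lapply(metrics, function(m) {
    v <- vapply(reports, function(r) r[[m]], 1)
    data.frame(metric = m, mean = mean(v), sd = stats::sd(v))
  }))
}

#' Summary of the MCA weight matrices per stage
#'
#' Reports the entrywise arithmetic mean of the query, key and value
#' weight matrices of each cross-attention stage, plus the
#' initialization reference row (0 / 1 / 1 following the published
#' convention for the zero and identity initializations; note the
#' entrywise mean of a d x d identity matrix is 1/d, which is what the
#' freshly initialized rows show).
#'
#' @param model a dual `cgs_model`.
#' @return data frame with rows `Weight init`, `First cross` ...
#'   `Fourth cross` and columns `queries`, `keys`, `values`.
#' @export
mca_weight_summary <- function(model) {
  if (model$config$mode != "dual") {
    stop("MCA weight summary requires a dual model")
  }
  rows <- data.frame(cross = "Weight init", queries = 0, keys = 1, values = 1)
  labels <- c("First cross", "Second cross", "Third cross", "Fourth cross")
  for (i in 1:4) {
    nm <- paste0("mca.s", i)
    rows <- rbind(rows, data.frame(
      cross = labels[i],
      queries = mean(model$params[[paste0(nm, ".wq")]]),
      keys = mean(model$params[[paste0(nm, ".wk")]]),
      values = mean(model$params[[paste0(nm, ".wv")]])))
  }
  rows
}
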