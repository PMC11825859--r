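# Desk-scale context-benefit experiment: a synthetic cohort in which
# ambiguous-texture discs cover the whole detail field of view, so the
# label of every ambiguous pixel is decided by a marker ring that lies
# outside the detail patch but inside the context patch. A detail-only
# model is at chance on these pixels by construction; a dual model can
# learn to read the ring through the cross-attention pathway.

#' Build one ambiguous-disc slide for the context-benefit cohort
#'
#' Discs of radius `disc_r` (covering a `tile` x `tile` detail window)
#' are placed on a jittered grid; each is cancerous with probability
#' 1/2, in which case a dark ring of radius `ring_r` (outside the
#' detail window, inside the context window) surrounds it.
#'
#' @param seed slide seed; `n_grid` discs per axis.
#' @param tile detail window side (level-2 px).
#' @keywords internal
#' @export
ambiguous_slide <- function(seed, slide_id, n_grid = 4L, tile = 32L,
                            disc_r = 23, ring_r = 28, size = 672L) {
  set.seed(seed)
  space <- (size - 160L) / (n_grid - 1L)
  discs <- list()
  for (i in seq_len(n_grid)) {
    for (j in seq_len(n_grid)) {
      cx <- 80 + (i - 1L) * space + stats::runif(1, -8, 8)
      cy <- 80 + (j - 1L) * space + stats::runif(1, -8, 8)
      discs[[length(discs) + 1L]] <-
        list(cx = cx, cy = cy, r = disc_r,
             cancer = stats::runif(1) < 0.5, ring_radius = ring_r)
    }
  }
  spec <- synthetic_slide_spec(size, size, tissue_blob_count = 3L,
                               ambiguous_discs = discs,
                               seed = seed, slide_id = slide_id)
  generate_slide(spec)
}

disc_samples <- function(slide, tile) {
  recs <- lapply(slide$ambiguous_discs, function(d) {
    new_record(slide$pyramid$slide_id, "cancer",
               as.integer(round(d$cx)), as.integer(round(d$cy)), 1L,
               c(tissue_frac = 1, cancer_frac = as.numeric(d$cancer),
                 noncancer_frac = 1 - as.numeric(d$cancer)))
  })
  lapply(recs, function(r) extract_pair(slide, r, patch_size = tile))
}

pair_to_sample <- function(pr, which = c("dual", "detail", "context")) {
  which <- match.arg(which)
  switch(which,
    dual = list(detail = pr$detail_image, context = pr$context_image,
                mask = pr$detail_mask * 1),
    detail = list(detail = pr$detail_image, context = NULL,
                  mask = pr$detail_mask * 1),
    context = list(detail = pr$context_image, context = NULL,
                   mask = pr$context_mask * 1))
}

#' Run the context-benefit experiment for one seed
#'
#' Generates train/val/test slides of ambiguous discs, trains the
#' level-2 and level-3 single models and the dual CGS-Net with the
#' staged schedule (scaled down to desk size), and reports the held-out
#' pixel AUC of the single-detail model and the dual model.
#'
#' @param seed integer seed controlling cohort, weights and training.
#' @param tile detail window side in level-2 pixels.
#' @param n_train_slides,n_val_slides,n_test_slides cohort sizes.
#' @param schedule scaled [training_schedule].
#' @param opt [optimizer_config].
#' @return list with `auc_single`, `auc_dual`, histories and models.
#' @export
context_benefit_run <- function(seed, tile = 32L, n_grid = 4L,
                                n_train_slides = 2L, n_val_slides = 1L,
                                n_test_slides = 1L,
                                schedule = training_schedule(
                                  single_frozen_epochs = 2L,
                                  single_total_epochs = 10L,
                                  dual_mca_only_epochs = 6L,
                                  dual_joint_epochs = 6L),
                                opt = optimizer_config(
                                  lr_encoder = 3e-4, lr_decoder = 1e-3,
                                  lr_mca = 1e-3, batch_size = 8L)) {
  n_all <- n_train_slides + n_val_slides + n_test_slides
  slides <- lapply(seq_len(n_all), function(k) {
    ambiguous_slide(seed * 100L + k, sprintf("amb_%02d", k), n_grid = n_grid,
                    tile = tile)
  })
  grab <- function(ix) unlist(lapply(slides[ix], disc_samples, tile = tile),
                              recursive = FALSE)
  tr <- grab(seq_len(n_train_slides))
  va <- grab(n_train_slides + seq_len(n_val_slides))
  te <- grab(n_train_slides + n_val_slides + seq_len(n_test_slides))

  mk <- function(prs, which) lapply(prs, pair_to_sample, which = which)
  cfg_s2 <- model_config("single_detail", "mit", "test_tiny",
                         input_size = tile, dropout = 0.05)
  cfg_s3 <- model_config("single_context", "mit", "test_tiny",
                         input_size = tile, dropout = 0.05)
  cfg_d <- model_config("dual", "mit", "test_tiny",
                        input_size = tile, dropout = 0.05)

  s2 <- train_single(list(train = mk(tr, "detail"), val = mk(va, "detail")),
                     cfg_s2, schedule, opt, seed = seed + 1L)
  s3 <- train_single(list(train = mk(tr, "context"), val = mk(va, "context")),
                     cfg_s3, schedule, opt, seed = seed + 2L)
  du <- train_dual(list(train = mk(tr, "dual"), val = mk(va, "dual")),
                   list(detail = s2, context = s3), cfg_d, schedule, opt,
                   seed = seed + 3L)

  ev_single <- evaluate_pairs_single_detail(s2$model, te)
  ev_dual <- evaluate_pairs(du$model, te)
  list(auc_single = ev_single$auc, auc_dual = ev_dual$auc,
       dice_single = ev_single$cancer_dice, dice_dual = ev_dual$cancer_dice,
       single_detail = s2, single_context = s3, dual = du)
}

evaluate_pairs_single_detail <- function(model, pairs, threshold = 0.5) {
  preds <- lapply(pairs, function(pr) predict_patch(model, pr$detail_image))
  masks <- lapply(pairs, function(pr) pr$detail_mask * 1)
  pool <- pool_pixels(preds, masks)
  list(auc = roc_auc(pool), cancer_dice = cancer_dice(pool, threshold),
       threshold = threshold, n_pixels = pool$n_pixels)
}

#' Repeat the context-benefit experiment over several seeds
#'
#' @param seeds integer vector.
#' @param ... forwarded to [context_benefit_run].
#' @return data frame with one row per seed: `auc_single`, `auc_dual`,
#'   `gap`.
#' @export
context_benefit_experiment <- function(seeds = 1:5, ...) {
  rows <- lapply(seeds, function(s) {
    r <- context_benefit_run(s, ...)
    data.frame(seed = s, auc_single = r$auc_single, auc_dual = r$auc_dual,
               gap = r$auc_dual - r$auc_single)
  })
  do.call(rbind, rows)
}
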