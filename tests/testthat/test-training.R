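# Losses against scalar oracles, paired augmentation, regularization
# eligibility, and the staged-training contracts: bitwise freezing,
# MCA-only phase isolation and combined retraining.

test_that("composite loss matches an independent scalar evaluation", {
  p <- matrix(c(0.9, 0.8, 0.1, 0.2), 2, 2)
  t <- matrix(c(1, 1, 0, 0), 2, 2)
  # scalar-by-scalar oracle
  eps <- 1e-6; gam <- 2
  f_oracle <- 0; n <- 0
  for (i in 1:2) for (j in 1:2) {
    pc <- min(max(p[i, j], eps), 1 - eps)
    pt <- if (t[i, j] == 1) pc else 1 - pc
    f_oracle <- f_oracle - (1 - pt)^gam * log(pt); n <- n + 1
  }
  f_oracle <- f_oracle / n
  d_oracle <- 1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)
  expect_equal(focal_loss(p, t), f_oracle, tolerance = 1e-12)
  expect_equal(dice_loss(p, t), d_oracle, tolerance = 1e-12)
  expect_equal(composite_loss(p, t), 0.95 * f_oracle + 0.05 * d_oracle,
               tolerance = 1e-12)
  # perfect binary prediction gives (near) zero loss
  expect_lt(composite_loss(t, t), 1e-6)
  # the autodiff loss evaluates to the same number
  ad_begin()
  node <- cgsnet:::fw_composite_loss(ad_leaf(matrix(as.numeric(p), ncol = 1)),
                                     as.numeric(t))
  expect_equal(as.numeric(node$v), composite_loss(p, t), tolerance = 1e-12)
})

test_that("alpha balancing reweights the focal term", {
  p <- matrix(c(0.7, 0.3), 1, 2); t <- matrix(c(1, 0), 1, 2)
  fa <- focal_loss(p, t, alpha = 0.75)
  eps <- 1e-6
  o <- (-0.75 * (1 - 0.7)^2 * log(0.7) - 0.25 * (1 - 0.7)^2 * log(0.7)) / 2
  expect_equal(fa, o, tolerance = 1e-9)
})

test_that("augmentation applies one geometric draw to all four arrays", {
  set.seed(71)
  mk_pair <- function() {
    mask <- matrix(rbinom(32 * 32, 1, 0.4), 32, 32)
    img <- array(0, c(32, 32, 3))
    img[, , 1] <- mask * 255          # image channel mirrors the mask
    structure(list(detail_image = img, context_image = img,
                   detail_mask = mask, context_mask = mask),
              class = "patch_pair")
  }
  cfg <- augmentation_config(shift = 4L, hsv_strength = 0, blur = FALSE,
                             coarse_dropout = FALSE)
  for (k in 1:25) {
    out <- augment_pair(mk_pair(), cfg)
    expect_identical(out$detail_image[, , 1] / 255, out$detail_mask * 1)
    expect_identical(out$context_image[, , 1] / 255, out$context_mask * 1)
    expect_true(all(out$detail_mask %in% c(0, 1)))
  }
  # identity configuration leaves the pair untouched
  idcfg <- augmentation_config(transpose = FALSE, hflip = FALSE, vflip = FALSE,
                               rot90 = FALSE, shift = 0L,
                               coarse_dropout = FALSE, blur = FALSE,
                               hsv_strength = 0)
  pr <- mk_pair()
  expect_identical(augment_pair(pr, idcfg), pr)
  # color jitter leaves masks binary and geometry untouched
  ccfg <- augmentation_config(transpose = FALSE, hflip = FALSE, vflip = FALSE,
                              rot90 = FALSE, shift = 0L, p_color = 1)
  out <- augment_pair(pr, ccfg)
  expect_identical(out$detail_mask, pr$detail_mask)
})

test_that("the L1/L2 penalty covers only eligible groups", {
  m <- build_single(tiny_cfg("single_detail"), seed = 21)
  reg <- regularization_config(l1 = 0.01, l2 = 0.001)
  expect_equal(penalty(m, reg, character(0)), 0)
  expect_equal(penalty(m, regularization_config(0, 0), "decoder"), 0)
  dec_names <- names(m$params)[m$groups[names(m$params)] == "decoder"]
  hand <- sum(vapply(dec_names, function(nm) {
    w <- m$params[[nm]]
    0.01 * sum(abs(w)) + 0.001 * sum(w^2)
  }, 1))
  expect_equal(penalty(m, reg, "decoder"), hand, tolerance = 1e-12)
})

test_that("single training freezes the encoder bitwise, then unfreezes", {
  data <- list(train = micro_samples(3, seed = 22, with_context = FALSE),
               val = micro_samples(1, seed = 23, with_context = FALSE))
  sch <- training_schedule(single_frozen_epochs = 2L, single_total_epochs = 3L,
                           dual_mca_only_epochs = 1L, dual_joint_epochs = 1L)
  opt <- optimizer_config(lr_encoder = 1e-3, lr_decoder = 1e-3, batch_size = 2L)
  set.seed(24); init_ref <- build_single(tiny_cfg("single_detail"))
  enc0 <- param_snapshot(init_ref, "encoder")
  r <- train_single(data, tiny_cfg("single_detail"), sch, opt, seed = 24)
  expect_equal(nrow(r$history), 3L)
  expect_equal(r$best_val_epoch, which.min(r$history$val_loss))
  # during frozen epochs the encoder equals its initial values; training
  # with an entirely frozen run keeps it bitwise identical
  r2 <- train_single(data, tiny_cfg("single_detail"),
                     training_schedule(2L, 2L, 1L, 1L), opt, seed = 24)
  expect_identical(param_snapshot(r2$model, "encoder"), enc0)
  # after unfreezing the encoder moved
  expect_false(identical(param_snapshot(r$model, "encoder"), enc0))
  expect_error(train_single(list(train = list(), val = list()),
                            tiny_cfg("single_detail")), "empty")
})

test_that("dual training: MCA-only phase touches only MCA parameters", {
  data_s <- list(train = micro_samples(3, seed = 25, with_context = FALSE),
                 val = micro_samples(1, seed = 26, with_context = FALSE))
  data_d <- list(train = micro_samples(3, seed = 25),
                 val = micro_samples(1, seed = 26))
  sch <- training_schedule(1L, 2L, 2L, 0L)
  opt <- optimizer_config(lr_encoder = 1e-3, lr_decoder = 1e-3,
                          lr_mca = 1e-3, batch_size = 2L)
  s2 <- train_single(data_s, tiny_cfg("single_detail"), sch, opt, seed = 27)
  s3 <- train_single(data_s, tiny_cfg("single_context"), sch, opt, seed = 28)
  # phase 1 only: frozen encoders/decoder stay at their transferred values
  r <- train_dual(data_d, list(detail = s2, context = s3), tiny_cfg("dual"),
                  sch, opt, seed = 29)
  expect_identical(param_snapshot(r$model, c("detail_encoder")),
                   setNames(param_snapshot(s2$model, "encoder"),
                            sub("^enc", "denc",
                                names(param_snapshot(s2$model, "encoder")))))
  expect_identical(r$model$params[["dec.head.w"]], s2$model$params[["dec.head.w"]])
  # the MCA queries moved away from zero
  expect_gt(sum(abs(r$model$params[["mca.s1.wq"]])), 0)
  # at epoch 0 (after transfer, before training) predictions ignore context
  d0 <- build_cgsnet(tiny_cfg("dual"), seed = 30)
  transfer_weights(s2$model, s3$model, d0)
  det <- random_image(32, seed = 31)
  p1 <- predict_patch(d0, structure(list(detail_image = det,
                                         context_image = random_image(32, seed = 32)),
                                    class = "patch_pair"))
  p2 <- predict_patch(d0, structure(list(detail_image = det,
                                         context_image = random_image(32, seed = 33)),
                                    class = "patch_pair"))
  expect_lt(max(abs(p1 - p2)), 1e-6)
})

test_that("combined retraining runs the truncated schedule deterministically", {
  data <- list(train = micro_samples(2, seed = 34, with_context = FALSE),
               val = micro_samples(1, seed = 35, with_context = FALSE))
  sch <- training_schedule(1L, 3L, 1L, 1L)
  opt <- optimizer_config(lr_encoder = 1e-3, lr_decoder = 1e-3, batch_size = 2L)
  m1 <- retrain_combined(data, tiny_cfg("single_detail"), best_val_epoch = 2L,
                         schedule = sch, opt = opt, seed = 36)
  m2 <- retrain_combined(data, tiny_cfg("single_detail"), best_val_epoch = 2L,
                         schedule = sch, opt = opt, seed = 36)
  expect_identical(m1$params, m2$params)
  expect_error(retrain_combined(data, tiny_cfg("single_detail"), 0L))
})
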