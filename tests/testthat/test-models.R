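# Model builders: output contracts, init-time context independence of
# the dual model, weight transfer, parameter-count decomposition and
# sliding-window inference.

test_that("single models map patches to probability maps of the input size", {
  m <- build_single(tiny_cfg("single_detail", 64L), seed = 1)
  p <- predict_patch(m, random_image(64, seed = 2))
  expect_equal(dim(p), c(64L, 64L))
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(is.finite(predict_patch(m, array(0, c(64, 64, 3))))))
  expect_true(all(is.finite(predict_patch(m, array(255, c(64, 64, 3))))))
  expect_error(model_config("single_detail", input_size = 100L), "divisible")
})

test_that("decoder output resolution equals the input for several sizes", {
  for (n in c(32L, 96L)) {
    m <- build_single(tiny_cfg("single_detail", n), seed = 3)
    expect_equal(dim(predict_patch(m, random_image(n, seed = 4))), c(n, n))
  }
})

test_that("CGS-Net at init is a function of the detail input only", {
  det <- random_image(64, seed = 5)
  c1 <- random_image(64, seed = 6)
  c2 <- random_image(64, seed = 7)
  for (fam in c("mit", "swinv2")) {
    d <- build_cgsnet(model_config("dual", fam, "test_tiny", input_size = 64L),
                      seed = 8)
    pp <- function(ctx) predict_patch(d, structure(
      list(detail_image = det, context_image = ctx), class = "patch_pair"))
    expect_lt(max(abs(pp(c1) - pp(c2))), 1e-6)
    # perturbing a query matrix breaks the independence
    d$params[["mca.s2.wq"]] <- matrix(rnorm(32 * 32, sd = 0.5), 32, 32)
    expect_gt(max(abs(pp(c1) - pp(c2))), 1e-8)
  }
})

test_that("weight transfer copies encoders and decoder, leaves MCA at init", {
  s2 <- build_single(tiny_cfg("single_detail"), seed = 9)
  s3 <- build_single(tiny_cfg("single_context"), seed = 10)
  d <- build_cgsnet(tiny_cfg("dual"), seed = 11)
  transfer_weights(s2, s3, d)
  expect_identical(d$params[["denc.s1.embed.w"]], s2$params[["enc.s1.embed.w"]])
  expect_identical(d$params[["cenc.s4.b1.mlp.fc2.w"]],
                   s3$params[["enc.s4.b1.mlp.fc2.w"]])
  expect_identical(d$params[["dec.head.w"]], s2$params[["dec.head.w"]])
  expect_true(all(d$params[["mca.s1.wq"]] == 0))
  expect_equal(d$params[["mca.s3.wk"]], diag(64))
  # the dual detail branch reproduces the single encoder's stage outputs
  img <- random_image(32, seed = 12)
  tok <- cgsnet:::image_to_tokens(img)
  ad_begin()
  Ps <- cgsnet:::make_param_provider(s2, track = FALSE)
  sk_s <- cgsnet:::fw_encoder(Ps, "enc", s2$config$encoder,
                              ad_leaf(tok, track = FALSE), 32L, 32L)
  Pd <- cgsnet:::make_param_provider(d, track = FALSE)
  sk_d <- cgsnet:::fw_encoder(Pd, "denc", d$config$encoder,
                              ad_leaf(tok, track = FALSE), 32L, 32L)
  for (i in 1:4) expect_identical(sk_s[[i]]$x$v, sk_d[[i]]$x$v)
  # transfer between different variants fails
  sb <- build_single(model_config("single_detail", "mit", "b1"), init = "zeros")
  expect_error(transfer_weights(sb, s3, d))
})

test_that("dual parameter count decomposes into encoders, MCAs and decoder", {
  s <- build_single(tiny_cfg("single_detail"), init = "zeros")
  d <- build_cgsnet(tiny_cfg("dual"), init = "zeros")
  bg <- count_parameters_by_group(d)
  sg <- count_parameters_by_group(s)
  expect_equal(unname(bg[["detail_encoder"]]), unname(sg[["encoder"]]))
  expect_equal(unname(bg[["context_encoder"]]), unname(sg[["encoder"]]))
  expect_equal(unname(bg[["decoder"]]), unname(sg[["decoder"]]))
  expect_equal(sum(bg), count_parameters(d, millions = FALSE))
  expect_gt(count_parameters(d, millions = FALSE),
            2 * unname(sg[["encoder"]]))
})

test_that("checkpoints round-trip weights and write a config sidecar", {
  m <- build_single(tiny_cfg("single_detail", 32L), seed = 16)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  m2 <- load_checkpoint(path)
  expect_identical(m2$params, m$params)
  img <- random_image(32, seed = 17)
  expect_identical(predict_patch(m2, img), predict_patch(m, img))
})

test_that("sliding-window inference tiles and averages probabilities", {
  m <- build_single(tiny_cfg("single_detail", 32L), seed = 13)
  pyr <- structure(list(level2_image = random_image(96, seed = 14),
                        level3_image = random_image(48, seed = 15),
                        slide_id = "s"), class = "slide_pyramid")
  heat <- wsi_inference(m, pyr, stride = 32L)
  expect_equal(dim(heat), c(96L, 96L))
  expect_true(all(heat >= 0 & heat <= 1))
  expect_error(wsi_inference(m, pyr, stride = 64L), "gaps")
})
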