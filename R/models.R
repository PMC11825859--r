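# Model configurations and builders: single-input segmentation models
# (one encoder + extended U-Net decoder) and the dual-input CGS-Net
# (two encoders, per-stage multi-cross-attention fusion, one decoder).

#' Encoder configuration
#'
#' Published stage recipes for the mix-transformer (`mit`: `b1`, `b2`)
#' and Swin Transformer V2 (`swinv2`: `tiny`, `small`) families, plus a
#' `test_tiny` miniature per family for CPU-scale testing.
#'
#' @param family `"mit"` or `"swinv2"`.
#' @param variant `"b1"`, `"b2"`, `"tiny"`, `"small"` or `"test_tiny"`.
#' @return a list describing the encoder stages.
#' @export
encoder_config <- function(family = c("mit", "swinv2"),
                           variant = "b1") {
  family <- match.arg(family)
  if (family == "mit") {
    base <- list(family = "mit", variant = variant,
                 stage_dims = c(64L, 128L, 320L, 512L),
                 heads = c(1L, 2L, 5L, 8L), sr_ratios = c(8L, 4L, 2L, 1L),
                 mlp_ratio = 4L, stage_strides = c(4L, 8L, 16L, 32L))
    base$depths <- switch(variant,
      b1 = c(2L, 2L, 2L, 2L),
      b2 = c(3L, 4L, 6L, 3L),
      test_tiny = c(1L, 1L, 1L, 1L),
      stop("unknown mit variant: ", variant))
    if (variant == "test_tiny") {
      base$stage_dims <- c(16L, 32L, 64L, 96L)
      base$heads <- c(1L, 2L, 4L, 6L)
      base$mlp_ratio <- 2L
    }
    base
  } else {
    base <- list(family = "swinv2", variant = variant,
                 stage_dims = c(96L, 192L, 384L, 768L),
                 heads = c(3L, 6L, 12L, 24L), window = 8L,
                 mlp_ratio = 4L, stage_strides = c(4L, 8L, 16L, 32L))
    base$depths <- switch(variant,
      tiny = c(2L, 2L, 6L, 2L),
      small = c(2L, 2L, 18L, 2L),
      test_tiny = c(1L, 1L, 1L, 1L),
      stop("unknown swinv2 variant: ", variant))
    if (variant == "test_tiny") {
      base$stage_dims <- c(16L, 32L, 64L, 128L)
      base$heads <- c(1L, 2L, 4L, 8L)
      base$window <- 4L
      base$mlp_ratio <- 2L
    }
    base
  }
}

# Decoder head widths and MCA refinement hidden widths, calibrated per
# encoder family so that the whole-model trainable parameter counts
# reproduce the published model sizes (see the methods vignette).
decoder_widths_for <- function(enc_cfg) {
  if (enc_cfg$variant == "test_tiny") return(c(32L, 24L, 16L, 12L, 8L))
  if (enc_cfg$family == "mit") c(152L, 120L, 88L, 56L, 40L)
  else c(128L, 112L, 88L, 56L, 40L)
}

mca_refine_hidden_for <- function(enc_cfg) {
  if (enc_cfg$variant == "test_tiny") return(pmax(4L, enc_cfg$stage_dims %/% 4L))
  if (enc_cfg$family == "mit") c(24L, 48L, 112L, 152L)
  else c(32L, 64L, 128L, 256L)
}

#' Model configuration
#'
#' @param mode `"single_detail"`, `"single_context"` or `"dual"`.
#' @param family,variant forwarded to [encoder_config].
#' @param input_size input side length in pixels; must be divisible by 32.
#' @param residual whether the MCA adds the detail tokens back onto the
#'   attention output (default on; preserves detail features at init).
#' @param dropout 2D dropout rate applied to decoder and MCA outputs
#'   during training.
#' @return a config list consumed by [build_single] / [build_cgsnet].
#' @export
model_config <- function(mode = c("single_detail", "single_context", "dual"),
                         family = "mit", variant = "b1",
                         input_size = 224L, residual = TRUE,
                         dropout = 0.15) {
  mode <- match.arg(mode)
  input_size <- as.integer(input_size)
  if (input_size %% 32L != 0L) stop("input_size must be divisible by 32")
  enc <- encoder_config(family, variant)
  list(mode = mode, encoder = enc,
       decoder = list(skip_dims = enc$stage_dims,
                      head_widths = decoder_widths_for(enc),
                      out_channels = 1L),
       mca = list(residual = residual,
                  stage_dims = enc$stage_dims,
                  refine_hidden = mca_refine_hidden_for(enc)),
       input_size = input_size, dropout = dropout)
}

reg_encoder <- function(model, prefix, enc_cfg, group, init) {
  if (enc_cfg$family == "mit") reg_mit_encoder(model, prefix, enc_cfg, group, init)
  else reg_swin_encoder(model, prefix, enc_cfg, group, init)
}

fw_encoder <- function(P, prefix, enc_cfg, x, H, W) {
  if (enc_cfg$family == "mit") fw_mit_encoder(P, prefix, enc_cfg, x, H, W)
  else fw_swin_encoder(P, prefix, enc_cfg, x, H, W)
}

#' Build a single-input segmentation model
#'
#' One encoder plus the extended U-Net decoder; maps a
#' `input_size^2 x 3` RGB patch to a per-pixel cancer probability map of
#' the same spatial size (sigmoid head).
#'
#' @param config from [model_config] with a `single_*` mode.
#' @param init `"trunc_normal"` (default) or `"zeros"` (weight-shaped
#'   model without random draws; parameter counts are identical).
#' @param seed optional seed for the weight initialization.
#' @return a `cgs_model` environment.
#' @export
build_single <- function(config, init = "trunc_normal", seed = NULL) {
  if (!config$mode %in% c("single_detail", "single_context")) {
    stop("config mode must be single_detail or single_context")
  }
  if (!is.null(seed)) set.seed(seed)
  m <- new_model_env(config)
  reg_encoder(m, "enc", config$encoder, "encoder", init)
  reg_decoder(m, "dec", config$decoder$skip_dims, config$decoder$head_widths,
              "decoder", init)
  m
}

#' Build the dual-encoder CGS-Net
#'
#' Two parallel encoders of identical configuration; at each of the four
#' stages the detail features provide keys/values and the context
#' features provide queries to a multi-cross-attention module with the
#' zero-query / identity initialization; the fused (post-MCA) features
#' feed the decoder skips.
#'
#' @inheritParams build_single
#' @export
build_cgsnet <- function(config, init = "trunc_normal", seed = NULL) {
  if (config$mode != "dual") stop("config mode must be dual")
  if (!is.null(seed)) set.seed(seed)
  m <- new_model_env(config)
  reg_encoder(m, "denc", config$encoder, "detail_encoder", init)
  reg_encoder(m, "cenc", config$encoder, "context_encoder", init)
  dims <- config$encoder$stage_dims
  rh <- config$mca$refine_hidden
  for (i in 1:4) reg_mca_stage(m, paste0("mca.s", i), dims[i], rh[i], "mca", init)
  reg_decoder(m, "dec", config$decoder$skip_dims, config$decoder$head_widths,
              "decoder", init)
  m
}

# image (H x W x 3, 0..255) -> normalized token matrix
image_to_tokens <- function(img) {
  H <- dim(img)[1]; W <- dim(img)[2]
  tok <- matrix(0, H * W, 3L)
  for (ch in 1:3) tok[, ch] <- as.numeric(t(img[, , ch]))
  (tok / 255 - 0.5) / 0.25
}

#' Forward pass (builds a fresh autodiff tape)
#'
#' @param model a `cgs_model`.
#' @param detail detail RGB patch (H x W x 3, values 0..255).
#' @param context context RGB patch (dual models only).
#' @param training apply dropout and keep the tape for backprop.
#' @param track accumulate gradients into parameters.
#' @return list with `prob` (node) and `P` (parameter provider); spatial
#'   size equals the input.
#' @keywords internal
#' @export
model_forward <- function(model, detail, context = NULL, training = FALSE,
                          track = training) {
  cfg <- model$config
  H <- dim(detail)[1]; W <- dim(detail)[2]
  if (H %% 32L != 0L || W %% 32L != 0L) stop("input size must be divisible by 32")
  ad_begin()
  P <- make_param_provider(model, track = track)
  drop <- if (training) cfg$dropout else 0
  xin <- ad_leaf(image_to_tokens(detail), track = FALSE)
  if (cfg$mode == "dual") {
    if (is.null(context)) stop("dual model requires a context patch")
    if (!all(dim(context) == dim(detail))) stop("context/detail size mismatch")
    cin <- ad_leaf(image_to_tokens(context), track = FALSE)
    dskips <- fw_encoder(P, "denc", cfg$encoder, xin, H, W)
    cskips <- fw_encoder(P, "cenc", cfg$encoder, cin, H, W)
    dims <- cfg$encoder$stage_dims
    fused <- vector("list", 4L)
    for (i in 1:4) {
      fx <- fw_mca_stage(P, paste0("mca.s", i), cskips[[i]]$x, dskips[[i]]$x,
                         dims[i], residual = cfg$mca$residual,
                         dropout = drop, training = training)
      fused[[i]] <- list(x = fx, H = dskips[[i]]$H, W = dskips[[i]]$W)
    }
    out <- fw_decoder(P, "dec", fused, cfg$decoder$head_widths, drop, training)
  } else {
    skips <- fw_encoder(P, "enc", cfg$encoder, xin, H, W)
    out <- fw_decoder(P, "dec", skips, cfg$decoder$head_widths, drop, training)
  }
  list(prob = out$prob, H = out$H, W = out$W, P = P)
}

#' Predict a probability map for one patch (or patch pair)
#'
#' @param model a built (or trained) model.
#' @param pair a `patch_pair` (see [extract_pair]) or a plain RGB array
#'   for single models.
#' @return numeric matrix (H x W) of cancer probabilities in \[0, 1\].
#' @export
predict_patch <- function(model, pair) {
  if (inherits(pair, "patch_pair")) {
    detail <- pair$detail_image; context <- pair$context_image
  } else {
    detail <- pair; context <- NULL
  }
  fw <- model_forward(model, detail, context, training = FALSE, track = FALSE)
  H <- fw$H; W <- fw$W
  t(matrix(fw$prob$v, W, H))
}

#' Count trainable parameters
#'
#' @param model a `cgs_model`.
#' @param millions return millions rounded to 2 decimals (default) or
#'   the raw integer count.
#' @export
count_parameters <- function(model, millions = TRUE) {
  n <- sum(vapply(model$params, length, 1L))
  if (millions) round(n / 1e6, 2) else n
}

#' Per-group parameter counts (encoders, decoder, MCA)
#' @param model a `cgs_model`.
#' @return named numeric vector of raw counts per optimizer group.
#' @export
count_parameters_by_group <- function(model) {
  lens <- vapply(model$params, length, 1L)
  tapply(lens, model$groups[names(lens)], sum)
}

#' Transfer single-model weights into a CGS-Net
#'
#' Copies the level-2 single model's encoder into the detail branch, the
#' level-3 single model's encoder into the context branch and the
#' level-2 single model's decoder into the dual decoder. MCA weights are
#' left at their zero-query / identity initialization.
#'
#' @param single_detail,single_context trained single models of matching
#'   encoder configuration.
#' @param dual a freshly built CGS-Net.
#' @return `dual`, modified in place and returned.
#' @export
transfer_weights <- function(single_detail, single_context, dual) {
  stopifnot(identical(single_detail$config$encoder$variant,
                      dual$config$encoder$variant),
            identical(single_context$config$encoder$variant,
                      dual$config$encoder$variant))
  copy_block <- function(src, from_prefix, to_prefix) {
    nms <- grep(paste0("^", from_prefix, "\\."), names(src$params), value = TRUE)
    for (nm in nms) {
      tgt <- sub(paste0("^", from_prefix), to_prefix, nm)
      if (is.null(dual$params[[tgt]])) {
        stop("transfer target missing tensor: ", tgt)
      }
      if (!all(dim(dual$params[[tgt]]) == dim(src$params[[nm]]))) {
        stop("shape mismatch transferring tensor: ", nm)
      }
      dual$params[[tgt]] <- src$params[[nm]]
    }
  }
  copy_block(single_detail, "enc", "denc")
  copy_block(single_context, "enc", "cenc")
  copy_block(single_detail, "dec", "dec")
  invisible(dual)
}

#' Save / load a model checkpoint
#'
#' The weight archive is R-native serialization; a JSON sidecar
#' (`<path>.json`) stores the model configuration so a checkpoint is
#' reproducible without the R session that created it.
#'
#' @param model a `cgs_model`.
#' @param path checkpoint file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(params = model$params, groups = model$groups,
               config = model$config), path)
  jsonlite::write_json(model$config, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  blob <- readRDS(path)
  m <- new_model_env(blob$config)
  m$params <- blob$params
  m$groups <- blob$groups
  m
}

#' Sliding-window whole-slide inference
#'
#' Tiles the level-2 image with windows of the model input size at the
#' given stride, averaging probabilities where windows overlap.
#'
#' @param model single or dual model.
#' @param slide a `slide_pyramid` (see [generate_slide]).
#' @param stride tile stride in level-2 pixels; must be <= the window so
#'   the heatmap has no gaps.
#' @return numeric matrix at level-2 resolution with values in \[0, 1\].
#' @export
wsi_inference <- function(model, slide, stride = 224L) {
  win <- model$config$input_size
  if (stride > win) stop("stride larger than the window leaves gaps")
  img2 <- slide$level2_image; img3 <- slide$level3_image
  H <- dim(img2)[1]; W <- dim(img2)[2]
  heat <- matrix(0, H, W); cnt <- matrix(0, H, W)
  ys <- unique(c(seq(1L, H - win + 1L, by = stride), H - win + 1L))
  xs <- unique(c(seq(1L, W - win + 1L, by = stride), W - win + 1L))
  dual <- model$config$mode == "dual"
  for (y in ys) {
    for (x in xs) {
      det <- img2[y:(y + win - 1L), x:(x + win - 1L), , drop = FALSE]
      ctx <- NULL
      if (dual) {
        cy <- (y + win %/% 2L - 1L) %/% 2L  # context center, level-3
        cx <- (x + win %/% 2L - 1L) %/% 2L
        ctx <- crop_with_padding(img3, cy, cx, win)
      }
      p <- predict_patch(model, if (dual) {
        structure(list(detail_image = det, context_image = ctx),
                  class = "patch_pair")
      } else det)
      heat[y:(y + win - 1L), x:(x + win - 1L)] <-
        heat[y:(y + win - 1L), x:(x + win - 1L)] + p
      cnt[y:(y + win - 1L), x:(x + win - 1L)] <-
        cnt[y:(y + win - 1L), x:(x + win - 1L)] + 1
    }
  }
  heat / pmax(cnt, 1)
}

# crop a window of side `win` centered at (cy, cx) (1-based), replicating
# edge pixels where the window exceeds the array bounds
crop_with_padding <- function(img, cy, cx, win) {
  half <- win %/% 2L
  ys <- (cy - half):(cy + half - 1L)
  xs <- (cx - half):(cx + half - 1L)
  ys <- pmin(pmax(ys, 1L), dim(img)[1])
  xs <- pmin(pmax(xs, 1L), dim(img)[2])
  img[ys, xs, , drop = FALSE]
}
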