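# Mix-transformer (MiT) hierarchical encoder: four stages of overlapped
# patch merging (stride-4 stem, then stride-2), transformer blocks with
# efficient (sequence-reduced) self-attention and Mix-FFN (an MLP with a
# 3x3 depthwise convolution). Stage recipes follow the published B1/B2
# sizes; `test_tiny` is a depth-1 miniature for CPU-scale tests.

mit_stage_specs <- function(cfg) {
  list(kernel = c(7L, 3L, 3L, 3L),
       stride = c(4L, 2L, 2L, 2L),
       pad    = c(3L, 1L, 1L, 1L),
       dims   = cfg$stage_dims,
       depths = cfg$depths,
       heads  = cfg$heads,
       sr     = cfg$sr_ratios,
       mlp    = cfg$mlp_ratio)
}

reg_mit_encoder <- function(model, prefix, cfg, group, init = "trunc_normal") {
  sp <- mit_stage_specs(cfg)
  cin <- 3L
  for (i in 1:4) {
    d <- sp$dims[i]
    nm <- function(...) paste0(prefix, ".s", i, ...)
    reg_conv(model, nm(".embed"), cin, d, sp$kernel[i], group, init)
    reg_ln(model, nm(".embed_ln"), d, group, init)
    for (j in seq_len(sp$depths[i])) {
      b <- function(...) nm(".b", j, ...)
      reg_ln(model, b(".norm1"), d, group, init)
      reg_linear(model, b(".attn.q"), d, d, group, init)
      reg_linear(model, b(".attn.k"), d, d, group, init)
      reg_linear(model, b(".attn.v"), d, d, group, init)
      reg_linear(model, b(".attn.proj"), d, d, group, init)
      if (sp$sr[i] > 1L) {
        reg_conv(model, b(".attn.sr"), d, d, sp$sr[i], group, init)
        reg_ln(model, b(".attn.sr_ln"), d, group, init)
      }
      reg_ln(model, b(".norm2"), d, group, init)
      h <- d * sp$mlp
      reg_linear(model, b(".mlp.fc1"), d, h, group, init)
      reg_dwconv(model, b(".mlp.dw"), h, group, init)
      reg_linear(model, b(".mlp.fc2"), h, d, group, init)
    }
    reg_ln(model, nm(".norm"), d, group, init)
    cin <- d
  }
  invisible(model)
}

# multi-head attention with optional sequence reduction of keys/values
fw_mit_attn <- function(P, name, xn, H, W, d, heads, sr) {
  q <- fw_linear(P, paste0(name, ".q"), xn)
  kv_src <- xn
  if (sr > 1L) {
    red <- fw_conv(P, paste0(name, ".sr"), xn, H, W, sr, sr, 0L)
    kv_src <- fw_ln(P, paste0(name, ".sr_ln"), red$x)
  }
  k <- fw_linear(P, paste0(name, ".k"), kv_src)
  v <- fw_linear(P, paste0(name, ".v"), kv_src)
  dh <- d %/% heads
  outs <- vector("list", heads)
  for (h in seq_len(heads)) {
    j0 <- (h - 1L) * dh + 1L; j1 <- h * dh
    qh <- ad_colsel(q, j0, j1)
    kh <- ad_colsel(k, j0, j1)
    vh <- ad_colsel(v, j0, j1)
    A <- ad_softmax_rows(ad_scale(ad_mm(qh, ad_t(kh)), 1 / sqrt(dh)))
    outs[[h]] <- ad_mm(A, vh)
  }
  x <- if (heads == 1L) outs[[1L]] else ad_cbind(outs)
  fw_linear(P, paste0(name, ".proj"), x)
}

fw_mit_block <- function(P, name, x, H, W, d, heads, sr) {
  a <- fw_mit_attn(P, paste0(name, ".attn"), fw_ln(P, paste0(name, ".norm1"), x),
                   H, W, d, heads, sr)
  x <- ad_add(x, a)
  m <- fw_ln(P, paste0(name, ".norm2"), x)
  m <- fw_linear(P, paste0(name, ".mlp.fc1"), m)
  m <- fw_dwconv3(P, paste0(name, ".mlp.dw"), m, H, W)
  m <- ad_gelu(m)
  m <- fw_linear(P, paste0(name, ".mlp.fc2"), m)
  ad_add(x, m)
}

# returns list of 4 stage outputs: list(x = node (HW x C), H, W)
fw_mit_encoder <- function(P, prefix, cfg, x, H, W) {
  sp <- mit_stage_specs(cfg)
  skips <- vector("list", 4L)
  for (i in 1:4) {
    nm <- function(...) paste0(prefix, ".s", i, ...)
    emb <- fw_conv(P, nm(".embed"), x, H, W, sp$kernel[i], sp$stride[i], sp$pad[i])
    x <- fw_ln(P, nm(".embed_ln"), emb$x); H <- emb$H; W <- emb$W
    for (j in seq_len(sp$depths[i])) {
      x <- fw_mit_block(P, nm(".b", j), x, H, W, sp$dims[i], sp$heads[i], sp$sr[i])
    }
    x <- fw_ln(P, nm(".norm"), x)
    skips[[i]] <- list(x = x, H = H, W = W)
  }
  skips
}
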