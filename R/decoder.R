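# Extended U-Net decoder: three transposed-convolution upsampling steps
# with encoder skips, plus two additional transposed convolutions (no
# skips) that bring the map back to the full input resolution, so the
# ground truth is never downsampled. Double convolutions use
# GroupNorm(1 group) + ReLU; normalization statistics are per sample.

reg_decoder <- function(model, prefix, skip_dims, head_widths, group = "decoder",
                        init = "trunc_normal") {
  stopifnot(length(skip_dims) == 4L, length(head_widths) == 5L)
  u <- head_widths
  nm <- function(...) paste0(prefix, ...)
  reg_dc <- function(name, cin, cout) {
    reg_conv(model, paste0(name, ".c1"), cin, cout, 3L, group, init)
    reg_ln(model, paste0(name, ".n1"), cout, group, init)
    reg_conv(model, paste0(name, ".c2"), cout, cout, 3L, group, init)
    reg_ln(model, paste0(name, ".n2"), cout, group, init)
  }
  reg_convt(model, nm(".up1"), skip_dims[4], u[1], group, init)
  reg_dc(nm(".dc1"), u[1] + skip_dims[3], u[1])
  reg_convt(model, nm(".up2"), u[1], u[2], group, init)
  reg_dc(nm(".dc2"), u[2] + skip_dims[2], u[2])
  reg_convt(model, nm(".up3"), u[2], u[3], group, init)
  reg_dc(nm(".dc3"), u[3] + skip_dims[1], u[3])
  reg_convt(model, nm(".up4"), u[3], u[4], group, init)
  reg_dc(nm(".dc4"), u[4], u[4])
  reg_convt(model, nm(".up5"), u[4], u[5], group, init)
  reg_dc(nm(".dc5"), u[5], u[5])
  reg_conv(model, nm(".head"), u[5], 1L, 1L, group, init)
  invisible(model)
}

fw_double_conv <- function(P, name, x, H, W, dropout = 0, training = FALSE) {
  y <- fw_conv(P, paste0(name, ".c1"), x, H, W, 3L, 1L, 1L)$x
  y <- ad_relu(fw_mapnorm(P, paste0(name, ".n1"), y))
  y <- fw_conv(P, paste0(name, ".c2"), y, H, W, 3L, 1L, 1L)$x
  y <- ad_relu(fw_mapnorm(P, paste0(name, ".n2"), y))
  fw_dropout2d(y, dropout, training)
}

# skips: list of 4 stage outputs (x, H, W); returns sigmoid probability
# node (HW x 1) at the full input resolution.
fw_decoder <- function(P, prefix, skips, head_widths, dropout = 0,
                       training = FALSE) {
  u <- head_widths
  nm <- function(...) paste0(prefix, ...)
  up <- fw_convt(P, nm(".up1"), skips[[4]]$x, skips[[4]]$H, skips[[4]]$W, u[1])
  x <- ad_cbind(list(up$x, skips[[3]]$x))
  x <- fw_double_conv(P, nm(".dc1"), x, up$H, up$W, dropout, training)
  up <- fw_convt(P, nm(".up2"), x, up$H, up$W, u[2])
  x <- ad_cbind(list(up$x, skips[[2]]$x))
  x <- fw_double_conv(P, nm(".dc2"), x, up$H, up$W, dropout, training)
  up <- fw_convt(P, nm(".up3"), x, up$H, up$W, u[3])
  x <- ad_cbind(list(up$x, skips[[1]]$x))
  x <- fw_double_conv(P, nm(".dc3"), x, up$H, up$W, dropout, training)
  up <- fw_convt(P, nm(".up4"), x, up$H, up$W, u[4])
  x <- fw_double_conv(P, nm(".dc4"), up$x, up$H, up$W, dropout, training)
  up <- fw_convt(P, nm(".up5"), x, up$H, up$W, u[5])
  x <- fw_double_conv(P, nm(".dc5"), up$x, up$H, up$W, dropout, training)
  logits <- fw_conv(P, nm(".head"), x, up$H, up$W, 1L, 1L, 0L)$x
  list(prob = ad_sigmoid(logits), H = up$H, W = up$W)
}
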