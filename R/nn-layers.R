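# Layer primitives on top of the autodiff engine.
#
# A model is an environment with `params` (named list of base-R matrices),
# `groups` (named character: which optimizer group each parameter belongs
# to) and a `config`. Feature maps travel through the network as
# (H*W x C) token matrices in row-major pixel order, with the spatial
# shape carried alongside.

.cgs_cache <- new.env(parent = emptyenv())

cache_get <- function(key, maker) {
  if (is.null(.cgs_cache[[key]])) .cgs_cache[[key]] <- maker()
  .cgs_cache[[key]]
}

# ---- parameter registry --------------------------------------------------

new_model_env <- function(config = list()) {
  m <- new.env(parent = emptyenv())
  m$params <- list()
  m$groups <- character(0)
  m$config <- config
  class(m) <- "cgs_model"
  m
}

add_param <- function(model, name, value, group) {
  model$params[[name]] <- value
  model$groups[[name]] <- group
  invisible(model)
}

#' Truncated-normal initializer (clipped at two standard deviations)
#' @keywords internal
trunc_normal <- function(n, sd = 0.02) {
  x <- stats::rnorm(n, sd = sd)
  pmin(pmax(x, -2 * sd), 2 * sd)
}

init_mat <- function(nr, nc, mode = c("trunc_normal", "zeros", "kaiming"),
                     fan_in = nr) {
  mode <- match.arg(mode)
  if (mode == "zeros") return(matrix(0, nr, nc))
  if (mode == "kaiming") {
    b <- sqrt(6 / fan_in)
    return(matrix(stats::runif(nr * nc, -b, b), nr, nc))
  }
  matrix(trunc_normal(nr * nc), nr, nc)
}

# `init` may be "zeros" to build a weight-shaped model without drawing
# random numbers (parameter counting does not depend on values).
reg_linear <- function(model, name, d_in, d_out, group, init = "trunc_normal",
                       bias = TRUE) {
  add_param(model, paste0(name, ".w"), init_mat(d_in, d_out, init), group)
  if (bias) add_param(model, paste0(name, ".b"), matrix(0, 1, d_out), group)
  invisible(model)
}

reg_ln <- function(model, name, C, group, init = "trunc_normal") {
  ones <- if (init == "zeros") matrix(0, 1, C) else matrix(1, 1, C)
  add_param(model, paste0(name, ".g"), ones, group)
  add_param(model, paste0(name, ".b"), matrix(0, 1, C), group)
  invisible(model)
}

reg_conv <- function(model, name, cin, cout, k, group, init = "trunc_normal") {
  mode <- if (init == "zeros") "zeros" else "kaiming"
  add_param(model, paste0(name, ".w"),
            init_mat(k * k * cin, cout, mode, fan_in = k * k * cin), group)
  add_param(model, paste0(name, ".b"), matrix(0, 1, cout), group)
  invisible(model)
}

reg_dwconv <- function(model, name, C, group, init = "trunc_normal") {
  mode <- if (init == "zeros") "zeros" else "kaiming"
  add_param(model, paste0(name, ".w"), init_mat(9, C, mode, fan_in = 9), group)
  add_param(model, paste0(name, ".b"), matrix(0, 1, C), group)
  invisible(model)
}

reg_convt <- function(model, name, cin, cout, group, init = "trunc_normal") {
  mode <- if (init == "zeros") "zeros" else "kaiming"
  add_param(model, paste0(name, ".w"),
            init_mat(cin, 4 * cout, mode, fan_in = cin), group)
  add_param(model, paste0(name, ".b"), matrix(0, 1, cout), group)
  invisible(model)
}

# ---- forward-time parameter provider ------------------------------------

# Wraps each parameter into exactly one leaf node per forward pass so
# gradients accumulate in a single place; `collect_grads` reads them back.
make_param_provider <- function(model, track = TRUE) {
  store <- new.env(parent = emptyenv())
  P <- function(name) {
    nd <- store[[name]]
    if (is.null(nd)) {
      v <- model$params[[name]]
      if (is.null(v)) stop("unknown parameter: ", name)
      nd <- ad_leaf(v, track = track)
      store[[name]] <- nd
    }
    nd
  }
  attr(P, "store") <- store
  P
}

collect_grads <- function(P) {
  store <- attr(P, "store")
  out <- list()
  for (nm in ls(store)) {
    g <- store[[nm]]$g
    if (!is.null(g)) out[[nm]] <- g
  }
  out
}

# ---- spatial index helpers ----------------------------------------------

# Row-major pixel order: pixel (r, c) of an H x W map is token (r-1)*W + c.
conv_indices <- function(H, W, k, stride, pad) {
  key <- paste("conv", H, W, k, stride, pad, sep = "_")
  cache_get(key, function() {
    Hp <- H + 2L * pad; Wp <- W + 2L * pad
    Ho <- (H + 2L * pad - k) %/% stride + 1L
    Wo <- (W + 2L * pad - k) %/% stride + 1L
    # map padded pixel -> source row (HW+1 = zero row)
    pr <- rep(seq_len(Hp), each = Wp) - pad
    pc <- rep(seq_len(Wp), times = Hp) - pad
    inside <- pr >= 1L & pr <= H & pc >= 1L & pc <= W
    pidx <- ifelse(inside, (pr - 1L) * W + pc, H * W + 1L)
    # gather indices (into the padded map) for each kernel offset
    r0 <- (rep(seq_len(Ho), each = Wo) - 1L) * stride
    c0 <- (rep(seq_len(Wo), times = Ho) - 1L) * stride
    gidx <- vector("list", k * k)
    o <- 0L
    for (dr in seq_len(k)) {
      for (dc in seq_len(k)) {
        o <- o + 1L
        gidx[[o]] <- (r0 + dr - 1L) * Wp + (c0 + dc)
      }
    }
    list(pidx = pidx, gidx = gidx, Ho = Ho, Wo = Wo)
  })
}

convt_indices <- function(H, W) {
  key <- paste("convt", H, W, sep = "_")
  cache_get(key, function() {
    # out pixel (ro, co) of a 2H x 2W map comes from input ((ro+1)%/%2,
    # (co+1)%/%2), block b = (ro-1)%%2 * 2 + (co-1)%%2 + 1
    ro <- rep(seq_len(2L * H), each = 2L * W)
    co <- rep(seq_len(2L * W), times = 2L * H)
    ri <- (ro + 1L) %/% 2L; ci <- (co + 1L) %/% 2L
    b <- ((ro - 1L) %% 2L) * 2L + ((co - 1L) %% 2L) + 1L
    (b - 1L) * (H * W) + (ri - 1L) * W + ci
  })
}

# ---- fused layer ops -----------------------------------------------------

# Fused affine map y = x W + b (single tape node).
ad_linear <- function(x, w, b = NULL) {
  y <- x$v %*% w$v
  if (!is.null(b)) y <- sweep(y, 2L, as.numeric(b$v), "+")
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  new_node(y, parents, function(nd) {
    accum(x, nd$g %*% t(w$v))
    accum(w, crossprod(x$v, nd$g))
    if (!is.null(b)) accum(b, matrix(colSums(nd$g), 1L))
  })
}

# Fused im2col convolution: gathers, column-concatenation, matmul and
# bias in one node; the backward scatters gradients back through the
# padded image analytically (col2im).
ad_conv <- function(x, w, b, ci, cin) {
  np <- length(ci$pidx)
  xpad <- rbind(x$v, 0)[ci$pidx, , drop = FALSE]
  k2 <- length(ci$gidx)
  no <- length(ci$gidx[[1]])
  cols <- matrix(0, no, k2 * cin)
  for (o in seq_len(k2)) {
    cols[, ((o - 1L) * cin + 1L):(o * cin)] <- xpad[ci$gidx[[o]], , drop = FALSE]
  }
  y <- sweep(cols %*% w$v, 2L, as.numeric(b$v), "+")
  new_node(y, list(x, w, b), function(nd) {
    accum(w, crossprod(cols, nd$g))
    accum(b, matrix(colSums(nd$g), 1L))
    if (isTRUE(x$track) || !is.null(x$bk)) {
      gcols <- nd$g %*% t(w$v)
      gpad <- matrix(0, np, cin)
      for (o in seq_len(k2)) {
        ix <- ci$gidx[[o]]
        gpad[ix, ] <- gpad[ix, ] + gcols[, ((o - 1L) * cin + 1L):(o * cin)]
      }
      gx <- matrix(0, nrow(x$v), cin)
      inside <- ci$pidx <= nrow(x$v)
      gx[ci$pidx[inside], ] <- gx[ci$pidx[inside], ] +
        gpad[inside, , drop = FALSE]
      accum(x, gx)
    }
  })
}

# Fused 3x3 depthwise convolution (stride 1, pad 1).
ad_dwconv3 <- function(x, w, b, ci) {
  xpad <- rbind(x$v, 0)[ci$pidx, , drop = FALSE]
  wv <- w$v
  y <- sweep(xpad[ci$gidx[[1]], , drop = FALSE], 2L, wv[1, ], "*")
  for (o in 2:9) {
    y <- y + sweep(xpad[ci$gidx[[o]], , drop = FALSE], 2L, wv[o, ], "*")
  }
  y <- sweep(y, 2L, as.numeric(b$v), "+")
  C <- ncol(x$v)
  new_node(y, list(x, w, b), function(nd) {
    gw <- matrix(0, 9L, C)
    gpad <- matrix(0, length(ci$pidx), C)
    for (o in 1:9) {
      xo <- xpad[ci$gidx[[o]], , drop = FALSE]
      gw[o, ] <- colSums(nd$g * xo)
      gpad[ci$gidx[[o]], ] <- gpad[ci$gidx[[o]], ] +
        sweep(nd$g, 2L, wv[o, ], "*")
    }
    accum(w, gw)
    accum(b, matrix(colSums(nd$g), 1L))
    if (isTRUE(x$track) || !is.null(x$bk)) {
      gx <- matrix(0, nrow(x$v), C)
      inside <- ci$pidx <= nrow(x$v)
      gx[ci$pidx[inside], ] <- gx[ci$pidx[inside], ] +
        gpad[inside, , drop = FALSE]
      accum(x, gx)
    }
  })
}

# Fused 2x2-stride-2 transposed convolution (pixel shuffle of x W).
ad_convt <- function(x, w, b, perm, cout) {
  z <- x$v %*% w$v                      # HW x 4*cout
  stacked <- rbind(z[, 1:cout, drop = FALSE],
                   z[, (cout + 1L):(2L * cout), drop = FALSE],
                   z[, (2L * cout + 1L):(3L * cout), drop = FALSE],
                   z[, (3L * cout + 1L):(4L * cout), drop = FALSE])
  y <- sweep(stacked[perm, , drop = FALSE], 2L, as.numeric(b$v), "+")
  n <- nrow(x$v)
  new_node(y, list(x, w, b), function(nd) {
    gst <- matrix(0, 4L * n, cout)
    gst[perm, ] <- nd$g
    gz <- cbind(gst[1:n, , drop = FALSE],
                gst[(n + 1L):(2L * n), , drop = FALSE],
                gst[(2L * n + 1L):(3L * n), , drop = FALSE],
                gst[(3L * n + 1L):(4L * n), , drop = FALSE])
    accum(w, crossprod(x$v, gz))
    accum(b, matrix(colSums(nd$g), 1L))
    accum(x, gz %*% t(w$v))
  })
}

# ---- layer forwards ------------------------------------------------------

fw_linear <- function(P, name, x, bias = TRUE) {
  ad_linear(x, P(paste0(name, ".w")),
            if (bias) P(paste0(name, ".b")) else NULL)
}

fw_ln <- function(P, name, x) {
  ad_layernorm(x, P(paste0(name, ".g")), P(paste0(name, ".b")))
}

fw_conv <- function(P, name, x, H, W, k, stride, pad) {
  ci <- conv_indices(H, W, k, stride, pad)
  y <- ad_conv(x, P(paste0(name, ".w")), P(paste0(name, ".b")), ci,
               ncol(x$v))
  list(x = y, H = ci$Ho, W = ci$Wo)
}

fw_dwconv3 <- function(P, name, x, H, W) {
  ci <- conv_indices(H, W, 3L, 1L, 1L)
  ad_dwconv3(x, P(paste0(name, ".w")), P(paste0(name, ".b")), ci)
}

fw_convt <- function(P, name, x, H, W, cout) {
  perm <- convt_indices(H, W)
  y <- ad_convt(x, P(paste0(name, ".w")), P(paste0(name, ".b")), perm, cout)
  list(x = y, H = 2L * H, W = 2L * W)
}

fw_mapnorm <- function(P, name, x) {
  ad_mapnorm(x, P(paste0(name, ".g")), P(paste0(name, ".b")))
}

# L2-normalize rows (used by scaled cosine attention)
ad_l2norm_rows <- function(x, eps = 1e-12) {
  xv <- x$v
  nrm <- sqrt(rowSums(xv^2) + eps)
  y <- xv / nrm
  new_node(y, list(x), function(nd) {
    s <- rowSums(nd$g * y)
    accum(x, (nd$g - y * s) / nrm)
  })
}

ad_exp <- function(x) {
  e <- exp(x$v)
  new_node(e, list(x), function(nd) accum(x, nd$g * e))
}

ad_minconst <- function(x, cmax) {
  m <- x$v < cmax
  new_node(pmin(x$v, cmax), list(x), function(nd) accum(x, nd$g * m))
}

# 2D dropout: zeroes whole channels (columns of the token matrix).
# Inverted scaling; identity when rate == 0 or not training.
fw_dropout2d <- function(x, rate, training) {
  if (!training || rate <= 0) return(x)
  C <- ncol(x$v)
  keep <- stats::runif(C) >= rate
  scale <- ifelse(keep, 1 / (1 - rate), 0)
  sc <- ad_leaf(matrix(scale, 1L), track = FALSE)
  ad_mul_brow(x, sc)
}
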