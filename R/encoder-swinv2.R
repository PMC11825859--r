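# Swin Transformer V2 hierarchical encoder: windowed attention with
# residual post-normalization, scaled cosine attention and a continuous
# log-spaced relative position bias (a small MLP on relative window
# coordinates). Stage recipes follow the published Tiny/Small sizes.

swin_stage_dims <- function(cfg) cfg$stage_dims

reg_swin_encoder <- function(model, prefix, cfg, group, init = "trunc_normal") {
  dims <- cfg$stage_dims
  for (i in 1:4) {
    d <- dims[i]
    nm <- function(...) paste0(prefix, ".s", i, ...)
    if (i == 1L) {
      reg_conv(model, nm(".embed"), 3L, d, 4L, group, init)
      reg_ln(model, nm(".embed_ln"), d, group, init)
    } else {
      # patch merging: concat 2x2 neighborhood (4*prev) -> linear -> LN
      reg_linear(model, nm(".merge"), 4L * dims[i - 1L], d, group, init,
                 bias = FALSE)
      reg_ln(model, nm(".merge_ln"), d, group, init)
    }
    h <- cfg$heads[i]
    for (j in seq_len(cfg$depths[i])) {
      b <- function(...) nm(".b", j, ...)
      # qkv without bias + separate trainable q/v biases (k has none)
      reg_linear(model, b(".attn.qkv"), d, 3L * d, group, init, bias = FALSE)
      add_param(model, b(".attn.q_bias"), matrix(0, 1, d), group)
      add_param(model, b(".attn.v_bias"), matrix(0, 1, d), group)
      add_param(model, b(".attn.logit_scale"),
                matrix(log(10), 1, h), group)
      reg_linear(model, b(".attn.cpb1"), 2L, 512L, group, init)
      reg_linear(model, b(".attn.cpb2"), 512L, h, group, init, bias = FALSE)
      reg_linear(model, b(".attn.proj"), d, d, group, init)
      reg_ln(model, b(".norm1"), d, group, init)
      m <- d * cfg$mlp_ratio
      reg_linear(model, b(".mlp.fc1"), d, m, group, init)
      reg_linear(model, b(".mlp.fc2"), m, d, group, init)
      reg_ln(model, b(".norm2"), d, group, init)
    }
    reg_ln(model, nm(".norm"), d, group, init)
  }
  invisible(model)
}

# ---- window geometry (cached) -------------------------------------------

swin_window_geom <- function(H, W, win, shift) {
  key <- paste("swinwin", H, W, win, shift, sep = "_")
  cache_get(key, function() {
    stopifnot(H %% win == 0L, W %% win == 0L)
    nWr <- H %/% win; nWc <- W %/% win
    # circularly shifted token index grid
    rows <- ((seq_len(H) - 1L + shift) %% H) + 1L
    cols <- ((seq_len(W) - 1L + shift) %% W) + 1L
    grid <- outer(rows - 1L, cols, function(r, c) r * W + c)  # H x W
    widx <- vector("list", nWr * nWc)
    k <- 0L
    for (wr in seq_len(nWr)) {
      for (wc in seq_len(nWc)) {
        k <- k + 1L
        rr <- ((wr - 1L) * win + 1L):(wr * win)
        cc <- ((wc - 1L) * win + 1L):(wc * win)
        widx[[k]] <- as.integer(t(grid[rr, cc]))
      }
    }
    inv <- integer(H * W)
    pos <- unlist(widx)
    inv[pos] <- seq_along(pos)
    # attention masks for shifted windows (region-id trick)
    masks <- NULL
    if (shift > 0L) {
      rid <- function(n) {
        id <- integer(n)
        id[seq_len(n - win)] <- 0L
        if (win - shift > 0L) id[(n - win + 1L):(n - shift)] <- 1L
        id[(n - shift + 1L):n] <- 2L
        id
      }
      ridH <- rid(H); ridW <- rid(W)
      reg <- outer(ridH * 3L, ridW, "+")  # H x W region ids (unshifted grid)
      # region id of each token in each (shifted) window
      regs <- matrix(0L, win * win, nWr * nWc)
      rshift <- ((seq_len(H) - 1L + shift) %% H) + 1L
      k <- 0L
      for (wr in seq_len(nWr)) {
        for (wc in seq_len(nWc)) {
          k <- k + 1L
          rr <- rshift[((wr - 1L) * win + 1L):(wr * win)]
          cc <- rshift[((wc - 1L) * win + 1L):(wc * win)]
          regs[, k] <- as.integer(t(reg[rr, cc]))
        }
      }
      masks <- lapply(seq_len(nWr * nWc), function(k) {
        r <- regs[, k]
        m <- outer(r, r, "!=") * (-100)
        if (all(m == 0)) NULL else m
      })
    }
    list(widx = widx, inv = inv, n_win = nWr * nWc, masks = masks)
  })
}

swin_rel_geom <- function(win) {
  key <- paste("swinrel", win, sep = "_")
  cache_get(key, function() {
    # log-spaced continuous relative coordinate table, (2w-1)^2 x 2
    rng <- seq.int(-(win - 1L), win - 1L)
    tab <- as.matrix(expand.grid(dy = rng, dx = rng))
    tn <- tab / max(1L, win - 1L)
    tn <- sign(tn) * log1p(8 * abs(tn)) / log1p(8)
    # relative position index for each token pair in a window
    coord <- expand.grid(x = seq_len(win), y = seq_len(win))  # row-major: x fast
    dy <- outer(coord$y, coord$y, "-")
    dx <- outer(coord$x, coord$x, "-")
    ridx <- (dx + win - 1L) * (2L * win - 1L) + (dy + win) # 1-based into tab
    list(table = tn, ridx = as.integer(ridx), n = win * win)
  })
}

fw_swin_attn <- function(P, name, x, H, W, d, heads, win, shift) {
  geom <- swin_window_geom(H, W, win, shift)
  rel <- swin_rel_geom(win)
  qkv <- fw_linear(P, paste0(name, ".qkv"), x, bias = FALSE)
  q <- ad_add(ad_colsel(qkv, 1L, d), P(paste0(name, ".q_bias")))
  k <- ad_colsel(qkv, d + 1L, 2L * d)
  v <- ad_add(ad_colsel(qkv, 2L * d + 1L, 3L * d), P(paste0(name, ".v_bias")))
  # continuous position bias: MLP on the coordinate table, then gather
  tabn <- ad_leaf(rel$table, track = FALSE)
  cpb <- fw_linear(P, paste0(name, ".cpb1"), tabn)
  cpb <- ad_relu(cpb)
  cpb <- fw_linear(P, paste0(name, ".cpb2"), cpb, bias = FALSE)
  cpb <- ad_scale(ad_sigmoid(cpb), 16)
  bias_rows <- ad_rowsel(cpb, rel$ridx)  # (w^2*w^2) x heads
  ls <- P(paste0(name, ".logit_scale"))
  dh <- d %/% heads
  n2 <- rel$n
  out_windows <- vector("list", geom$n_win)
  for (wi in seq_len(geom$n_win)) {
    idx <- geom$widx[[wi]]
    qw <- ad_rowsel(q, idx); kw <- ad_rowsel(k, idx); vw <- ad_rowsel(v, idx)
    houts <- vector("list", heads)
    for (h in seq_len(heads)) {
      j0 <- (h - 1L) * dh + 1L; j1 <- h * dh
      qh <- ad_l2norm_rows(ad_colsel(qw, j0, j1))
      kh <- ad_l2norm_rows(ad_colsel(kw, j0, j1))
      sc <- ad_exp(ad_minconst(ad_colsel(ls, h, h), log(100)))
      logits <- ad_mul(ad_mm(qh, ad_t(kh)), sc)
      bh <- ad_reshape_col(ad_colsel(bias_rows, h, h), n2, n2)
      logits <- ad_add(logits, bh)
      if (!is.null(geom$masks) && !is.null(geom$masks[[wi]])) {
        logits <- ad_add(logits, ad_leaf(geom$masks[[wi]], track = FALSE))
      }
      A <- ad_softmax_rows(logits)
      houts[[h]] <- ad_mm(A, ad_colsel(vw, j0, j1))
    }
    xw <- if (heads == 1L) houts[[1L]] else ad_cbind(houts)
    out_windows[[wi]] <- xw
  }
  merged <- ad_rowsel(ad_rbind(out_windows), geom$inv)
  fw_linear(P, paste0(name, ".proj"), merged)
}

# reshape a (n*m x 1) column into an n x m matrix (column-major fill)
ad_reshape_col <- function(x, n, m) {
  new_node(matrix(x$v, n, m), list(x), function(nd) {
    accum(x, matrix(as.numeric(nd$g), n * m, 1L))
  })
}

fw_swin_block <- function(P, name, x, H, W, d, heads, win, shift) {
  a <- fw_swin_attn(P, paste0(name, ".attn"), x, H, W, d, heads, win, shift)
  x <- ad_add(x, fw_ln(P, paste0(name, ".norm1"), a))          # post-norm
  m <- fw_linear(P, paste0(name, ".mlp.fc1"), x)
  m <- ad_gelu(m)
  m <- fw_linear(P, paste0(name, ".mlp.fc2"), m)
  ad_add(x, fw_ln(P, paste0(name, ".norm2"), m))
}

merge_indices <- function(H, W) {
  key <- paste("merge", H, W, sep = "_")
  cache_get(key, function() {
    stopifnot(H %% 2L == 0L, W %% 2L == 0L)
    r0 <- rep(seq.int(1L, H, 2L), each = W %/% 2L)
    c0 <- rep(seq.int(1L, W, 2L), times = H %/% 2L)
    list(i00 = (r0 - 1L) * W + c0,
         i01 = (r0 - 1L) * W + c0 + 1L,
         i10 = r0 * W + c0,
         i11 = r0 * W + c0 + 1L)
  })
}

fw_swin_encoder <- function(P, prefix, cfg, x, H, W) {
  dims <- cfg$stage_dims
  skips <- vector("list", 4L)
  for (i in 1:4) {
    nm <- function(...) paste0(prefix, ".s", i, ...)
    if (i == 1L) {
      emb <- fw_conv(P, nm(".embed"), x, H, W, 4L, 4L, 0L)
      x <- fw_ln(P, nm(".embed_ln"), emb$x); H <- emb$H; W <- emb$W
    } else {
      mi <- merge_indices(H, W)
      x <- ad_cbind(list(ad_rowsel(x, mi$i00), ad_rowsel(x, mi$i01),
                         ad_rowsel(x, mi$i10), ad_rowsel(x, mi$i11)))
      x <- fw_linear(P, nm(".merge"), x, bias = FALSE)
      x <- fw_ln(P, nm(".merge_ln"), x)
      H <- H %/% 2L; W <- W %/% 2L
    }
    win <- min(cfg$window, H, W)
    for (j in seq_len(cfg$depths[i])) {
      shift <- if (j %% 2L == 0L && win < min(H, W)) win %/% 2L else 0L
      x <- fw_swin_block(P, nm(".b", j), x, H, W, dims[i], cfg$heads[i],
                         win, shift)
    }
    x <- fw_ln(P, nm(".norm"), x)
    skips[[i]] <- list(x = x, H = H, W = W)
  }
  skips
}
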