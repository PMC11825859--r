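# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every differentiable quantity is a "node": an environment holding the
# value (`v`, a base-R matrix), the accumulated gradient (`g`), the parent
# nodes and a backward closure. Nodes are appended to a tape in creation
# order; ad_backward() walks the tape in reverse. All heavy lifting is
# plain BLAS-backed matrix arithmetic, which is what keeps desk-scale
# training of the tiny model variants practical on one CPU.

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL

#' Start a fresh autodiff tape
#'
#' Clears the recording tape. Call once per forward pass before any
#' differentiable op is evaluated.
#' @return Invisibly, the (empty) tape environment.
#' @keywords internal
#' @export
ad_begin <- function() {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 256L)
  tape$n <- 0L
  .ad$tape <- tape
  invisible(tape)
}

ad_push <- function(node) {
  tape <- .ad$tape
  if (is.null(tape)) stop("no active tape; call ad_begin() first")
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- node
  tape$n <- n
  node
}

new_node <- function(value, parents = NULL, backward = NULL, track = TRUE) {
  nd <- new.env(parent = emptyenv())
  nd$v <- value
  nd$g <- NULL
  nd$prt <- parents
  nd$bk <- backward
  nd$track <- track
  class(nd) <- "ad_node"
  ad_push(nd)
}

#' Create a leaf node
#'
#' @param value numeric matrix (or vector, coerced to a row matrix).
#' @param track whether gradients should be accumulated into this leaf.
#' @return an `ad_node`.
#' @keywords internal
#' @export
ad_leaf <- function(value, track = TRUE) {
  if (!is.matrix(value)) value <- matrix(value, nrow = 1L)
  new_node(value, track = track)
}

accum <- function(node, g) {
  if (is.null(node) || !isTRUE(node$track)) return(invisible(NULL))
  if (is.null(node$g)) node$g <- g else node$g <- node$g + g
  invisible(NULL)
}

#' Run backpropagation from a scalar node
#'
#' @param node node holding a 1x1 value.
#' @param seed gradient seed, default 1.
#' @keywords internal
#' @export
ad_backward <- function(node, seed = 1) {
  tape <- .ad$tape
  node$g <- matrix(seed, nrow(node$v), ncol(node$v))
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$bk) && !is.null(nd$g)) nd$bk(nd)
  }
  invisible(NULL)
}

# ---- arithmetic ----------------------------------------------------------

#' @keywords internal
#' @export
ad_mm <- function(a, b) {
  new_node(a$v %*% b$v, list(a, b), function(nd) {
    accum(a, nd$g %*% t(b$v))
    accum(b, crossprod(a$v, nd$g))
  })
}

#' Add two nodes; `b` may be a 1-row bias broadcast over rows of `a`
#' @keywords internal
#' @export
ad_add <- function(a, b) {
  av <- a$v; bv <- b$v
  if (nrow(bv) == 1L && nrow(av) > 1L) {
    val <- sweep(av, 2L, as.numeric(bv), "+")
    new_node(val, list(a, b), function(nd) {
      accum(a, nd$g)
      accum(b, matrix(colSums(nd$g), 1L))
    })
  } else {
    new_node(av + bv, list(a, b), function(nd) {
      accum(a, nd$g)
      accum(b, nd$g)
    })
  }
}

#' @keywords internal
#' @export
ad_sub <- function(a, b) {
  new_node(a$v - b$v, list(a, b), function(nd) {
    accum(a, nd$g)
    accum(b, -nd$g)
  })
}

#' Elementwise product; shapes must match or one operand be 1x1
#' @keywords internal
#' @export
ad_mul <- function(a, b) {
  av <- a$v; bv <- b$v
  if (length(bv) == 1L) {
    new_node(av * as.numeric(bv), list(a, b), function(nd) {
      accum(a, nd$g * as.numeric(bv))
      accum(b, matrix(sum(nd$g * av), 1L, 1L))
    })
  } else if (length(av) == 1L) {
    ad_mul(b, a)
  } else {
    new_node(av * bv, list(a, b), function(nd) {
      accum(a, nd$g * bv)
      accum(b, nd$g * av)
    })
  }
}

#' Multiply each row of `a` by a 1-row node `brow`
#' @keywords internal
#' @export
ad_mul_brow <- function(a, brow) {
  bv <- as.numeric(brow$v)
  new_node(sweep(a$v, 2L, bv, "*"), list(a, brow), function(nd) {
    accum(a, sweep(nd$g, 2L, bv, "*"))
    accum(brow, matrix(colSums(nd$g * a$v), 1L))
  })
}

#' Scale by a plain numeric constant
#' @keywords internal
#' @export
ad_scale <- function(a, s) {
  new_node(a$v * s, list(a), function(nd) accum(a, nd$g * s))
}

#' Elementwise division; `b` may be 1x1
#' @keywords internal
#' @export
ad_div <- function(a, b) {
  av <- a$v; bv <- b$v
  if (length(bv) == 1L) {
    s <- as.numeric(bv)
    new_node(av / s, list(a, b), function(nd) {
      accum(a, nd$g / s)
      accum(b, matrix(-sum(nd$g * av) / s^2, 1L, 1L))
    })
  } else {
    new_node(av / bv, list(a, b), function(nd) {
      accum(a, nd$g / bv)
      accum(b, -nd$g * av / bv^2)
    })
  }
}

# ---- nonlinearities ------------------------------------------------------

#' @keywords internal
#' @export
ad_relu <- function(a) {
  m <- a$v > 0
  new_node(a$v * m, list(a), function(nd) accum(a, nd$g * m))
}

#' Exact (erf-based) GELU
#' @keywords internal
#' @export
ad_gelu <- function(a) {
  x <- a$v
  ph <- stats::pnorm(x)
  new_node(x * ph, list(a), function(nd) {
    accum(a, nd$g * (ph + x * stats::dnorm(x)))
  })
}

#' @keywords internal
#' @export
ad_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$v))
  new_node(s, list(a), function(nd) accum(a, nd$g * s * (1 - s)))
}

#' @keywords internal
#' @export
ad_log <- function(a) {
  new_node(log(a$v), list(a), function(nd) accum(a, nd$g / a$v))
}

#' Elementwise power with a constant exponent
#' @keywords internal
#' @export
ad_pow <- function(a, p) {
  new_node(a$v^p, list(a), function(nd) accum(a, nd$g * p * a$v^(p - 1)))
}

#' Clamp to [lo, hi]; gradient passes only inside the interval
#' @keywords internal
#' @export
ad_clamp <- function(a, lo, hi) {
  inside <- a$v > lo & a$v < hi
  new_node(pmin(pmax(a$v, lo), hi), list(a), function(nd) {
    accum(a, nd$g * inside)
  })
}

#' Row-wise numerically stable softmax
#'
#' The row-max shift is treated as a constant in the backward pass, which
#' is exact (softmax is shift invariant). For an all-zero input row the
#' result is the uniform 1/n row.
#' @keywords internal
#' @export
ad_softmax_rows <- function(a) {
  x <- a$v
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  y <- e / rowSums(e)
  new_node(y, list(a), function(nd) {
    accum(a, y * (nd$g - rowSums(nd$g * y)))
  })
}

# ---- normalization -------------------------------------------------------

#' Layer normalization over channels (columns), per row
#' @param x node (n x C); gamma, beta nodes (1 x C)
#' @keywords internal
#' @export
ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- x$v
  mu <- rowMeans(xv)
  xc <- xv - mu
  va <- rowMeans(xc^2)
  isd <- 1 / sqrt(va + eps)
  xh <- xc * isd
  gv <- as.numeric(gamma$v)
  y <- sweep(sweep(xh, 2L, gv, "*"), 2L, as.numeric(beta$v), "+")
  C <- ncol(xv)
  new_node(y, list(x, gamma, beta), function(nd) {
    accum(gamma, matrix(colSums(nd$g * xh), 1L))
    accum(beta, matrix(colSums(nd$g), 1L))
    dxh <- sweep(nd$g, 2L, gv, "*")
    t1 <- rowSums(dxh)
    t2 <- rowSums(dxh * xh)
    accum(x, (dxh - t1 / C - xh * t2 / C) * isd)
  })
}

#' Whole-map normalization (GroupNorm with one group)
#'
#' Normalizes over every element of the (pixels x channels) map, then
#' applies a per-channel affine. Statistics are per sample, so training
#' does not depend on batch composition.
#' @keywords internal
#' @export
ad_mapnorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- x$v
  N <- length(xv)
  mu <- mean(xv)
  xc <- xv - mu
  va <- mean(xc^2)
  isd <- 1 / sqrt(va + eps)
  xh <- xc * isd
  gv <- as.numeric(gamma$v)
  y <- sweep(sweep(xh, 2L, gv, "*"), 2L, as.numeric(beta$v), "+")
  new_node(y, list(x, gamma, beta), function(nd) {
    accum(gamma, matrix(colSums(nd$g * xh), 1L))
    accum(beta, matrix(colSums(nd$g), 1L))
    dxh <- sweep(nd$g, 2L, gv, "*")
    t1 <- sum(dxh)
    t2 <- sum(dxh * xh)
    accum(x, (dxh - t1 / N - xh * t2 / N) * isd)
  })
}

# ---- shape ops -----------------------------------------------------------

#' Gather rows (duplicates allowed); backward scatter-adds
#' @keywords internal
#' @export
ad_rowsel <- function(x, idx) {
  new_node(x$v[idx, , drop = FALSE], list(x), function(nd) {
    if (!isTRUE(x$track) && is.null(x$bk)) return(invisible(NULL))
    gp <- matrix(0, nrow(x$v), ncol(x$v))
    rs <- rowsum(nd$g, group = idx)
    gp[as.integer(rownames(rs)), ] <- rs
    accum(x, gp)
  })
}

#' Column slice [j0, j1]
#' @keywords internal
#' @export
ad_colsel <- function(x, j0, j1) {
  new_node(x$v[, j0:j1, drop = FALSE], list(x), function(nd) {
    gp <- matrix(0, nrow(x$v), ncol(x$v))
    gp[, j0:j1] <- nd$g
    accum(x, gp)
  })
}

#' Column-concatenate a list of nodes
#' @keywords internal
#' @export
ad_cbind <- function(nodes) {
  vals <- lapply(nodes, function(n) n$v)
  widths <- vapply(vals, ncol, 1L)
  off <- cumsum(c(0L, widths))
  new_node(do.call(cbind, vals), nodes, function(nd) {
    for (i in seq_along(nodes)) {
      accum(nodes[[i]], nd$g[, (off[i] + 1L):off[i + 1L], drop = FALSE])
    }
  })
}

#' Row-concatenate a list of nodes
#' @keywords internal
#' @export
ad_rbind <- function(nodes) {
  vals <- lapply(nodes, function(n) n$v)
  heights <- vapply(vals, nrow, 1L)
  off <- cumsum(c(0L, heights))
  new_node(do.call(rbind, vals), nodes, function(nd) {
    for (i in seq_along(nodes)) {
      accum(nodes[[i]], nd$g[(off[i] + 1L):off[i + 1L], , drop = FALSE])
    }
  })
}

#' Append one all-zero row (used as the padding source for gathers)
#' @keywords internal
#' @export
ad_pad_zero_row <- function(x) {
  new_node(rbind(x$v, 0), list(x), function(nd) {
    accum(x, nd$g[-nrow(nd$g), , drop = FALSE])
  })
}

#' Matrix transpose
#' @keywords internal
#' @export
ad_t <- function(x) {
  new_node(t(x$v), list(x), function(nd) accum(x, t(nd$g)))
}

# ---- reductions ----------------------------------------------------------

#' Sum of all elements (1x1 node)
#' @keywords internal
#' @export
ad_sum <- function(x) {
  new_node(matrix(sum(x$v), 1L, 1L), list(x), function(nd) {
    accum(x, matrix(as.numeric(nd$g), nrow(x$v), ncol(x$v)))
  })
}

#' Mean of all elements (1x1 node)
#' @keywords internal
#' @export
ad_mean <- function(x) {
  N <- length(x$v)
  new_node(matrix(mean(x$v), 1L, 1L), list(x), function(nd) {
    accum(x, matrix(as.numeric(nd$g) / N, nrow(x$v), ncol(x$v)))
  })
}
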