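# Reverse-mode automatic differentiation over 4-D feature arrays.
#
# Every feature tensor has dim c(H, W, N, C): spatial rows, spatial columns,
# batch, channels.  Channels last keeps matrix(x, H*W*N, C) a zero-copy view
# of the per-pixel feature matrix, so convolutions and normalization reduce
# to BLAS matrix products.
#
# A "tape" records operation nodes in execution order; backward() walks the
# tape in reverse, each node scattering its output gradient to its parents.
# Persistent parameters live outside the tape (see nn_param) and are wrapped
# as leaf nodes per forward pass, accumulating gradients in place.

new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- list()
  tp
}

tape_node <- function(tape, val, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$backward <- backward
  nd$tape <- tape
  if (!is.null(tape)) tape$nodes[[length(tape$nodes) + 1L]] <- nd
  nd
}

node_accum <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(nd)
}

tape_backward <- function(tape, loss_node) {
  loss_node$grad <- 1
  for (nd in rev(tape$nodes)) {
    if (!is.null(nd$backward) && !is.null(nd$grad)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

# Persistent trainable parameter (survives across forward passes).
nn_param <- function(val) {
  p <- new.env(parent = emptyenv())
  p$val <- val
  p$grad <- NULL
  p
}

param_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# Wrap a persistent parameter as a tape leaf; gradients flow into p$grad.
tape_param <- function(tape, p) {
  tape_node(tape, p$val, backward = function(g) {
    p$grad <- if (is.null(p$grad)) g else p$grad + g
  })
}

tape_leaf <- function(tape, val) tape_node(tape, val)

# ---- shape helpers ---------------------------------------------------------

fm_dim <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 4L)
  d
}

# Coerce user input (matrix, 3-D array of H x W x N, or 4-D) to H x W x N x C.
as_feature_array <- function(x) {
  if (is.matrix(x)) {
    dim(x) <- c(dim(x), 1L, 1L)
  } else if (length(dim(x)) == 3L) {
    dim(x) <- c(dim(x), 1L)
  }
  stopifnot(length(dim(x)) == 4L)
  x
}

# valid source/destination row ranges when shifting by offset d with zero pad
shift_ranges <- function(n, d) {
  lo <- max(1L, 1L - d); hi <- min(n, n - d)
  dst <- if (lo > hi) integer(0) else lo:hi
  list(dst = dst, src = dst + d)
}

# ---- convolution -----------------------------------------------------------

# 3x3 (or 1x1) convolution, "same" padding, stride 1 or 2.
# w: array (k, k, Cin, Cout); b: numeric length Cout.
op_conv <- function(x, w, b, stride = 1L) {
  tp <- x$tape
  k <- dim(w$val)[1]
  d <- fm_dim(x$val)
  H <- d[1]; W <- d[2]; N <- d[3]; Cin <- d[4]; Cout <- dim(w$val)[4]
  P <- H * W * N

  if (k == 1L) {
    xm <- matrix(x$val, P, Cin)
    wm <- matrix(w$val, Cin, Cout)
    ym <- xm %*% wm
    ym <- sweep_bias(ym, b$val)
    yfull <- array(ym, c(H, W, N, Cout))
    out <- subsample_stride(yfull, stride)
    bw <- function(g) {
      gf <- upscatter_stride(g, H, W, stride)
      gm <- matrix(gf, P, Cout)
      node_accum(w, array(crossprod(xm, gm), dim(w$val)))
      node_accum(b, colSums(gm))
      node_accum(x, array(tcrossprod(gm, wm), d))
    }
    return(tape_node(tp, out, bw))
  }

  offs <- expand.grid(dy = -1:1, dx = -1:1)
  xs_list <- vector("list", nrow(offs))
  ym <- matrix(0, P, Cout)
  for (o in seq_len(nrow(offs))) {
    dy <- offs$dy[o]; dx <- offs$dx[o]
    xs <- array(0, d)
    ry <- shift_ranges(H, dy); rx <- shift_ranges(W, dx)
    xs[ry$dst, rx$dst, , ] <- x$val[ry$src, rx$src, , , drop = FALSE]
    xsm <- matrix(xs, P, Cin)
    xs_list[[o]] <- xsm
    wk <- matrix(w$val[offs$dy[o] + 2L, offs$dx[o] + 2L, , ], Cin, Cout)
    ym <- ym + xsm %*% wk
  }
  ym <- sweep_bias(ym, b$val)
  yfull <- array(ym, c(H, W, N, Cout))
  out <- subsample_stride(yfull, stride)

  bw <- function(g) {
    gf <- upscatter_stride(g, H, W, stride)
    gm <- matrix(gf, P, Cout)
    node_accum(b, colSums(gm))
    dw <- array(0, dim(w$val))
    dx_arr <- array(0, d)
    for (o in seq_len(nrow(offs))) {
      dy <- offs$dy[o]; dx <- offs$dx[o]
      wk <- matrix(w$val[dy + 2L, dx + 2L, , ], Cin, Cout)
      dw[dy + 2L, dx + 2L, , ] <- crossprod(xs_list[[o]], gm)
      dxs <- array(tcrossprod(gm, wk), d)
      ry <- shift_ranges(H, dy); rx <- shift_ranges(W, dx)
      dx_arr[ry$src, rx$src, , ] <- dx_arr[ry$src, rx$src, , , drop = FALSE] +
        dxs[ry$dst, rx$dst, , , drop = FALSE]
    }
    node_accum(w, dw)
    node_accum(x, dx_arr)
  }
  tape_node(tp, out, bw)
}

sweep_bias <- function(ym, b) ym + rep(b, each = nrow(ym))

subsample_stride <- function(y, stride) {
  if (stride == 1L) return(y)
  d <- dim(y)
  y[seq(1L, d[1], by = stride), seq(1L, d[2], by = stride), , , drop = FALSE]
}

upscatter_stride <- function(g, H, W, stride) {
  if (stride == 1L) return(g)
  d <- dim(g)
  gf <- array(0, c(H, W, d[3], d[4]))
  gf[seq(1L, H, by = stride), seq(1L, W, by = stride), , ] <- g
  gf
}

# ---- batch normalization ---------------------------------------------------

# state: environment with rmean, rvar (running statistics), eps, momentum
op_batchnorm <- function(x, gamma, beta, state, training) {
  tp <- x$tape
  d <- fm_dim(x$val)
  C <- d[4]
  P <- prod(d[1:3])
  xm <- matrix(x$val, P, C)
  eps <- state$eps
  if (training) {
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = P)
    v <- colMeans(xc * xc)
    ivar <- 1 / sqrt(v + eps)
    xhat <- xc * rep(ivar, each = P)
    state$rmean <- (1 - state$momentum) * state$rmean + state$momentum * mu
    state$rvar <- (1 - state$momentum) * state$rvar + state$momentum * v
  } else {
    ivar <- 1 / sqrt(state$rvar + eps)
    xhat <- (xm - rep(state$rmean, each = P)) * rep(ivar, each = P)
  }
  ym <- xhat * rep(gamma$val, each = P) + rep(beta$val, each = P)
  out <- array(ym, d)
  bw <- function(g) {
    gm <- matrix(g, P, C)
    node_accum(gamma, colSums(gm * xhat))
    node_accum(beta, colSums(gm))
    gi <- rep(gamma$val * ivar, each = P)
    if (training) {
      sg <- rep(colMeans(gm), each = P)
      sgx <- rep(colMeans(gm * xhat), each = P)
      dx <- gi * (gm - sg - xhat * sgx)
    } else {
      dx <- gi * gm
    }
    node_accum(x, array(dx, d))
  }
  tape_node(tp, out, bw)
}

# ---- elementwise / structural ops ------------------------------------------

op_relu <- function(x) {
  mask <- x$val > 0
  tape_node(x$tape, x$val * mask, function(g) node_accum(x, g * mask))
}

op_add <- function(a, b) {
  tape_node(a$tape, a$val + b$val, function(g) {
    node_accum(a, g); node_accum(b, g)
  })
}

op_add_list <- function(xs) {
  out <- xs[[1]]$val
  for (i in seq_along(xs)[-1]) out <- out + xs[[i]]$val
  tape_node(xs[[1]]$tape, out, function(g) for (x in xs) node_accum(x, g))
}

# multiply a feature map by a scalar parameter (alpha weight)
op_scale <- function(x, alpha) {
  a <- as.numeric(alpha$val)
  tape_node(x$tape, x$val * a, function(g) {
    node_accum(alpha, sum(g * x$val))
    node_accum(x, g * a)
  })
}

op_scale_const <- function(x, a) {
  tape_node(x$tape, x$val * a, function(g) node_accum(x, g * a))
}

op_concat_channels <- function(xs) {
  d <- fm_dim(xs[[1]]$val)
  cs <- vapply(xs, function(x) fm_dim(x$val)[4], integer(1))
  out <- array(0, c(d[1], d[2], d[3], sum(cs)))
  at <- 0L
  for (i in seq_along(xs)) {
    out[, , , at + seq_len(cs[i])] <- xs[[i]]$val
    at <- at + cs[i]
  }
  tape_node(xs[[1]]$tape, out, function(g) {
    at <- 0L
    for (i in seq_along(xs)) {
      node_accum(xs[[i]], g[, , , at + seq_len(cs[i]), drop = FALSE])
      at <- at + cs[i]
    }
  })
}

# ---- bilinear 2x upsampling ------------------------------------------------

# Interpolation matrix mapping n source samples to 2n outputs; output centers
# at (o + 0.5)/2 - 0.5 in source coordinates (half-pixel convention), edge
# clamped.  Cached per size.
.upsample_cache <- new.env(parent = emptyenv())

bilinear_matrix2x <- function(n) {
  key <- as.character(n)
  if (!is.null(.upsample_cache[[key]])) return(.upsample_cache[[key]])
  m <- matrix(0, 2L * n, n)
  for (o in 0:(2L * n - 1L)) {
    src <- (o + 0.5) / 2 - 0.5
    i0 <- floor(src)
    f <- src - i0
    i0c <- min(max(i0, 0), n - 1)
    i1c <- min(max(i0 + 1, 0), n - 1)
    m[o + 1L, i0c + 1L] <- m[o + 1L, i0c + 1L] + (1 - f)
    m[o + 1L, i1c + 1L] <- m[o + 1L, i1c + 1L] + f
  }
  .upsample_cache[[key]] <- m
  m
}

# apply M (m x H) along dim 1 and K (k x W) along dim 2 of an (H,W,N,C) array
apply_sep_linear <- function(x, M, K) {
  d <- dim(x)
  t1 <- M %*% matrix(x, d[1], prod(d[2:4]))              # (m, W*N*C)
  t1 <- array(t1, c(nrow(M), d[2], d[3], d[4]))
  t1p <- aperm(t1, c(2, 1, 3, 4))                        # (W, m, N, C)
  t2 <- K %*% matrix(t1p, d[2], nrow(M) * d[3] * d[4])   # (k, m*N*C)
  t2 <- array(t2, c(nrow(K), nrow(M), d[3], d[4]))
  aperm(t2, c(2, 1, 3, 4))                               # (m, k, N, C)
}

op_upsample2x <- function(x) {
  d <- fm_dim(x$val)
  UH <- bilinear_matrix2x(d[1])
  UW <- bilinear_matrix2x(d[2])
  out <- apply_sep_linear(x$val, UH, UW)
  tape_node(x$tape, out, function(g) {
    node_accum(x, apply_sep_linear(g, t(UH), t(UW)))
  })
}

# ---- output nonlinearities -------------------------------------------------

op_softmax_channels <- function(x) {
  d <- fm_dim(x$val)
  P <- prod(d[1:3]); C <- d[4]
  M <- matrix(x$val, P, C)
  mx <- M[, 1]
  if (C > 1) for (cc in 2:C) mx <- pmax(mx, M[, cc])
  E <- exp(M - mx)
  Y <- E / rowSums(E)
  out <- array(Y, d)
  bw <- function(g) {
    G <- matrix(g, P, C)
    dz <- Y * (G - rowSums(G * Y))
    node_accum(x, array(dz, d))
  }
  tape_node(x$tape, out, bw)
}

op_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$val))
  tape_node(x$tape, s, function(g) node_accum(x, g * s * (1 - s)))
}
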