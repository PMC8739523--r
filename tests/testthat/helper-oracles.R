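# Naive reference implementations used as independent oracles.  These are
# deliberately written as plain loops over single-sample (H, W, C) arrays,
# sharing no code with the package's vectorized engine.

naive_conv3 <- function(x, w, b) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]; Cout <- dim(w)[4]
  y <- array(0, c(H, W, Cout))
  for (co in seq_len(Cout)) {
    acc <- matrix(b[co], H, W)
    for (ci in seq_len(Cin)) {
      for (dy in -1:1) for (dx in -1:1) {
        wv <- w[dy + 2, dx + 2, ci, co]
        if (wv == 0) next
        for (r in 1:H) for (cc in 1:W) {
          rs <- r + dy; cs <- cc + dx
          if (rs >= 1 && rs <= H && cs >= 1 && cs <= W) {
            acc[r, cc] <- acc[r, cc] + wv * x[rs, cs, ci]
          }
        }
      }
    }
    y[, , co] <- acc
  }
  y
}

# inference-mode normalization with explicit running statistics
naive_bn_eval <- function(x, gamma, beta, rmean, rvar, eps = 1e-5) {
  y <- x
  for (ci in seq_len(dim(x)[3])) {
    y[, , ci] <- (x[, , ci] - rmean[ci]) / sqrt(rvar[ci] + eps) * gamma[ci] +
      beta[ci]
  }
  y
}

naive_relu <- function(x) pmax(x, 0)

# bilinear 2x upsampling, half-pixel centers, edge clamped
naive_up2x <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  y <- array(0, c(2 * H, 2 * W, C))
  interp1 <- function(v, o) {
    src <- (o + 0.5) / 2 - 0.5
    i0 <- floor(src); f <- src - i0
    i0c <- min(max(i0, 0), length(v) - 1)
    i1c <- min(max(i0 + 1, 0), length(v) - 1)
    (1 - f) * v[i0c + 1] + f * v[i1c + 1]
  }
  for (ci in seq_len(C)) {
    tmp <- matrix(0, 2 * H, W)
    for (cc in 1:W) for (o in 0:(2 * H - 1)) {
      tmp[o + 1, cc] <- interp1(x[, cc, ci], o)
    }
    for (r in 1:(2 * H)) for (o in 0:(2 * W - 1)) {
      y[r, o + 1, ci] <- interp1(tmp[r, ], o)
    }
  }
  y
}

# run a model's conv+BN+ReLU unit in inference mode through the naive path
naive_cbr_eval <- function(layer, x) {
  h <- naive_conv3(x, layer$conv$w$val, layer$conv$b$val)
  st <- layer$bn$state
  naive_relu(naive_bn_eval(h, layer$bn$gamma$val, layer$bn$beta$val,
                           st$rmean, st$rvar, st$eps))
}

naive_db_eval <- function(layer, x) {
  naive_up2x(naive_conv3(x, layer$conv$w$val, layer$conv$b$val))
}

# drop the batch dimension of a single-sample (H, W, 1, C) array
squeeze1 <- function(a) array(a[, , 1, ], dim(a)[c(1, 2, 4)])

unsqueeze1 <- function(a) array(a, c(dim(a)[1:2], 1L, dim(a)[3]))

# set-based segmentation metrics from explicit pixel index sets
set_based_metrics <- function(pred, gt, cls) {
  A <- which(pred == cls)
  B <- which(gt == cls)
  inter <- length(intersect(A, B))
  uni <- length(union(A, B))
  total <- length(pred)
  c(DSC = 2 * inter / (length(A) + length(B)),
    IoU = inter / uni,
    Acc = (total - uni + inter) / total,
    Sen = inter / length(B),
    Pre = inter / length(A)) * 100
}
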