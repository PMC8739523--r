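# Parameterized layers built on the autodiff ops.  A layer is a plain list
# of nn_param objects plus static metadata; apply_* functions run it on a
# tape node.  Weight init is He-normal (fan-in of the kernel), biases zero,
# BN gamma 1 / beta 0 -- drawn from R's global RNG so that build_network
# can make initialization reproducible with a single seed.

layer_conv <- function(k, cin, cout, stride = 1L, bias = TRUE) {
  sd <- sqrt(2 / (k * k * cin))
  w <- nn_param(array(stats::rnorm(k * k * cin * cout, sd = sd),
                      c(k, k, cin, cout)))
  b <- nn_param(if (bias) numeric(cout) else NULL)
  list(type = "conv", k = k, stride = stride, w = w, b = b,
       cin = cin, cout = cout)
}

layer_bn <- function(c, eps = 1e-5, momentum = 0.1) {
  state <- new.env(parent = emptyenv())
  state$rmean <- numeric(c)
  state$rvar <- rep(1, c)
  state$eps <- eps
  state$momentum <- momentum
  list(type = "bn", gamma = nn_param(rep(1, c)), beta = nn_param(numeric(c)),
       state = state, c = c)
}

apply_conv <- function(layer, x, tape) {
  op_conv(x, tape_param(tape, layer$w), tape_param(tape, layer$b),
          stride = layer$stride)
}

apply_bn <- function(layer, x, tape, training) {
  op_batchnorm(x, tape_param(tape, layer$gamma), tape_param(tape, layer$beta),
               layer$state, training)
}

# conv + BN + ReLU, the grid's standard unit
layer_cbr <- function(k, cin, cout, stride = 1L) {
  list(type = "cbr", conv = layer_conv(k, cin, cout, stride), bn = layer_bn(cout))
}

apply_cbr <- function(layer, x, tape, training) {
  op_relu(apply_bn(layer$bn, apply_conv(layer$conv, x, tape), tape, training))
}

# plain encoder stage: two conv-BN-ReLU, the first at stride 2
layer_plain_stage <- function(cin, cout) {
  list(type = "plain_stage",
       a = layer_cbr(3L, cin, cout, stride = 2L),
       b = layer_cbr(3L, cout, cout))
}

apply_plain_stage <- function(layer, x, tape, training) {
  apply_cbr(layer$b, apply_cbr(layer$a, x, tape, training), tape, training)
}

# residual stage: basic block with stride-2 downsampling and projection skip
layer_res_stage <- function(cin, cout) {
  list(type = "res_stage",
       conv1 = layer_conv(3L, cin, cout, stride = 2L),
       bn1 = layer_bn(cout),
       conv2 = layer_conv(3L, cout, cout),
       bn2 = layer_bn(cout),
       proj = layer_conv(1L, cin, cout, stride = 2L),
       bnp = layer_bn(cout))
}

apply_res_stage <- function(layer, x, tape, training) {
  h <- op_relu(apply_bn(layer$bn1, apply_conv(layer$conv1, x, tape), tape, training))
  h <- apply_bn(layer$bn2, apply_conv(layer$conv2, h, tape), tape, training)
  s <- apply_bn(layer$bnp, apply_conv(layer$proj, x, tape), tape, training)
  op_relu(op_add(h, s))
}

# decode block: 3x3 conv projecting to the parent level's channels, then
# bilinear 2x upsampling
layer_db <- function(cin, cout) {
  list(type = "db", conv = layer_conv(3L, cin, cout))
}

apply_db <- function(layer, x, tape) {
  op_upsample2x(apply_conv(layer$conv, x, tape))
}

# recursively harvest nn_param objects from a nested layer list
collect_params <- function(x) {
  if (is.environment(x) && !is.null(x$val)) return(list(x))
  if (is.list(x)) {
    out <- list()
    for (el in x) out <- c(out, collect_params(el))
    return(out)
  }
  list()
}

# ---- Adam optimizer --------------------------------------------------------

adam_init <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$t <- 0L
  st$m <- lapply(params, function(p) p$val * 0)
  st$v <- lapply(params, function(p) p$val * 0)
  st
}

adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    opt$m[[i]] <- opt$beta1 * opt$m[[i]] + (1 - opt$beta1) * g
    opt$v[[i]] <- opt$beta2 * opt$v[[i]] + (1 - opt$beta2) * g * g
    mhat <- opt$m[[i]] / bc1
    vhat <- opt$v[[i]] / bc2
    p$val <- p$val - opt$lr * mhat / (sqrt(vhat) + opt$eps)
  }
  param_zero_grad(opt$params)
  invisible(opt)
}
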