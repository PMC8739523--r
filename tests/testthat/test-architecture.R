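test_that("alpha weight census matches brute-force index enumeration", {
  # enumerate (i, j, k) with 0 <= i <= 2, 2 <= j <= 4 - i, 0 <= k <= j - 2
  triples <- list()
  for (i in 0:4) for (j in 0:4) for (k in 0:4) {
    if (i + j <= 4 && j >= 2 && k <= j - 2) {
      triples[[length(triples) + 1L]] <- c(i, j, k)
    }
  }
  counts <- table(vapply(triples, `[`, numeric(1), 1))
  expect_length(triples, 10L)
  expect_equal(as.integer(counts), c(6L, 3L, 1L))

  m <- build_network(tiny_variant("dwnet"))
  expect_identical(n_learnable_alphas(m), 10L)
  snap <- alpha_snapshot(m)
  expect_equal(nrow(snap), 10L)
  expect_true(all(snap$value == 1))
  expect_equal(snap$index, snap$j * 2L + snap$k)

  frozen <- build_network(tiny_variant("res18unetpp"))
  expect_identical(n_learnable_alphas(frozen), 0L)
  fsnap <- alpha_snapshot(frozen)
  expect_false(attr(fsnap, "trainable"))
  expect_true(all(fsnap$value == 1))

  expect_error(alpha_snapshot(build_network(tiny_variant("backbone"))),
               "no alpha")
})

test_that("presets map to the documented field combinations", {
  cfg <- make_variant("dwnet")
  expect_equal(cfg$encoder_kind, "residual")
  expect_equal(cfg$connection_kind, "weighted_add")
  expect_equal(cfg$alpha_policy, "learnable")
  expect_equal(cfg$head_kind, "dn_avg")
  expect_equal(cfg$output_kind, "multiclass")
  expect_equal(cfg$channel_plan, c(64L, 64L, 128L, 256L, 512L))

  expect_equal(make_variant("backbone")$connection_kind, "concat")
  expect_equal(make_variant("backbone")$alpha_policy, "absent")
  expect_equal(make_variant("res18unetpp")$alpha_policy, "fixed_one")
  expect_equal(make_variant("adaptiveunetpp")$encoder_kind, "plain")
  expect_equal(make_variant("adaptiveunetpp")$alpha_policy, "learnable")
  cfg2 <- make_variant("dwnet2")
  expect_equal(cfg2$output_kind, "binary")
  expect_equal(cfg2$num_classes, 1L)

  expect_error(make_variant("unet"), "unknown preset")
  expect_error(network_config(output_kind = "binary", num_classes = 9L),
               "num_classes = 1")
  expect_error(network_config(channel_plan = c(64L, 128L)), "5 entries")
})

test_that("builds are deterministic given the seed", {
  m1 <- build_network(tiny_variant("dwnet", seed = 42L))
  m2 <- build_network(tiny_variant("dwnet", seed = 42L))
  v1 <- lapply(dwnet:::model_params(m1, trainable_only = FALSE), function(p) p$val)
  v2 <- lapply(dwnet:::model_params(m2, trainable_only = FALSE), function(p) p$val)
  expect_identical(v1, v2)
  x <- array(stats::runif(32 * 32), c(32, 32, 1, 1))
  expect_identical(forward(m1, x), forward(m2, x))
  expect_identical(forward(m1, x), forward(m1, x))  # eval-mode determinism
})

test_that("encoder column follows the stride and channel plan", {
  m <- build_network(make_variant("dwnet", seed = 3L))
  x <- array(stats::runif(64 * 64), c(64, 64, 1, 1))
  grid <- encode(m, x)
  dims <- lapply(grid, dim)
  expect_equal(dims[["0,0"]], c(32L, 32L, 1L, 64L))   # stride-2 stem
  expect_equal(dims[["1,0"]], c(16L, 16L, 1L, 64L))
  expect_equal(dims[["2,0"]], c(8L, 8L, 1L, 128L))
  expect_equal(dims[["3,0"]], c(4L, 4L, 1L, 256L))
  expect_equal(dims[["4,0"]], c(2L, 2L, 1L, 512L))
  expect_error(encode(m, array(0, c(48, 64, 1, 1))), "divisible by 32")
  expect_error(encode(m, array(0, c(64, 64, 1, 3))), "channels")
})

test_that("encoder output stays finite on degenerate input", {
  m <- build_network(tiny_variant("dwnet"))
  grid <- encode(m, array(0, c(32, 32, 2, 1)))
  for (g in grid) expect_true(all(is.finite(g)))
})

test_that("decode block projects channels and doubles the spatial extents", {
  child <- array(stats::rnorm(4 * 4 * 256), c(4, 4, 1, 256))
  out <- decode_block(child, 128L)
  expect_equal(dim(out), c(8L, 8L, 1L, 128L))
  out2 <- decode_block(array(stats::rnorm(8 * 8 * 64), c(8, 8, 1, 64)), 64L)
  expect_equal(dim(out2), c(16L, 16L, 1L, 64L))
  # four decode hops from the deepest node plus the head's 2x restore 1/1
  h <- array(stats::rnorm(2 * 2 * 8), c(2, 2, 1, 8))
  for (i in 1:4) h <- decode_block(h, 8L, seed = i)
  expect_equal(dim(h)[1:2] * 2L, c(64L, 64L))
})

test_that("weighted nodes match the naive direct-convolution oracle", {
  m <- build_network(tiny_variant("dwnet", seed = 9L))
  set.seed(4)
  # hand-built 4x4 grid inputs at level 2 (channels 8) and child level 3
  g <- list(
    "2,0" = array(stats::rnorm(4 * 4 * 8), c(4, 4, 1, 8)),
    "2,1" = array(stats::rnorm(4 * 4 * 8), c(4, 4, 1, 8)),
    "3,1" = array(stats::rnorm(2 * 2 * 8), c(2, 2, 1, 8))
  )
  alpha <- m$alphas[["2_2_0"]]

  # all alpha = 1: node (2,2) equals Conv(X20 + X21 + DB(X31)) via naive path
  out <- weighted_node(m, g, 2L, 2L)
  db <- naive_db_eval(m$db[["2,2"]], squeeze1(g[["3,1"]]))
  fused <- squeeze1(g[["2,0"]]) + squeeze1(g[["2,1"]]) + db
  ref <- naive_cbr_eval(m$node[["2,2"]], fused)
  expect_equal(squeeze1(out), ref, tolerance = 1e-10)

  # alpha = 0: the weighted sum term drops out entirely
  alpha$val <- 0
  out0 <- weighted_node(m, g, 2L, 2L)
  ref0 <- naive_cbr_eval(m$node[["2,2"]], squeeze1(g[["2,1"]]) + db)
  expect_equal(squeeze1(out0), ref0, tolerance = 1e-10)

  # doubled alpha scales only the encoder-map contribution
  alpha$val <- 2
  out2 <- weighted_node(m, g, 2L, 2L)
  ref2 <- naive_cbr_eval(m$node[["2,2"]],
                         2 * squeeze1(g[["2,0"]]) + squeeze1(g[["2,1"]]) + db)
  expect_equal(squeeze1(out2), ref2, tolerance = 1e-10)
  alpha$val <- 1
})

test_that("alpha weights feed only their own node", {
  m <- build_network(tiny_variant("dwnet", seed = 2L))
  x <- array(stats::runif(32 * 32), c(32, 32, 1, 1))
  grid <- encode(m, x)
  for (j in 1:4) for (i in 0:(4L - j)) {
    grid[[paste0(i, ",", j)]] <- weighted_node(m, grid, i, j)
  }
  before_04 <- grid[["0,4"]]
  before_13 <- grid[["1,3"]]
  a <- m$alphas[["0_4_0"]]  # the weight indexed (i = 0, 2j + k = 8)
  a$val <- 2
  expect_false(isTRUE(all.equal(weighted_node(m, grid, 0L, 4L), before_04)))
  expect_identical(weighted_node(m, grid, 1L, 3L), before_13)
  a$val <- 1
})

test_that("grid dependencies are causal in the column order", {
  m <- build_network(tiny_variant("dwnet", seed = 2L))
  x <- array(stats::runif(32 * 32), c(32, 32, 1, 1))
  grid <- encode(m, x)
  for (j in 1:4) for (i in 0:(4L - j)) {
    grid[[paste0(i, ",", j)]] <- weighted_node(m, grid, i, j)
  }
  perturbed <- grid
  perturbed[["1,1"]] <- grid[["1,1"]] + 0.5
  # nodes in the same column at deeper levels do not consume (1,1)
  expect_identical(weighted_node(m, perturbed, 2L, 1L), grid[["2,1"]])
  expect_identical(weighted_node(m, perturbed, 3L, 1L), grid[["3,1"]])
  # its own consumers do change
  expect_false(isTRUE(all.equal(weighted_node(m, perturbed, 1L, 2L),
                                grid[["1,2"]])))
  expect_false(isTRUE(all.equal(weighted_node(m, perturbed, 0L, 2L),
                                grid[["0,2"]])))
})

test_that("fusion head normalizes and restores the input resolution", {
  m <- build_network(tiny_variant("dwnet", seed = 5L))
  x <- array(stats::runif(64 * 64 * 2), c(64, 64, 2, 1))
  p <- forward(m, x)
  expect_equal(dim(p), c(64L, 64L, 2L, 9L))
  sums <- apply(p, c(1, 2, 3), sum)
  expect_true(max(abs(sums - 1)) < 1e-5)

  b <- build_network(tiny_variant("dwnet2", seed = 5L))
  pb <- forward(b, x)
  expect_equal(dim(pb), c(64L, 64L, 2L, 1L))
  expect_true(all(pb >= 0 & pb <= 1))
})

test_that("fusion reduces to a single branch when branches coincide", {
  m <- build_network(tiny_variant("dwnet", seed = 6L))
  # make all four heads identical to head 1 and feed identical branch maps
  for (j in 2:4) {
    for (nm in c("c1", "c2")) {
      m$heads[[j]][[nm]]$conv$w$val <- m$heads[[1]][[nm]]$conv$w$val
      m$heads[[j]][[nm]]$conv$b$val <- m$heads[[1]][[nm]]$conv$b$val
      m$heads[[j]][[nm]]$bn$gamma$val <- m$heads[[1]][[nm]]$bn$gamma$val
      m$heads[[j]][[nm]]$bn$beta$val <- m$heads[[1]][[nm]]$bn$beta$val
    }
    m$heads[[j]]$out$w$val <- m$heads[[1]]$out$w$val
    m$heads[[j]]$out$b$val <- m$heads[[1]]$out$b$val
  }
  xb <- array(stats::rnorm(16 * 16 * 4), c(16, 16, 1, 4))
  grid <- list("0,1" = xb, "0,2" = xb, "0,3" = xb, "0,4" = xb)
  fused <- fuse_outputs(m, grid)
  # reference: one branch through head 1, then softmax
  tape <- dwnet:::new_tape()
  branch <- dwnet:::op_upsample2x(dwnet:::tape_leaf(tape, xb))
  branch <- dwnet:::apply_cbr(m$heads[[1]]$c1, branch, tape, FALSE)
  branch <- dwnet:::apply_cbr(m$heads[[1]]$c2, branch, tape, FALSE)
  branch <- dwnet:::apply_conv(m$heads[[1]]$out, branch, tape)
  sm <- dwnet:::op_softmax_channels(branch)
  expect_equal(fused, sm$val, tolerance = 1e-10)
})

test_that("forward equals the explicit composition of the grid operations", {
  for (preset in c("dwnet", "backbone")) {
    m <- build_network(tiny_variant(preset, seed = 8L))
    x <- array(stats::runif(32 * 32 * 2), c(32, 32, 2, 1))
    grid <- encode(m, x)
    for (j in 1:4) for (i in 0:(4L - j)) {
      grid[[paste0(i, ",", j)]] <- weighted_node(m, grid, i, j)
    }
    expect_identical(forward(m, x), fuse_outputs(m, grid))
  }
})

test_that("output extents track any 32-divisible input extents", {
  m <- build_network(tiny_variant("dwnet"))
  for (d in list(c(32L, 32L), c(32L, 64L), c(96L, 32L))) {
    x <- array(stats::runif(prod(d)), c(d, 1L, 1L))
    expect_equal(dim(forward(m, x)), c(d, 1L, 9L))
  }
})

test_that("every preset trains: the compound loss falls on a fixed batch", {
  ph <- phantom_set(4L, size = 32L, seed = 21L)
  xb <- array(unlist(ph$images), c(32, 32, 4, 1))
  steps <- 200L
  for (preset in c("dwnet", "backbone", "res18unetpp", "adaptiveunetpp",
                   "dwnet2")) {
    m <- build_network(tiny_variant(preset, seed = 13L))
    yb <- dwnet:::masks_to_target(ph$masks, 1:4, m$config)
    params <- dwnet:::model_params(m)
    dwnet:::param_zero_grad(params)
    opt <- dwnet:::adam_init(params, lr = 2e-3)
    losses <- numeric(steps)
    for (s in seq_len(steps)) {
      tape <- dwnet:::new_tape()
      res <- dwnet:::run_full_graph(m, dwnet:::tape_leaf(tape, xb), tape, TRUE)
      ls <- dwnet:::op_total_loss(res$prob, yb)
      dwnet:::tape_backward(tape, ls$node)
      dwnet:::adam_step(opt)
      losses[s] <- ls$node$val
    }
    expect_lt(losses[steps], 0.5 * losses[1],
              label = paste0(preset, " final loss"))
  }
})
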