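#' Network configuration for the weighted nested segmentation grid
#'
#' Describes one architecture variant of the dynamic multi-hierarchical
#' weighting segmentation network: the encoder path, how grid nodes fuse
#' their inputs, the alpha-weight policy, the output head, and the channel
#' plan.  [make_variant()] supplies the five named presets.
#'
#' The network is a doubly indexed grid of feature maps \eqn{X^{i,j}}
#' (level \eqn{i} = resolution, column \eqn{j} = depth towards the output),
#' defined where \eqn{i + j \le 4}.  Column 0 is the encoder path; nodes
#' with \eqn{j \ge 1} fuse same-level predecessors with the decoded child
#' node one level below.
#'
#' @param encoder_kind `"plain"` (stacked conv-BN-ReLU stages) or
#'   `"residual"` (basic residual blocks with projection skips).
#' @param connection_kind `"weighted_add"` (alpha-weighted pixel addition)
#'   or `"concat"` (channel concatenation, the nested-UNet baseline).
#' @param alpha_policy `"learnable"`, `"fixed_one"` (weights exist but are
#'   frozen at 1), or `"absent"` (no weights; required for `"concat"`).
#' @param head_kind `"dn_avg"` (per-branch dynamic fusion module: bilinear
#'   upsample + two 1x1 conv-norm-ReLU stages + 1x1 compression) or
#'   `"conv_avg"` (single 1x1 conv per branch, the baseline head).
#' @param output_kind `"multiclass"` (softmax over `num_classes`) or
#'   `"binary"` (sigmoid, forces `num_classes = 1`).
#' @param num_classes number of output classes (default 9: background,
#'   7 retinal-layer classes, CNV).
#' @param input_channels image channels (default 1, grayscale OCT).
#' @param channel_plan integer vector of length 5: channels of the stem
#'   output and the four encoder stages.
#' @param diagonal_tail_channels channels of the last diagonal node
#'   \eqn{X^{0,4}} (default 32).
#' @param use_pretrained_encoder reserved flag; the package always
#'   initializes randomly from `seed` (default `FALSE`).
#' @param seed integer seed controlling parameter initialization.
#' @return A `dw_config` list.
#' @export
network_config <- function(encoder_kind = c("residual", "plain"),
                           connection_kind = c("weighted_add", "concat"),
                           alpha_policy = c("learnable", "fixed_one", "absent"),
                           head_kind = c("dn_avg", "conv_avg"),
                           output_kind = c("multiclass", "binary"),
                           num_classes = 9L,
                           input_channels = 1L,
                           channel_plan = c(64L, 64L, 128L, 256L, 512L),
                           diagonal_tail_channels = 32L,
                           use_pretrained_encoder = FALSE,
                           seed = 1L) {
  encoder_kind <- match.arg(encoder_kind)
  connection_kind <- match.arg(connection_kind)
  alpha_policy <- match.arg(alpha_policy)
  head_kind <- match.arg(head_kind)
  output_kind <- match.arg(output_kind)
  if (length(channel_plan) != 5L) {
    stop("channel_plan must have exactly 5 entries (stem + 4 encoder stages)")
  }
  if (output_kind == "binary" && num_classes != 1L) {
    stop("binary output requires num_classes = 1")
  }
  if (connection_kind == "concat" && alpha_policy != "absent") {
    stop("concat connections carry no alpha weights (alpha_policy must be 'absent')")
  }
  structure(list(
    encoder_kind = encoder_kind,
    connection_kind = connection_kind,
    alpha_policy = alpha_policy,
    head_kind = head_kind,
    output_kind = output_kind,
    num_classes = as.integer(num_classes),
    input_channels = as.integer(input_channels),
    channel_plan = as.integer(channel_plan),
    diagonal_tail_channels = as.integer(diagonal_tail_channels),
    use_pretrained_encoder = isTRUE(use_pretrained_encoder),
    alpha_init = 1.0,
    seed = as.integer(seed)
  ), class = "dw_config")
}

#' Named architecture presets
#'
#' @param name one of `"dwnet"` (residual encoder, learnable alpha-weighted
#'   addition, dynamic fusion head), `"backbone"` (plain encoder,
#'   concatenation, 1x1-conv head: the nested-UNet baseline),
#'   `"res18unetpp"` (residual encoder, pixel addition with alpha frozen
#'   at 1, 1x1-conv head), `"adaptiveunetpp"` (plain encoder, learnable
#'   alpha-weighted addition, 1x1-conv head), or `"dwnet2"` (dwnet with a
#'   single sigmoid output channel for lesion-only segmentation).
#' @param ... overrides passed on to [network_config()] (e.g. `seed`,
#'   `channel_plan`, `input_channels`).
#' @return A `dw_config`.
#' @export
make_variant <- function(name, ...) {
  presets <- list(
    dwnet = list(encoder_kind = "residual", connection_kind = "weighted_add",
                 alpha_policy = "learnable", head_kind = "dn_avg",
                 output_kind = "multiclass"),
    backbone = list(encoder_kind = "plain", connection_kind = "concat",
                    alpha_policy = "absent", head_kind = "conv_avg",
                    output_kind = "multiclass"),
    res18unetpp = list(encoder_kind = "residual", connection_kind = "weighted_add",
                       alpha_policy = "fixed_one", head_kind = "conv_avg",
                       output_kind = "multiclass"),
    adaptiveunetpp = list(encoder_kind = "plain", connection_kind = "weighted_add",
                          alpha_policy = "learnable", head_kind = "conv_avg",
                          output_kind = "multiclass"),
    dwnet2 = list(encoder_kind = "residual", connection_kind = "weighted_add",
                  alpha_policy = "learnable", head_kind = "dn_avg",
                  output_kind = "binary", num_classes = 1L)
  )
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; choose one of: ",
         paste(names(presets), collapse = ", "))
  }
  args <- utils::modifyList(presets[[name]], list(...))
  do.call(network_config, args)
}

# output channels of grid node (i, j)
ch_of <- function(config, i, j) {
  if (i == 0L && j == 4L) config$diagonal_tail_channels
  else config$channel_plan[i + 1L]
}

grid_key <- function(i, j) paste0(i, ",", j)

# enumerate the alpha-weight index triples (level i, target column j,
# source column k): i in 0..2, j in 2..4-i, k in 0..j-2
alpha_triples <- function() {
  out <- list()
  for (i in 0:2) for (j in 2:(4 - i)) for (k in 0:(j - 2)) {
    out[[length(out) + 1L]] <- c(i = i, j = j, k = k)
  }
  as.data.frame(do.call(rbind, out))
}

alpha_key <- function(i, j, k) paste(i, j, k, sep = "_")

#' Build a segmentation model from a configuration
#'
#' Instantiates all parameters of the grid (stem, four encoder stages,
#' decode blocks, node convolutions, alpha weights where the policy calls
#' for them, and the four output heads).  Initialization is He-normal and
#' fully determined by `config$seed`.
#'
#' @param config a `dw_config`, e.g. from [make_variant()].
#' @return A `dw_model` (mutable; parameters update in place when trained).
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "dw_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)

  plan <- config$channel_plan
  stem <- layer_cbr(3L, config$input_channels, plan[1], stride = 2L)
  enc <- vector("list", 4L)
  for (i in 1:4) {
    enc[[i]] <- if (config$encoder_kind == "residual") {
      layer_res_stage(plan[i], plan[i + 1])
    } else {
      layer_plain_stage(plan[i], plan[i + 1])
    }
  }

  db <- list()
  node <- list()
  for (j in 1:4) {
    for (i in 0:(4L - j)) {
      key <- grid_key(i, j)
      db[[key]] <- layer_db(ch_of(config, i + 1L, j - 1L), plan[i + 1])
      in_ch <- if (config$connection_kind == "concat") {
        (j + 1L) * plan[i + 1]
      } else {
        plan[i + 1]
      }
      node[[key]] <- layer_cbr(3L, in_ch, ch_of(config, i, j))
    }
  }

  alphas <- NULL
  if (config$alpha_policy != "absent") {
    tri <- alpha_triples()
    alphas <- list()
    for (r in seq_len(nrow(tri))) {
      alphas[[alpha_key(tri$i[r], tri$j[r], tri$k[r])]] <-
        nn_param(config$alpha_init)
    }
  }

  heads <- vector("list", 4L)
  tail_ch <- config$diagonal_tail_channels
  for (j in 1:4) {
    hc <- ch_of(config, 0L, j)
    heads[[j]] <- if (config$head_kind == "dn_avg") {
      list(c1 = layer_cbr(1L, hc, tail_ch),
           c2 = layer_cbr(1L, tail_ch, tail_ch),
           out = layer_conv(1L, tail_ch, config$num_classes))
    } else {
      list(out = layer_conv(1L, hc, config$num_classes))
    }
  }

  model <- list(config = config, stem = stem, enc = enc, db = db,
                node = node, alphas = alphas, heads = heads)
  class(model) <- "dw_model"
  model
}

#' @export
print.dw_model <- function(x, ...) {
  cfg <- x$config
  np <- sum(vapply(model_params(x, trainable_only = FALSE),
                   function(p) length(p$val), numeric(1)))
  cat("<dw_model> ", cfg$encoder_kind, "/", cfg$connection_kind, "/",
      cfg$alpha_policy, "/", cfg$head_kind, "/", cfg$output_kind,
      " | classes: ", cfg$num_classes,
      " | parameters: ", format(np, big.mark = ","), "\n", sep = "")
  invisible(x)
}

# all nn_param objects of the model; trainable_only drops frozen alphas
model_params <- function(model, trainable_only = TRUE) {
  ps <- c(collect_params(model$stem), collect_params(model$enc),
          collect_params(model$db), collect_params(model$node),
          collect_params(model$heads))
  if (!is.null(model$alphas) &&
      (!trainable_only || model$config$alpha_policy == "learnable")) {
    ps <- c(ps, unname(model$alphas))
  }
  ps
}

#' Number of learnable alpha fusion weights in a model
#'
#' @param model a `dw_model`.
#' @return Integer count (0 when the policy is `fixed_one` or `absent`).
#' @export
n_learnable_alphas <- function(model) {
  if (is.null(model$alphas) || model$config$alpha_policy != "learnable") 0L
  else length(model$alphas)
}

# ---- graph runner ----------------------------------------------------------

check_input_extents <- function(model, x) {
  d <- dim(x)
  if (d[4] != model$config$input_channels) {
    stop("input has ", d[4], " channels; config expects ",
         model$config$input_channels)
  }
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L) {
    stop("input height and width must be divisible by 32 (got ",
         d[1], "x", d[2], ")")
  }
  invisible(d)
}

run_encoder_nodes <- function(model, x, tape, training) {
  grid <- list()
  h <- apply_cbr(model$stem, x, tape, training)
  grid[[grid_key(0L, 0L)]] <- h
  for (i in 1:4) {
    fn <- if (model$config$encoder_kind == "residual") apply_res_stage else apply_plain_stage
    h <- fn(model$enc[[i]], h, tape, training)
    grid[[grid_key(i, 0L)]] <- h
  }
  grid
}

run_grid_node <- function(model, grid, i, j, tape, training) {
  key <- grid_key(i, j)
  child <- grid[[grid_key(i + 1L, j - 1L)]]
  if (is.null(child)) stop("grid node (", i + 1L, ",", j - 1L, ") missing")
  up <- apply_db(model$db[[key]], child, tape)
  if (model$config$connection_kind == "concat") {
    parts <- lapply(0:(j - 1L), function(k) grid[[grid_key(i, k)]])
    fused <- op_concat_channels(c(parts, list(up)))
  } else if (j == 1L) {
    fused <- op_add(grid[[grid_key(i, 0L)]], up)
  } else {
    parts <- list()
    for (k in 0:(j - 2L)) {
      xk <- grid[[grid_key(i, k)]]
      parts[[length(parts) + 1L]] <- if (!is.null(model$alphas)) {
        op_scale(xk, tape_param(tape, model$alphas[[alpha_key(i, j, k)]]))
      } else {
        xk
      }
    }
    parts[[length(parts) + 1L]] <- grid[[grid_key(i, j - 1L)]]
    parts[[length(parts) + 1L]] <- up
    fused <- op_add_list(parts)
  }
  apply_cbr(model$node[[key]], fused, tape, training)
}

run_fusion_head <- function(model, grid, tape, training) {
  branches <- vector("list", 4L)
  for (j in 1:4) {
    x <- grid[[grid_key(0L, j)]]
    if (is.null(x)) stop("grid node (0,", j, ") missing")
    hd <- model$heads[[j]]
    branches[[j]] <- if (model$config$head_kind == "dn_avg") {
      h <- op_upsample2x(x)
      h <- apply_cbr(hd$c1, h, tape, training)
      h <- apply_cbr(hd$c2, h, tape, training)
      apply_conv(hd$out, h, tape)
    } else {
      op_upsample2x(apply_conv(hd$out, x, tape))
    }
  }
  avg <- op_scale_const(op_add_list(branches), 0.25)
  if (model$config$output_kind == "binary") op_sigmoid(avg)
  else op_softmax_channels(avg)
}

# full forward on one tape; returns all nodes for training / inspection
run_full_graph <- function(model, x, tape, training) {
  grid <- run_encoder_nodes(model, x, tape, training)
  for (j in 1:4) {
    for (i in 0:(4L - j)) {
      grid[[grid_key(i, j)]] <- run_grid_node(model, grid, i, j, tape, training)
    }
  }
  prob <- run_fusion_head(model, grid, tape, training)
  list(grid = grid, prob = prob)
}

# ---- public functional surface (eval mode, arrays in / arrays out) ---------

wrap_grid <- function(tape, grid_arrays) {
  lapply(grid_arrays, function(a) tape_leaf(tape, a))
}

#' Run the encoder column
#'
#' Applies the stem convolution and the four encoder stages, producing grid
#' column 0: \eqn{X^{0,0} \ldots X^{4,0}} at 1/2 ... 1/32 of the input
#' resolution with the configured channel plan.  Runs in inference mode
#' (frozen normalization statistics).
#'
#' @param model a `dw_model`.
#' @param images array `H x W x N x C` (or a matrix / `H x W x N` array,
#'   promoted to single-channel); `H`, `W` divisible by 32.
#' @return Named list of feature arrays keyed `"0,0" ... "4,0"`.
#' @export
encode <- function(model, images) {
  images <- as_feature_array(images)
  check_input_extents(model, images)
  tape <- new_tape()
  grid <- run_encoder_nodes(model, tape_leaf(tape, images), tape, training = FALSE)
  lapply(grid, function(nd) nd$val)
}

#' Apply one decode block
#'
#' The decode block of the grid: a 3x3 convolution projecting the child's
#' channels to `target_channels`, followed by bilinear 2x upsampling.  A
#' freshly initialized block (seeded) is applied; inside a model each node
#' owns its block's parameters.
#'
#' @param child feature array `H x W x N x C`.
#' @param target_channels output channels.
#' @param seed initialization seed.
#' @return Feature array `2H x 2W x N x target_channels`.
#' @export
decode_block <- function(child, target_channels, seed = 1L) {
  child <- as_feature_array(child)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  layer <- layer_db(dim(child)[4], as.integer(target_channels))
  tape <- new_tape()
  apply_db(layer, tape_leaf(tape, child), tape)$val
}

#' Compute one interior grid node
#'
#' For column `j = 1` the node is `Conv(X[i,0] + DB(X[i+1,0]))`; for
#' `j >= 2` it is the alpha-weighted fusion
#' `Conv(sum_k alpha[i,2j+k] * X[i,k] + X[i,j-1] + DB(X[i+1,j-1]))`
#' (with channel concatenation replacing the additions when the model's
#' `connection_kind` is `"concat"`).  Runs in inference mode.
#'
#' @param model a `dw_model`.
#' @param grid named list of feature arrays containing at least
#'   `X[i,0..j-1]` and `X[i+1,j-1]` (keys as produced by [encode()]).
#' @param i grid level (0-based).
#' @param j grid column (>= 1).
#' @return Feature array of the node's output.
#' @export
weighted_node <- function(model, grid, i, j) {
  stopifnot(j >= 1L, i >= 0L, i + j <= 4L)
  tape <- new_tape()
  nodes <- wrap_grid(tape, grid)
  run_grid_node(model, nodes, i, j, tape, training = FALSE)$val
}

#' Fuse the four output branches into a probability map
#'
#' Each top-level node `X[0,1..4]` passes through its head (dynamic fusion
#' module or plain 1x1 conv, restoring the input resolution), the four
#' results are pixel-averaged, and softmax (multiclass) or sigmoid (binary)
#' maps them to probabilities.
#'
#' @param model a `dw_model`.
#' @param grid named list with feature arrays `"0,1" ... "0,4"`.
#' @return Probability array `H x W x N x num_classes`.
#' @export
fuse_outputs <- function(model, grid) {
  tape <- new_tape()
  nodes <- wrap_grid(tape, grid)
  run_fusion_head(model, nodes, tape, training = FALSE)$val
}

#' Full forward pass
#'
#' Composes [encode()], all interior grid nodes in column-major order, and
#' [fuse_outputs()].  Deterministic in inference mode.
#'
#' @param model a `dw_model`.
#' @param images input array (see [encode()]).
#' @return Probability array `H x W x N x num_classes` at the input
#'   resolution.
#' @export
forward <- function(model, images) {
  images <- as_feature_array(images)
  check_input_extents(model, images)
  tape <- new_tape()
  res <- run_full_graph(model, tape_leaf(tape, images), tape, training = FALSE)
  res$prob$val
}

#' Snapshot of the alpha fusion weights
#'
#' Returns the current values of the ten scalar fusion weights, keyed by
#' level `i` and the flattened index `2j + k` used when logging their
#' trajectory across training epochs.
#'
#' @param model a `dw_model` whose `alpha_policy` is not `"absent"`.
#' @return `data.frame` with columns `i`, `j`, `k`, `index` (`= 2j + k`),
#'   `value`, and a `trainable` attribute.
#' @export
alpha_snapshot <- function(model) {
  if (is.null(model$alphas)) {
    stop("this variant has no alpha weights (alpha_policy = 'absent')")
  }
  tri <- alpha_triples()
  tri$index <- 2L * tri$j + tri$k
  tri$value <- vapply(seq_len(nrow(tri)), function(r) {
    as.numeric(model$alphas[[alpha_key(tri$i[r], tri$j[r], tri$k[r])]]$val)
  }, numeric(1))
  attr(tri, "trainable") <- model$config$alpha_policy == "learnable"
  tri
}
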