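# Data loading, preprocessing, volume-grouped cross-validation, training,
# prediction and experiment orchestration.

#' Training configuration
#'
#' Defaults follow the reference training protocol: Adam with learning
#' rate 1e-4, batch size 4, 100 epochs, inputs resized to 512 x 512.
#' Scaled-down runs (tests, examples) override `target_size`,
#' `learning_rate` and `max_steps`.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size slices per optimizer step.
#' @param epochs passes over the training set.
#' @param optimizer only `"adam"` is provided.
#' @param target_size square resize target in pixels (divisible by 32), or
#'   `NULL` to keep native extents.
#' @param seed seed for batch shuffling (model init uses the model's own
#'   config seed).
#' @param max_steps optional cap on total optimizer steps (overrides
#'   `epochs` when reached first).
#' @param smooth Dice smoothing constant.
#' @return A `dw_train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 4L,
                         epochs = 100L, optimizer = "adam",
                         target_size = 512L, seed = 1L,
                         max_steps = NULL, smooth = 1e-5) {
  stopifnot(learning_rate > 0, batch_size >= 1L,
            identical(optimizer, "adam"))
  if (!is.null(target_size) && target_size %% 32L != 0L) {
    stop("target_size must be divisible by 32")
  }
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), optimizer = optimizer,
                 target_size = if (is.null(target_size)) NULL else as.integer(target_size),
                 seed = as.integer(seed),
                 max_steps = if (is.null(max_steps)) NULL else as.integer(max_steps),
                 smooth = smooth),
            class = "dw_train_config")
}

#' Load one image/mask pair
#'
#' @param image_path grayscale (or RGB, converted by luma weights) PNG.
#' @param mask_path single-channel indexed PNG with labels
#'   `0 .. max_label`.
#' @param max_label largest admissible label (default 8).
#' @return List `image` (numeric matrix in `[0, 1]`) and `mask` (integer
#'   matrix); extents are checked to match.
#' @export
load_pair <- function(image_path, mask_path, max_label = 8L) {
  img <- png::readPNG(image_path)
  if (length(dim(img)) == 3L) {
    img <- if (dim(img)[3] >= 3L) {
      0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    } else {
      img[, , 1]
    }
  }
  msk <- png::readPNG(mask_path)
  if (length(dim(msk)) == 3L) msk <- msk[, , 1]
  msk <- matrix(as.integer(round(msk * 255)), nrow(msk), ncol(msk))
  if (any(msk < 0L | msk > max_label)) {
    stop("mask '", mask_path, "' contains labels outside 0..", max_label)
  }
  if (!identical(dim(img), dim(msk))) {
    stop("image and mask extents differ for '", image_path, "'")
  }
  list(image = img, mask = msk)
}

#' Resize an image/mask pair to a square target
#'
#' The image is resized by bilinear interpolation, the mask by
#' nearest-neighbour so that no new labels are invented.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param mask integer label matrix of the same extents.
#' @param target_size square output size (divisible by 32).
#' @return List `image`, `mask` of extents `target_size x target_size`.
#' @export
resize_pair <- function(image, mask, target_size = 512L) {
  if (target_size %% 32L != 0L) stop("target_size must be divisible by 32")
  if (all(dim(image) == target_size) && all(dim(mask) == target_size)) {
    return(list(image = image, mask = mask))
  }
  img <- EBImage::resize(image, w = target_size, h = target_size,
                         filter = "bilinear")
  msk <- EBImage::resize(mask, w = target_size, h = target_size,
                         filter = "none")
  list(image = matrix(as.numeric(img), target_size, target_size),
       mask = matrix(as.integer(round(msk)), target_size, target_size))
}

#' Read a dataset manifest
#'
#' @param data_dir directory containing `manifest.csv` as written by
#'   [generate_dataset()] (paths relative to the directory).
#' @return data.frame with columns `image_path`, `mask_path`,
#'   `volume_id`, `has_cnv`, paths resolved against `data_dir`.
#' @export
read_manifest <- function(data_dir) {
  path <- file.path(data_dir, "manifest.csv")
  if (!file.exists(path)) stop("no manifest.csv under '", data_dir, "'")
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  man$image_path <- file.path(data_dir, man$image_path)
  man$mask_path <- file.path(data_dir, man$mask_path)
  ok <- file.exists(man$image_path) & file.exists(man$mask_path)
  if (!all(ok)) stop("missing files referenced by the manifest")
  man
}

#' Volume-grouped fold assignment
#'
#' Assigns whole volumes to `n_folds` groups with slice counts as balanced
#' as possible: volumes are sorted by slice count (descending, ties broken
#' by a seeded shuffle) and each is given to the currently lightest fold.
#' No volume is ever split across folds.
#'
#' @param manifest manifest data.frame (see [read_manifest()]).
#' @param n_folds number of folds (default 4).
#' @param seed tie-break seed.
#' @return A `dw_split_plan`: list with `fold_assignment` (named integer
#'   vector, volume id -> fold in `0 .. n_folds-1`), `fold_slices`
#'   (slice counts per fold), `n_folds`.
#' @export
make_folds <- function(manifest, n_folds = 4L, seed = 1L) {
  counts <- table(manifest$volume_id)
  if (length(counts) < n_folds) {
    stop("need at least ", n_folds, " volumes for ", n_folds, " folds")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  ord <- order(-as.integer(counts), stats::runif(length(counts)))
  load <- integer(n_folds)
  assignment <- integer(length(counts))
  names(assignment) <- names(counts)
  for (v in ord) {
    f <- which.min(load)
    assignment[v] <- f - 1L
    load[f] <- load[f] + as.integer(counts[v])
  }
  structure(list(fold_assignment = assignment, fold_slices = load,
                 n_folds = as.integer(n_folds)),
            class = "dw_split_plan")
}

# load all pairs of a manifest into memory, optionally resized
load_dataset <- function(manifest, target_size = NULL) {
  images <- vector("list", nrow(manifest))
  masks <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    pr <- load_pair(manifest$image_path[i], manifest$mask_path[i])
    if (!is.null(target_size)) pr <- resize_pair(pr$image, pr$mask, target_size)
    images[[i]] <- pr$image
    masks[[i]] <- pr$mask
  }
  list(images = images, masks = masks)
}

# masks -> target array for the model's output kind; binary collapses to
# lesion-vs-rest
masks_to_target <- function(masks, idx, config, cnv_class = 8L) {
  if (config$output_kind == "binary") {
    arrs <- lapply(idx, function(i) (masks[[i]] == cnv_class) * 1)
    a <- array(unlist(arrs), c(dim(masks[[idx[1]]]), length(idx), 1L))
    a
  } else {
    m <- array(unlist(masks[idx]), c(dim(masks[[idx[1]]]), length(idx)))
    one_hot(m, config$num_classes)
  }
}

images_to_batch <- function(images, idx) {
  array(unlist(images[idx]), c(dim(images[[idx[1]]]), length(idx), 1L))
}

# snapshot / restore all parameter values (used for best-epoch checkpoints)
param_values <- function(model) {
  lapply(model_params(model, trainable_only = FALSE), function(p) p$val)
}

set_param_values <- function(model, values) {
  ps <- model_params(model, trainable_only = FALSE)
  stopifnot(length(ps) == length(values))
  for (i in seq_along(ps)) ps[[i]]$val <- values[[i]]
  invisible(model)
}

collect_bn_states <- function(x) {
  out <- list()
  if (is.list(x)) {
    if (identical(x$type, "bn")) out <- c(out, list(x$state))
    for (el in x) if (is.list(el)) out <- c(out, collect_bn_states(el))
  }
  out
}

model_bn_states <- function(model) {
  c(collect_bn_states(model$stem), collect_bn_states(model$enc),
    collect_bn_states(model$db), collect_bn_states(model$node),
    collect_bn_states(model$heads))
}

bn_values <- function(model) {
  lapply(model_bn_states(model), function(s) list(rmean = s$rmean, rvar = s$rvar))
}

set_bn_values <- function(model, values) {
  sts <- model_bn_states(model)
  stopifnot(length(sts) == length(values))
  for (i in seq_along(sts)) {
    sts[[i]]$rmean <- values[[i]]$rmean
    sts[[i]]$rvar <- values[[i]]$rvar
  }
  invisible(model)
}

#' Train a model on in-memory slices
#'
#' Runs Adam on the compound Dice + cross-entropy loss of the fused
#' output.  Logs per-epoch mean losses and (for variants with learnable
#' weights) the alpha trajectory, evaluates validation macro foreground
#' DSC each epoch when validation data are supplied, and keeps the
#' parameters of the best validation epoch.
#'
#' @param model a `dw_model` (updated in place).
#' @param images list of `H x W` matrices in `[0, 1]`.
#' @param masks list of integer label matrices.
#' @param cfg a `dw_train_config`.
#' @param val_images,val_masks optional validation slices.
#' @return List: the `model` (best-epoch parameters restored when
#'   validation was used), `history` (data.frame epoch/total/ce/dice/
#'   val_dsc), `alpha_history` (data.frame, long form, or `NULL`),
#'   `best_val_dsc`.
#' @export
train_model <- function(model, images, masks, cfg = train_config(),
                        val_images = NULL, val_masks = NULL) {
  stopifnot(length(images) == length(masks), length(images) >= 1L)
  n <- length(images)
  params <- model_params(model, trainable_only = TRUE)
  param_zero_grad(params)
  opt <- adam_init(params, lr = cfg$learning_rate)
  has_val <- !is.null(val_images) && length(val_images) > 0L
  include_bg <- TRUE

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(cfg$seed)

  history <- list()
  alpha_hist <- list()
  best <- list(dsc = -Inf, params = NULL, bn = NULL, epoch = NA_integer_)
  step <- 0L
  done <- FALSE
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_tot <- ep_ce <- ep_dice <- 0
    nb <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      xb <- images_to_batch(images, idx)
      yb <- masks_to_target(masks, idx, model$config)
      tape <- new_tape()
      res <- run_full_graph(model, tape_leaf(tape, xb), tape, training = TRUE)
      ls <- op_total_loss(res$prob, yb, smooth = cfg$smooth,
                          include_background = include_bg)
      tape_backward(tape, ls$node)
      adam_step(opt)
      ep_tot <- ep_tot + ls$node$val; ep_ce <- ep_ce + ls$ce
      ep_dice <- ep_dice + ls$dice; nb <- nb + 1L
      step <- step + 1L
      if (!is.null(cfg$max_steps) && step >= cfg$max_steps) { done <- TRUE; break }
    }
    val_dsc <- NA_real_
    if (has_val) {
      pred <- predict_masks(model, val_images, batch_size = cfg$batch_size)
      val_dsc <- macro_foreground_dsc(pred, val_masks, model$config)
      if (val_dsc > best$dsc) {
        best <- list(dsc = val_dsc, params = param_values(model),
                     bn = bn_values(model), epoch = epoch)
      }
    }
    history[[epoch]] <- data.frame(epoch = epoch, steps = step,
                                   total = ep_tot / nb, ce = ep_ce / nb,
                                   dice = ep_dice / nb, val_dsc = val_dsc)
    if (!is.null(model$alphas)) {
      snap <- alpha_snapshot(model)
      snap$epoch <- epoch
      alpha_hist[[epoch]] <- snap
    }
    if (done) break
  }
  if (has_val && !is.null(best$params)) {
    set_param_values(model, best$params)
    set_bn_values(model, best$bn)
  }
  list(model = model,
       history = do.call(rbind, history),
       alpha_history = if (length(alpha_hist)) do.call(rbind, alpha_hist) else NULL,
       best_val_dsc = if (has_val) best$dsc else NA_real_)
}

# macro DSC over foreground classes of a predicted/gold mask list
macro_foreground_dsc <- function(pred_list, gt_list, config) {
  if (config$output_kind == "binary") {
    gt <- lapply(gt_list, function(m) (m == 8L) * 1L)
    rep <- metric_report(pred_list, gt, num_classes = 2L, cnv_class = 1L)
    unname(rep$per_class$DSC[2])
  } else {
    rep <- metric_report(pred_list, gt_list, num_classes = config$num_classes)
    unname(rep$macro["DSC"])
  }
}

#' Predict label masks
#'
#' Argmax of the fused probability map for multiclass models; 0.5
#' thresholding of the sigmoid map for binary models.
#'
#' @param model a `dw_model`.
#' @param images list of `H x W` matrices in `[0, 1]`.
#' @param batch_size slices per forward pass.
#' @param return_probs also return the per-slice probability arrays.
#' @return List of integer label matrices (with `probs` attribute when
#'   requested).
#' @export
predict_masks <- function(model, images, batch_size = 4L,
                          return_probs = FALSE) {
  n <- length(images)
  out <- vector("list", n)
  probs <- if (return_probs) vector("list", n) else NULL
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    xb <- images_to_batch(images, idx)
    pr <- forward(model, xb)
    d <- dim(pr)
    for (b in seq_along(idx)) {
      p <- pr[, , b, , drop = FALSE]
      if (model$config$output_kind == "binary") {
        lab <- matrix(as.integer(p[, , 1, 1] > 0.5), d[1], d[2])
      } else {
        m <- matrix(p, d[1] * d[2], d[4])
        lab <- matrix(max.col(m, ties.method = "first") - 1L, d[1], d[2])
      }
      out[[idx[b]]] <- lab
      if (return_probs) probs[[idx[b]]] <- array(p, c(d[1], d[2], d[4]))
    }
  }
  if (return_probs) attr(out, "probs") <- probs
  out
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single file holding the full configuration, every
#' parameter value, the normalization running statistics and any training
#' history passed along; loading rebuilds the network and restores all
#' values bit-exactly.
#'
#' @param model a `dw_model`.
#' @param path file path.
#' @param history optional list stored alongside (e.g. the result of
#'   [train_model()] minus the model).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a list `model`, `history`.
#' @export
save_checkpoint <- function(model, path, history = NULL) {
  saveRDS(list(config = model$config,
               params = param_values(model),
               bn = bn_values(model),
               history = history), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  st <- readRDS(path)
  model <- build_network(st$config)
  set_param_values(model, st$params)
  set_bn_values(model, st$bn)
  list(model = model, history = st$history)
}

#' Run a cross-validated segmentation experiment
#'
#' Loads a phantom dataset, assigns volumes to folds, and for each fold
#' trains the requested variant on the remaining folds, predicts the
#' held-out fold, computes the per-class metric report and the per-volume
#' CNV volumes.  Writes `metrics_per_fold.csv`, `summary.csv`,
#' `cnv_volumes.csv` and a resolved-config snapshot under `out_dir`.
#'
#' @param data_dir dataset directory with a `manifest.csv`.
#' @param preset variant name for [make_variant()].
#' @param cfg a `dw_train_config`.
#' @param out_dir output directory (created; default a fresh tempdir).
#' @param n_folds number of folds (default 4).
#' @param folds which folds to run (default all).
#' @param preset_args extra arguments to [make_variant()] (e.g. a reduced
#'   `channel_plan`).
#' @param voxel_dims voxel dimensions for volumetry (mm).
#' @return List with `fold_reports`, `summary`, `volumes`, `split`,
#'   `histories`, `out_dir`.
#' @export
run_experiment <- function(data_dir, preset = "dwnet", cfg = train_config(),
                           out_dir = tempfile("dwnet_run"), n_folds = 4L,
                           folds = NULL,
                           preset_args = list(),
                           voxel_dims = c(6 / 512, 2 / 1024, 6 / 128)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- read_manifest(data_dir)
  data <- load_dataset(manifest, target_size = cfg$target_size)
  split <- make_folds(manifest, n_folds = n_folds, seed = cfg$seed)
  fold_of_slice <- split$fold_assignment[manifest$volume_id]
  if (is.null(folds)) folds <- 0:(n_folds - 1L)

  fold_reports <- list()
  histories <- list()
  vol_rows <- list()
  per_fold_rows <- list()
  for (f in folds) {
    tr_idx <- which(fold_of_slice != f)
    te_idx <- which(fold_of_slice == f)
    if (length(tr_idx) == 0L) stop("empty training fold")
    config <- do.call(make_variant,
                      c(list(name = preset, seed = cfg$seed + f), preset_args))
    model <- build_network(config)
    fit <- train_model(model, data$images[tr_idx], data$masks[tr_idx], cfg,
                       val_images = data$images[te_idx],
                       val_masks = data$masks[te_idx])
    pred <- predict_masks(fit$model, data$images[te_idx],
                          batch_size = cfg$batch_size)
    gt <- data$masks[te_idx]
    if (config$output_kind == "binary") {
      gt <- lapply(gt, function(m) (m == 8L) * 1L)
      rep <- metric_report(pred, gt, num_classes = 2L, cnv_class = 1L)
      cnv_id <- 1L
    } else {
      rep <- metric_report(pred, gt, num_classes = config$num_classes)
      cnv_id <- config$num_classes - 1L
    }
    fold_reports[[as.character(f)]] <- rep
    histories[[as.character(f)]] <- fit$history
    pc <- rep$per_class
    pc$fold <- f
    per_fold_rows[[as.character(f)]] <- pc
    for (vid in unique(manifest$volume_id[te_idx])) {
      sl <- which(manifest$volume_id[te_idx] == vid)
      vol_rows[[length(vol_rows) + 1L]] <- data.frame(
        volume_id = vid, fold = f,
        gt_mm3 = cnv_volume(gt[sl], voxel_dims, cnv_class = cnv_id),
        pred_mm3 = cnv_volume(pred[sl], voxel_dims, cnv_class = cnv_id))
    }
  }
  summary <- if (length(fold_reports) >= 2L) {
    aggregate_folds(fold_reports, which = "macro")
  } else {
    r <- fold_reports[[1]]
    data.frame(metric = names(r$macro), mean = as.numeric(r$macro), sd = NA_real_)
  }
  volumes <- do.call(rbind, vol_rows)
  per_fold <- do.call(rbind, per_fold_rows)
  utils::write.csv(per_fold, file.path(out_dir, "metrics_per_fold.csv"),
                   row.names = FALSE)
  utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(volumes, file.path(out_dir, "cnv_volumes.csv"),
                   row.names = FALSE)
  snapshot <- c(list(preset = preset, n_folds = n_folds), unclass(cfg))
  writeLines(paste0(names(snapshot), ": ",
                    vapply(snapshot, function(v) paste(format(v), collapse = " "),
                           character(1))),
             file.path(out_dir, "run_config.txt"))
  list(fold_reports = fold_reports, summary = summary, volumes = volumes,
       split = split, histories = histories, out_dir = out_dir)
}
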