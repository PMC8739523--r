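# Shared fixtures: reduced-width model configurations and in-memory
# phantom batches.  Everything is generated in code under fixed seeds.

tiny_plan <- c(4L, 4L, 8L, 8L, 8L)

tiny_variant <- function(name, seed = 1L, ...) {
  make_variant(name, channel_plan = tiny_plan, diagonal_tail_channels = 4L,
               seed = seed, ...)
}

# the 1/8-width plan used for scaled-down training runs
small_plan <- c(8L, 8L, 16L, 32L, 64L)

# in-memory phantom slices: list(images, masks), images in [0, 1]
phantom_set <- function(n, size = 32L, seed = 1L, cnv_probability = 1) {
  cfg <- phantom_config(width = size, height = size,
                        cnv_probability = cnv_probability)
  withr::with_seed(seed, {
    images <- vector("list", n)
    masks <- vector("list", n)
    for (i in seq_len(n)) {
      s <- phantom_sample(cfg)
      images[[i]] <- s$image / 255
      masks[[i]] <- s$mask
    }
    list(images = images, masks = masks)
  })
}

# a phantom dataset written to disk; regenerated per call
phantom_dataset_dir <- function(n_volumes = 4L, slices = c(4L, 4L),
                                size = 32L, seed = 5L) {
  dir <- tempfile("phantoms")
  cfg <- phantom_config(width = size, height = size, seed = seed)
  generate_dataset(cfg, n_volumes = n_volumes, slices_per_volume = slices,
                   out_dir = dir, seed = seed)
  dir
}
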