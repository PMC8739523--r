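test_that("boundary sampling is deterministic, ordered and within ranges", {
  cfg <- phantom_config(width = 64L, height = 128L)
  b1 <- withr::with_seed(10, sample_boundaries(cfg))
  b2 <- withr::with_seed(10, sample_boundaries(cfg))
  expect_identical(b1, b2)

  withr::with_seed(11, {
    for (r in 1:50) {
      b <- sample_boundaries(cfg)
      expect_true(all(diff(b) > 0))        # strict depth order per column
      th <- rowMeans(b[2:8, , drop = FALSE] - b[1:7, , drop = FALSE])
      expect_true(all(th >= cfg$thickness_range[, 1] - 1e-9))
      expect_true(all(th <= cfg$thickness_range[, 2] + 1e-9))
    }
  })
})

test_that("lesion implantation lifts overlying boundaries and respects bounds", {
  cfg <- phantom_config(width = 96L, height = 128L, cnv_probability = 1)
  off <- phantom_config(width = 96L, height = 128L, cnv_probability = 0)

  withr::with_seed(4, {
    b <- sample_boundaries(off)
    res <- implant_cnv(b, off)
    expect_identical(res$boundaries, b)
    expect_false(res$has_cnv)
    expect_false(any(res$lesion))
  })

  withr::with_seed(5, {
    areas <- numeric(50)
    for (r in 1:50) {
      b <- sample_boundaries(cfg)
      res <- implant_cnv(b, cfg)
      expect_true(res$has_cnv)
      # boundaries above the lesion move up, never down
      expect_true(all(res$boundaries[1:7, ] <= b[1:7, ] + 1e-9))
      expect_true(any(res$boundaries[1:7, ] < b[1:7, ] - 0.5))
      expect_identical(res$boundaries[8, ], b[8, ])
      # ordering survives the deformation
      expect_true(all(diff(res$boundaries) > 0))
      # no lesion pixel above the inner limiting membrane
      ilm <- matrix(res$boundaries[1, ], 128, 96, byrow = TRUE)
      rows <- matrix(seq_len(128), 128, 96)
      expect_false(any(res$lesion & rows <= ilm))
      areas[r] <- sum(res$lesion)
    }
    # pixelated circle areas stay near pi r^2 over the radius range
    expect_true(all(areas >= 0.85 * pi * cfg$cnv_radius_range[1]^2))
    expect_true(all(areas <= 1.10 * pi * cfg$cnv_radius_range[2]^2))
  })
})

test_that("rendering paints classes, speckle and the lesion override", {
  cfg <- phantom_config(width = 64L, height = 128L, speckle_strength = 0,
                        cnv_probability = 1)
  withr::with_seed(6, {
    b <- sample_boundaries(cfg)
    res <- implant_cnv(b, cfg)
    out <- render_phantom(res$boundaries, res$lesion, cfg)
    # noise-free image is piecewise constant at the class means
    for (cls in sort(unique(as.vector(out$mask)))) {
      px <- out$image[out$mask == cls]
      expect_true(all(px == round(cfg$intensity_mean[cls + 1])))
    }
    expect_setequal(sort(unique(as.vector(out$mask))), 0:8)
    expect_equal(out$cnv_pixel_count, sum(out$mask == 8L))

    nolesion <- render_phantom(b, NULL, cfg)
    expect_setequal(sort(unique(as.vector(nolesion$mask))), 0:7)
    expect_false(nolesion$has_cnv)
  })

  # with default speckle, pooled per-class mean gray stays near the target
  noisy <- phantom_config(width = 64L, height = 128L, cnv_probability = 1)
  withr::with_seed(7, {
    sums <- numeric(9); counts <- numeric(9)
    for (r in 1:50) {
      s <- phantom_sample(noisy)
      for (cls in 0:8) {
        px <- s$image[s$mask == cls]
        sums[cls + 1] <- sums[cls + 1] + sum(px)
        counts[cls + 1] <- counts[cls + 1] + length(px)
      }
    }
    means <- sums / counts
    expect_true(all(abs(means - noisy$intensity_mean) < 2))
  })
})

test_that("every phantom column is anatomically ordered", {
  cfg <- phantom_config(width = 48L, height = 64L, cnv_probability = 0.7)
  withr::with_seed(8, {
    for (r in 1:25) {
      s <- phantom_sample(cfg)
      for (x in seq_len(ncol(s$mask))) {
        col <- s$mask[, x]
        layers <- col[col %in% 1:7]
        expect_true(all(diff(layers) >= 0))  # nondecreasing depth order
        # lesion only at/below the outer band's neighborhood: never above
        # the first OPSL+RPE-or-deeper pixel minus the lift allowance
        if (any(col == 8L)) {
          first_lesion <- which(col == 8L)[1]
          expect_gt(first_lesion, which(col %in% 1:7)[1])
        }
      }
    }
  })
})

test_that("dataset generation is reproducible and round-trips through the reader", {
  dir1 <- tempfile(); dir2 <- tempfile()
  cfg <- phantom_config(width = 32L, height = 32L)
  man1 <- generate_dataset(cfg, n_volumes = 3L, slices_per_volume = c(2L, 4L),
                           out_dir = dir1, seed = 17L)
  man2 <- generate_dataset(cfg, n_volumes = 3L, slices_per_volume = c(2L, 4L),
                           out_dir = dir2, seed = 17L)
  expect_identical(man1, man2)
  expect_identical(readLines(file.path(dir1, "manifest.csv")),
                   readLines(file.path(dir2, "manifest.csv")))
  expect_equal(nrow(man1), sum(table(man1$volume_id)))

  # masks and images round-trip bit-exactly through the pipeline reader
  loaded <- read_manifest(dir1)
  for (i in seq_len(nrow(loaded))) {
    pr <- load_pair(loaded$image_path[i], loaded$mask_path[i])
    expect_true(all(pr$mask %in% 0:8))
    expect_true(all(pr$image >= 0 & pr$image <= 1))
  }
  # the reader returns exactly what was written
  pr1 <- load_pair(loaded$image_path[1], loaded$mask_path[1])
  s1 <- png::readPNG(file.path(dir1, man1$image_path[1]))
  expect_identical(pr1$image, s1)
})
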