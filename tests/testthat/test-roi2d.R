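# Hand-built monolayer plane: a round CEA-positive islet (cancer-like) and
# a CEA-negative elongated region (fibroblast-like) on black background.
make_monolayer <- function(marker_in = "fibroblast", marker_level = 40) {
  dyx <- c(96, 96)
  dapi <- matrix(0, dyx[1], dyx[2])
  cea <- matrix(0, dyx[1], dyx[2])
  marker <- matrix(0, dyx[1], dyx[2])
  islet <- outer(seq_len(dyx[1]), seq_len(dyx[2]), function(y, x)
    ((y - 30) / 14)^2 + ((x - 30) / 14)^2 <= 1)
  spindle <- outer(seq_len(dyx[1]), seq_len(dyx[2]), function(y, x)
    ((y - 70) / 6)^2 + ((x - 55) / 26)^2 <= 1)
  dapi[islet | spindle] <- 120
  cea[islet] <- 90
  if (marker_in == "fibroblast") marker[spindle] <- marker_level
  else marker[islet] <- marker_level
  vox <- array(0, c(1, dyx, 3))
  vox[1, , , 1] <- dapi; vox[1, , , 2] <- cea; vox[1, , , 3] <- marker
  list(stack = image_stack(vox, c("dapi", "cea", "marker")),
       islet = islet, spindle = spindle)
}

test_that("a CEA-high islet lands in the cancer mask and a CEA-null
           spindle in the fibroblast mask", {
  ml <- make_monolayer()
  rois <- build_rois_2d(ml$stack)
  # compare on the core of each region (smoothing blurs 2-3 px of rim)
  core_islet <- ml$islet &
    outer(seq_len(96), seq_len(96), function(y, x)
      ((y - 30) / 9)^2 + ((x - 30) / 9)^2 <= 1)
  core_spindle <- ml$spindle &
    outer(seq_len(96), seq_len(96), function(y, x)
      ((y - 70) / 3)^2 + ((x - 55) / 18)^2 <= 1)
  expect_true(all(rois$cancer_mask[core_islet]))
  expect_true(all(rois$fibroblast_mask[core_spindle]))
  expect_false(any(rois$cancer_mask & rois$fibroblast_mask))
  expect_true(all(rois$cancer_mask <= rois$cell_mask))
  expect_true(all(rois$fibroblast_mask <= rois$cell_mask))
})

test_that("a zero CEA channel yields an empty cancer mask", {
  ml <- make_monolayer()
  vox <- ml$stack$voxels
  vox[, , , 2] <- 0
  rois <- build_rois_2d(image_stack(vox, ml$stack$channels))
  expect_false(any(rois$cancer_mask))
  expect_identical(rois$fibroblast_mask, rois$cell_mask)
})

test_that("dilation_px = 0 gives the exact set difference", {
  ml <- make_monolayer()
  rois <- build_rois_2d(ml$stack, dilation_px = 0)
  expect_identical(rois$fibroblast_mask,
                   rois$cell_mask & !rois$cancer_mask)
  guarded <- build_rois_2d(ml$stack, dilation_px = 3)
  expect_lt(sum(guarded$fibroblast_mask), sum(rois$fibroblast_mask))
})

test_that("compartment means recover construction levels and empty
           compartments are labelled missing", {
  ml <- make_monolayer(marker_in = "fibroblast", marker_level = 40)
  rois <- build_rois_2d(ml$stack)
  q <- quantify_rois(ml$stack, rois, "marker")
  fib <- q$mean_intensity[q$compartment == "fibroblast"]
  can <- q$mean_intensity[q$compartment == "cancer"]
  expect_gt(fib, 0.75 * 40)  # core at 40; smoothed rim dilutes the mean
  expect_equal(can, 0, tolerance = 1e-9)
  # constant channel: raw means are the constant, subtracted means zero
  vox <- ml$stack$voxels; vox[, , , 3] <- 4
  s4 <- image_stack(vox, ml$stack$channels)
  raw <- quantify_rois(s4, rois, "marker", subtract = FALSE)
  expect_true(all(raw$mean_intensity == 4))
  subd <- quantify_rois(s4, rois, "marker")
  expect_true(all(subd$mean_intensity == 0))
  # an empty compartment is NA, never a silent zero
  empty_rois <- rois
  empty_rois$cancer_mask[] <- FALSE
  q2 <- quantify_rois(ml$stack, empty_rois, "marker")
  expect_true(is.na(q2$mean_intensity[q2$compartment == "cancer"]))
  expect_equal(q2$n_pixels[q2$compartment == "cancer"], 0L)
})

test_that("compartment means ignore background pixels entirely", {
  ml <- make_monolayer()
  rois <- build_rois_2d(ml$stack)
  q1 <- quantify_rois(ml$stack, rois, "marker")
  # embed the same scene in a larger, emptier field
  vox_big <- array(0, c(1, 160, 160, 3))
  vox_big[1, 1:96, 1:96, ] <- ml$stack$voxels[1, , , ]
  big <- image_stack(vox_big, ml$stack$channels)
  rois_big <- rois
  for (f in c("cell_mask", "cancer_mask", "fibroblast_mask")) {
    m <- matrix(FALSE, 160, 160); m[1:96, 1:96] <- rois[[f]]
    rois_big[[f]] <- m
  }
  q2 <- quantify_rois(big, rois_big, "marker")
  expect_equal(q2$mean_intensity, q1$mean_intensity, tolerance = 1e-12)
})

test_that("ground-truth masks recover configured marker levels and the
           co/mono fibroblast ratio", {
  gen2d <- function(marker_mean, seed) {
    fib <- fibroblast_population(12, channel_levels = list(
      cea = c(30, 15), coll4 = c(120, 60), marker = c(marker_mean, 5)))
    generate_stack(c(1, 128, 128), list(fib),
                   channels = c("dapi", "cea", "marker"),
                   blur_sigma_px = c(0, 0, 0),
                   noise = list(gaussian_sd = 0, poisson_scaling = 0),
                   background_level = 0, seed = seed)
  }
  means <- vapply(c(mono = 40, co = 100), function(mm) {
    out <- gen2d(mm, seed = 61)
    dyx <- dim(out$truth$label_volume)[2:3]
    truth_rois <- structure(list(
      cell_mask = matrix(out$truth$label_volume[1, , ] > 0, dyx[1], dyx[2]),
      cancer_mask = matrix(FALSE, dyx[1], dyx[2]),
      fibroblast_mask = matrix(out$truth$label_volume[1, , ] == 2L &
                                 !out$truth$nucleus_mask[1, , ],
                               dyx[1], dyx[2]),
      dilation_px = 0L), class = "roi_set_2d")
    q <- quantify_rois(out$stack, truth_rois, "marker")
    q$mean_intensity[q$compartment == "fibroblast"]
  }, numeric(1))
  expect_equal(means[["mono"]], 40, tolerance = 4)
  expect_equal(means[["co"]], 100, tolerance = 8)
  expect_gt(means[["co"]] / means[["mono"]], 1)
})

test_that("replicate summaries aggregate across images with SEM", {
  mk <- function(m) data.frame(compartment = c("cancer", "fibroblast"),
                               mean_intensity = c(m, m / 2),
                               n_pixels = 100L, stringsAsFactors = FALSE)
  sm <- summarize_roi_means(list(mk(10), mk(12), mk(14)))
  can <- sm[sm$compartment == "cancer", ]
  expect_equal(can$mean, 12)
  expect_equal(can$sem, sd(c(10, 12, 14)) / sqrt(3))
  expect_equal(can$n_images, 3L)
  one <- summarize_roi_means(list(mk(10)))
  expect_true(is.na(one$sem[1]))
})
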