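test_that("Otsu separates two well-separated value classes", {
  thr <- otsu_threshold(c(rep(0, 50), rep(10, 50)))
  expect_gt(thr, 0)
  expect_lt(thr, 10)
  expect_error(otsu_threshold(rep(3, 10)), "degenerate")
  expect_error(otsu_threshold(c(1, 2), n_bins = 1), "n_bins")
})

test_that("Otsu matches the exhaustive between-class-variance oracle", {
  set.seed(11)
  v <- c(rnorm(300, 20, 2), rnorm(300, 200, 2))
  thr <- otsu_threshold(v)
  expect_gt(thr, 30)
  expect_lt(thr, 190)
  expect_equal(thr, otsu_oracle(v), tolerance = 1e-12)
  # skewed unimodal input as well
  w <- rexp(500, 1 / 30)
  expect_equal(otsu_threshold(w), otsu_oracle(w), tolerance = 1e-12)
})

test_that("Otsu is scale-equivariant up to one bin width", {
  set.seed(12)
  v <- c(rnorm(200, 10, 1), rnorm(200, 40, 3))
  t1 <- otsu_threshold(v)
  t2 <- otsu_threshold(2 * v)
  bin_w <- diff(range(2 * v)) / 256
  expect_lt(abs(t2 - 2 * t1), bin_w + 1e-9)
})

test_that("Otsu agrees with an independent library implementation", {
  set.seed(13)
  v <- pmin(pmax(c(rnorm(5000, 0.2, 0.05), rnorm(5000, 0.7, 0.05)), 0), 1)
  ours <- otsu_threshold(c(v, 0, 1))   # pin the range to [0, 1]
  ref <- EBImage::otsu(EBImage::Image(matrix(c(v, 0, 1), ncol = 1)),
                       range = c(0, 1), levels = 256)
  expect_lt(abs(ours - ref), 2 / 256)
})

test_that("smoothing with sigma_z = 0 never leaks across z-planes", {
  vol <- array(0, c(2, 32, 32))
  vol[1, , ] <- 50    # one bright, one dark plane
  sm <- gaussian_smooth(vol, c(4, 4, 0))
  expect_identical(sm[2, , ] == 0, matrix(TRUE, 32, 32))
  expect_equal(sum(sm[1, , ]), sum(vol[1, , ]), tolerance = 1e-9)
})

test_that("plane-wise smoothing agrees with an independent 2-D Gaussian", {
  set.seed(14)
  vol <- array(runif(32 * 32, 0, 100), c(1, 32, 32))
  ours <- gaussian_smooth(vol, c(3, 3, 0))[1, , ]
  ref <- EBImage::gblur(EBImage::Image(vol[1, , ]), sigma = 3,
                        boundary = "replicate")
  expect_lt(max(abs(ours - ref)) / max(ref), 0.01)
})

test_that("segment_dapi covers bright structures, extends beyond them,
           and is scale invariant", {
  # a bright cylinder spanning all z: every plane sees the same disc, so
  # plane-wise smoothing cannot starve any slice of signal
  vox <- array(0, c(12, 48, 48, 1))
  disc <- outer(seq_len(48), seq_len(48), function(y, x)
    (y - 24)^2 + (x - 24)^2 <= 10^2)
  core <- outer(seq_len(48), seq_len(48), function(y, x)
    (y - 24)^2 + (x - 24)^2 <= 7^2)
  for (z in 1:12) vox[z, , , 1][disc] <- 100
  s <- image_stack(vox, "dapi")
  nuc <- s$voxels[, , , 1] > 0
  fm <- segment_dapi(s)
  expect_identical(dim(fm$mask), dim(nuc))
  for (z in 1:12) expect_true(all(fm$mask[z, , ][core]))  # covers the core
  expect_gt(sum(fm$mask), sum(nuc))         # adjacent regions included
  expect_gt(fm$otsu_threshold, min(gaussian_smooth(s$voxels[, , , 1])))
  s3 <- image_stack(s$voxels * 3, s$channels)
  fm3 <- segment_dapi(s3)
  expect_identical(fm$mask, fm3$mask)
  expect_error(segment_dapi(image_stack(array(7, c(2, 8, 8, 1)), "dapi")),
               "degenerate")
})

test_that("background subtraction uses the per-channel background median", {
  vox <- array(0, c(1, 4, 4, 2))
  vox[, , , 1] <- 5                               # constant channel
  vox[1, 1, 1:2, 2] <- 100; vox[1, 2, 1, 2] <- 100  # 3 fg voxels
  vox[1, , , 2][vox[1, , , 2] == 0] <- 10           # bg at 10
  mask <- array(FALSE, c(1, 4, 4)); mask[1, 1, 1:2] <- TRUE
  mask[1, 2, 1] <- TRUE
  s <- image_stack(vox, c("dapi", "cea"))
  sub <- subtract_background(s, mask)
  expect_identical(unique(as.vector(get_channel(sub, "dapi"))), 0)
  expect_identical(sort(unique(as.vector(get_channel(sub, "cea")))),
                   c(0, 90))
  expect_identical(get_channel(s, "cea")[1, 1, 1], 100)  # input untouched
})

test_that("a background sample with median zero leaves the channel as is", {
  vox <- array(0, c(1, 1, 4, 1))
  vox[1, 1, , 1] <- c(50, 0, 0, 10)      # fg voxel 1; bg = {0, 0, 10}
  mask <- array(c(TRUE, FALSE, FALSE, FALSE), c(1, 1, 4))
  s <- image_stack(vox, "cea")
  sub <- subtract_background(s, mask)
  expect_identical(as.vector(sub$voxels), as.vector(vox))
  expect_error(subtract_background(s, array(TRUE, c(1, 1, 4))),
               "all-foreground")
})

test_that("nuclei recall on default synthetic mono-cultures is >= 0.95", {
  for (cond in c("mono_fibroblast", "mono_cancer")) {
    cav <- generate_condition_set(cond, n_cavities = 1,
                                  shape = c(32, 128, 128), seed = 21)[[1]]
    fm <- segment_dapi(cav$stack)
    nuc <- cav$truth$nucleus_mask
    expect_gte(sum(fm$mask & nuc) / sum(nuc), 0.95)
  }
})
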