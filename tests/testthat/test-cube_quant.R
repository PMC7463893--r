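test_that("the cube partition tiles with the floor rule", {
  g1 <- partition_grid(c(16, 32, 32))
  expect_equal(nrow(g1), 1L)
  expect_equal(unlist(g1[1, ]), c(ix = 0, iy = 0, iz = 0,
                                  z0 = 0, y0 = 0, x0 = 0))
  g2 <- partition_grid(c(32, 64, 96))
  expect_equal(nrow(g2), 12L)   # 2 * 2 * 3
  # pairwise disjoint and union = full volume
  covered <- array(0L, c(32, 64, 96))
  for (i in seq_len(nrow(g2))) {
    z <- g2$z0[i] + 1:16; y <- g2$y0[i] + 1:32; x <- g2$x0[i] + 1:32
    covered[z, y, x] <- covered[z, y, x] + 1L
  }
  expect_true(all(covered == 1L))
  g3 <- partition_grid(c(17, 33, 33))
  expect_equal(nrow(g3), 1L)    # 1-voxel margins dropped
  expect_warning(partition_grid(c(8, 64, 64)), "empty partition")
})

test_that("a cube with exactly 50% foreground is excluded (strictly more
           than half required)", {
  vox <- array(1, c(16, 32, 32, 1))
  s <- image_stack(vox, "cea")
  mask <- array(FALSE, c(16, 32, 32))
  mask[seq_len(8192)] <- TRUE                     # exactly half
  expect_equal(nrow(quantify_cubes(s, mask)$records), 0L)
  mask[8193] <- TRUE                              # one voxel more
  t1 <- quantify_cubes(s, mask)
  expect_equal(nrow(t1$records), 1L)
  expect_equal(t1$records$n_fg_voxels, 8193L)
  expect_equal(t1$records$fg_fraction, 8193 / 16384)
})

test_that("means are over foreground voxels only", {
  # all-foreground mask, constant channel
  s7 <- image_stack(array(7, c(32, 64, 64, 1)), "marker")
  t7 <- quantify_cubes(s7, array(TRUE, c(32, 64, 64)))
  expect_equal(nrow(t7$records), 8L)
  expect_true(all(t7$records$mean_marker == 7))
  # 9000 foreground voxels at 10, 7384 background voxels at 99
  vox <- array(0, c(16, 32, 32, 1))
  mask <- array(FALSE, c(16, 32, 32))
  mask[seq_len(9000)] <- TRUE
  vox[, , , 1][mask] <- 10
  vox[, , , 1][!mask] <- 99
  tb <- quantify_cubes(image_stack(vox, "cea"), mask)
  expect_equal(tb$records$mean_cea, 10)
  expect_equal(tb$records$n_fg_voxels, 9000L)
})

test_that("quantification matches a brute-force per-voxel oracle", {
  cav <- generate_stack(c(32, 64, 64),
                        list(cancer_population(40),
                             fibroblast_population(40)),
                        seed = 33)
  fm <- segment_dapi(cav$stack)
  sub <- subtract_background(cav$stack, fm)
  got <- quantify_cubes(sub, fm)
  oracle <- cube_oracle(sub, fm)
  inc <- Filter(function(o) o$included, oracle)
  expect_equal(nrow(got$records), length(inc))
  # conservation: foreground voxels summed over all cubes = mask total
  expect_equal(sum(vapply(oracle, `[[`, numeric(1), "n_fg")),
               sum(fm$mask))   # 64/32, 64/32, 32/16 tile exactly
  for (o in inc) {
    row <- got$records[got$records$ix == o$ix & got$records$iy == o$iy &
                         got$records$iz == o$iz, ]
    expect_equal(nrow(row), 1L)
    expect_identical(row$n_fg_voxels, as.integer(o$n_fg))
    expect_equal(row$fg_fraction, o$frac, tolerance = 1e-12)
    for (ch in seq_along(got$channels))
      expect_equal(row[[paste0("mean_", got$channels[ch])]], o$means[ch],
                   tolerance = 1e-9)
  }
})

test_that("adding a constant to a channel shifts every cube mean exactly", {
  cav <- generate_stack(c(16, 64, 64), list(cancer_population(30)),
                        seed = 34)
  fm <- segment_dapi(cav$stack)
  t1 <- quantify_cubes(cav$stack, fm)
  vox2 <- cav$stack$voxels
  vox2[, , , 2] <- vox2[, , , 2] + 5.25
  t2 <- quantify_cubes(image_stack(vox2, cav$stack$channels), fm)
  expect_equal(t2$records$mean_cea, t1$records$mean_cea + 5.25,
               tolerance = 1e-12)
  expect_equal(t2$records$mean_dapi, t1$records$mean_dapi,
               tolerance = 1e-12)
})

test_that("pooling concatenates records and counts cavities", {
  mk <- function(id, n = 4) {
    rec <- data.frame(stack_id = id, ix = seq_len(n) - 1L, iy = 0L,
                      iz = 0L, fg_fraction = 0.75, n_fg_voxels = 12288L,
                      mean_dapi = runif(n), mean_cea = runif(n),
                      stringsAsFactors = FALSE)
    cube_table(rec, "mono_fibroblast", c("dapi", "cea"))
  }
  set.seed(9)
  pooled <- pool_cavities(lapply(paste0("cav", 1:5), mk, n = 40))
  expect_equal(nrow(pooled$records), 200L)
  expect_equal(pooled$n_cavities_pooled, 5L)
  one <- mk("solo")
  expect_identical(pool_cavities(list(one)), one)
  bad <- mk("x")
  bad$condition <- "co_culture"
  expect_error(pool_cavities(list(mk("a"), bad)), "different conditions")
  chan <- mk("y")
  chan$channels <- c("dapi", "coll4")
  names(chan$records)[7] <- "mean_coll4"
  expect_error(pool_cavities(list(mk("a"), chan)), "channel role")
})
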