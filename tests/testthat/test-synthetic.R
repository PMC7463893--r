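test_that("an empty population list gives pure background plus noise", {
  out <- generate_stack(c(4, 24, 24), list(), seed = 50,
                        background_level = 12)
  expect_true(all(out$truth$label_volume == 0L))
  expect_equal(nrow(out$truth$nucleus_centers), 0L)
  d <- get_channel(out$stack, "dapi")
  expect_equal(mean(d), 12, tolerance = 1)   # Poisson+Gaussian around bg
})

test_that("a single clean nucleus puts DAPI exactly on the ellipsoid and
           markers only in its halo", {
  pop <- cancer_population(1, dapi_cytoplasm_fraction = 0)
  out <- generate_stack(c(24, 48, 48), list(pop),
                        blur_sigma_px = c(0, 0, 0),
                        noise = list(gaussian_sd = 0, poisson_scaling = 0),
                        background_level = 0, seed = 51)
  dapi <- get_channel(out$stack, "dapi")
  cea <- get_channel(out$stack, "cea")
  nuc <- out$truth$nucleus_mask
  halo <- out$truth$label_volume == 1L & !nuc
  expect_gt(sum(nuc), 0)
  expect_identical(dapi > 0, nuc)
  expect_true(all(cea[halo] > 0))
  expect_true(all(cea[!halo] == 0))
})

test_that("generation is bit-identical under a fixed seed and differs
           across seeds", {
  args <- list(shape = c(8, 48, 48),
               populations = list(cancer_population(5),
                                  fibroblast_population(5)))
  a <- do.call(generate_stack, c(args, seed = 52))
  b <- do.call(generate_stack, c(args, seed = 52))
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$truth$label_volume, b$truth$label_volume)
  c_ <- do.call(generate_stack, c(args, seed = 53))
  expect_false(identical(a$truth$nucleus_centers, c_$truth$nucleus_centers))
})

test_that("condition sets contain the right populations and reseed
           deterministically", {
  fib <- generate_condition_set("mono_fibroblast", n_cavities = 3,
                                shape = c(16, 48, 48),
                                n_total_nuclei = 10, seed = 54)
  expect_length(fib, 3L)
  for (cv in fib) {
    expect_false(any(cv$truth$label_volume == 1L))  # no cancer voxels
    expect_true(any(cv$truth$label_volume == 2L))
  }
  co <- generate_condition_set("co_culture", n_cavities = 2,
                               shape = c(16, 48, 48),
                               n_total_nuclei = 10, seed = 54)
  for (cv in co) {
    expect_true(any(cv$truth$label_volume == 1L))
    expect_true(any(cv$truth$label_volume == 2L))
  }
  again <- generate_condition_set("mono_fibroblast", n_cavities = 3,
                                  shape = c(16, 48, 48),
                                  n_total_nuclei = 10, seed = 54)
  expect_identical(lapply(fib, function(x) x$stack$voxels),
                   lapply(again, function(x) x$stack$voxels))
})

test_that("clean per-population DAPI means match the configured levels and
           contrasts are never inverted", {
  pops <- list(cancer_population(12, dapi_level = c(240, 10),
                                 dapi_cytoplasm_fraction = 0),
               fibroblast_population(12, dapi_level = c(80, 5),
                                     dapi_cytoplasm_fraction = 0))
  out <- generate_stack(c(24, 64, 64), pops,
                        blur_sigma_px = c(0, 0, 0),
                        noise = list(gaussian_sd = 0, poisson_scaling = 0),
                        background_level = 0, seed = 55)
  dapi <- get_channel(out$stack, "dapi")
  nuc <- out$truth$nucleus_mask
  mean_cancer <- mean(dapi[nuc & out$truth$label_volume == 1L])
  mean_fibro <- mean(dapi[nuc & out$truth$label_volume == 2L])
  expect_equal(mean_cancer, 240, tolerance = 10)  # sampling error at sd 10
  expect_equal(mean_fibro, 80, tolerance = 5)
  expect_gt(mean_cancer, mean_fibro)
})

test_that("foreground volume grows monotonically with nucleus count", {
  fills <- vapply(c(5, 15, 30), function(n) {
    out <- generate_stack(c(16, 48, 48), list(cancer_population(n)),
                          blur_sigma_px = c(0, 0, 0),
                          noise = list(gaussian_sd = 0,
                                       poisson_scaling = 0),
                          background_level = 0, seed = 56)
    mean(out$truth$label_volume > 0L)
  }, numeric(1))
  expect_true(all(diff(fills) > 0))
})

test_that("impossible packing fails with a placement error naming the
           population", {
  expect_error(
    generate_stack(c(8, 16, 16), list(fibroblast_population(500)),
                   seed = 57, max_attempts = 20),
    "fibroblast")
})

test_that("cube truth labels report the majority population", {
  lv <- array(0L, c(16, 32, 32))
  lv[1:8, 1:20, ] <- 1L       # cancer block
  lv[1:8, 21:32, ] <- 2L      # smaller fibroblast block
  truth <- structure(list(label_volume = lv), class = "ground_truth")
  tl <- cube_truth_labels(truth)
  expect_equal(nrow(tl), 1L)
  expect_equal(tl$truth_label, "cancer")
  expect_equal(tl$n_labeled, 8L * 32L * 32L)
})
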