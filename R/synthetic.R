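# Seeded synthetic co-culture stacks with per-voxel ground truth.
#
# Nuclei are rigid, randomly oriented ellipsoids placed without overlap by
# rejection sampling; each cell contributes nuclear DAPI signal and a
# perinuclear cytoplasmic halo carrying the population's marker channels.
# The clean volume is blurred by an anisotropic Gaussian (a PSF surrogate),
# offset by a uniform background and corrupted by Poisson photon noise plus
# additive Gaussian read noise. All randomness flows from one seed, so a
# given seed reproduces a stack bit-identically.
#
# The default populations encode the documented contrasts between the two
# cell types: cancer cells have bright, small, round nuclei and high CEA;
# fibroblasts have dim, large, elongated nuclei and high collagen IV. The
# numeric levels are stand-ins (no intensity distributions are available
# for the real stains) chosen so nuclear segmentation is well-posed at
# roughly a 3x DAPI and 4x marker contrast.

#' Describe one cell population for the stack generator
#'
#' @param label `"cancer"` or `"fibroblast"`.
#' @param n_nuclei Number of nuclei to place (>= 0).
#' @param nucleus_radius_um Mean and spread (sd) of the short ellipsoid
#'   semi-axis, micrometres.
#' @param elongation Mean and spread of the long-to-short axis ratio
#'   (>= 1).
#' @param dapi_level Mean and spread of nuclear DAPI intensity.
#' @param channel_levels Named list, role -> `c(mean, sd)` of cytoplasmic
#'   intensity in the perinuclear halo; roles absent from the list emit
#'   nothing.
#' @param cytoplasm_halo_um Thickness of the marker-bearing shell around
#'   each nucleus, micrometres.
#' @param dapi_cytoplasm_fraction Fraction of the nuclear DAPI level also
#'   emitted by the cytoplasmic halo (default 0.3), emulating residual
#'   RNA-bound dye and out-of-focus nuclear light that brighten the cell
#'   mass between nuclei in real stacks.
#' @return Object of class `population_spec`.
#' @export
population_spec <- function(label, n_nuclei,
                            nucleus_radius_um = c(3, 0.3),
                            elongation = c(1.2, 0.1),
                            dapi_level = c(100, 15),
                            channel_levels = list(),
                            cytoplasm_halo_um = 3,
                            dapi_cytoplasm_fraction = 0.3) {
  label <- match.arg(label, c("cancer", "fibroblast"))
  stopifnot(n_nuclei >= 0, nucleus_radius_um[1L] > 0,
            cytoplasm_halo_um > 0, dapi_level[1L] >= 0,
            elongation[1L] >= 1)
  for (lv in channel_levels) stopifnot(lv[1L] >= 0)
  stopifnot(dapi_cytoplasm_fraction >= 0, dapi_cytoplasm_fraction <= 1)
  structure(list(label = label, n_nuclei = as.integer(n_nuclei),
                 nucleus_radius_um = nucleus_radius_um,
                 elongation = elongation, dapi_level = dapi_level,
                 channel_levels = channel_levels,
                 cytoplasm_halo_um = cytoplasm_halo_um,
                 dapi_cytoplasm_fraction = dapi_cytoplasm_fraction),
            class = "population_spec")
}

#' Default cancer (HT-29-like) population: bright, small, round nuclei;
#' CEA-high, collagen-IV-low.
#' @param n_nuclei Number of nuclei.
#' @param ... Overrides passed to [population_spec()].
#' @return A `population_spec`.
#' @export
cancer_population <- function(n_nuclei, ...) {
  args <- utils::modifyList(
    list(label = "cancer", n_nuclei = n_nuclei,
         nucleus_radius_um = c(4.2, 0.4), elongation = c(1.15, 0.1),
         dapi_level = c(240, 30),
         channel_levels = list(cea = c(120, 60), coll4 = c(30, 15)),
         cytoplasm_halo_um = 2.5),
    list(...))
  do.call(population_spec, args)
}

#' Default fibroblast (CCD-1137Sk-like) population: dim, large, elongated
#' nuclei; CEA-low, collagen-IV-high.
#' @param n_nuclei Number of nuclei.
#' @param ... Overrides passed to [population_spec()].
#' @return A `population_spec`.
#' @export
fibroblast_population <- function(n_nuclei, ...) {
  args <- utils::modifyList(
    list(label = "fibroblast", n_nuclei = n_nuclei,
         nucleus_radius_um = c(3.5, 0.35), elongation = c(2.8, 0.4),
         dapi_level = c(80, 12),
         channel_levels = list(cea = c(30, 15), coll4 = c(120, 60)),
         cytoplasm_halo_um = 3),
    list(...))
  do.call(population_spec, args)
}

.random_rotation <- function(planar) {
  if (planar) {
    th <- stats::runif(1, 0, 2 * pi)
    matrix(c(1, 0, 0,
             0, cos(th), -sin(th),
             0, sin(th), cos(th)), 3, 3, byrow = TRUE)
  } else {
    qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
    Q <- qr.Q(qr_)
    if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
    Q
  }
}

# Voxel indices (linear, Z,Y,X order) inside an ellipsoid given in physical
# coordinates: center (z,y,x) um, semi-axes um (body frame), rotation R
# (body -> world). Voxel centers sit at (i - 0.5) * voxel_size.
.ellipsoid_voxels <- function(shape, voxel_size, center, semi, R) {
  e <- max(semi)
  lo <- pmax(1L, as.integer(floor((center - e) / voxel_size + 0.5)))
  hi <- pmin(shape, as.integer(ceiling((center + e) / voxel_size + 0.5)))
  if (any(lo > hi)) return(integer())
  zz <- lo[1L]:hi[1L]; yy <- lo[2L]:hi[2L]; xx <- lo[3L]:hi[3L]
  g <- expand.grid(z = zz, y = yy, x = xx)
  P <- cbind((g$z - 0.5) * voxel_size[1L],
             (g$y - 0.5) * voxel_size[2L],
             (g$x - 0.5) * voxel_size[3L])
  U <- sweep(P, 2L, center) %*% R    # world -> body: t(R) %*% p, row-wise
  q <- (U[, 1L] / semi[1L])^2 + (U[, 2L] / semi[2L])^2 +
       (U[, 3L] / semi[3L])^2
  ins <- q <= 1
  if (!any(ins)) return(integer())
  (g$z[ins]) + (g$y[ins] - 1L) * shape[1L] +
    (g$x[ins] - 1L) * shape[1L] * shape[2L]
}

.truncpos <- function(n, mean, sd, lower = 0) pmax(lower, stats::rnorm(n, mean, sd))

#' Generate a ground-truth-labelled synthetic 3-D stack
#'
#' @param shape Spatial extents `(Z, Y, X)` in voxels.
#' @param populations List of [population_spec()] objects (may be empty:
#'   pure background plus noise).
#' @param channels Channel roles to emit; must contain `dapi`.
#' @param blur_sigma_px Optical-blur sigmas `(sx, sy, sz)` in pixels.
#' @param noise List with `gaussian_sd` (additive read noise) and
#'   `poisson_scaling` (photon-noise gain; 0 disables Poisson noise).
#' @param background_level Uniform background intensity added before noise.
#' @param mixing `"interspersed"` (uniform random placement) or `"islets"`
#'   (each population clusters around a few islet centres of roughly 60
#'   cells, giving cell-type patches on the scale of a voxel cube).
#' @param cell_bed_fraction Fraction of the y extent occupied by cells
#'   (default 0.75). Imaged cavity fields contain cell-free medium as well
#'   as cell mass; the cell-free margin keeps the nuclear-channel histogram
#'   bimodal (as in real stacks) and gives the cube inclusion rule both
#'   kinds of region to act on. Set to 1 for a volume-filling culture.
#' @param voxel_size_um `(dz, dy, dx)` in micrometres.
#' @param seed Optional integer; fixes all randomness.
#' @param max_attempts Placement attempts per nucleus before giving up.
#' @return List with elements `stack` (an [image_stack()]) and `truth`
#'   (class `ground_truth`: `label_volume` with 0 = background, 1 = cancer,
#'   2 = fibroblast over nuclei and halos; `nucleus_mask`, logical, TRUE on
#'   nucleus voxels only; and `nucleus_centers`).
#' @export
generate_stack <- function(shape, populations,
                           channels = c("dapi", "cea", "coll4"),
                           blur_sigma_px = c(1, 1, 2),
                           noise = list(gaussian_sd = 2,
                                        poisson_scaling = 0.5),
                           background_level = 5,
                           mixing = c("interspersed", "islets"),
                           cell_bed_fraction = 0.75,
                           voxel_size_um = c(1, 1, 1), seed = NULL,
                           max_attempts = 500L) {
  mixing <- match.arg(mixing)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L), "dapi" %in% channels,
            cell_bed_fraction > 0, cell_bed_fraction <= 1)
  voxel_size <- as.numeric(voxel_size_um)
  phys <- shape * voxel_size
  bed <- phys
  bed[2L] <- phys[2L] * cell_bed_fraction   # cells confined in y
  .with_seed(seed, {
    clean <- lapply(channels, function(ch) array(0, shape))
    names(clean) <- channels
    label_vol <- array(0L, shape)
    occupancy <- array(FALSE, shape)
    centers <- list()
    pop_ids <- c(cancer = 1L, fibroblast = 2L)
    for (pop in populations) {
      stopifnot(inherits(pop, "population_spec"))
      pid <- pop_ids[[pop$label]]
      n_islets <- max(1L, ceiling(pop$n_nuclei / 60))
      islet_centers <- cbind(stats::runif(n_islets, 0, bed[1L]),
                             stats::runif(n_islets, 0, bed[2L]),
                             stats::runif(n_islets, 0, bed[3L]))
      islet_sd <- c(8, 22, 22)
      for (k in seq_len(pop$n_nuclei)) {
        placed <- FALSE
        for (attempt in seq_len(max_attempts)) {
          a <- .truncpos(1, pop$nucleus_radius_um[1L],
                         pop$nucleus_radius_um[2L], lower = 0.8)
          ratio <- max(1, stats::rnorm(1, pop$elongation[1L],
                                       pop$elongation[2L]))
          semi <- c(a, a, a * ratio)   # long axis = body x
          R <- .random_rotation(planar = shape[1L] == 1L)
          # islet placement falls back to uniform once half the attempt
          # budget is spent: stragglers that cannot fit into a saturated
          # cluster settle between islets instead of failing the run
          center <- if (mixing == "islets" && attempt <= max_attempts / 2) {
            ic <- islet_centers[sample.int(n_islets, 1L), ]
            pmin(pmax(ic + stats::rnorm(3, 0, islet_sd), 0.51 * voxel_size),
                 bed - 0.51 * voxel_size)
          } else {
            stats::runif(3, 0, bed)
          }
          if (shape[1L] == 1L) center[1L] <- 0.5 * voxel_size[1L]
          idx <- .ellipsoid_voxels(shape, voxel_size, center, semi, R)
          if (length(idx) == 0L || any(occupancy[idx])) next
          occupancy[idx] <- TRUE
          label_vol[idx] <- pid
          dapi_lv <- .truncpos(1, pop$dapi_level[1L], pop$dapi_level[2L])
          clean$dapi[idx] <- clean$dapi[idx] + dapi_lv
          halo_idx <- setdiff(
            .ellipsoid_voxels(shape, voxel_size, center,
                              semi + pop$cytoplasm_halo_um, R), idx)
          if (length(halo_idx)) {
            relabel <- halo_idx[label_vol[halo_idx] == 0L]
            label_vol[relabel] <- pid
            if (pop$dapi_cytoplasm_fraction > 0)
              clean$dapi[halo_idx] <- clean$dapi[halo_idx] +
                pop$dapi_cytoplasm_fraction * dapi_lv
            for (role in intersect(names(pop$channel_levels), channels)) {
              lv <- pop$channel_levels[[role]]
              clean[[role]][halo_idx] <- clean[[role]][halo_idx] +
                .truncpos(1, lv[1L], lv[2L])
            }
          }
          centers[[length(centers) + 1L]] <-
            data.frame(z = center[1L] / voxel_size[1L],
                       y = center[2L] / voxel_size[2L],
                       x = center[3L] / voxel_size[3L],
                       label = pop$label, stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
        if (!placed)
          stop("could not place nucleus ", k, " of population '",
               pop$label, "' without overlap after ", max_attempts,
               " attempts")
      }
    }
    vox <- array(0, c(shape, length(channels)))
    for (ci in seq_along(channels)) {
      ch <- clean[[channels[ci]]]
      if (any(blur_sigma_px > 0)) ch <- gaussian_smooth(ch, blur_sigma_px)
      ch <- ch + background_level
      ps <- noise$poisson_scaling
      if (!is.null(ps) && ps > 0)
        ch <- array(stats::rpois(length(ch), ch / ps) * ps, shape)
      gs <- noise$gaussian_sd
      if (!is.null(gs) && gs > 0)
        ch <- ch + array(stats::rnorm(length(ch), 0, gs), shape)
      vox[, , , ci] <- pmax(ch, 0)
    }
    nucleus_centers <- if (length(centers)) do.call(rbind, centers)
      else data.frame(z = numeric(), y = numeric(), x = numeric(),
                      label = character(), stringsAsFactors = FALSE)
    truth <- structure(list(label_volume = label_vol,
                            nucleus_mask = occupancy,
                            nucleus_centers = nucleus_centers,
                            labels = pop_ids),
                       class = "ground_truth")
    list(stack = image_stack(vox, channels, voxel_size),
         truth = truth)
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  d <- dim(x$label_volume)
  fr <- table(factor(x$label_volume, levels = 0:2,
                     labels = c("background", "cancer", "fibroblast")))
  cat(sprintf("<ground_truth> %d x %d x %d (Z,Y,X), %d nuclei\n",
              d[1], d[2], d[3], nrow(x$nucleus_centers)))
  cat("  voxels: ", paste(sprintf("%s %.1f%%", names(fr),
                                  100 * fr / sum(fr)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Generate a seeded condition set of cavities
#'
#' Emulates the study design of pooling several cavities per culture
#' condition (default 5). Mono conditions contain a single population at
#' the full seeding density; co-cultures contain both populations at half
#' density each (mirroring equal co-seeding at constant total cell
#' number). Cavity seeds are derived deterministically from the master
#' seed.
#'
#' @param condition `"mono_cancer"`, `"mono_fibroblast"` or
#'   `"co_culture"`.
#' @param n_cavities Number of cavities (default 5).
#' @param shape Per-cavity extents `(Z, Y, X)` in voxels.
#' @param n_total_nuclei Total nuclei per cavity; default scales with the
#'   volume at a dense-culture packing of about 3.9e-4 nuclei per voxel
#'   (roughly a quarter of the cell-bed volume is nuclear).
#' @param cancer,fibroblast Optional [population_spec()] templates; their
#'   `n_nuclei` is overridden by the condition's density rule.
#' @param mixing Placement mode; by default mono-cultures are uniformly
#'   interspersed while co-cultures grow in islets, matching the zoned
#'   architecture of real co-cultures (fibroblast clusters within the
#'   cancer colony).
#' @param seed Master seed (cavity `i` runs at
#'   `(seed + i * 7919) mod (2^31 - 1)`).
#' @param ... Further arguments passed to [generate_stack()]
#'   (`channels`, `blur_sigma_px`, `noise`, `background_level`, `mixing`,
#'   ...).
#' @return List of `n_cavities` elements, each a list with `stack`,
#'   `truth` and `stack_id`.
#' @export
generate_condition_set <- function(condition, n_cavities = 5,
                                   shape = c(32, 192, 192),
                                   n_total_nuclei = NULL,
                                   cancer = NULL, fibroblast = NULL,
                                   seed = 1, mixing = NULL, ...) {
  condition <- match.arg(condition,
                         c("mono_cancer", "mono_fibroblast", "co_culture"))
  stopifnot(n_cavities >= 1)
  if (is.null(mixing))
    mixing <- if (condition == "co_culture") "islets" else "interspersed"
  shape <- as.integer(shape)
  if (is.null(n_total_nuclei))
    n_total_nuclei <- round(3.9e-4 * prod(shape))
  mk_cancer <- function(n) {
    if (is.null(cancer)) cancer_population(n)
    else { cancer$n_nuclei <- as.integer(n); cancer }
  }
  mk_fibro <- function(n) {
    if (is.null(fibroblast)) fibroblast_population(n)
    else { fibroblast$n_nuclei <- as.integer(n); fibroblast }
  }
  pops <- switch(condition,
    mono_cancer = list(mk_cancer(n_total_nuclei)),
    mono_fibroblast = list(mk_fibro(n_total_nuclei)),
    co_culture = list(mk_cancer(round(n_total_nuclei / 2)),
                      mk_fibro(round(n_total_nuclei / 2))))
  lapply(seq_len(n_cavities), function(i) {
    cav_seed <- (seed + i * 7919) %% 2147483647
    out <- generate_stack(shape, pops, seed = cav_seed, mixing = mixing, ...)
    out$stack_id <- sprintf("%s_cavity%02d", condition, i)
    out
  })
}

#' Ground-truth majority label per cube
#'
#' For each cube of the partition, the majority cell-type label among its
#' non-background truth voxels (ties and all-background cubes give `NA`).
#'
#' @param truth A `ground_truth` from [generate_stack()].
#' @param cube_shape Cube dimensions `(x, y, z)` in voxels.
#' @return Data frame with columns `ix`, `iy`, `iz`, `truth_label`,
#'   `n_labeled`.
#' @export
cube_truth_labels <- function(truth, cube_shape = c(32, 32, 16)) {
  lv <- truth$label_volume
  grid <- partition_grid(dim(lv), cube_shape)
  cz <- cube_shape[3L]; cy <- cube_shape[2L]; cx <- cube_shape[1L]
  lab <- character(nrow(grid)); nl <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cube <- lv[grid$z0[i] + seq_len(cz), grid$y0[i] + seq_len(cy),
               grid$x0[i] + seq_len(cx)]
    n1 <- sum(cube == 1L); n2 <- sum(cube == 2L)
    nl[i] <- n1 + n2
    lab[i] <- if (n1 > n2) "cancer" else if (n2 > n1) "fibroblast"
      else NA_character_
  }
  data.frame(ix = grid$ix, iy = grid$iy, iz = grid$iz, truth_label = lab,
             n_labeled = nl, stringsAsFactors = FALSE)
}

#' Cube-level classification accuracy against ground truth
#'
#' Compares the `compartment` labels of a classified cube table with the
#' per-cube majority ground-truth labels of the generating simulation.
#'
#' @param classified A classified [cube_table()] (possibly pooled over
#'   cavities).
#' @param truths Named list of `ground_truth` objects keyed by `stack_id`.
#' @return Accuracy in `[0, 1]` with attribute `n_compared`.
#' @export
cube_label_accuracy <- function(classified, truths) {
  stopifnot(inherits(classified, "cube_table"))
  r <- classified$records
  if (!"compartment" %in% names(r))
    stop("table is not classified; run classify_cubes() first")
  truth_tabs <- lapply(truths, cube_truth_labels,
                       cube_shape = classified$cube_shape)
  hits <- 0L; n <- 0L
  for (i in seq_len(nrow(r))) {
    tt <- truth_tabs[[r$stack_id[i]]]
    if (is.null(tt)) stop("no ground truth for stack_id '", r$stack_id[i], "'")
    row <- tt[tt$ix == r$ix[i] & tt$iy == r$iy[i] & tt$iz == r$iz[i], ]
    if (nrow(row) != 1L || is.na(row$truth_label)) next
    pred <- if (r$compartment[i] == "putative_cancer") "cancer"
      else "fibroblast"
    n <- n + 1L
    if (pred == row$truth_label) hits <- hits + 1L
  }
  if (n == 0L) stop("no cubes with defined ground-truth majority label")
  structure(hits / n, n_compared = n)
}
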