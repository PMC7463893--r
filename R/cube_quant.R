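# Partition a stack into the non-overlapping voxel cubes (default
# 32 x 32 x 16 in x, y, z), apply the "> 50% foreground" inclusion rule and
# average each channel over foreground voxels only.

#' Partition a volume into a grid of non-overlapping cubes
#'
#' Cubes tile the volume from voxel (0,0,0) in half-open blocks; trailing
#' margins that do not fit a full cube are dropped, so every cube has the
#' same denominator (`prod(cube_shape)` voxels).
#'
#' @param spatial_shape Integer `(Z, Y, X)` extents of the volume.
#' @param cube_shape Cube dimensions `(x, y, z)` in voxels.
#' @return Data frame with 0-based columns `ix`, `iy`, `iz` (grid index)
#'   and `z0`, `y0`, `x0` (origin voxel).
#' @examples
#' nrow(partition_grid(c(32, 64, 96)))  # 2*2*3 = 12 cubes
#' @export
partition_grid <- function(spatial_shape, cube_shape = c(32, 32, 16)) {
  stopifnot(length(spatial_shape) == 3L, length(cube_shape) == 3L,
            all(cube_shape >= 1))
  cz <- cube_shape[3L]; cy <- cube_shape[2L]; cx <- cube_shape[1L]
  nz <- spatial_shape[1L] %/% cz
  ny <- spatial_shape[2L] %/% cy
  nx <- spatial_shape[3L] %/% cx
  if (nz * ny * nx == 0L) {
    warning("volume smaller than one cube in at least one dimension; ",
            "empty partition")
    return(data.frame(ix = integer(), iy = integer(), iz = integer(),
                      z0 = integer(), y0 = integer(), x0 = integer()))
  }
  g <- expand.grid(ix = seq_len(nx) - 1L, iy = seq_len(ny) - 1L,
                   iz = seq_len(nz) - 1L)
  data.frame(ix = g$ix, iy = g$iy, iz = g$iz,
             z0 = g$iz * cz, y0 = g$iy * cy, x0 = g$ix * cx)
}

#' Quantify per-cube mean foreground intensities
#'
#' For every cube of the partition the foreground fraction is computed from
#' the mask; only cubes with *strictly more than* `min_fg_fraction`
#' foreground are retained. For retained cubes each channel's mean is taken
#' over foreground voxels only. The stack is expected to be
#' background-subtracted already (the pipeline enforces the order
#' segment -> subtract -> quantify).
#'
#' @param stack A background-subtracted [image_stack()].
#' @param mask A `foreground_mask` (or logical array) aligned to `stack`.
#' @param cube_shape Cube dimensions `(x, y, z)` in voxels.
#' @param min_fg_fraction Inclusion threshold (strict; default 0.5).
#' @param stack_id Identifier recorded per cube.
#' @param condition Culture condition label for the resulting table.
#' @return A [cube_table()].
#' @export
quantify_cubes <- function(stack, mask, cube_shape = c(32, 32, 16),
                           min_fg_fraction = 0.5, stack_id = "stack",
                           condition = "co_culture") {
  stopifnot(inherits(stack, "image_stack"))
  m <- if (inherits(mask, "foreground_mask")) mask$mask else mask
  if (!identical(dim(m), spatial_shape(stack)))
    stop("mask shape does not match stack spatial shape")
  grid <- partition_grid(spatial_shape(stack), cube_shape)
  cz <- cube_shape[3L]; cy <- cube_shape[2L]; cx <- cube_shape[1L]
  n_vox <- cx * cy * cz
  rows <- vector("list", nrow(grid))
  kept <- 0L
  for (i in seq_len(nrow(grid))) {
    z <- grid$z0[i] + seq_len(cz); y <- grid$y0[i] + seq_len(cy)
    x <- grid$x0[i] + seq_len(cx)
    mc <- m[z, y, x]
    n_fg <- sum(mc)
    if (n_fg / n_vox <= min_fg_fraction) next
    kept <- kept + 1L
    rec <- list(stack_id = stack_id, ix = grid$ix[i], iy = grid$iy[i],
                iz = grid$iz[i], fg_fraction = n_fg / n_vox,
                n_fg_voxels = n_fg)
    for (ch in seq_along(stack$channels)) {
      cube <- stack$voxels[z, y, x, ch]
      rec[[paste0("mean_", stack$channels[ch])]] <- mean(cube[mc])
    }
    rows[[kept]] <- rec
  }
  rec_df <- if (kept == 0L) {
    cols <- c(list(stack_id = character(), ix = integer(), iy = integer(),
                   iz = integer(), fg_fraction = numeric(),
                   n_fg_voxels = integer()),
              stats::setNames(rep(list(numeric()), length(stack$channels)),
                              paste0("mean_", stack$channels)))
    as.data.frame(cols, stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(rows[seq_len(kept)], as.data.frame))
  }
  cube_table(rec_df, condition, stack$channels, cube_shape)
}

#' Pool cube tables from several cavities of one condition
#'
#' @param tables List of [cube_table()] objects sharing condition, channel
#'   roles and cube shape.
#' @return A single pooled [cube_table()] with `n_cavities_pooled` equal to
#'   the total number of cavities.
#' @export
pool_cavities <- function(tables) {
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, logical(1), "cube_table")))
  if (length(tables) == 1L) return(tables[[1L]])
  cond <- unique(vapply(tables, function(t) t$condition, character(1)))
  if (length(cond) > 1L)
    stop("cannot pool cavities of different conditions: ",
         paste(cond, collapse = ", "))
  chans <- lapply(tables, function(t) t$channels)
  if (!all(vapply(chans, identical, logical(1), chans[[1L]])))
    stop("cannot pool tables with different channel role sets")
  shp <- lapply(tables, function(t) t$cube_shape)
  if (!all(vapply(shp, identical, logical(1), shp[[1L]])))
    stop("cannot pool tables with different cube shapes")
  rec <- do.call(rbind, lapply(tables, function(t) t$records))
  cube_table(rec, cond, chans[[1L]], shp[[1L]],
             n_cavities_pooled = sum(vapply(tables, function(t)
               t$n_cavities_pooled, integer(1))))
}
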