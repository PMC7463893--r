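# Cell-type-agnostic fluorescence per cubic micrometre: total foreground
# intensity of a channel divided by the physical foreground volume. No
# cube partition and no inclusion rule on this path; it deliberately
# sidesteps any skew the cube-level population split may introduce.

#' Fluorescence intensity per cubic micrometre of foreground
#'
#' Sums a channel over mask-true voxels and divides by their physical
#' volume. The denominator is the segmented foreground volume, not the
#' whole imaged volume: empty cavity space would otherwise dilute the
#' measure.
#'
#' @param stack A background-subtracted [image_stack()] with known voxel
#'   size.
#' @param mask A `foreground_mask` (or logical array) aligned to `stack`;
#'   must contain at least one foreground voxel.
#' @param role Channel role to summarise.
#' @param stack_id,condition Provenance labels carried into the result.
#' @return One-row data frame with columns `stack_id`, `condition`, `role`,
#'   `total_intensity`, `foreground_volume_um3`, `intensity_per_um3`.
#' @export
intensity_per_volume <- function(stack, mask, role, stack_id = "stack",
                                 condition = "co_culture") {
  stopifnot(inherits(stack, "image_stack"))
  m <- if (inherits(mask, "foreground_mask")) mask$mask else mask
  if (!identical(dim(m), spatial_shape(stack)))
    stop("mask shape does not match stack spatial shape")
  n_fg <- sum(m)
  if (n_fg == 0L)
    stop("empty mask: intensity per volume is undefined")
  ch <- get_channel(stack, role)
  total <- sum(ch[m])
  vol <- n_fg * prod(stack$voxel_size_um)
  data.frame(stack_id = stack_id, condition = condition, role = role,
             total_intensity = total, foreground_volume_um3 = vol,
             intensity_per_um3 = total / vol, stringsAsFactors = FALSE)
}

#' Pool volumetric results across disjoint stacks
#'
#' The pooled ratio is (sum of totals) / (sum of volumes), i.e. the
#' intensity per um3 of the union of the foregrounds.
#'
#' @param results Data frame of rows from [intensity_per_volume()] sharing
#'   one role.
#' @return One-row data frame in the same format (stack_id `"pooled"`).
#' @export
pool_volumetric <- function(results) {
  stopifnot(is.data.frame(results), nrow(results) >= 1L)
  if (length(unique(results$role)) != 1L)
    stop("cannot pool volumetric results across different roles")
  total <- sum(results$total_intensity)
  vol <- sum(results$foreground_volume_um3)
  data.frame(stack_id = "pooled", condition = results$condition[1L],
             role = results$role[1L], total_intensity = total,
             foreground_volume_um3 = vol, intensity_per_um3 = total / vol,
             stringsAsFactors = FALSE)
}
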