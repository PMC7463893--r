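#' Recognised channel roles
#'
#' Channel planes are addressed by biological role, not by index: `dapi`
#' (nuclear counterstain), `cea` (carcinoembryonic antigen, cancer-cell
#' marker), `coll4` (collagen IV, fibroblast marker), `marker` (a generic
#' third stain such as HK-2, LDH, LC3 or P62), the two CellTracker dyes and
#' `tmrm` (mitochondrial membrane-potential dye).
#'
#' @format Character vector of valid role labels.
#' @export
CHANNEL_ROLES <- c("dapi", "cea", "coll4", "marker",
                   "tracker_green", "tracker_deepred", "tmrm")

#' Construct a multichannel 3-D image stack
#'
#' The package's central container: a Z x Y x X x C array of nonnegative
#' intensities with physical voxel dimensions and one role label per
#' channel. Axis order is fixed to Z, Y, X, C throughout the package;
#' readers transpose any input dialect into it.
#'
#' @param voxels Numeric array, either Z x Y x X x C or Z x Y x X (promoted
#'   to a single channel). All values must be >= 0.
#' @param channels Character vector of role labels (see [CHANNEL_ROLES]),
#'   one per channel, no duplicates.
#' @param voxel_size_um Numeric length-3 vector `(dz, dy, dx)` in
#'   micrometres; all components > 0.
#' @return An object of class `image_stack`: a list with elements `voxels`,
#'   `channels` and `voxel_size_um`.
#' @examples
#' s <- image_stack(array(1, c(2, 8, 8, 1)), "dapi")
#' dim(s$voxels)
#' @export
image_stack <- function(voxels, channels, voxel_size_um = c(1, 1, 1)) {
  if (length(dim(voxels)) == 3L) dim(voxels) <- c(dim(voxels), 1L)
  if (length(dim(voxels)) != 4L)
    stop("`voxels` must be a Z x Y x X x C array")
  if (any(voxels < 0)) stop("intensities must be nonnegative")
  channels <- as.character(channels)
  if (length(channels) != dim(voxels)[4L])
    stop("number of channel roles (", length(channels),
         ") does not match channel extent (", dim(voxels)[4L], ")")
  bad <- setdiff(channels, CHANNEL_ROLES)
  if (length(bad))
    stop("unknown channel role(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(channels))
    stop("duplicated channel roles are not allowed")
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) != 3L || any(voxel_size_um <= 0))
    stop("`voxel_size_um` must be three positive numbers (dz, dy, dx)")
  structure(list(voxels = voxels, channels = channels,
                 voxel_size_um = voxel_size_um),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d x %d x %d voxels (Z,Y,X), %d channel(s)\n",
              d[1], d[2], d[3], d[4]))
  cat("  channels:  ", paste(x$channels, collapse = ", "), "\n", sep = "")
  cat(sprintf("  voxel size: %.3g x %.3g x %.3g um (dz,dy,dx)\n",
              x$voxel_size_um[1], x$voxel_size_um[2], x$voxel_size_um[3]))
  invisible(x)
}

#' Extract one channel of a stack as a 3-D array
#'
#' @param stack An [image_stack()].
#' @param role Channel role label present in `stack$channels`.
#' @return Numeric Z x Y x X array.
#' @export
get_channel <- function(stack, role) {
  stopifnot(inherits(stack, "image_stack"))
  i <- match(role, stack$channels)
  if (is.na(i)) stop("stack has no channel with role '", role, "'")
  ch <- stack$voxels[, , , i, drop = FALSE]
  dim(ch) <- dim(stack$voxels)[1:3]
  ch
}

#' Spatial (Z, Y, X) dimensions of a stack
#' @param stack An [image_stack()].
#' @return Integer length-3 vector.
#' @export
spatial_shape <- function(stack) dim(stack$voxels)[1:3]
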