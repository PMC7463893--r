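# 2-D monolayer quantification: regions of interest from the DAPI and CEA
# channel thresholds. The cell-type calls on real monolayers also used
# morphology by eye; here only the stated thresholds plus a dilation guard
# band are formalised, which is a documented simplification.

#' Build 2-D regions of interest from DAPI and CEA thresholds
#'
#' `cell_mask` is the Otsu segmentation of the smoothed DAPI plane;
#' `cancer_mask` is the Otsu segmentation of the smoothed CEA signal
#' restricted to the cell mask; `fibroblast_mask` is the cell mask minus
#' the cancer mask dilated by `dilation_px` (a guard band against edge
#' bleed between adjacent cells). A CEA channel with no contrast inside
#' the cell mask yields an empty cancer mask.
#'
#' @param image A single-plane [image_stack()] (Z extent 1) with `dapi`
#'   and `cea` channels.
#' @param dilation_px Guard-band dilation radius in pixels (default 2;
#'   0 disables the guard band).
#' @param sigma_px In-plane smoothing sigmas `(sx, sy)` applied to both
#'   channels before thresholding (default `c(4, 4)`).
#' @param n_bins Histogram bins for the Otsu thresholds.
#' @return Object of class `roi_set_2d`: list with logical Y x X masks
#'   `cell_mask`, `cancer_mask`, `fibroblast_mask`, plus `dilation_px` and
#'   the thresholds used.
#' @export
build_rois_2d <- function(image, dilation_px = 2, sigma_px = c(4, 4),
                          n_bins = 256) {
  stopifnot(inherits(image, "image_stack"))
  if (spatial_shape(image)[1L] != 1L)
    stop("build_rois_2d expects a single-plane stack (Z = 1)")
  sig3 <- c(sigma_px[1L], sigma_px[2L], 0)
  dyx <- spatial_shape(image)[2:3]

  dapi <- gaussian_smooth(get_channel(image, "dapi"), sig3)[1L, , ]
  dim(dapi) <- dyx
  dapi_thr <- otsu_threshold(dapi, n_bins = n_bins)
  cell <- dapi >= dapi_thr

  cea <- gaussian_smooth(get_channel(image, "cea"), sig3)[1L, , ]
  dim(cea) <- dyx
  cea_in <- cea[cell]
  cea_thr <- NA_real_
  cancer <- array(FALSE, dyx)
  if (length(cea_in) >= 2L && min(cea_in) < max(cea_in)) {
    cea_thr <- otsu_threshold(cea_in, n_bins = n_bins)
    cancer <- cell & (cea >= cea_thr)
  }
  guard <- cancer
  if (dilation_px > 0 && any(cancer)) {
    brush <- EBImage::makeBrush(2L * as.integer(dilation_px) + 1L, "disc")
    guard <- EBImage::dilate(EBImage::Image(cancer * 1), brush) > 0
    guard <- matrix(as.vector(guard), dyx[1L], dyx[2L])
  }
  structure(list(cell_mask = cell, cancer_mask = cancer,
                 fibroblast_mask = cell & !guard,
                 dilation_px = as.integer(dilation_px),
                 dapi_threshold = dapi_thr, cea_threshold = cea_thr,
                 sigma_px = as.numeric(sigma_px)),
            class = "roi_set_2d")
}

#' @export
print.roi_set_2d <- function(x, ...) {
  cat(sprintf(paste0("<roi_set_2d> cell %.1f%%, cancer %.1f%%, ",
                     "fibroblast %.1f%% of pixels (guard band %d px)\n"),
              100 * mean(x$cell_mask), 100 * mean(x$cancer_mask),
              100 * mean(x$fibroblast_mask), x$dilation_px))
  invisible(x)
}

#' Per-compartment mean marker intensity of one 2-D image
#'
#' Subtracts the background (median intensity outside the cell mask) from
#' the requested channel, clips at zero, and averages over the cancer and
#' fibroblast compartment masks. An empty compartment is reported as `NA`
#' (labelled missing), never as zero.
#'
#' @param image A single-plane [image_stack()].
#' @param rois A `roi_set_2d` from [build_rois_2d()] (or ground-truth
#'   masks packed into the same structure).
#' @param role Channel role to quantify.
#' @param subtract Subtract the background estimate before averaging
#'   (default TRUE); set FALSE to report raw compartment means.
#' @return Data frame with one row per compartment: `compartment`,
#'   `mean_intensity`, `n_pixels`.
#' @export
quantify_rois <- function(image, rois, role, subtract = TRUE) {
  stopifnot(inherits(image, "image_stack"))
  dyx <- spatial_shape(image)[2:3]
  ch <- get_channel(image, role)[1L, , ]
  dim(ch) <- dyx
  if (subtract) {
    outside <- !rois$cell_mask
    if (!any(outside))
      stop("cell mask covers the whole image: no background sample")
    ch <- pmax(ch - stats::median(ch[outside]), 0)
  }
  one <- function(mask, name) {
    n <- sum(mask)
    data.frame(compartment = name,
               mean_intensity = if (n > 0L) mean(ch[mask]) else NA_real_,
               n_pixels = n, stringsAsFactors = FALSE)
  }
  rbind(one(rois$cancer_mask, "cancer"),
        one(rois$fibroblast_mask, "fibroblast"))
}

#' Aggregate per-image compartment means to mean +/- SEM
#'
#' Replicate-level aggregation across images ("n experiments"), not across
#' pixels: each image contributes one mean per compartment.
#'
#' @param per_image_results List of data frames from [quantify_rois()].
#' @return Data frame with `compartment`, `mean`, `sem`, `n_images`
#'   (images with a missing compartment are excluded from that
#'   compartment's n).
#' @export
summarize_roi_means <- function(per_image_results) {
  df <- do.call(rbind, per_image_results)
  out <- lapply(split(df, df$compartment), function(g) {
    v <- g$mean_intensity[!is.na(g$mean_intensity)]
    n <- length(v)
    data.frame(compartment = g$compartment[1L],
               mean = if (n > 0L) mean(v) else NA_real_,
               sem = if (n > 1L) stats::sd(v) / sqrt(n) else NA_real_,
               n_images = n, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
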