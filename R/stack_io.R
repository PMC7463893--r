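# TIFF I/O.  Pages are stored z-major with channel varying fastest
# (page = z*C + c), matching the OME "XYCZT" dimension order.

.parse_ome_description <- function(desc) {
  if (is.null(desc) || !nzchar(desc) || !grepl("<OME", desc, fixed = TRUE))
    return(NULL)
  doc <- tryCatch(xml2::read_xml(desc), error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  # strip namespaces so the OME schema version does not matter
  xml2::xml_ns_strip(doc)
  px <- xml2::xml_find_first(doc, ".//Pixels")
  if (inherits(px, "xml_missing")) return(NULL)
  num_attr <- function(a) {
    v <- xml2::xml_attr(px, a)
    if (is.na(v)) NA_real_ else as.numeric(v)
  }
  list(
    physical_size_um = c(z = num_attr("PhysicalSizeZ"),
                         y = num_attr("PhysicalSizeY"),
                         x = num_attr("PhysicalSizeX")),
    size_z = num_attr("SizeZ"),
    size_c = num_attr("SizeC"),
    dimension_order = xml2::xml_attr(px, "DimensionOrder")
  )
}

.sidecar_path <- function(path) paste0(path, ".yml")

#' Read a multichannel 3-D stack from a TIFF / OME-TIFF file
#'
#' Pages are assembled into the package's fixed Z, Y, X, C axis order.
#' Voxel size is taken, in order of precedence, from OME-XML metadata in the
#' file's ImageDescription tag, from a YAML sidecar written by
#' [write_stack()], from the `voxel_size_um` argument, and finally defaults
#' to 1 um isotropic with a warning.
#'
#' @param path Path to a single- or multi-page TIFF.
#' @param channel_roles Character vector of role labels, one per channel;
#'   its length must divide the page count.
#' @param voxel_size_um Optional `(dz, dy, dx)` in micrometres, used when
#'   the file carries no voxel-size metadata.
#' @return An [image_stack()]. Integer input intensities are preserved
#'   losslessly.
#' @export
read_stack <- function(path, channel_roles, voxel_size_um = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  n_pages <- length(pages)
  nc <- length(channel_roles)
  if (n_pages %% nc != 0L)
    stop("page count (", n_pages, ") is not a multiple of the number of ",
         "channel roles (", nc, "): axes cannot be resolved")
  nz <- n_pages %/% nc

  ome <- .parse_ome_description(attr(pages[[1L]], "description"))
  z_fastest <- FALSE
  if (!is.null(ome)) {
    if (is.finite(ome$size_c) && ome$size_c != nc)
      stop("OME metadata declares ", ome$size_c, " channels but ",
           nc, " roles were given")
    if (is.finite(ome$size_z)) nz <- as.integer(ome$size_z)
    if (!is.na(ome$dimension_order) &&
        grepl("^XYZ", ome$dimension_order)) z_fastest <- TRUE
  }
  if (nz * nc != n_pages)
    stop("cannot resolve ", n_pages, " pages into Z=", nz, " x C=", nc)

  d1 <- dim(pages[[1L]])[1:2]
  vox <- array(0, c(nz, d1[1L], d1[2L], nc))
  for (p in seq_len(n_pages)) {
    if (z_fastest) {
      z <- (p - 1L) %% nz + 1L
      ch <- (p - 1L) %/% nz + 1L
    } else {
      ch <- (p - 1L) %% nc + 1L
      z <- (p - 1L) %/% nc + 1L
    }
    pg <- pages[[p]]
    if (!identical(dim(pg)[1:2], d1)) stop("pages differ in size")
    vox[z, , , ch] <- pg[, ]
  }

  vs <- NULL
  if (!is.null(ome) && any(is.finite(ome$physical_size_um))) {
    vs <- ome$physical_size_um
    fallback <- if (!is.null(voxel_size_um)) as.numeric(voxel_size_um)
                else c(1, 1, 1)
    vs[!is.finite(vs)] <- fallback[!is.finite(vs)]
  } else if (file.exists(.sidecar_path(path))) {
    sc <- yaml::read_yaml(.sidecar_path(path))
    if (!is.null(sc$voxel_size_um)) vs <- as.numeric(sc$voxel_size_um)
    if (!is.null(sc$intensity_scale)) vox <- vox * sc$intensity_scale
  }
  if (is.null(vs)) {
    if (!is.null(voxel_size_um)) {
      vs <- as.numeric(voxel_size_um)
    } else {
      warning("no voxel-size metadata found; assuming 1 um isotropic")
      vs <- c(1, 1, 1)
    }
  }
  image_stack(vox, channel_roles, unname(vs))
}

#' Write a stack as a multi-page TIFF with a YAML metadata sidecar
#'
#' Integer-valued stacks are written losslessly at 8 or 16 bit. Non-integer
#' stacks are rescaled to 16 bit; the scale factor is recorded in the
#' sidecar and reapplied by [read_stack()], so the round trip is exact up to
#' 16-bit quantisation. The sidecar (`<path>.yml`) carries channel roles and
#' voxel size.
#'
#' @param stack An [image_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  v <- stack$voxels
  d <- dim(v)
  integral <- all(v == round(v))
  scale <- NULL
  if (integral && max(v) <= 255) {
    bits <- 8L; denom <- 255
  } else if (integral && max(v) <= 65535) {
    bits <- 16L; denom <- 65535
  } else {
    bits <- 16L
    top <- max(v)
    scale <- if (top > 0) top / 65535 else 1
    v <- round(v / scale)
    denom <- 65535
  }
  pages <- vector("list", d[1L] * d[4L])
  p <- 0L
  for (z in seq_len(d[1L])) for (ch in seq_len(d[4L])) {
    p <- p + 1L
    pg <- v[z, , , ch]
    dim(pg) <- d[2:3]
    pages[[p]] <- pg / denom
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits,
                  compression = "none", reduce = FALSE)
  sc <- list(channels = as.list(stack$channels),
             voxel_size_um = as.list(stack$voxel_size_um),
             bits_per_sample = bits)
  if (!is.null(scale)) sc$intensity_scale <- scale
  yaml::write_yaml(sc, .sidecar_path(path))
  invisible(path)
}

#' Export a binary foreground mask as an 8-bit TIFF (0/255)
#'
#' @param mask A [segment_dapi()] result or a logical Z x Y x X array.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  m <- if (inherits(mask, "foreground_mask")) mask$mask else mask
  d <- dim(m)
  pages <- lapply(seq_len(d[1L]), function(z) {
    pg <- m[z, , ]
    dim(pg) <- d[2:3]
    pg * 1.0
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L,
                  compression = "none", reduce = FALSE)
  invisible(path)
}

# ---- cube tables -----------------------------------------------------------

#' Construct a cube table
#'
#' Holds the per-cube records of one or more cavities of a single culture
#' condition, after the foreground-fraction inclusion rule has been applied.
#'
#' @param records Data frame with columns `stack_id`, `ix`, `iy`, `iz`,
#'   `fg_fraction`, `n_fg_voxels` and one `mean_<role>` column per channel.
#' @param condition One of `"mono_cancer"`, `"mono_fibroblast"`,
#'   `"co_culture"`.
#' @param channels Character vector of channel roles quantified.
#' @param cube_shape Cube dimensions `(x, y, z)` in voxels.
#' @param n_cavities_pooled Number of cavities pooled into `records`.
#' @return Object of class `cube_table`.
#' @export
cube_table <- function(records, condition, channels,
                       cube_shape = c(32, 32, 16), n_cavities_pooled = 1L) {
  condition <- match.arg(condition,
                         c("mono_cancer", "mono_fibroblast", "co_culture"))
  if (n_cavities_pooled < 1L) stop("n_cavities_pooled must be positive")
  need <- c("stack_id", "ix", "iy", "iz", "fg_fraction", "n_fg_voxels",
            paste0("mean_", channels))
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack column(s): ", paste(miss, collapse = ", "))
  key <- paste(records$stack_id, records$ix, records$iy, records$iz)
  if (anyDuplicated(key)) stop("duplicate cube grid indices within a stack")
  structure(list(records = records, condition = condition,
                 channels = channels, cube_shape = as.integer(cube_shape),
                 n_cavities_pooled = as.integer(n_cavities_pooled)),
            class = "cube_table")
}

#' @export
print.cube_table <- function(x, ...) {
  cat(sprintf("<cube_table> %d cube(s), condition '%s', %d cavity(ies)\n",
              nrow(x$records), x$condition, x$n_cavities_pooled))
  cat("  cube shape (x,y,z): ", paste(x$cube_shape, collapse = " x "),
      " voxels\n", sep = "")
  cat("  channels: ", paste(x$channels, collapse = ", "), "\n", sep = "")
  if ("compartment" %in% names(x$records)) {
    tb <- table(x$records$compartment)
    cat("  compartments: ",
        paste(sprintf("%s n=%d", names(tb), as.integer(tb)), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Write a cube table to CSV
#'
#' Columns: `stack_id`, `condition`, `ix`, `iy`, `iz`, `fg_fraction`, then
#' one mean-intensity column per channel role. Numbers are serialised at
#' full double precision so that [read_cube_table()] reproduces the table
#' exactly.
#'
#' @param table A [cube_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cube_table <- function(table, path) {
  stopifnot(inherits(table, "cube_table"))
  r <- table$records
  out <- data.frame(stack_id = r$stack_id,
                    condition = rep(table$condition, nrow(r)),
                    ix = r$ix, iy = r$iy, iz = r$iz,
                    fg_fraction = sprintf("%.17g", r$fg_fraction),
                    stringsAsFactors = FALSE)
  for (ch in table$channels)
    out[[paste0("mean_", ch)]] <- sprintf("%.17g", r[[paste0("mean_", ch)]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cube table written by [write_cube_table()]
#'
#' @param path CSV path.
#' @param cube_shape Cube dimensions `(x, y, z)` used when the table was
#'   built (the CSV stores fractions; voxel counts are recovered from them).
#' @return A [cube_table()].
#' @export
read_cube_table <- function(path, cube_shape = c(32, 32, 16)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  roles <- sub("^mean_", "", grep("^mean_", names(df), value = TRUE))
  cond <- unique(df$condition)
  if (length(cond) > 1L) stop("mixed conditions in one cube-table file")
  if (nrow(df) == 0L) cond <- "co_culture"
  rec <- df[setdiff(names(df), "condition")]
  rec$n_fg_voxels <- as.integer(round(rec$fg_fraction * prod(cube_shape)))
  n_cav <- max(1L, length(unique(df$stack_id)))
  cube_table(rec, cond, roles, cube_shape, n_cavities_pooled = n_cav)
}
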