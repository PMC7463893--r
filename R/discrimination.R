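# Population discrimination at the cube level: the CEA reference threshold
# derived from fibroblast mono-cultures (the "red line" of the scatter
# plots) and the resulting putative cancer / fibroblast split.

#' Compute the mono-culture CEA reference threshold
#'
#' The cutoff is the intensity bounding a fraction `q` (default 95%) of all
#' fibroblast mono-culture cubes: the nearest-rank-above quantile, i.e. the
#' `ceiling(q * n)`-th order statistic of the cube CEA means. Being an
#' observed cube value, the realised coverage (fraction of cubes at or
#' below the cutoff) is always >= `q`.
#'
#' @param mono_fibroblast_table A [cube_table()] with condition
#'   `mono_fibroblast` and a `cea` channel.
#' @param q Coverage fraction in (0, 1); default 0.95.
#' @return Object of class `reference_threshold`: list with `cea_cutoff`,
#'   `coverage`, `q`, `source_condition`, `n_cubes`, `quantile_method`.
#' @export
compute_reference_threshold <- function(mono_fibroblast_table, q = 0.95) {
  t <- mono_fibroblast_table
  stopifnot(inherits(t, "cube_table"), q > 0, q < 1)
  if (t$condition != "mono_fibroblast")
    stop("reference threshold must come from a mono_fibroblast table, got '",
         t$condition, "'")
  if (!"cea" %in% t$channels) stop("table has no cea channel")
  v <- t$records$mean_cea
  n <- length(v)
  if (n == 0L) stop("empty cube table")
  if (n < 20L)
    warning("only ", n, " cubes: the ", q, " quantile is unstable")
  cutoff <- sort(v)[ceiling(q * n)]
  structure(list(cea_cutoff = cutoff, coverage = mean(v <= cutoff), q = q,
                 source_condition = t$condition, n_cubes = n,
                 quantile_method = "nearest_rank_above"),
            class = "reference_threshold")
}

#' @export
print.reference_threshold <- function(x, ...) {
  cat(sprintf(paste0("<reference_threshold> CEA cutoff %.6g ",
                     "(coverage %.4f of %d %s cubes, %s)\n"),
              x$cea_cutoff, x$coverage, x$n_cubes, x$source_condition,
              x$quantile_method))
  invisible(x)
}

#' Save / load a reference threshold as YAML
#' @param ref A `reference_threshold`.
#' @param path YAML file path.
#' @return `path` invisibly, or the reloaded `reference_threshold`.
#' @export
write_reference_threshold <- function(ref, path) {
  stopifnot(inherits(ref, "reference_threshold"))
  yaml::write_yaml(unclass(ref), path)
  invisible(path)
}

#' @rdname write_reference_threshold
#' @export
read_reference_threshold <- function(path) {
  structure(yaml::read_yaml(path), class = "reference_threshold")
}

#' Classify cubes against the CEA reference threshold
#'
#' Cubes whose mean CEA intensity exceeds the cutoff are labelled
#' `putative_cancer`; cubes at or below it (the "contains 95%" side) are
#' `putative_fibroblast`. Labels are added as a `compartment` column; all
#' original fields are untouched. Because the split can be skewed towards
#' the cancer population, compartment sizes are always reported alongside
#' (see `print.cube_table`).
#'
#' @param table A [cube_table()] with a `cea` channel.
#' @param ref A `reference_threshold`.
#' @return The table with a `compartment` column added to its records.
#' @export
classify_cubes <- function(table, ref) {
  stopifnot(inherits(table, "cube_table"),
            inherits(ref, "reference_threshold"))
  if (!"cea" %in% table$channels) stop("table has no cea channel")
  table$records$compartment <-
    ifelse(table$records$mean_cea > ref$cea_cutoff,
           "putative_cancer", "putative_fibroblast")
  table$reference <- ref
  table
}

#' Compartment sizes of a classified cube table
#' @param table A classified [cube_table()].
#' @return Named integer vector (cubes per compartment).
#' @export
compartment_sizes <- function(table) {
  stopifnot(inherits(table, "cube_table"))
  if (!"compartment" %in% names(table$records))
    stop("table is not classified; run classify_cubes() first")
  tb <- table(factor(table$records$compartment,
                     levels = c("putative_fibroblast", "putative_cancer")))
  stats::setNames(as.integer(tb), names(tb))
}

#' Export cube-level scatter data (marker vs CEA)
#'
#' One row per cube with x, y and colour values, mirroring the
#' marker-versus-CEA scatter plots with the red reference line.
#'
#' @param table A [cube_table()] (classified or not).
#' @param y_role Channel role plotted on y.
#' @param x_role Channel role on x (default `cea`).
#' @param color_role Channel role colouring the points (default `dapi`).
#' @param ref Optional `reference_threshold`; drawn as a vertical line.
#' @param path Optional CSV output path.
#' @param plot_file Optional PNG output path (plots are convenience, not
#'   contract).
#' @return Data frame with columns `stack_id`, `x`, `y`, `color` and, when
#'   present, `compartment`.
#' @export
export_scatter <- function(table, y_role, x_role = "cea",
                           color_role = "dapi", ref = NULL, path = NULL,
                           plot_file = NULL) {
  stopifnot(inherits(table, "cube_table"))
  for (role in c(x_role, y_role, color_role))
    if (!role %in% table$channels)
      stop("table has no channel with role '", role, "'")
  r <- table$records
  out <- data.frame(stack_id = r$stack_id,
                    x = r[[paste0("mean_", x_role)]],
                    y = r[[paste0("mean_", y_role)]],
                    color = r[[paste0("mean_", color_role)]],
                    stringsAsFactors = FALSE)
  if ("compartment" %in% names(r)) out$compartment <- r$compartment
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  if (!is.null(plot_file) && nrow(out) > 0L) {
    grDevices::png(plot_file, width = 700, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
    pal <- grDevices::hcl.colors(64, "viridis")
    idx <- if (max(out$color) > min(out$color))
      1L + as.integer(63 * (out$color - min(out$color)) /
                        (max(out$color) - min(out$color)))
    else rep(1L, nrow(out))
    graphics::plot(out$x, out$y, col = pal[idx], pch = 16,
                   xlab = paste("mean", x_role, "intensity"),
                   ylab = paste("mean", y_role, "intensity"),
                   main = sprintf("%s vs %s (colour: %s)", y_role, x_role,
                                  color_role))
    if (!is.null(ref))
      graphics::abline(v = ref$cea_cutoff, col = "red", lwd = 2)
  }
  out
}
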