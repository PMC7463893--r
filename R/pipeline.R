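# End-to-end orchestration: generate (or load) -> segment -> subtract ->
# cube-quantify -> discriminate -> summarize, with a manifest that makes a
# run reproducible from its seed and parameters alone.

#' Build a run configuration
#'
#' All analysis parameters default to the reference settings: smoothing
#' sigmas `(4, 4, 0)` px, 256 histogram bins, `32 x 32 x 16` cubes, strict
#' 0.5 foreground inclusion, 0.95 reference quantile, PSF block 3 px, 10
#' randomizations, 5 cavities per condition.
#'
#' @param seed Master seed for every source of randomness.
#' @param out_dir Output directory for [run_pipeline()].
#' @param conditions Conditions to simulate and analyse.
#' @param shape Per-cavity extents `(Z, Y, X)` voxels.
#' @param n_cavities Cavities per condition.
#' @param n_total_nuclei Per-cavity total nuclei (NULL = density default).
#' @param channels Channel roles to simulate.
#' @param mixing Placement mode; NULL (default) lets each condition pick
#'   its own (mono interspersed, co-culture islets).
#' @param sigma_px Segmentation smoothing sigmas `(sx, sy, sz)`.
#' @param n_bins Otsu histogram bins.
#' @param cube_shape Cube dimensions `(x, y, z)`.
#' @param min_fg_fraction Strict cube inclusion threshold.
#' @param q Reference-threshold coverage fraction.
#' @param psf_block_px Costes randomization block edge.
#' @param n_randomizations Costes randomizations.
#' @param write_stacks Also write the generated stacks as TIFF (slower).
#' @return Object of class `run_config` (a named list; round-trips
#'   losslessly through YAML via [write_run_config()]).
#' @export
run_config <- function(seed = 1, out_dir = tempfile("voxcube_run_"),
                       conditions = c("mono_cancer", "mono_fibroblast",
                                      "co_culture"),
                       shape = c(32, 192, 192), n_cavities = 5,
                       n_total_nuclei = NULL,
                       channels = c("dapi", "cea", "coll4"),
                       mixing = NULL,
                       sigma_px = c(4, 4, 0), n_bins = 256,
                       cube_shape = c(32, 32, 16), min_fg_fraction = 0.5,
                       q = 0.95, psf_block_px = 3, n_randomizations = 10,
                       write_stacks = FALSE) {
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 conditions = conditions, shape = as.integer(shape),
                 n_cavities = as.integer(n_cavities),
                 n_total_nuclei = n_total_nuclei, channels = channels,
                 mixing = mixing, sigma_px = as.numeric(sigma_px),
                 n_bins = as.integer(n_bins),
                 cube_shape = as.integer(cube_shape),
                 min_fg_fraction = min_fg_fraction, q = q,
                 psf_block_px = as.integer(psf_block_px),
                 n_randomizations = as.integer(n_randomizations),
                 write_stacks = isTRUE(write_stacks)),
            class = "run_config")
}

#' Save / load a run configuration as YAML
#' @param config A `run_config`.
#' @param path YAML file path.
#' @return `path` invisibly, or the reloaded `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  cfg <- unclass(config)
  cfg$out_dir <- NULL   # location is not part of the analysis identity
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$out_dir)) raw$out_dir <- tempfile("voxcube_run_")
  raw$shape <- as.integer(unlist(raw$shape))
  raw$sigma_px <- as.numeric(unlist(raw$sigma_px))
  raw$cube_shape <- as.integer(unlist(raw$cube_shape))
  raw$conditions <- as.character(unlist(raw$conditions))
  raw$channels <- as.character(unlist(raw$channels))
  structure(raw, class = "run_config")
}

.stage <- function(name, stack_id, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s | %s] %s", name, stack_id,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline on synthetic condition sets
#'
#' For each configured condition: generate `n_cavities` seeded cavities,
#' segment the DAPI channel, subtract background, quantify voxel cubes and
#' pool the cavities. If a `mono_fibroblast` condition is present, the CEA
#' reference threshold is computed from it and every pooled table is
#' classified against it. Volumetric (per-um3) intensities are computed
#' per cavity for every non-DAPI channel. All tabular outputs, the
#' reference threshold, a condition summary and a manifest (parameters,
#' seed, versions, output hashes) are written under `config$out_dir`.
#' Rerunning the same config reproduces every output bit-identically.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the pooled (classified) tables, the
#'   reference threshold, volumetric results, ground truths, the summary
#'   data frame and the manifest path.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  tables <- list(); truths <- list(); vol_rows <- list()
  for (cond in config$conditions) {
    cavs <- .stage("synthetic_stacks", cond,
      generate_condition_set(cond, n_cavities = config$n_cavities,
                             shape = config$shape,
                             n_total_nuclei = config$n_total_nuclei,
                             channels = config$channels,
                             mixing = config$mixing, seed = config$seed))
    cav_tables <- vector("list", length(cavs))
    for (i in seq_along(cavs)) {
      cv <- cavs[[i]]
      truths[[cv$stack_id]] <- cv$truth
      mask <- .stage("segmentation", cv$stack_id,
                     segment_dapi(cv$stack, sigma_px = config$sigma_px,
                                  n_bins = config$n_bins))
      sub <- .stage("segmentation", cv$stack_id,
                    subtract_background(cv$stack, mask))
      cav_tables[[i]] <- .stage("cube_quant", cv$stack_id,
        quantify_cubes(sub, mask, cube_shape = config$cube_shape,
                       min_fg_fraction = config$min_fg_fraction,
                       stack_id = cv$stack_id, condition = cond))
      for (role in setdiff(config$channels, "dapi"))
        vol_rows[[length(vol_rows) + 1L]] <- .stage(
          "volumetric_intensity", cv$stack_id,
          intensity_per_volume(sub, mask, role, stack_id = cv$stack_id,
                               condition = cond))
      if (config$write_stacks)
        write_stack(cv$stack,
                    file.path(config$out_dir,
                              paste0(cv$stack_id, ".tif")))
    }
    tables[[cond]] <- .stage("cube_quant", cond, pool_cavities(cav_tables))
  }
  volumetric <- do.call(rbind, vol_rows)

  ref <- NULL
  if ("mono_fibroblast" %in% names(tables) &&
      "cea" %in% config$channels) {
    ref <- .stage("discrimination", "mono_fibroblast",
                  compute_reference_threshold(tables$mono_fibroblast,
                                              q = config$q))
    write_reference_threshold(ref,
      file.path(config$out_dir, "reference_threshold.yml"))
    for (cond in names(tables))
      tables[[cond]] <- classify_cubes(tables[[cond]], ref)
  }
  for (cond in names(tables))
    write_cube_table(tables[[cond]],
                     file.path(config$out_dir,
                               paste0("cubes_", cond, ".csv")))
  if (!is.null(volumetric))
    utils::write.csv(volumetric,
                     file.path(config$out_dir, "volumetric.csv"),
                     row.names = FALSE)
  summary_df <- summarize_conditions(tables, volumetric)
  utils::write.csv(summary_df, file.path(config$out_dir, "summary.csv"),
                   row.names = FALSE)
  write_run_config(config, file.path(config$out_dir, "config.yml"))

  outputs <- sort(setdiff(list.files(config$out_dir), "manifest.yml"))
  hashes <- as.list(tools::md5sum(file.path(config$out_dir, outputs)))
  names(hashes) <- outputs
  manifest <- list(package = "voxcube",
                   version = as.character(utils::packageVersion("voxcube")),
                   seed = config$seed,
                   parameters = unclass(config),
                   outputs = hashes)
  manifest_path <- file.path(config$out_dir, "manifest.yml")
  yaml::write_yaml(manifest, manifest_path)
  invisible(list(tables = tables, reference = ref,
                 volumetric = volumetric, truths = truths,
                 summary = summary_df, manifest = manifest_path))
}

#' Condition-level summary of cube tables and volumetric results
#'
#' Per condition: cube counts, cavities pooled, compartment sizes (when
#' classified), per-channel median cube intensity, and the mean +/- SEM
#' across cavities of each channel's intensity per um3. The result is
#' independent of cavity order; SEM is `NA` for a single cavity.
#'
#' @param tables Named list of (classified) [cube_table()] objects, keyed
#'   by condition.
#' @param volumetric Data frame of [intensity_per_volume()] rows, or NULL.
#' @return Data frame with one row per condition and channel role.
#' @export
summarize_conditions <- function(tables, volumetric = NULL) {
  stopifnot(length(tables) >= 1L)
  rows <- list()
  for (cond in sort(names(tables))) {
    t <- tables[[cond]]
    cs <- if ("compartment" %in% names(t$records)) compartment_sizes(t)
      else c(putative_fibroblast = NA_integer_,
             putative_cancer = NA_integer_)
    for (role in t$channels) {
      med <- stats::median(t$records[[paste0("mean_", role)]])
      vm <- NA_real_; vs <- NA_real_
      if (!is.null(volumetric)) {
        v <- volumetric$intensity_per_um3[volumetric$condition == cond &
                                            volumetric$role == role]
        if (length(v) > 0L) vm <- mean(v)
        if (length(v) > 1L) vs <- stats::sd(v) / sqrt(length(v))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, role = role, n_cubes = nrow(t$records),
        n_cavities = t$n_cavities_pooled,
        n_putative_fibroblast = cs[["putative_fibroblast"]],
        n_putative_cancer = cs[["putative_cancer"]],
        median_cube_intensity = med,
        mean_intensity_per_um3 = vm, sem_intensity_per_um3 = vs,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
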