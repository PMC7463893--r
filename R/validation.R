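# Seeded validation experiments that exercise the whole pipeline on the
# synthetic study conditions: the CEA-contrast recovery panel, the
# autophagy-marker volumetric comparison and the tracker/TMRM
# colocalization ordering. These are the package's sensitivity checks --
# they validate that the pipeline recovers contrasts it is fed, not any
# biological claim.

.process_cavity <- function(cv, cond, sigma_px = c(4, 4, 0),
                            cube_shape = c(32, 32, 16),
                            min_fg_fraction = 0.5) {
  m <- segment_dapi(cv$stack, sigma_px = sigma_px)
  s <- subtract_background(cv$stack, m)
  quantify_cubes(s, m, cube_shape = cube_shape,
                 min_fg_fraction = min_fg_fraction,
                 stack_id = cv$stack_id, condition = cond)
}

#' CEA-contrast classification recovery panel
#'
#' For each seed and CEA contrast level: simulates a fibroblast
#' mono-culture cavity (reference) and a co-culture cavity whose cancer
#' population expresses CEA at `contrast` times the fibroblast level (mean
#' scaled, per-cell spread held at the default), runs the full
#' segment/subtract/quantify/classify pipeline, and scores cube labels
#' against the ground-truth majority.
#'
#' @param seeds Integer vector of panel seeds.
#' @param contrasts CEA contrast ratios to test (default `c(2, 4, 8)`).
#' @param shape Per-cavity extents `(Z, Y, X)`.
#' @param fibroblast_cea Fibroblast CEA `c(mean, sd)`; the cancer mean is
#'   `contrast * fibroblast_cea[1]`.
#' @param cancer_cea_sd Per-cell spread of cancer CEA, fixed across
#'   contrasts.
#' @return Data frame with columns `contrast`, `seed`, `accuracy`,
#'   `n_cubes`.
#' @export
cea_contrast_panel <- function(seeds, contrasts = c(2, 4, 8),
                               shape = c(32, 128, 128),
                               fibroblast_cea = c(30, 15),
                               cancer_cea_sd = 60) {
  rows <- list()
  for (seed in seeds) {
    ref_cav <- generate_condition_set("mono_fibroblast", n_cavities = 1,
                                      shape = shape, seed = seed)
    ref_tab <- pool_cavities(lapply(ref_cav, .process_cavity,
                                    cond = "mono_fibroblast"))
    ref <- compute_reference_threshold(ref_tab)
    for (ct in contrasts) {
      can <- cancer_population(0, channel_levels = list(
        cea = c(ct * fibroblast_cea[1L], cancer_cea_sd),
        coll4 = c(30, 15)))
      co_cav <- generate_condition_set("co_culture", n_cavities = 1,
                                       shape = shape, seed = seed + 500,
                                       cancer = can)
      co_tab <- pool_cavities(lapply(co_cav, .process_cavity,
                                     cond = "co_culture"))
      cl <- classify_cubes(co_tab, ref)
      truths <- stats::setNames(lapply(co_cav, `[[`, "truth"),
                                vapply(co_cav, `[[`, character(1),
                                       "stack_id"))
      acc <- cube_label_accuracy(cl, truths)
      rows[[length(rows) + 1L]] <- data.frame(
        contrast = ct, seed = seed, accuracy = as.numeric(acc),
        n_cubes = attr(acc, "n_compared"))
    }
  }
  do.call(rbind, rows)
}

#' Volumetric autophagy-marker comparison (co-culture vs fibroblast mono)
#'
#' Simulates the study contrast in which an autophagy-type marker is
#' expressed moderately in mono-cultured fibroblasts and strongly in
#' co-culture, and measures the pooled cell-type-agnostic intensity per
#' cubic micrometre of the marker channel in both conditions.
#'
#' @param seed Master seed.
#' @param n_cavities Cavities per condition.
#' @param shape Per-cavity extents `(Z, Y, X)`.
#' @param mono_marker,co_fibro_marker,co_cancer_marker Marker levels
#'   `c(mean, sd)` for the three cell populations involved.
#' @return Data frame with one row per condition: `condition`,
#'   `intensity_per_um3`.
#' @export
marker_volumetric_comparison <- function(seed, n_cavities = 2,
                                         shape = c(32, 128, 128),
                                         mono_marker = c(40, 10),
                                         co_fibro_marker = c(100, 25),
                                         co_cancer_marker = c(60, 15)) {
  channels <- c("dapi", "cea", "marker")
  one_condition <- function(cond, fib_marker, can_marker, seed_off) {
    fib <- fibroblast_population(0, channel_levels = list(
      cea = c(30, 15), marker = fib_marker))
    can <- cancer_population(0, channel_levels = list(
      cea = c(120, 60), marker = can_marker))
    cavs <- generate_condition_set(cond, n_cavities = n_cavities,
                                   shape = shape, seed = seed + seed_off,
                                   cancer = can, fibroblast = fib,
                                   channels = channels)
    res <- lapply(cavs, function(cv) {
      m <- segment_dapi(cv$stack)
      s <- subtract_background(cv$stack, m)
      intensity_per_volume(s, m, "marker", stack_id = cv$stack_id,
                           condition = cond)
    })
    pool_volumetric(do.call(rbind, res))
  }
  mono <- one_condition("mono_fibroblast", mono_marker, NULL, 0L)
  co <- one_condition("co_culture", co_fibro_marker, co_cancer_marker,
                      1000L)
  data.frame(condition = c(mono$condition, co$condition),
             intensity_per_um3 = c(mono$intensity_per_um3,
                                   co$intensity_per_um3),
             stringsAsFactors = FALSE)
}

#' Tracker/TMRM colocalization ordering on a live-imaging co-culture
#'
#' Simulates the live-cell design: cancer cells carry the green
#' CellTracker and a strong TMRM-like mitochondrial signal, fibroblasts
#' carry the deep-red CellTracker and almost no TMRM. Returns the
#' thresholded Pearson correlation of TMRM with each tracker.
#'
#' @param seed Master seed.
#' @param shape Per-cavity extents `(Z, Y, X)`.
#' @param n_randomizations Randomizations for the significance test of the
#'   green-tracker correlation.
#' @param run_test Also run the block-randomization significance test on
#'   the green-tracker pair (default TRUE; set FALSE when only the two
#'   correlations are needed).
#' @return List with `r_green` (tracker_green vs tmrm), `r_deepred`
#'   (tracker_deepred vs tmrm) and `green_test` (a `coloc_result`, or NULL
#'   when `run_test = FALSE`).
#' @export
tracker_tmrm_correlations <- function(seed, shape = c(16, 96, 96),
                                      n_randomizations = 10,
                                      run_test = TRUE) {
  channels <- c("dapi", "tracker_green", "tracker_deepred", "tmrm")
  can <- cancer_population(0, channel_levels = list(
    tracker_green = c(120, 20), tmrm = c(100, 40)))
  fib <- fibroblast_population(0, channel_levels = list(
    tracker_deepred = c(120, 20), tmrm = c(6, 3)))
  cav <- generate_condition_set("co_culture", n_cavities = 1,
                                shape = shape, seed = seed, cancer = can,
                                fibroblast = fib,
                                channels = channels)[[1L]]
  tmrm <- get_channel(cav$stack, "tmrm")
  ctg <- get_channel(cav$stack, "tracker_green")
  ctdr <- get_channel(cav$stack, "tracker_deepred")
  r_g <- pearson_above_threshold(ctg, tmrm, costes_thresholds(ctg, tmrm))
  r_dr <- pearson_above_threshold(ctdr, tmrm,
                                  costes_thresholds(ctdr, tmrm))
  test <- if (run_test)
    coloc_randomization_test(ctg, tmrm,
                             n_randomizations = n_randomizations,
                             seed = seed)
  list(r_green = as.numeric(r_g), r_deepred = as.numeric(r_dr),
       green_test = test)
}
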