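#' Experiment configuration
#'
#' Bundles every knob of one experiment into a serialisable object. The
#' default grids are the desk-scale profile used throughout the package's
#' examples and checks: phantom experiments reconstruct on a 64^3 grid at
#' 9.6 mm (the clinical 128^3 / 4.8 mm grid downsampled by two, same 614 mm
#' field of view, so the 450 mm table fits) with the CT at 3.2 mm in-plane;
#' cohort studies reconstruct on 80 x 80 x 40 voxels at 6 mm. Full-resolution
#' grids are a configuration choice away.
#'
#' @param experiment `"qc_phantom"`, `"mpi_phantom"` or `"cohort"`.
#' @param seed integer seed controlling every random draw.
#' @param n_studies cohort size (cohort experiment only).
#' @param table a [table_model()].
#' @param phantom a [phantom_spec()] (phantom experiments).
#' @param ranges cohort sampling ranges ([cohort_ranges()]).
#' @param noise a [noise_model()]; disabled by default so runs are exactly
#'   reproducible.
#' @param recon a [recon_params()].
#' @param removal a [table_removal_params()].
#' @param calib a [mu_calibration()].
#' @param windows an [energy_windows()].
#' @param spect_grid,ct_grid [grid_spec()]s; `NULL` picks the profile above.
#' @param mask_frac support mask threshold for [percentage_difference()].
#' @param output_dir directory for artefacts (volumes, figures, manifest),
#'   or `NULL` to keep everything in memory.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(experiment = c("qc_phantom", "mpi_phantom", "cohort"),
                              seed = 1L, n_studies = 19L,
                              table = table_model(), phantom = phantom_spec(),
                              ranges = cohort_ranges(),
                              noise = noise_model(enabled = FALSE),
                              recon = recon_params(),
                              removal = table_removal_params(),
                              calib = mu_calibration(),
                              windows = energy_windows(),
                              spect_grid = NULL, ct_grid = NULL,
                              mask_frac = 0.05, output_dir = NULL) {
  experiment <- match.arg(experiment)
  # patient studies are count-limited: the cohort defaults to Poisson noise
  # at a typical study count level, phantom runs to noiseless (reproducible
  # bit for bit)
  if (missing(noise) && experiment == "cohort")
    noise <- noise_model(enabled = TRUE, total_expected_counts = 5e5)
  if (is.null(spect_grid))
    spect_grid <- if (experiment == "cohort")
      grid_spec(c(68, 68, 32), c(7.5, 7.5, 7.5)) else
      grid_spec(c(64, 64, 64), c(9.6, 9.6, 9.6))
  if (is.null(ct_grid))
    ct_grid <- if (experiment == "cohort")
      grid_spec(c(160, 160, 32), c(3.2, 3.2, 7.5)) else
      grid_spec(c(192, 192, 64), c(3.2, 3.2, 9.6))
  structure(list(experiment = experiment, seed = as.integer(seed),
                 n_studies = as.integer(n_studies), table = table,
                 phantom = phantom, ranges = ranges, noise = noise,
                 recon = recon, removal = removal, calib = calib,
                 windows = windows, spect_grid = spect_grid,
                 ct_grid = ct_grid, mask_frac = mask_frac,
                 output_dir = output_dir), class = "experiment_config")
}

# recursively drop S3 classes so configs serialise as plain lists
strip_s3 <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_s3) else x
}

#' Serialise an experiment configuration to YAML (and back)
#'
#' @param cfg an [experiment_config()].
#' @param path YAML file path.
#' @return `read_config()` returns an [experiment_config()] equal to the one
#'   written.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(strip_s3(cfg), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  gs <- function(g) grid_spec(g$shape, g$spacing_mm, g$origin_mm)
  experiment_config(
    experiment = raw$experiment, seed = raw$seed, n_studies = raw$n_studies,
    table = do.call(table_model, raw$table),
    phantom = do.call(phantom_spec, raw$phantom),
    ranges = raw$ranges,
    noise = do.call(noise_model, raw$noise),
    recon = do.call(recon_params, raw$recon),
    removal = do.call(table_removal_params, raw$removal),
    calib = do.call(mu_calibration, raw$calib),
    windows = do.call(energy_windows, raw$windows),
    spect_grid = gs(raw$spect_grid), ct_grid = gs(raw$ct_grid),
    mask_frac = raw$mask_frac,
    output_dir = raw$output_dir)
}

# write the manifest + NIfTI artefacts of an experiment; partial outputs are
# removed if any write fails
write_artifacts <- function(dir, cfg, volumes, figures = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written))
  manifest <- list(config = strip_s3(cfg),
                   package_version = as.character(utils::packageVersion("spectable")),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, null = "null",
                       digits = NA)
  written <- c(written, mf)
  for (nm in names(volumes)) {
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    write_volume(volumes[[nm]], p)
    written <- c(written, p)
  }
  for (nm in names(figures)) {
    p <- file.path(dir, paste0(nm, ".png"))
    png(p, width = 1400, height = 500, res = 120)
    tryCatch(figures[[nm]](), finally = dev.off())
    written <- c(written, p)
  }
  ok <- TRUE
  invisible(written)
}

#' Run a phantom experiment end to end
#'
#' Generates the phantom with the table, simulates projections through the
#' true attenuation map, applies the noise/scatter model and the
#' energy-window scatter correction, reconstructs both attenuation-correction
#' arms (table in / table stripped from the CT), and quantifies the
#' difference. Noiseless runs are exactly reproducible.
#'
#' @param cfg an [experiment_config()] with experiment `"qc_phantom"` or
#'   `"mpi_phantom"`.
#' @return An object of class `phantom_experiment`: the study, the
#'   reconstruction pair, the [percentage_difference()] `diff`, the removal
#'   sensitivity/specificity report and the per-angle count-reduction
#'   profile.
#' @export
run_phantom_experiment <- function(cfg = experiment_config("qc_phantom")) {
  if (!cfg$experiment %in% c("qc_phantom", "mpi_phantom"))
    stop("cfg$experiment must be qc_phantom or mpi_phantom")
  protocol <- acquisition_protocol(if (cfg$experiment == "qc_phantom") "qc" else "mpi")
  study <- generate_jaszczak(cfg$phantom, cfg$table, cfg$ct_grid, cfg$spect_grid)
  mu_true <- resample_to_grid(hu_to_mu(study$ct, cfg$calib), cfg$spect_grid)
  projs <- forward_project(study$activity, mu_true, protocol)
  projs <- add_noise_and_scatter(projs, cfg$noise)
  projs <- scatter_correct(projs, cfg$windows)
  pair <- reconstruct_pair(projs, study$ct, cfg$removal, cfg$calib,
                           cfg$recon, cfg$spect_grid)
  diff <- percentage_difference(pair$with_table, pair$without_table,
                                cfg$mask_frac)
  report <- if (sum(study$truth$table_mask) > 0)
    removal_report(pair$removal, study$truth) else NULL
  reduction <- if (sum(study$truth$table_mask) > 0) {
    mu_wo <- resample_to_grid(hu_to_mu(pair$removal$ct_without_table,
                                       cfg$calib), cfg$spect_grid)
    count_reduction_profile(study$activity, mu_true, mu_wo, protocol)
  } else NULL
  out <- structure(list(cfg = cfg, protocol = protocol, study = study,
                        projections = projs, pair = pair, diff = diff,
                        removal_report = report,
                        count_reduction = reduction),
                   class = "phantom_experiment")
  if (!is.null(cfg$output_dir))
    write_artifacts(cfg$output_dir, cfg,
                    list(ct = study$ct, activity = study$activity,
                         recon_with_table = pair$with_table,
                         recon_without_table = pair$without_table,
                         pct_diff = voxel_volume(diff$pct_diff, diff$grid)),
                    list(difference = function() plot(out)))
  out
}

#' @export
print.phantom_experiment <- function(x, ...) {
  cat(sprintf("phantom_experiment [%s]: max |pct diff| = %.2f%%",
              x$cfg$experiment, x$diff$max_abs_pct))
  if (!is.null(x$count_reduction))
    cat(sprintf(", mean count reduction = %.2f%%",
                100 * mean(x$count_reduction)))
  cat("\n")
  if (!is.null(x$removal_report))
    cat(sprintf("  table removal sensitivity %.3f, specificity %.3f\n",
                x$removal_report$sensitivity, x$removal_report$specificity))
  invisible(x)
}

#' Side-by-side display of the two arms and their percentage difference
#'
#' Shows the axial slice holding the largest percentage difference; the
#' difference panel's colour scale is annotated at the observed maximum.
#'
#' @param x a `phantom_experiment`.
#' @param ... ignored.
#' @export
plot.phantom_experiment <- function(x, ...) {
  k <- x$diff$argmax_slice
  op <- par(mfrow = c(1, 3), mar = c(1, 1, 2, 4)); on.exit(par(op))
  sh <- function(v, main, pal) {
    image(v[, dim(v)[2]:1], col = pal, axes = FALSE, main = main, asp = 1)
  }
  pal <- hcl.colors(64, "Inferno")
  sh(x$pair$with_table$values[, , k], "AC with table", pal)
  sh(x$pair$without_table$values[, , k], "AC without table", pal)
  sh(x$diff$pct_diff[, , k], sprintf("pct difference (slice %d)", k),
     hcl.colors(64, "Blue-Red 3"))
  mtext(sprintf("max = %.1f%%", x$diff$max_abs_pct), side = 4, line = 1)
  invisible(x)
}

# full processing of one cardiac study: returns scores for both arms and the
# polar maps
process_cardiac_study <- function(spec, cfg, seed) {
  study <- generate_cardiac_study(spec, cfg$table, cfg$ct_grid,
                                  cfg$spect_grid, seed = seed)
  protocol <- acquisition_protocol("mpi")
  mu_true <- resample_to_grid(hu_to_mu(study$ct, cfg$calib), cfg$spect_grid)
  projs <- forward_project(study$activity, mu_true, protocol,
                           center = study$truth$lv_center[1:2])
  noise <- cfg$noise
  noise$seed <- as.integer(seed)  # independent counting noise per study
  projs <- add_noise_and_scatter(projs, noise)
  projs <- scatter_correct(projs, cfg$windows)
  pair <- reconstruct_pair(projs, study$ct, cfg$removal, cfg$calib,
                           cfg$recon, cfg$spect_grid)
  # sample from the middle of the apical cap to just inside the basal cut so
  # every slice's rays cross myocardium
  c_out <- study$truth$lv_long_semi_axis
  c_in <- spec$lv_inner_axes_mm[3]
  geom <- list(apex_z_mm = -(c_out + c_in) / 2, base_z_mm = 0.2 * c_out,
               max_radius_mm = max(spec$lv_outer_axes_mm[1:2]) + 10)
  pm <- lapply(pair[c("with_table", "without_table")], function(rec) {
    sa <- reorient_short_axis(rec, study$truth$lv_axis, study$truth$lv_center)
    polar_map(sa, polar_map_model(), geom)
  })
  list(spec = spec,
       scores = list(with = score_segments(pm$with_table),
                     without = score_segments(pm$without_table)),
       polar_with = pm$with_table, polar_without = pm$without_table)
}

#' Run the synthetic-cohort experiment end to end
#'
#' Samples `cfg$n_studies` study specifications, processes each through both
#' attenuation-correction arms to AHA segment scores, and compares the arms.
#' The study with the largest absolute score difference is kept with its
#' paired polar maps for display.
#'
#' @param cfg an [experiment_config()] with experiment `"cohort"`.
#' @return An object of class `cohort_experiment`: per-study score pairs,
#'   the pooled [compare_scores()] `comparison`, [segment_panels()] data and
#'   the worst-study polar maps.
#' @export
run_cohort_experiment <- function(cfg = experiment_config("cohort")) {
  if (cfg$experiment != "cohort") stop("cfg$experiment must be cohort")
  specs <- sample_cohort(cfg$n_studies, cfg$seed, cfg$ranges)
  studies <- vector("list", length(specs))
  for (i in seq_along(specs))
    studies[[i]] <- process_cardiac_study(specs[[i]], cfg,
                                          seed = cfg$seed + i)
  pairs <- lapply(studies, `[[`, "scores")
  comparison <- compare_scores(pairs)
  absdiff <- vapply(pairs, function(p)
    sum(abs(p$with$scores - p$without$scores)), numeric(1))
  worst <- which.max(absdiff)
  out <- structure(list(cfg = cfg, specs = specs, pairs = pairs,
                        comparison = comparison,
                        panels = segment_panels(comparison),
                        worst_study = worst,
                        worst_polar_with = studies[[worst]]$polar_with,
                        worst_polar_without = studies[[worst]]$polar_without),
                   class = "cohort_experiment")
  if (!is.null(cfg$output_dir))
    write_artifacts(cfg$output_dir, cfg, list(),
                    list(score_scatter = function() plot(out$comparison),
                         segment_panels = function() plot(out$panels),
                         worst_polar = function() {
                           op <- par(mfrow = c(1, 2))
                           plot(out$worst_polar_with, main = "AC with table")
                           plot(out$worst_polar_without, main = "AC without table")
                           par(op)
                         }))
  out
}

#' @export
print.cohort_experiment <- function(x, ...) {
  cat(sprintf("cohort_experiment: %d studies\n", x$cfg$n_studies))
  print(x$comparison)
  invisible(x)
}
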