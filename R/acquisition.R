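#' Energy-window definition
#'
#' Photopeak 129-150 keV with one contiguous lower scatter window 108-129 keV.
#' With a lower window only, the upper-window term of the triple-energy-window
#' scatter estimate is zero.
#'
#' @param peak_lo_keV,peak_hi_keV,scat_lo_keV,scat_hi_keV window edges (keV).
#' @return An object of class `energy_windows`.
#' @export
energy_windows <- function(peak_lo_keV = 129, peak_hi_keV = 150,
                           scat_lo_keV = 108, scat_hi_keV = 129) {
  if (peak_hi_keV <= peak_lo_keV || scat_hi_keV <= scat_lo_keV)
    stop("window widths must be positive")
  if (scat_hi_keV != peak_lo_keV)
    stop("scatter and photopeak windows must be contiguous")
  structure(list(peak_lo_keV = peak_lo_keV, peak_hi_keV = peak_hi_keV,
                 scat_lo_keV = scat_lo_keV, scat_hi_keV = scat_hi_keV),
            class = "energy_windows")
}

#' Acquisition protocol (orbit geometry)
#'
#' Two presets follow clinical practice for the scanner emulated here:
#' quality control (`"qc"`) acquires 64 projections over a full 360-degree
#' circular orbit; myocardial perfusion (`"mpi"`) acquires 34 projections over
#' a 204-degree arc centred on the anterior axis (-102 to +102 degrees).
#' Angles are measured from anterior, rotating towards patient left. Full
#' orbits place views at `start + i * arc/n`; partial arcs use bin centres
#' `start + (i + 1/2) * arc/n` so the sweep is symmetric about the anterior
#' axis.
#'
#' @param label `"qc"` or `"mpi"`; selects the preset, individual fields can
#'   be overridden.
#' @param n_projections number of views (>= 2).
#' @param arc_deg,start_angle_deg swept arc and its start (degrees).
#' @param orbit_radius_mm nominal orbit radius (metadata; rays are parallel).
#' @return An object of class `acquisition_protocol` with an `angles_deg`
#'   field.
#' @export
acquisition_protocol <- function(label = c("qc", "mpi"), n_projections = NULL,
                                 arc_deg = NULL, start_angle_deg = NULL,
                                 orbit_radius_mm = 250) {
  label <- match.arg(label)
  def <- if (label == "qc") list(n = 64L, arc = 360, start = 0)
         else list(n = 34L, arc = 204, start = -102)
  n <- as.integer(if (is.null(n_projections)) def$n else n_projections)
  arc <- if (is.null(arc_deg)) def$arc else arc_deg
  start <- if (is.null(start_angle_deg)) def$start else start_angle_deg
  if (n < 2L) stop("n_projections must be >= 2")
  angles <- if (arc >= 360) start + (seq_len(n) - 1L) * arc / n
            else start + (seq_len(n) - 0.5) * arc / n
  structure(list(label = label, n_projections = n, arc_deg = arc,
                 start_angle_deg = start, orbit = "circular",
                 orbit_radius_mm = orbit_radius_mm, angles_deg = angles),
            class = "acquisition_protocol")
}

new_projection_set <- function(peak, scatter_window, protocol, det_spacing,
                               nu, grid, center, step_mm) {
  structure(list(peak = peak, scatter_window = scatter_window,
                 angles_deg = protocol$angles_deg, protocol = protocol,
                 detector_spacing_mm = det_spacing, nu = nu, grid = grid,
                 center = center, step_mm = step_mm),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  cat(sprintf("projection_set [%s]: %d views x %d x %d bins, %.3g counts\n",
              x$protocol$label, length(x$angles_deg), dim(x$peak)[1],
              dim(x$peak)[2], sum(x$peak)))
  invisible(x)
}

#' Attenuated parallel-beam forward projection
#'
#' Simulates noiseless photopeak projections of an activity volume through an
#' attenuation map. For each view the detector sits at the protocol angle;
#' rays are confined to transaxial planes and sampled at `step_mm`
#' (at most half the smallest in-plane voxel spacing). Each sample
#' contributes `step * a * exp(-step_cm * sum(mu))` with the attenuation sum
#' running from the emission sample to the detector.
#'
#' @param activity a [voxel_volume()] of type `"activity"`.
#' @param mu a [voxel_volume()] of type `"mu"` on the same grid, or `NULL`
#'   for no attenuation.
#' @param protocol an [acquisition_protocol()].
#' @param center in-plane world rotation centre (mm); defaults to the grid
#'   centre. For cardiocentric orbits pass the LV centre.
#' @param nu number of detector bins per row; defaults to the grid's nx.
#' @param detector_spacing_mm detector bin size; defaults to the in-plane
#'   voxel spacing.
#' @param step_mm ray sampling interval; default half the smallest in-plane
#'   spacing.
#' @return A `projection_set` with `peak` of dimension `[nu, nz, n_views]`
#'   and an all-zero `scatter_window`.
#' @export
forward_project <- function(activity, mu = NULL, protocol = acquisition_protocol("qc"),
                            center = NULL, nu = NULL,
                            detector_spacing_mm = NULL, step_mm = NULL) {
  g <- activity$grid
  if (!is.null(mu)) {
    if (!identical(mu$grid$shape, g$shape) ||
        !isTRUE(all.equal(mu$grid$spacing_mm, g$spacing_mm)) ||
        !isTRUE(all.equal(mu$grid$origin_mm, g$origin_mm)))
      stop("activity and mu must share the same grid")
    muv <- mu$values
  } else muv <- array(0, g$shape)
  if (is.null(nu)) nu <- g$shape[1]
  if (is.null(detector_spacing_mm)) detector_spacing_mm <- g$spacing_mm[1]
  if (is.null(step_mm)) step_mm <- min(g$spacing_mm[1:2]) / 2
  if (step_mm > min(g$spacing_mm[1:2]) / 2 + 1e-9)
    stop("step_mm must not exceed half the smallest in-plane voxel spacing")
  if (is.null(center)) center <- grid_center(g)[1:2]
  peak <- cpp_forward_project(activity$values, muv, g$shape, g$spacing_mm,
                              g$origin_mm, protocol$angles_deg,
                              detector_spacing_mm, as.integer(nu),
                              center, step_mm)
  dim(peak) <- c(nu, g$shape[3], protocol$n_projections)
  new_projection_set(peak, array(0, dim(peak)), protocol, detector_spacing_mm,
                     nu, g, center, step_mm)
}

#' Poisson noise and energy-window scatter model
#'
#' Synthetic detection model for noiseless projections: the primary photopeak
#' signal is scaled to the expected study count level, a spatially blurred
#' copy populates the lower scatter window at `scatter_fraction` of the
#' primary counts, a configurable fraction of that blurred component
#' contaminates the photopeak window (in-window scatter), and both windows
#' are Poisson-sampled.
#'
#' @param enabled logical; disabled returns projections unchanged.
#' @param total_expected_counts expected total photopeak-window counts.
#' @param seed RNG seed for the Poisson draw.
#' @param scatter_fraction lower-window counts as a fraction of primary
#'   counts, in \[0, 1).
#' @param scatter_blur_mm Gaussian blur sigma of the scatter component (mm).
#' @param inwindow_fraction fraction of the blurred component added to the
#'   photopeak window; 0.5 makes the TEW estimate unbiased in expectation.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(enabled = TRUE, total_expected_counts = 1e6,
                        seed = 1L, scatter_fraction = 0.3,
                        scatter_blur_mm = 40, inwindow_fraction = 0.5) {
  if (scatter_fraction < 0 || scatter_fraction >= 1)
    stop("scatter_fraction must be in [0, 1)")
  if (scatter_blur_mm <= 0) stop("scatter_blur_mm must be positive")
  structure(list(enabled = enabled,
                 total_expected_counts = total_expected_counts,
                 seed = as.integer(seed), scatter_fraction = scatter_fraction,
                 scatter_blur_mm = scatter_blur_mm,
                 inwindow_fraction = inwindow_fraction),
            class = "noise_model")
}

# separable Gaussian blur of a [nu x nz] image with edge renormalisation
# (rows of the band matrix sum to one, so totals are preserved exactly)
blur_matrix <- function(n, sigma_bins) {
  if (sigma_bins <= 0) return(diag(n))
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  k <- exp(-0.5 * (d / sigma_bins)^2)
  k / rowSums(k)
}

#' Apply the noise and scatter model to a projection set
#'
#' @param noiseless a `projection_set` from [forward_project()].
#' @param model a [noise_model()].
#' @return A `projection_set` with Poisson-sampled `peak` and
#'   `scatter_window` counts; deterministic given `model$seed`.
#' @export
add_noise_and_scatter <- function(noiseless, model = noise_model()) {
  if (!model$enabled) return(noiseless)
  if (model$total_expected_counts <= 0)
    stop("total_expected_counts must be positive")
  pk <- noiseless$peak
  tot <- sum(pk)
  if (tot <= 0) stop("cannot scale all-zero projections to a count level")
  sf <- model$scatter_fraction
  # split the photopeak-window budget between primary and in-window scatter
  primary <- pk * (model$total_expected_counts /
                     ((1 + model$inwindow_fraction * sf) * tot))
  d <- dim(primary)
  bu <- blur_matrix(d[1], model$scatter_blur_mm / noiseless$detector_spacing_mm)
  bz <- blur_matrix(d[2], model$scatter_blur_mm / noiseless$grid$spacing_mm[3])
  scat <- array(0, d)
  for (v in seq_len(d[3])) scat[, , v] <- sf * (bu %*% primary[, , v] %*% t(bz))
  peak_mean <- primary + model$inwindow_fraction * scat
  set.seed(model$seed)
  out <- noiseless
  out$peak <- array(rpois(length(peak_mean), peak_mean), d)
  out$scatter_window <- array(rpois(length(scat), scat), d)
  out
}

#' Energy-window scatter correction
#'
#' Triple-energy-window estimate with a single lower window (the upper-window
#' term is zero): per detector bin the scatter estimate is
#' `S = (C_scatter / W_scatter) * W_peak / 2`; with the 21 keV / 21 keV
#' windows this is half the lower-window counts. The corrected photopeak is
#' clamped at zero and the scatter window zeroed.
#'
#' @param projs a `projection_set`.
#' @param windows an [energy_windows()].
#' @return The corrected `projection_set`.
#' @export
scatter_correct <- function(projs, windows = energy_windows()) {
  ws <- windows$scat_hi_keV - windows$scat_lo_keV
  wp <- windows$peak_hi_keV - windows$peak_lo_keV
  s <- projs$scatter_window / ws * wp / 2
  projs$peak <- pmax(projs$peak - s, 0)
  projs$scatter_window[] <- 0
  projs
}

#' Per-angle count loss caused by an attenuation-path difference
#'
#' Projects the activity noiselessly through both attenuation maps and
#' reports, per view, `1 - counts_with / counts_without`. Used to calibrate
#' the synthetic table against the published 2-12 percent count-reduction
#' band.
#'
#' @param activity a [voxel_volume()] of type `"activity"`.
#' @param mu_with,mu_without attenuation maps on the activity grid, e.g. with
#'   and without the patient table.
#' @param protocol an [acquisition_protocol()].
#' @param ... passed to [forward_project()].
#' @return Numeric vector of fractional reductions with attribute
#'   `angles_deg`.
#' @export
count_reduction_profile <- function(activity, mu_with, mu_without,
                                    protocol = acquisition_protocol("qc"), ...) {
  pw <- forward_project(activity, mu_with, protocol, ...)
  pwo <- forward_project(activity, mu_without, protocol, ...)
  sw <- apply(pw$peak, 3, sum)
  swo <- apply(pwo$peak, 3, sum)
  if (any(swo <= 0)) stop("zero counts without table at one or more angles")
  structure(1 - sw / swo, angles_deg = protocol$angles_deg)
}
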