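#' AHA polar-map sampling model
#'
#' Seventeen segments: 6 basal, 6 mid, 4 apical, 1 apex. The angular
#' convention places 0 degrees at the anterior wall with angles increasing
#' towards the septum (as viewed from the apex); slices run apex to base.
#'
#' @param radial_samples angular samples per slice (default 60).
#' @param n_slices short-axis slices apex to base (default 20).
#' @return An object of class `polar_map_model`.
#' @export
polar_map_model <- function(radial_samples = 60L, n_slices = 20L) {
  if (radial_samples < 8L || n_slices < 4L)
    stop("too few angular or slice samples")
  structure(list(n_segments = 17L, radial_samples = as.integer(radial_samples),
                 n_slices = as.integer(n_slices)), class = "polar_map_model")
}

# AHA segment number for slice fraction f (0 apex .. 1 base) and angle deg
# (0 anterior, 90 septal). Rings: apex cap, 4 apical, 6 mid, 6 basal.
aha_segment <- function(f, angle_deg) {
  a <- angle_deg %% 360
  sector6 <- (floor(((a + 30) %% 360) / 60)) + 1L       # 1 anterior .. 6 anterolateral
  sector4 <- (floor(((a + 45) %% 360) / 90)) + 1L       # 1 ant, 2 sept, 3 inf, 4 lat
  ifelse(f < 0.25, 17L,
         ifelse(f < 0.5, 12L + sector4,
                ifelse(f < 0.75, 6L + sector6, sector6)))
}

#' Reorient a reconstruction into short-axis alignment
#'
#' Resamples the volume so that the LV base-to-apex axis maps onto -z (apex
#' at low z) and the anterior direction onto -y, with the LV centre moved to
#' the grid centre. The ground-truth axis from the generator is used rather
#' than automatic axis finding.
#'
#' @param recon an activity [voxel_volume()].
#' @param lv_axis unit base-to-apex axis vector in world coordinates.
#' @param lv_center LV centre in world coordinates (mm).
#' @param out_grid output [grid_spec()]; defaults to the input grid centred
#'   on the origin.
#' @return The reoriented [voxel_volume()]; the LV centre sits at the centre
#'   of the output grid.
#' @export
reorient_short_axis <- function(recon, lv_axis, lv_center, out_grid = NULL) {
  nrm <- sqrt(sum(lv_axis^2))
  if (nrm < 1e-12) stop("zero-length LV axis")
  u <- lv_axis / nrm
  ant <- c(0, -1, 0)
  if (abs(sum(ant * u)) > 0.999) ant <- c(1, 0, 0)
  e1 <- ant - sum(ant * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  # rotation taking e1 -> -y, e2 -> -x, u -> -z
  m_local <- cbind(e1, e2, u)
  m_target <- cbind(c(0, -1, 0), c(-1, 0, 0), c(0, 0, -1))
  rot <- m_target %*% t(m_local)
  if (is.null(out_grid))
    out_grid <- grid_spec(recon$grid$shape, recon$grid$spacing_mm)
  qc <- grid_center(out_grid)
  amat <- t(rot)  # world point sampled in the source volume
  b <- as.numeric(lv_center - amat %*% qc)
  out <- cpp_resample_affine(recon$values, recon$grid$shape,
                             recon$grid$spacing_mm, recon$grid$origin_mm,
                             out_grid$shape, out_grid$spacing_mm,
                             out_grid$origin_mm, amat, b, 0)
  dim(out) <- out_grid$shape
  voxel_volume(out, out_grid, recon$type)
}

#' Maximal-count polar map of a short-axis volume
#'
#' For each short-axis slice (apex to base) and each angle, the maximum value
#' along the radial ray crossing the myocardial wall is sampled
#' (maximal-count sampling, the standard in perfusion quantification). The
#' samples are normalised to the polar-map maximum (x100) and averaged into
#' the 17 AHA segment means.
#'
#' @param sa_volume short-axis-aligned activity volume (LV centre at the grid
#'   centre, apex towards low z), as produced by [reorient_short_axis()].
#' @param model a [polar_map_model()].
#' @param lv_geometry list with `apex_z_mm`, `base_z_mm` (world z of apex and
#'   base in the short-axis frame) and `max_radius_mm` (outer sampling
#'   radius).
#' @return An object of class `polar_map`: `samples` (slices x angles),
#'   `normalized` (percent of maximum) and `segment_means` (named 1-17).
#' @export
polar_map <- function(sa_volume, model = polar_map_model(), lv_geometry) {
  g <- sa_volume$grid
  ctr <- grid_center(g)
  zs <- seq(lv_geometry$apex_z_mm, lv_geometry$base_z_mm,
            length.out = model$n_slices)
  na <- model$radial_samples
  angs <- (seq_len(na) - 1L) * 360 / na
  rstep <- min(g$spacing_mm[1:2]) / 2
  rr <- seq(0, lv_geometry$max_radius_mm, by = rstep)
  # ray directions: 0 deg anterior (-y), increasing towards septum (-x)
  dx <- -sin(angs * pi / 180); dy <- -cos(angs * pi / 180)
  samples <- matrix(0, model$n_slices, na)
  empty <- 0L
  for (s in seq_len(model$n_slices)) {
    pts <- cbind(ctr[1] + as.vector(outer(rr, dx)),
                 ctr[2] + as.vector(outer(rr, dy)),
                 zs[s])
    v <- matrix(trilinear_sample(sa_volume, pts), length(rr), na)
    mx <- apply(v, 2, max)
    empty <- empty + sum(mx <= 0)
    samples[s, ] <- pmax(mx, 0)
  }
  if (empty > 0)
    warning(sprintf("%d polar samples found no activity along their ray", empty))
  normalized <- 100 * samples / max(samples)
  f <- (seq_len(model$n_slices) - 0.5) / model$n_slices
  seg <- outer(f, angs, aha_segment)
  segment_means <- vapply(1:17, function(k) mean(normalized[seg == k]),
                          numeric(1))
  names(segment_means) <- as.character(1:17)
  structure(list(samples = samples, normalized = normalized,
                 segment_means = segment_means, model = model,
                 slice_fractions = f, angles_deg = angs),
            class = "polar_map")
}

#' @export
print.polar_map <- function(x, ...) {
  cat("polar_map:", nrow(x$samples), "slices x", ncol(x$samples),
      "angles; segment means (% of max):\n")
  print(round(x$segment_means, 1))
  invisible(x)
}

#' Bull's-eye display of a polar map
#'
#' Apex at the centre, base at the rim, anterior wall up, septum to the
#' left.
#'
#' @param x a [polar_map()].
#' @param main plot title.
#' @param ... ignored.
#' @export
plot.polar_map <- function(x, main = "polar map", ...) {
  op <- par(mar = c(1, 1, 2, 1), pty = "s"); on.exit(par(op))
  plot(NA, xlim = c(-1, 1), ylim = c(-1, 1), axes = FALSE, xlab = "",
       ylab = "", main = main, asp = 1)
  pal <- hcl.colors(64, "Inferno")
  ns <- nrow(x$normalized); na <- ncol(x$normalized)
  for (s in seq_len(ns)) {
    r0 <- (s - 1) / ns; r1 <- s / ns
    for (j in seq_len(na)) {
      # display: anterior (0 deg) up, septal (90 deg) left
      a0 <- (90 + x$angles_deg[j] - 180 / na) * pi / 180
      a1 <- (90 + x$angles_deg[j] + 180 / na) * pi / 180
      aa <- seq(a0, a1, length.out = 4)
      col <- pal[pmax(1, ceiling(x$normalized[s, j] / 100 * 64))]
      polygon(c(r0 * cos(aa), r1 * cos(rev(aa))),
              c(r0 * sin(aa), r1 * sin(rev(aa))), col = col, border = NA)
    }
  }
  invisible(x)
}

#' Integer perfusion scores of the 17 AHA segments
#'
#' Each segment mean (percent of the polar-map maximum) is binned through a
#' strictly descending threshold list into a score of 0 (normal uptake) to 4
#' (absent uptake). The default cuts are >= 70 -> 0, 50-69 -> 1, 30-49 -> 2,
#' 10-29 -> 3, < 10 -> 4.
#'
#' @param pm a [polar_map()].
#' @param thresholds strictly descending percent cut-offs (length 4).
#' @return An object of class `segment_scores` with integer `scores`
#'   named 1-17.
#' @export
score_segments <- function(pm, thresholds = c(70, 50, 30, 10)) {
  if (any(diff(thresholds) >= 0)) stop("thresholds must be strictly descending")
  m <- pm$segment_means
  scores <- length(thresholds) - findInterval(m, rev(thresholds))
  names(scores) <- names(m)
  structure(list(scores = as.integer(scores), thresholds_pct = thresholds),
            class = "segment_scores")
}

#' @export
print.segment_scores <- function(x, ...) {
  s <- x$scores; names(s) <- as.character(1:17)
  print(s)
  invisible(x)
}
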