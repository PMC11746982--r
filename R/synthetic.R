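#' Parametric patient-table model
#'
#' The table is modelled as an arc-shaped carbon-fibre shell (an annular
#' sector in cross-section, constant along z) lying posterior to the imaged
#' object. The object rests in the concave trough: the trough's deepest inner
#' point sits `gap_mm` posterior to the object's most posterior point, and the
#' shell rises by `arc_sagitta_mm` towards its lateral edges.
#'
#' `hu_value` must stay above the -700 HU removal threshold, otherwise the
#' table could not be segmented and generation refuses the model.
#' `thickness_mm = 0` (or `enabled = FALSE`) means no table.
#'
#' @param enabled logical; generate the table at all.
#' @param arc_sagitta_mm depth of curvature of the trough (mm).
#' @param chord_width_mm lateral chord width of the arc (mm).
#' @param thickness_mm shell thickness (mm); 0 disables the table.
#' @param gap_mm air gap between object's lowest point and the trough (mm).
#' @param hu_value CT number of the shell (carbon-fibre composite ~ -400 HU).
#' @return An object of class `table_model`.
#' @export
table_model <- function(enabled = TRUE, arc_sagitta_mm = 60,
                        chord_width_mm = 450, thickness_mm = 15,
                        gap_mm = 10, hu_value = -400) {
  if (arc_sagitta_mm <= 0 || chord_width_mm <= 0)
    stop("arc sagitta and chord width must be positive")
  if (thickness_mm < 0 || gap_mm < 0)
    stop("thickness and gap must be non-negative")
  if (enabled && thickness_mm > 0 && hu_value <= -700)
    stop("table hu_value must exceed -700 HU (the removal threshold)")
  structure(list(enabled = enabled, arc_sagitta_mm = arc_sagitta_mm,
                 chord_width_mm = chord_width_mm, thickness_mm = thickness_mm,
                 gap_mm = gap_mm, hu_value = hu_value), class = "table_model")
}

# circle radius of the arc from sagitta s and chord w
table_arc_radius <- function(table) {
  s <- table$arc_sagitta_mm; w <- table$chord_width_mm
  (s^2 + (w / 2)^2) / (2 * s)
}

# analytic cross-sectional area (mm^2) of the arc shell: annulus R..R+t
# restricted to |x| <= w/2 below the circle centre
table_arc_area <- function(table) {
  R <- table_arc_radius(table)
  w <- table$chord_width_mm; t <- table$thickness_mm
  if (t <= 0) return(0)
  f <- function(r) 2 * asin(pmin(1, w / (2 * r))) * r
  stats::integrate(f, R, R + t, rel.tol = 1e-10)$value
}

# in-plane logical mask of the table on (x, y) axes; y_obj_max = most
# posterior point of the imaged object
table_mask_2d <- function(table, x, y, y_obj_max) {
  if (!table$enabled || table$thickness_mm <= 0)
    return(matrix(FALSE, length(x), length(y)))
  R <- table_arc_radius(table)
  cy <- y_obj_max + table$gap_mm - R
  r2 <- outer(x^2, (y - cy)^2, "+")
  inband <- r2 >= R^2 & r2 <= (R + table$thickness_mm)^2
  lower <- outer(rep(TRUE, length(x)), y > cy)
  chord <- outer(abs(x) <= table$chord_width_mm / 2, rep(TRUE, length(y)))
  inband & lower & chord
}

#' Jaszczak-type cylindrical phantom specification
#'
#' A fillable cylinder (interior diameter/height) with a plastic shell, used
#' for SPECT uniformity quality control. Sphere and rod inserts are omitted:
#' the questions addressed here concern attenuation, not resolution.
#'
#' @param interior_diameter_mm,interior_height_mm interior dimensions (mm).
#' @param shell_thickness_mm wall thickness (mm).
#' @param shell_hu,fill_hu CT numbers of the shell and of the fill.
#' @param activity_concentration uniform interior activity (arbitrary
#'   units per voxel).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(interior_diameter_mm = 216, interior_height_mm = 186,
                         shell_thickness_mm = 9.5, shell_hu = 120,
                         fill_hu = 0, activity_concentration = 1) {
  if (interior_diameter_mm <= 0 || interior_height_mm <= 0 ||
      shell_thickness_mm <= 0 || activity_concentration <= 0)
    stop("phantom dimensions and activity must be positive")
  structure(list(interior_diameter_mm = interior_diameter_mm,
                 interior_height_mm = interior_height_mm,
                 shell_thickness_mm = shell_thickness_mm,
                 shell_hu = shell_hu, fill_hu = fill_hu,
                 activity_concentration = activity_concentration),
            class = "phantom_spec")
}

# check that an object of world half-extents (hx, hy, hz) about the world
# origin fits a grid with >= margin voxels to spare; names the offender
check_fit <- function(grid, lo, hi, what, margin = 2) {
  ext <- grid_extent(grid)
  pad <- margin * grid$spacing_mm
  for (ax in 1:3) {
    if (lo[ax] < ext["lo", ax] + pad[ax] || hi[ax] > ext["hi", ax] - pad[ax])
      stop(sprintf("%s exceeds the %s grid along %s", what,
                   paste(grid$shape, collapse = "x"), c("x", "y", "z")[ax]))
  }
  invisible(TRUE)
}

# replicate an in-plane [nx x ny] matrix over nz slices, optionally gated by
# a logical z profile
rep_slices <- function(m, nz, zsel = rep(TRUE, nz)) {
  a <- array(as.vector(m), dim = c(dim(m), nz))
  if (!all(zsel)) a[, , !zsel] <- if (is.logical(m)) FALSE else 0
  a
}

#' Generate a Jaszczak phantom study (CT + activity + ground truth)
#'
#' Builds the phantom CT on `ct_grid` (air -1000 HU, shell `shell_hu`,
#' interior `fill_hu`) with the arc-shell patient table beneath it, and the
#' uniform-activity volume on `spect_grid`. Ground-truth voxel masks of the
#' table, the phantom body and the active interior are returned for oracle
#' evaluation of the downstream stages.
#'
#' @param spec a [phantom_spec()].
#' @param table a [table_model()].
#' @param ct_grid,spect_grid [grid_spec()]s for the CT and activity volumes.
#' @return A list of class `synthetic_study` with elements `ct`
#'   ([voxel_volume()] of type `"ct"`), `activity` (type `"activity"`) and
#'   `truth` (masks + geometry).
#' @export
generate_jaszczak <- function(spec = phantom_spec(), table = table_model(),
                              ct_grid, spect_grid) {
  rad_in <- spec$interior_diameter_mm / 2
  rad_out <- rad_in + spec$shell_thickness_mm
  hz_in <- spec$interior_height_mm / 2
  hz_out <- hz_in + spec$shell_thickness_mm
  check_fit(ct_grid, c(-rad_out, -rad_out, -hz_out), c(rad_out, rad_out, hz_out),
            "phantom interior_diameter_mm/interior_height_mm")
  check_fit(spect_grid, c(-rad_out, -rad_out, -hz_out),
            c(rad_out, rad_out, hz_out),
            "phantom interior_diameter_mm/interior_height_mm")
  if (table$enabled && table$thickness_mm > 0) {
    s <- table$arc_sagitta_mm
    tab_lo <- c(-table$chord_width_mm / 2, rad_out + table$gap_mm - s, 0)
    tab_hi <- c(table$chord_width_mm / 2,
                rad_out + table$gap_mm + table$thickness_mm, 0)
    check_fit(ct_grid, tab_lo, tab_hi, "table chord_width_mm/thickness_mm")
  }

  build <- function(grid, want_ct) {
    x <- grid_axis(grid, 1); y <- grid_axis(grid, 2); z <- grid_axis(grid, 3)
    r2 <- outer(x^2, y^2, "+")
    disc_in <- r2 <= rad_in^2
    disc_out <- r2 <= rad_out^2
    nz <- grid$shape[3]
    z_in <- abs(z) <= hz_in
    z_out <- abs(z) <= hz_out
    interior <- rep_slices(disc_in, nz, z_in)
    body <- rep_slices(disc_out, nz, z_out)
    if (!want_ct) return(list(interior = interior, body = body))
    tab2d <- table_mask_2d(table, x, y, rad_out)
    tab <- rep_slices(tab2d, nz)
    ct <- array(-1000, grid$shape)
    ct[tab] <- table$hu_value
    ct[body] <- spec$shell_hu
    ct[interior] <- spec$fill_hu
    list(ct = ct, interior = interior, body = body, table = tab)
  }

  on_ct <- build(ct_grid, want_ct = TRUE)
  on_spect <- build(spect_grid, want_ct = FALSE)
  act <- array(0, spect_grid$shape)
  act[on_spect$interior] <- spec$activity_concentration

  truth <- list(table_mask = on_ct$table, body_mask = on_ct$body,
                interior_mask = on_spect$interior, mask_grid = ct_grid,
                activity_grid = spect_grid,
                table_volume_mm3 = table_arc_area(table) *
                  ct_grid$shape[3] * ct_grid$spacing_mm[3])
  structure(list(ct = voxel_volume(on_ct$ct, ct_grid, "ct"),
                 activity = voxel_volume(act, spect_grid, "activity"),
                 truth = truth, spec = spec, table = table),
            class = "synthetic_study")
}

#' Synthetic torso + left-ventricle study specification
#'
#' Describes one myocardial-perfusion study: an elliptical soft-tissue torso
#' cylinder with a half-ellipsoid left-ventricular (LV) shell placed anterior
#' to the torso centre (the heart sits close to the front of the chest). The
#' shell carries `myocardium_activity`; surrounding tissue carries
#' `background_activity_fraction` of it; an optional perfusion `defect`
#' (angular wall region) scales shell activity by a residual-uptake fraction.
#'
#' @param body_axes_mm in-plane semi-axes (x, y) of the torso ellipse (mm).
#' @param lv_center_mm world position of the LV centre (mm).
#' @param lv_outer_axes_mm,lv_inner_axes_mm semi-axes of the outer/inner
#'   ellipsoid bounding the myocardial shell: two transverse then one along
#'   the long axis (mm).
#' @param lv_axis_tilt_deg pair (azimuth, elevation): the base-to-apex axis is
#'   tilted `elevation` degrees away from -z, in the azimuthal direction
#'   measured from +x towards +y.
#' @param myocardium_activity activity per voxel in the healthy shell.
#' @param background_activity_fraction tissue activity as a fraction of
#'   `myocardium_activity`, in \[0, 1).
#' @param defect `NULL`, or `list(region =, residual =)` with region one of
#'   `"inferior"`, `"anterior"`, `"septal"`, `"lateral"` and residual uptake in
#'   \[0, 1\].
#' @param protocol_label `"stress"` or `"rest"` (metadata only).
#' @return An object of class `cardiac_study_spec`.
#' @export
cardiac_study_spec <- function(body_axes_mm = c(175, 120),
                               lv_center_mm = c(30, -45, 0),
                               lv_outer_axes_mm = c(34, 34, 44),
                               lv_inner_axes_mm = c(22, 22, 32),
                               lv_axis_tilt_deg = c(-30, 40),
                               myocardium_activity = 1,
                               background_activity_fraction = 0.1,
                               defect = NULL,
                               protocol_label = c("stress", "rest")) {
  protocol_label <- match.arg(protocol_label)
  if (any(lv_inner_axes_mm >= lv_outer_axes_mm))
    stop("inner LV axes must be strictly inside the outer axes")
  if (lv_center_mm[2] >= 0)
    stop("LV centre must be anterior to the torso centre (y < 0)")
  if (background_activity_fraction < 0 || background_activity_fraction >= 1)
    stop("background_activity_fraction must be in [0, 1)")
  if (!is.null(defect)) {
    if (!defect$region %in% c("inferior", "anterior", "septal", "lateral"))
      stop("unknown defect region")
    if (defect$residual < 0 || defect$residual > 1)
      stop("defect residual-uptake fraction must be in [0, 1]")
  }
  structure(list(body_axes_mm = body_axes_mm, lv_center_mm = lv_center_mm,
                 lv_outer_axes_mm = lv_outer_axes_mm,
                 lv_inner_axes_mm = lv_inner_axes_mm,
                 lv_axis_tilt_deg = lv_axis_tilt_deg,
                 myocardium_activity = myocardium_activity,
                 background_activity_fraction = background_activity_fraction,
                 defect = defect, protocol_label = protocol_label),
            class = "cardiac_study_spec")
}

# unit base-to-apex axis and transverse frame (e1 towards anterior, e2 = u x e1)
lv_frame <- function(spec) {
  az <- spec$lv_axis_tilt_deg[1] * pi / 180
  el <- spec$lv_axis_tilt_deg[2] * pi / 180
  u <- c(sin(el) * cos(az), sin(el) * sin(az), -cos(el))
  ant <- c(0, -1, 0)
  e1 <- ant - sum(ant * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(u = u, e1 = e1, e2 = e2)
}

# angular range (deg) of a named wall region in the LV frame, where 0 deg is
# anterior and 90 deg is septal
defect_angles <- function(region) {
  switch(region,
         anterior = c(-60, 60), septal = c(30, 150),
         inferior = c(120, 240), lateral = c(210, 330))
}

#' Generate a synthetic cardiac perfusion study
#'
#' Builds the torso CT (soft tissue 0 HU, air elsewhere, arc-shell table) on
#' `ct_grid` and the activity volume (myocardial shell + tissue background,
#' with any perfusion defect applied) on `spect_grid`, along with ground-truth
#' masks and LV geometry. Deterministic given the spec; `seed` is accepted for
#' interface symmetry with stochastic generators and reserved for optional
#' activity texture.
#'
#' @inheritParams generate_jaszczak
#' @param spec a [cardiac_study_spec()].
#' @param seed integer; fixed before any random draw.
#' @return A list of class `synthetic_study`; `truth` additionally carries
#'   `lv_shell_mask`, `lv_axis`, `lv_center` and `defect_mask`.
#' @export
generate_cardiac_study <- function(spec = cardiac_study_spec(),
                                   table = table_model(), ct_grid, spect_grid,
                                   seed = 0L) {
  set.seed(as.integer(seed))
  ax <- spec$body_axes_mm[1]; ay <- spec$body_axes_mm[2]
  check_fit(ct_grid, c(-ax, -ay, 0), c(ax, ay, 0), "torso body_axes_mm")
  if (table$enabled && table$thickness_mm > 0) {
    s <- table$arc_sagitta_mm
    check_fit(ct_grid, c(-table$chord_width_mm / 2, ay + table$gap_mm - s, 0),
              c(table$chord_width_mm / 2,
                ay + table$gap_mm + table$thickness_mm, 0),
              "table chord_width_mm/thickness_mm")
  }

  fr <- lv_frame(spec)
  c_out <- spec$lv_outer_axes_mm[3]

  shell_and_defect <- function(grid) {
    x <- grid_axis(grid, 1); y <- grid_axis(grid, 2); z <- grid_axis(grid, 3)
    n <- grid$shape
    wx <- outer(x - spec$lv_center_mm[1], rep(1, n[2]))
    wy <- outer(rep(1, n[1]), y - spec$lv_center_mm[2])
    shell <- array(FALSE, n); dmask <- array(FALSE, n)
    ang <- if (!is.null(spec$defect)) defect_angles(spec$defect$region)
    for (k in seq_len(n[3])) {
      wz <- z[k] - spec$lv_center_mm[3]
      w1 <- wx * fr$e1[1] + wy * fr$e1[2] + wz * fr$e1[3]
      w2 <- wx * fr$e2[1] + wy * fr$e2[2] + wz * fr$e2[3]
      wt <- wx * fr$u[1] + wy * fr$u[2] + wz * fr$u[3]
      e_out <- (w1 / spec$lv_outer_axes_mm[1])^2 +
        (w2 / spec$lv_outer_axes_mm[2])^2 + (wt / c_out)^2
      e_in <- (w1 / spec$lv_inner_axes_mm[1])^2 +
        (w2 / spec$lv_inner_axes_mm[2])^2 + (wt / spec$lv_inner_axes_mm[3])^2
      sl <- e_out <= 1 & e_in >= 1 & wt >= -0.25 * c_out
      shell[, , k] <- sl
      if (!is.null(ang)) {
        beta <- (atan2(w2, w1) * 180 / pi) %% 360
        lo <- ang[1] %% 360; hi <- ang[2] %% 360
        inang <- if (lo < hi) beta >= lo & beta <= hi else beta >= lo | beta <= hi
        dmask[, , k] <- sl & inang & wt >= -0.25 * c_out & wt <= 0.6 * c_out
      }
    }
    list(shell = shell, defect = dmask)
  }

  # CT grid: torso + table
  x <- grid_axis(ct_grid, 1); y <- grid_axis(ct_grid, 2)
  body2d <- outer(x^2 / ax^2, y^2 / ay^2, "+") <= 1
  nz_ct <- ct_grid$shape[3]
  body <- rep_slices(body2d, nz_ct)
  tab <- rep_slices(table_mask_2d(table, x, y, ay), nz_ct)
  ct <- array(-1000, ct_grid$shape)
  ct[tab] <- table$hu_value
  ct[body] <- 0

  # SPECT grid: activity
  sd <- shell_and_defect(spect_grid)
  xs <- grid_axis(spect_grid, 1); ys <- grid_axis(spect_grid, 2)
  body_s <- rep_slices(outer(xs^2 / ax^2, ys^2 / ay^2, "+") <= 1,
                       spect_grid$shape[3])
  act <- array(0, spect_grid$shape)
  act[body_s] <- spec$background_activity_fraction * spec$myocardium_activity
  act[sd$shell] <- spec$myocardium_activity
  if (!is.null(spec$defect))
    act[sd$defect] <- spec$defect$residual * spec$myocardium_activity

  truth <- list(table_mask = tab, body_mask = body, mask_grid = ct_grid,
                lv_shell_mask = sd$shell, defect_mask = sd$defect,
                activity_grid = spect_grid, lv_axis = fr$u,
                lv_frame = fr, lv_center = spec$lv_center_mm,
                lv_long_semi_axis = c_out)
  structure(list(ct = voxel_volume(ct, ct_grid, "ct"),
                 activity = voxel_volume(act, spect_grid, "activity"),
                 truth = truth, spec = spec, table = table),
            class = "synthetic_study")
}

#' Default habitus and defect sampling ranges for the synthetic cohort
#'
#' BMI-like habitus draws follow the cohort statistics of the emulated
#' clinical population (mean 29.7, SD 6.0, truncated to 17.3-40.8); torso
#' semi-axes scale linearly with the draw between the configured bounds.
#' 13:6 stress:rest mix and roughly one third of studies carrying a defect.
#'
#' @return A list of sampling parameters, see source for fields.
#' @export
cohort_ranges <- function() {
  list(bmi_mean = 29.7, bmi_sd = 6.0, bmi_range = c(17.3, 40.8),
       body_ax_range = c(150, 205), body_ay_range = c(95, 135),
       stress_prob = 13 / 19, defect_prob = 1 / 3,
       defect_regions = c("inferior", "anterior", "septal", "lateral"),
       residual_range = c(0.2, 0.6), lv_scale_range = c(0.9, 1.1))
}

#' Sample a reproducible cohort of cardiac study specifications
#'
#' @param n_studies number of studies (>= 1).
#' @param seed RNG seed; the same seed reproduces the same cohort.
#' @param ranges habitus/defect distributions, see [cohort_ranges()].
#' @return A list of `n_studies` [cardiac_study_spec()] objects.
#' @export
sample_cohort <- function(n_studies, seed = 1L, ranges = cohort_ranges()) {
  if (n_studies < 1) stop("n_studies must be >= 1")
  set.seed(as.integer(seed))
  out <- vector("list", n_studies)
  for (i in seq_len(n_studies)) {
    bmi <- min(max(rnorm(1, ranges$bmi_mean, ranges$bmi_sd),
                   ranges$bmi_range[1]), ranges$bmi_range[2])
    f <- (bmi - ranges$bmi_range[1]) / diff(ranges$bmi_range)
    ax <- ranges$body_ax_range[1] + f * diff(ranges$body_ax_range)
    ay <- ranges$body_ay_range[1] + f * diff(ranges$body_ay_range)
    lvs <- runif(1, ranges$lv_scale_range[1], ranges$lv_scale_range[2])
    stress <- rbinom(1, 1, ranges$stress_prob) == 1
    defect <- NULL
    if (runif(1) < ranges$defect_prob)
      defect <- list(region = sample(ranges$defect_regions, 1),
                     residual = runif(1, ranges$residual_range[1],
                                      ranges$residual_range[2]))
    out[[i]] <- cardiac_study_spec(
      body_axes_mm = c(ax, ay),
      lv_center_mm = c(0.15 * ax, -0.4 * ay, 0),
      lv_outer_axes_mm = lvs * c(34, 34, 44),
      lv_inner_axes_mm = lvs * c(22, 22, 32),
      lv_axis_tilt_deg = c(runif(1, -45, -15), runif(1, 30, 50)),
      defect = defect,
      protocol_label = if (stress) "stress" else "rest")
  }
  out
}
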