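#' CT-number to attenuation-coefficient calibration
#'
#' Standard bilinear (two-segment) conversion at the Tc-99m emission energy
#' of 140 keV: below water the coefficient scales linearly to zero at air,
#' above water the slope is reduced by `bone_slope` because the HU of bone
#' overstates its attenuation at emission energies relative to CT energies.
#'
#' @param mu_water_cm linear attenuation coefficient of water at the emission
#'   energy (cm^-1); 0.154 at 140 keV.
#' @param bone_slope fractional slope of the positive-HU segment, in (0, 1].
#' @return An object of class `mu_calibration`.
#' @export
mu_calibration <- function(mu_water_cm = 0.154, bone_slope = 0.5) {
  if (mu_water_cm <= 0) stop("mu_water_cm must be positive")
  if (bone_slope <= 0 || bone_slope > 1) stop("bone_slope must be in (0, 1]")
  structure(list(mu_water_cm = mu_water_cm, bone_slope = bone_slope),
            class = "mu_calibration")
}

#' Convert a CT volume to a linear-attenuation map
#'
#' HU <= 0: `mu = mu_water * (1 + HU/1000)` clamped at zero;
#' HU > 0: `mu = mu_water * (1 + bone_slope * HU/1000)`. Units cm^-1.
#'
#' @param ct a [voxel_volume()] of type `"ct"`.
#' @param calib a [mu_calibration()].
#' @return A [voxel_volume()] of type `"mu"` on the same grid.
#' @examples
#' g <- grid_spec(c(8, 8, 8), c(1, 1, 1))
#' ct <- voxel_volume(array(0, c(8, 8, 8)), g, "ct")
#' range(hu_to_mu(ct)$values)  # 0.154 everywhere
#' @export
hu_to_mu <- function(ct, calib = mu_calibration()) {
  hu <- ct$values
  mu <- ifelse(hu <= 0,
               pmax(0, calib$mu_water_cm * (1 + hu / 1000)),
               calib$mu_water_cm * (1 + calib$bone_slope * hu / 1000))
  voxel_volume(mu, ct$grid, "mu")
}
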