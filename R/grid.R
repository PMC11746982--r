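#' Regular 3-D voxel grid geometry
#'
#' Defines the sampling lattice shared by all volumes: `shape` voxels along
#' (x, y, z), voxel centres at `origin_mm + index * spacing_mm` with 0-based
#' indices. World axes follow the scanner convention used throughout the
#' package: x = patient left, y = patient posterior (the table side is +y),
#' z = axial.
#'
#' @param shape integer triple (nx, ny, nz); in-plane dimensions >= 8,
#'   at least one axial slice (thin test grids are legitimate).
#' @param spacing_mm positive real triple, voxel size in mm.
#' @param origin_mm real triple, world position (mm) of the centre of voxel
#'   (0, 0, 0), or `"centered"` (default) to centre the grid on the world
#'   origin.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(c(64, 64, 64), c(9.6, 9.6, 9.6))
#' grid_extent(g)
#' @export
grid_spec <- function(shape, spacing_mm, origin_mm = "centered") {
  shape <- as.integer(shape)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(shape) != 3L || any(shape[1:2] < 8L) || shape[3] < 1L)
    stop("grid shape must be a triple with in-plane entries >= 8 and nz >= 1")
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("grid spacing must be a positive triple")
  if (identical(origin_mm, "centered"))
    origin_mm <- -(shape - 1L) / 2 * spacing_mm
  origin_mm <- as.numeric(origin_mm)
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("grid origin must be a finite triple")
  structure(list(shape = shape, spacing_mm = spacing_mm,
                 origin_mm = origin_mm), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("grid_spec:", paste(x$shape, collapse = " x "), "voxels @",
      paste(signif(x$spacing_mm, 4), collapse = " x "), "mm\n")
  invisible(x)
}

#' @rdname grid_spec
#' @param grid a `grid_spec`.
#' @return `grid_extent()`: 2 x 3 matrix of world bounds (voxel-centre range).
#' @export
grid_extent <- function(grid) {
  lo <- grid$origin_mm
  hi <- grid$origin_mm + (grid$shape - 1L) * grid$spacing_mm
  rbind(lo = lo, hi = hi)
}

#' @rdname grid_spec
#' @return `grid_center()`: world coordinates (mm) of the grid centre.
#' @export
grid_center <- function(grid) {
  grid$origin_mm + (grid$shape - 1L) / 2 * grid$spacing_mm
}

# world coordinates of voxel centres along one axis (1 = x, 2 = y, 3 = z)
grid_axis <- function(grid, axis) {
  grid$origin_mm[axis] + (seq_len(grid$shape[axis]) - 1L) * grid$spacing_mm[axis]
}

#' 3-D scalar volume on a regular grid
#'
#' Couples a numeric array with its [grid_spec()]. The `type` records the
#' physical quantity and enforces its range: CT values in Hounsfield units
#' within \[-1024, 3071\], activity (counts/voxel) and attenuation
#' coefficients (cm^-1) non-negative.
#'
#' @param values numeric array whose dimensions match `grid$shape`.
#' @param grid a [grid_spec()].
#' @param type one of `"generic"`, `"ct"`, `"activity"`, `"mu"`.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, grid, type = c("generic", "ct", "activity", "mu")) {
  type <- match.arg(type)
  if (!is.array(values) || !identical(dim(values), as.integer(grid$shape)))
    stop("values must be an array with dimensions matching the grid shape")
  if (any(!is.finite(values)))
    stop("volume values must be finite")
  if (type == "ct" && (min(values) < -1024 || max(values) > 3071))
    stop("CT values must lie in [-1024, 3071] HU")
  if (type %in% c("activity", "mu") && min(values) < 0)
    stop(sprintf("%s values must be >= 0", type))
  structure(list(values = values, grid = grid, type = type),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("voxel_volume<%s>: %s voxels @ %s mm, range [%.4g, %.4g]\n",
              x$type, paste(x$grid$shape, collapse = "x"),
              paste(signif(x$grid$spacing_mm, 3), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

# default out-of-support fill value by volume type
default_fill <- function(type) if (identical(type, "ct")) -1000 else 0

#' Resample a volume onto a target grid
#'
#' Trilinear interpolation in world coordinates; source and target grids share
#' the world frame. Points outside the source extent receive `fill`
#' (-1000 HU for CT, 0 otherwise).
#'
#' @param vol a [voxel_volume()].
#' @param target a [grid_spec()] to resample onto.
#' @param fill value used outside the source extent; defaults by volume type.
#' @return A [voxel_volume()] of the same type on `target`.
#' @export
resample_to_grid <- function(vol, target, fill = default_fill(vol$type)) {
  if (!inherits(target, "grid_spec")) stop("target must be a grid_spec")
  out <- cpp_resample_affine(vol$values, vol$grid$shape, vol$grid$spacing_mm,
                             vol$grid$origin_mm, target$shape,
                             target$spacing_mm, target$origin_mm,
                             diag(3), rep(0, 3), fill)
  dim(out) <- target$shape
  voxel_volume(out, target, vol$type)
}

# trilinear point sampling at world coordinates (n x 3 matrix), fill outside
trilinear_sample <- function(vol, pts, fill = 0) {
  g <- vol$grid
  cx <- (pts[, 1] - g$origin_mm[1]) / g$spacing_mm[1]
  cy <- (pts[, 2] - g$origin_mm[2]) / g$spacing_mm[2]
  cz <- (pts[, 3] - g$origin_mm[3]) / g$spacing_mm[3]
  n <- g$shape
  inside <- cx >= 0 & cx <= n[1] - 1 & cy >= 0 & cy <= n[2] - 1 &
    cz >= 0 & cz <= n[3] - 1
  out <- rep(fill, nrow(pts))
  if (!any(inside)) return(out)
  cx <- cx[inside]; cy <- cy[inside]; cz <- cz[inside]
  ix <- pmin(floor(cx), n[1] - 2); iy <- pmin(floor(cy), n[2] - 2)
  iz <- pmin(floor(cz), n[3] - 2)
  fx <- cx - ix; fy <- cy - iy; fz <- cz - iz
  v <- vol$values
  idx <- function(dx, dy, dz) v[cbind(ix + 1 + dx, iy + 1 + dy, iz + 1 + dz)]
  val <- (idx(0, 0, 0) * (1 - fx) + idx(1, 0, 0) * fx) * (1 - fy) * (1 - fz) +
         (idx(0, 1, 0) * (1 - fx) + idx(1, 1, 0) * fx) * fy * (1 - fz) +
         (idx(0, 0, 1) * (1 - fx) + idx(1, 0, 1) * fx) * (1 - fy) * fz +
         (idx(0, 1, 1) * (1 - fx) + idx(1, 1, 1) * fx) * fy * fz
  out[inside] <- val
  out
}
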