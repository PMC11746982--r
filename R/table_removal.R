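#' Parameters of the automatic table-removal algorithm
#'
#' The algorithm thresholds the central axial CT slice at `threshold_hu`,
#' labels connected components, classifies the component with the most
#' posterior centroid as the table, enlarges it by repeated dilation with a
#' square kernel, subtracts the (undilated) body components so dilation can
#' never eat into the body, and removes the resulting in-slice region from
#' every slice by overwriting it with `replacement_hu` (air, so the
#' attenuation-map conversion treats it as non-attenuating).
#'
#' @param threshold_hu binarisation threshold (HU); voxels above it are
#'   object.
#' @param dilation_iterations number of dilation passes (>= 0).
#' @param kernel_size odd square structuring-element width (>= 3).
#' @param replacement_hu value written into removed voxels.
#' @param connectivity pixel connectivity for component labelling, 4 or 8.
#' @return An object of class `table_removal_params`.
#' @export
table_removal_params <- function(threshold_hu = -700, dilation_iterations = 3L,
                                 kernel_size = 9L, replacement_hu = -1000,
                                 connectivity = 8L) {
  if (kernel_size < 3L || kernel_size %% 2L == 0L)
    stop("kernel_size must be odd and >= 3")
  if (dilation_iterations < 0L) stop("dilation_iterations must be >= 0")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  structure(list(threshold_hu = threshold_hu,
                 dilation_iterations = as.integer(dilation_iterations),
                 kernel_size = as.integer(kernel_size),
                 replacement_hu = replacement_hu,
                 connectivity = as.integer(connectivity)),
            class = "table_removal_params")
}

#' Remove the patient table from a CT volume
#'
#' @param ct a [voxel_volume()] of type `"ct"` with at least one axial slice.
#' @param params a [table_removal_params()].
#' @return An object of class `removal_result`: `ct_without_table`
#'   (input with the removed region set to `replacement_hu`),
#'   `table_mask_2d` (in-slice logical mask applied to all slices) and
#'   `n_components_found`.
#' @details The central slice for even slice counts is index
#'   `floor(nz / 2)` (0-based). With zero components above threshold the CT is
#'   considered empty (error); with exactly one component no table is present
#'   (warning, CT returned unchanged); a component touching both the anterior
#'   and posterior image edges cannot be separated (error).
#' @export
remove_table <- function(ct, params = table_removal_params()) {
  g <- ct$grid
  nz <- g$shape[3]
  if (nz < 1) stop("CT must have at least one axial slice")
  k <- floor(nz / 2) + 1L  # 0-based floor(nz/2)
  slice <- ct$values[, , k]
  bin <- slice > params$threshold_hu
  lab <- cpp_label_components(bin, params$connectivity)
  ncomp <- max(lab)
  if (ncomp == 0L) stop("empty CT: no voxels above threshold in central slice")
  if (ncomp == 1L) {
    warning("single component in central slice: no table present, CT unchanged")
    return(structure(list(ct_without_table = ct,
                          table_mask_2d = matrix(FALSE, nrow(bin), ncol(bin)),
                          n_components_found = 1L),
                     class = "removal_result"))
  }
  ny <- ncol(lab)
  for (cmp in seq_len(ncomp)) {
    rows <- which(lab == cmp, arr.ind = TRUE)
    if (any(rows[, 2] == 1L) && any(rows[, 2] == ny))
      stop("cannot separate body from table: a component touches both image edges")
  }
  # centroid posterior (+y) coordinate per component; most posterior = table
  cent_y <- vapply(seq_len(ncomp),
                   function(cmp) mean(which(lab == cmp, arr.ind = TRUE)[, 2]),
                   numeric(1))
  table_id <- which.max(cent_y)
  tab <- lab == table_id
  body <- lab > 0 & !tab
  if (params$dilation_iterations > 0) {
    brush <- EBImage::makeBrush(params$kernel_size, shape = "box")
    m <- tab * 1
    for (i in seq_len(params$dilation_iterations))
      m <- EBImage::dilate(m, brush)
    tab <- m > 0
  }
  mask2d <- tab & !body
  out <- ct$values
  out[rep_slices(mask2d, nz)] <- params$replacement_hu
  structure(list(ct_without_table = voxel_volume(out, g, "ct"),
                 table_mask_2d = mask2d,
                 n_components_found = as.integer(ncomp)),
            class = "removal_result")
}

#' @export
print.removal_result <- function(x, ...) {
  cat(sprintf("removal_result: %d component(s), %d in-slice pixels removed\n",
              x$n_components_found, sum(x$table_mask_2d)))
  invisible(x)
}

#' Sensitivity and specificity of table removal against ground truth
#'
#' Sensitivity is the fraction of true table voxels that were removed;
#' specificity is the fraction of true body voxels left untouched. Requires
#' the synthetic ground truth on the same CT grid.
#'
#' @param result a `removal_result` from [remove_table()].
#' @param truth the `truth` element of a [generate_jaszczak()] /
#'   [generate_cardiac_study()] study.
#' @return list(sensitivity =, specificity =).
#' @export
removal_report <- function(result, truth) {
  if (sum(truth$table_mask) == 0) stop("ground-truth table mask is empty")
  nz <- dim(truth$table_mask)[3]
  removed <- rep_slices(result$table_mask_2d, nz)
  list(sensitivity = sum(removed & truth$table_mask) / sum(truth$table_mask),
       specificity = sum(!removed & truth$body_mask) / sum(truth$body_mask))
}
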