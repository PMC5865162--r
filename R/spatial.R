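#' Voxelwise subtype probability maps
#'
#' For each subtype, the per-voxel probability of tumor presence: the number
#' of that subtype's tumor cores (TU + NC) intersecting the voxel divided by
#' the subtype's tumor count. Every voxel value is k / n for an integer k.
#'
#' @param core_masks List of logical 3D core masks sharing one grid.
#' @param subtype_labels Subtype label per mask.
#' @return Named list of `probability_map` objects (one per observed
#'   subtype): each holds `map` (3D array in [0, 1]), `n_tumors`, `subtype`.
#'   Subtypes with zero subjects are omitted with a warning.
#' @export
subtype_probability_map <- function(core_masks, subtype_labels) {
  stopifnot(length(core_masks) == length(subtype_labels))
  dims <- lapply(core_masks, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("core masks do not share one grid")
  labs <- unique(subtype_labels)
  empty <- setdiff(labs, subtype_labels)
  if (length(empty) > 0)
    warning("subtypes without subjects omitted: ", paste(empty, collapse = ", "))
  out <- lapply(labs, function(s) {
    idx <- which(subtype_labels == s)
    acc <- Reduce(`+`, lapply(core_masks[idx], function(m) m * 1))
    structure(list(subtype = s, map = acc / length(idx),
                   n_tumors = length(idx)),
              class = "probability_map")
  })
  names(out) <- labs
  out
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("Tumor frequency map for subtype '%s': %d tumors, max voxel probability %.2f\n",
              x$subtype, x$n_tumors, max(x$map)))
  invisible(x)
}

#' Regional tumor proportions of one core mask
#'
#' Percentage of tumor-core voxels in each of the nine atlas regions; the
#' same contract as [compute_location_features()], operating on a core mask
#' directly.
#'
#' @param core_mask Logical 3D array (TU + NC), nonempty.
#' @param atlas Integer atlas label map on the same grid.
#' @return Named numeric of 9 percentages.
#' @export
regional_tumor_proportions <- function(core_mask, atlas) {
  n <- sum(core_mask)
  if (n == 0) stop("tumor core mask is empty")
  counts <- tabulate(atlas[core_mask], nbins = 9L)
  stats::setNames(100 * counts / n, paste0("LOC_", atlas_region_names()))
}

#' Regional tumor proportions aggregated by subtype
#'
#' Mean of the member regional-proportion vectors within each subtype.
#'
#' @param core_masks List of logical 3D core masks.
#' @param subtype_labels Subtype label per mask.
#' @param atlas Atlas label map.
#' @return Matrix: subtypes x 9 regions.
#' @export
subtype_regional_summary <- function(core_masks, subtype_labels, atlas) {
  per <- t(vapply(core_masks, regional_tumor_proportions,
                  numeric(9), atlas = atlas))
  rs <- rowsum(per, subtype_labels)
  rs / as.vector(table(subtype_labels))
}
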