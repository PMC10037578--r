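#' Threshold a HU volume to a bone mask
#'
#' Bone segmentation by Hounsfield-unit thresholding: a voxel is bone
#' exactly when its value is `>= hu_min`. Cortical bone sits well above
#' soft tissue on the HU scale, so a single lower bound suffices for the
#' thin-shell geometry handled here.
#'
#' @param volume a [voxel_volume()].
#' @param hu_min lower HU bound for bone (default 300).
#' @return a [bone_mask()] with the same shape and spacing.
#' @export
threshold_bone <- function(volume, hu_min = 300) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (!is.finite(hu_min)) stop("hu_min must be finite")
  bone_mask(volume$values >= hu_min, volume$spacing)
}

#' Keep only the largest connected bone component
#'
#' The virtual tissue dissection step: after thresholding, disconnected
#' islands (noise specks, unrelated bone) are discarded and only the largest
#' connected component is retained. Ties are broken in favour of the
#' component containing the lowest linear voxel index.
#'
#' @param mask a [bone_mask()] with at least one true voxel.
#' @param connectivity 6 (face) or 26 (face/edge/corner) neighbourhood;
#'   26 preserves thin oblique shells at coarse spacing.
#' @return a [bone_mask()] containing only the largest component.
#' @export
largest_component <- function(mask, connectivity = 26) {
  stopifnot(inherits(mask, "bone_mask"))
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  if (!any(mask$values)) stop("empty mask: no bone voxels")
  labels <- .cpp_label_components(as.vector(mask$values),
                                  as.integer(dim(mask$values)),
                                  as.integer(connectivity))
  n_comp <- attr(labels, "n_components")
  if (n_comp > 1) {
    sizes <- tabulate(labels, nbins = n_comp)
    # labels are assigned in scan order, so which.max's first-match rule
    # breaks ties by the lowest first-voxel index
    keep <- which.max(sizes)
    vals <- array(labels == keep, dim = dim(mask$values))
  } else {
    vals <- mask$values
  }
  bone_mask(vals, mask$spacing)
}
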