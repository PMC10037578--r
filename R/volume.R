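#' HU voxel volume with physical spacing
#'
#' Minimal container for a CT-like scalar grid: a 3D array of Hounsfield
#' units plus the voxel spacing `(dx, dy, dz)` in mm.
#'
#' @param values 3D numeric array of HU.
#' @param spacing numeric length-3, mm, all positive.
#' @return an object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, spacing) {
  if (!is.array(values) || length(dim(values)) != 3)
    stop("values must be a 3D array")
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive finite values")
  if (any(!is.finite(values))) stop("volume contains non-finite values")
  structure(list(values = values, spacing = as.numeric(spacing)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("voxel_volume: %s voxels, spacing %s mm, HU range [%.0f, %.0f]\n",
              paste(dim(x$values), collapse = "x"),
              paste(x$spacing, collapse = "/"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Binary bone mask with physical spacing
#'
#' @param values 3D logical array.
#' @param spacing numeric length-3, mm.
#' @return an object of class `bone_mask`.
#' @export
bone_mask <- function(values, spacing) {
  if (!is.array(values) || length(dim(values)) != 3)
    stop("values must be a 3D array")
  if (!is.logical(values)) storage.mode(values) <- "logical"
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("spacing must be three positive values")
  structure(list(values = values, spacing = as.numeric(spacing)),
            class = "bone_mask")
}

#' @export
print.bone_mask <- function(x, ...) {
  cat(sprintf("bone_mask: %s voxels, spacing %s mm, %d bone voxels\n",
              paste(dim(x$values), collapse = "x"),
              paste(x$spacing, collapse = "/"), sum(x$values)))
  invisible(x)
}

#' Write a volume or mask to NIfTI
#'
#' Stores the grid with its voxel spacing in the NIfTI pixdim header. Masks
#' are written as uint8, HU volumes as float64 so the grid round-trips
#' bit-exactly.
#'
#' @param x a [voxel_volume()] or [bone_mask()].
#' @param path output file (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(x, path) {
  stopifnot(inherits(x, "voxel_volume") || inherits(x, "bone_mask"))
  vals <- x$values
  dtype <- if (inherits(x, "bone_mask")) {
    storage.mode(vals) <- "integer"
    "uint8"
  } else "double"
  attr(vals, "pixdim") <- x$spacing
  img <- RNifti::asNifti(vals, datatype = dtype)
  # NIfTI-2: float64 header fields, so voxel spacing survives bit-exactly
  RNifti::writeNifti(img, path, datatype = dtype, version = 2)
  invisible(path)
}

#' Read a NIfTI volume written by [write_volume_nifti()]
#'
#' @param path NIfTI file.
#' @param as one of `"volume"` or `"mask"`.
#' @return a [voxel_volume()] or [bone_mask()].
#' @export
read_volume_nifti <- function(path, as = c("volume", "mask")) {
  as <- match.arg(as)
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  vals <- array(as.vector(img), dim = dim(img))
  if (as == "mask") bone_mask(vals != 0, spacing)
  else voxel_volume(vals, spacing)
}

#' Serialize a phantom specification to YAML
#'
#' @param spec a [phantom_spec()].
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' Read a phantom specification from YAML
#'
#' @param path YAML file written by [write_phantom_spec()].
#' @return a validated [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  l <- yaml::read_yaml(path)
  phantom_spec(floor_kind = l$floor_kind, a = l$a, b = l$b,
               tilt_deg = l$tilt_deg, cap_radius_R = l$cap_radius_R,
               shell_thickness = l$shell_thickness,
               bone_hu = l$bone_hu, tissue_hu = l$tissue_hu,
               air_hu = l$air_hu, noise_sd = l$noise_sd,
               voxel_spacing = unlist(l$voxel_spacing),
               volume_extent = unlist(l$volume_extent),
               floor_margin = l$floor_margin, seed = l$seed)
}
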