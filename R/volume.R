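#' Volumetric image container
#'
#' A `volume_image` is the unit of reconstruction, restoration and analysis:
#' a 3D scalar grid (arbitrary units) with isotropic-or-not voxel spacing and
#' a world-frame origin, both in millimetres. The origin is the position of
#' the centre of voxel `[1, 1, 1]`.
#'
#' @param voxels 3D numeric array.
#' @param spacing Voxel spacing in mm; length 1 (isotropic) or 3.
#' @param origin World position (mm) of the first voxel centre; length 3.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(voxels, spacing = 1, origin = c(0, 0, 0)) {
  assert_that(is.array(voxels) && length(dim(voxels)) == 3,
              "voxels must be a 3D array")
  assert_that(all(is.finite(voxels)), "voxels must be finite")
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  assert_that(length(spacing) == 3 && all(spacing > 0),
              "spacing must be positive (length 1 or 3)")
  assert_that(length(origin) == 3, "origin must have length 3")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "volume_image")
}

#' @exportS3Method base::print
print.volume_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volume_image> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  range [%.4g, %.4g], origin (%s) mm\n",
              min(x$voxels), max(x$voxels),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' @export
dim.volume_image <- function(x) dim(x$voxels)

# World coordinates (mm) of every voxel centre, as an n x 3 matrix in
# column-major voxel order.
voxel_positions <- function(vol) {
  d <- dim(vol$voxels)
  ax <- lapply(1:3, function(k) vol$origin[k] + (seq_len(d[k]) - 1) * vol$spacing[k])
  as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                        KEEP.OUT.ATTRS = FALSE))
}

#' Template grid for reconstruction
#'
#' Convenience constructor for an all-zero [volume_image()] describing the
#' reconstruction grid: a cube of side `fov_mm` centred on `centre`.
#'
#' @param shape Integer vector of length 3 (voxels per axis).
#' @param fov_mm Physical side length of the field of view in mm.
#' @param centre World centre of the grid (mm).
#' @return A `volume_image` filled with zeros.
#' @export
volume_template <- function(shape, fov_mm = 12.8, centre = c(0, 0, 0)) {
  shape <- as.integer(shape)
  assert_that(length(shape) == 3 && all(shape >= 1), "shape must be 3 positive counts")
  spacing <- fov_mm / shape
  origin <- centre - fov_mm / 2 + spacing / 2
  volume_image(array(0, shape), spacing = spacing, origin = origin)
}

#' Read a volume from NIfTI or TIFF
#'
#' NIfTI (`.nii`, `.nii.gz`) carries voxel spacing; multi-page TIFF is read
#' as a z-stack with unit spacing (TIFF carries no calibrated 3D metadata).
#'
#' @param path File path.
#' @return A [volume_image()].
#' @export
read_volume <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(img)
    vox <- array(as.numeric(img), dim = dim(img))
    return(volume_image(vox, spacing = sp[1:3]))
  }
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    vox <- array(0, c(dim(pages[[1]])[1], dim(pages[[1]])[2], length(pages)))
    for (k in seq_along(pages)) vox[, , k] <- pages[[k]]
    return(volume_image(vox))
  }
  hd_stop(sprintf("unsupported volume format: %s", path))
}

#' Write a volume to NIfTI or TIFF
#'
#' @param vol A [volume_image()].
#' @param path Output path; format chosen by extension (`.nii`, `.nii.gz`,
#'   `.tif`, `.tiff`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  assert_that(inherits(vol, "volume_image"), "vol must be a volume_image")
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(vol$voxels)
    RNifti::pixdim(img) <- vol$spacing
    RNifti::writeNifti(img, path)
    return(invisible(path))
  }
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    v <- vol$voxels
    # 32-bit float TIFF pages expect [0,1]; rescale only if needed
    if (min(v) < 0 || max(v) > 1) v <- (v - min(v)) / max(max(v) - min(v), 1e-12)
    pages <- lapply(seq_len(dim(v)[3]), function(k) v[, , k])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    return(invisible(path))
  }
  hd_stop(sprintf("unsupported volume format: %s", path))
}
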