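#' @useDynLib patchgrade, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats coef lm mad median pf predict pt qnorm rbinom rnorm
#'   runif sd setNames var aov TukeyHSD chisq.test oneway.test p.adjust
#'   model.matrix complete.cases quantile
#' @importFrom utils read.csv write.csv
NULL

# Structure label codes used throughout: 0 = non-structure.
STRUCTURES <- c(HPC_L = 1L, HPC_R = 2L, EC_L = 3L, EC_R = 4L)

#' Create a volume object
#'
#' A volume is a plain 3D numeric array with a `voxel_size` attribute
#' (mm, isotropic). All grids in this package are isotropic and centred:
#' world coordinates are `(index - (n+1)/2) * voxel_size` per axis.
#'
#' @param data 3D numeric array.
#' @param voxel_size voxel edge length in mm.
#' @return the array with class `pg_volume`.
#' @export
as_volume <- function(data, voxel_size = 1) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  attr(data, "voxel_size") <- voxel_size
  class(data) <- c("pg_volume", class(data))
  data
}

#' @export
print.pg_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<pg_volume %dx%dx%d, %.3g mm iso, range [%.4g, %.4g]>\n",
              d[1], d[2], d[3], voxel_size(x), min(x), max(x)))
  invisible(x)
}

#' Voxel size of a volume
#' @param vol a volume.
#' @return voxel edge length in mm (1 if unset).
#' @export
voxel_size <- function(vol) {
  vs <- attr(vol, "voxel_size")
  if (is.null(vs)) 1 else vs
}

strip_volume <- function(vol) {
  # bare numeric array for the C++ kernels
  v <- as.numeric(vol)
  dim(v) <- dim(vol)
  v
}

#' Write a volume as NIfTI-1
#'
#' @param vol a volume (3D array).
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(vol, path) {
  vs <- voxel_size(vol)
  img <- RNifti::asNifti(strip_volume(vol), pixdim = c(vs, vs, vs))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path NIfTI file path.
#' @return a `pg_volume`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1]
  as_volume(array(as.numeric(img), dim = dim(img)), voxel_size = vs)
}

#' Dice overlap coefficient
#'
#' `2|A n B| / (|A| + |B|)` for two binary masks on the same grid.
#'
#' @param a,b logical arrays (or coercible).
#' @return Dice coefficient in \[0, 1\]; `NaN` when both masks are empty.
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  a <- as.logical(a); b <- as.logical(b)
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' Dilate a binary mask by a cubic structuring element
#'
#' @param mask logical 3D array.
#' @param r half-width of the cube in voxels.
#' @return dilated logical array, same grid.
#' @export
dilate_mask <- function(mask, r = 1L) {
  d <- dim(mask)
  out <- .pg_dilate_cube(as.logical(mask), as.integer(d), as.integer(r))
  dim(out) <- d
  out
}

#' Rigid-body transform matrix
#'
#' Builds the 4x4 homogeneous matrix for rotations (degrees, applied in
#' x-y-z order) about the grid centre followed by a translation (mm),
#' acting on centred world coordinates.
#'
#' @param rot length-3 rotations in degrees.
#' @param trans length-3 translation in mm.
#' @return 4x4 numeric matrix.
#' @export
rigid_matrix <- function(rot = c(0, 0, 0), trans = c(0, 0, 0)) {
  th <- rot * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), sin(th[1]), 0, -sin(th[1]), cos(th[1])), 3, 3)
  Ry <- matrix(c(cos(th[2]), 0, -sin(th[2]), 0, 1, 0, sin(th[2]), 0, cos(th[2])), 3, 3)
  Rz <- matrix(c(cos(th[3]), sin(th[3]), 0, -sin(th[3]), cos(th[3]), 0, 0, 0, 1), 3, 3)
  A <- diag(4)
  A[1:3, 1:3] <- Rz %*% Ry %*% Rx
  A[1:3, 4] <- trans
  A
}

#' Resample a volume through an affine transform
#'
#' `A` maps output world coordinates (mm, origin at grid centre) to input
#' world coordinates; the output value at `x` is `vol(A x)`. Trilinear
#' interpolation by default, nearest-neighbour for label fields.
#'
#' @param vol input volume.
#' @param A 4x4 homogeneous matrix.
#' @param out_dim output grid extent (defaults to the input grid).
#' @param voxel_size_out output voxel size in mm.
#' @param nearest use nearest-neighbour interpolation.
#' @param fill value for points sampling outside the input grid.
#' @return resampled volume.
#' @export
resample_affine <- function(vol, A, out_dim = dim(vol),
                            voxel_size_out = voxel_size(vol),
                            nearest = FALSE, fill = 0) {
  stopifnot(all(dim(A) == c(4, 4)), all(abs(A[4, ] - c(0, 0, 0, 1)) < 1e-12))
  out <- .pg_resample(strip_volume(vol), as.integer(dim(vol)), A,
                      as.integer(out_dim), voxel_size(vol), voxel_size_out,
                      nearest, fill)
  as_volume(out, voxel_size = voxel_size_out)
}

#' Label code of a structure
#'
#' Maps a structure name (`HPC_L`, `HPC_R`, `EC_L`, `EC_R`) to its
#' integer label-field code; integer input passes through.
#'
#' @param structure structure name or code.
#' @return integer label code.
#' @export
structure_code <- function(structure) {
  if (is.numeric(structure)) return(as.integer(structure))
  if (!structure %in% names(STRUCTURES))
    stop("unknown structure: ", structure)
  STRUCTURES[[structure]]
}
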