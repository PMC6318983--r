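## 3D intensity volumes with per-axis physical spacing.
## Coordinate convention: continuous, 0-based, voxel-centre coordinates.
## The centre of array voxel [1, 1, 1] is at coordinate (0, 0, 0); all surfel
## positions live in this frame. Physical spacing only matters when sampling
## along normals (so the search band is isotropic in physical space) and when
## reporting measurements in physical units.

#' Construct a 3D image
#'
#' @param voxels a numeric 3D array (x, y, z order; z is the slice index).
#' @param spacing numeric 3-vector of physical units per voxel along x, y, z.
#' @return An object of class `image3d`.
#' @export
image3d <- function(voxels, spacing = c(1, 1, 1)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3)
    stop("voxels must be a 3D array")
  if (any(dim(voxels) < 2)) stop("each image dimension must have >= 2 voxels")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive numbers")
  storage.mode(voxels) <- "double"
  structure(list(voxels = voxels, spacing = spacing), class = "image3d")
}

#' @export
print.image3d <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image3d: %d x %d x %d voxels, spacing (%g, %g, %g)\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Load a multi-page TIFF as a 3D volume
#'
#' The page index becomes the z axis; intensities are read as floats. When
#' the file carries x/y resolution tags the pixel size is taken as the
#' inverse resolution; otherwise spacing defaults to (1, 1, 1) with a
#' message (z spacing is never stored in plain TIFF and defaults to 1).
#'
#' @param path path to a grayscale multi-page TIFF.
#' @param spacing optional 3-vector overriding any metadata.
#' @return An [image3d()] object.
#' @export
load_volume <- function(path, spacing = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e) stop("cannot read TIFF: ",
                                             conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2) stop("a 3D volume needs at least 2 TIFF pages")
  first <- pages[[1]]
  if (length(dim(first)) == 3) {  # multi-channel page: take channel 1
    pages <- lapply(pages, function(m) m[, , 1])
    first <- pages[[1]]
  }
  ## readTIFF returns row x col = y x x; transpose to x, y
  nx <- ncol(first); ny <- nrow(first); nz <- length(pages)
  vol <- array(0, c(nx, ny, nz))
  for (k in seq_len(nz)) vol[, , k] <- t(pages[[k]])
  if (is.null(spacing)) {
    info <- attributes(pages[[1]])
    xr <- info$x.resolution
    yr <- info$y.resolution
    if (!is.null(xr) && !is.null(yr) && is.finite(xr) && is.finite(yr) &&
        xr > 0 && yr > 0) {
      spacing <- c(1 / xr, 1 / yr, 1)
    } else {
      message("no resolution metadata; assuming unit voxel spacing")
      spacing <- c(1, 1, 1)
    }
  }
  image3d(vol, spacing)
}

#' Write a volume as a multi-page float TIFF
#'
#' Intensities outside `[0, 1]` are rescaled affinely into that range (the
#' segmentation is invariant to affine intensity maps). Resolution tags
#' record the x/y pixel size.
#'
#' @param img an [image3d()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(img, path) {
  stopifnot(inherits(img, "image3d"))
  v <- img$voxels
  rng <- range(v)
  if (rng[1] < 0 || rng[2] > 1) {
    span <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
    v <- (v - rng[1]) / span
  }
  pages <- lapply(seq_len(dim(v)[3]), function(k) t(v[, , k]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                  reduce = FALSE)
  invisible(path)
}

#' Trilinear intensity sampling
#'
#' @param img an [image3d()].
#' @param position a 3-vector or an n x 3 matrix of continuous voxel
#'   coordinates.
#' @return Interpolated intensities; `NA` for positions outside the volume
#'   (callers rank `NA` below every in-volume intensity).
#' @export
sample_image <- function(img, position) {
  stopifnot(inherits(img, "image3d"))
  pts <- if (is.matrix(position)) position else matrix(as.numeric(position), 1)
  cpp_trilinear(as.vector(img$voxels), dim(img$voxels), pts)
}
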