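## Synthetic benchmark volumes. All phantoms render membrane-like shells
## (bright surfaces on a dark background) because the image force seeks
## intensity maxima along the normal; optional additive Gaussian noise comes
## from a seeded RNG so a given spec always yields the identical volume.

.phantom_noise <- function(vol, noise_sigma, seed) {
  if (noise_sigma > 0) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
    vol <- vol + array(stats::rnorm(length(vol), 0, noise_sigma), dim(vol))
  }
  vol
}

## squared distance of every voxel centre to a point, as a 3D array
.dist_grid <- function(size, center) {
  gx <- (seq_len(size[1]) - 1) - center[1]
  gy <- (seq_len(size[2]) - 1) - center[2]
  gz <- (seq_len(size[3]) - 1) - center[3]
  outer(outer(gx^2, gy^2, `+`), gz^2, `+`)
}

#' Sphere-shell phantom
#'
#' A hollow sphere: voxels whose distance to `center` falls within
#' `radius +- thickness/2` are set to 1, everything else to 0, then
#' Gaussian noise of standard deviation `noise_sigma` is added (the shell
#' has signal value 1 and is about 2 px thick by default, so `noise_sigma`
#' is directly the inverse signal-to-noise ratio).
#'
#' @param size integer 3-vector of volume dimensions, voxels.
#' @param center sphere centre, voxel coordinates; defaults to the volume
#'   centre.
#' @param radius shell radius, pixels.
#' @param thickness shell thickness, pixels (default 2).
#' @param noise_sigma additive Gaussian noise sd (0 = noiseless).
#' @param seed RNG seed for the noise.
#' @return An [image3d()].
#' @export
phantom_sphere_shell <- function(size = c(100, 100, 100),
                                 center = (size - 1) / 2, radius = 30,
                                 thickness = 2, noise_sigma = 0, seed = 1L) {
  size <- as.integer(size)
  if (thickness < 1) stop("thickness must be >= 1 voxel")
  if (radius + thickness / 2 + 2 > min(size) / 2)
    stop("sphere shell does not fit in the volume with a 2-voxel margin")
  d <- sqrt(.dist_grid(size, center))
  vol <- array(0, size)
  vol[d >= radius - thickness / 2 & d <= radius + thickness / 2] <- 1
  image3d(.phantom_noise(vol, noise_sigma, seed))
}

#' Plane-with-hole phantom
#'
#' The volume is cut in half by a bright slab at `z = z_plane` containing a
#' circular hole of radius `r_hole` centred on the volume's z axis — the
#' leakage/arrest test geometry: a surface inflating from below either
#' stops around the hole or flows through it depending on
#' `r_hole * f_pressure`.
#'
#' @param size volume dimensions (default 100^3).
#' @param r_hole hole radius, pixels (must leave the plane attached:
#'   `r_hole < 45` for the default size).
#' @param thickness slab thickness, pixels (default 2).
#' @param z_plane slab centre slice (default mid-volume).
#' @param noise_sigma,seed optional additive noise.
#' @return An [image3d()].
#' @export
phantom_plane_with_hole <- function(size = c(100, 100, 100), r_hole = 10,
                                    thickness = 2, z_plane = size[3] / 2,
                                    noise_sigma = 0, seed = 1L) {
  size <- as.integer(size)
  if (r_hole >= min(size[1], size[2]) / 2 - 5)
    stop("r_hole too large: the plane must stay attached to the volume sides")
  zc <- (seq_len(size[3]) - 1)
  in_slab <- abs(zc - z_plane) <= thickness / 2
  cx <- (size[1] - 1) / 2; cy <- (size[2] - 1) / 2
  gx <- (seq_len(size[1]) - 1) - cx
  gy <- (seq_len(size[2]) - 1) - cy
  r2 <- outer(gx^2, gy^2, `+`)
  slab <- matrix(1, size[1], size[2])
  if (r_hole > 0) slab[r2 <= r_hole^2] <- 0
  vol <- array(0, size)
  for (k in which(in_slab)) vol[, , k] <- slab
  image3d(.phantom_noise(vol, noise_sigma, seed))
}

#' Torus-shell phantom
#'
#' A hollow torus: voxels at distance `r_minor +- thickness/2` from the
#' spine circle (radius `R_major` in the plane `z = center[3]`) are bright.
#' Used for the fusion test: a spherical seed inflating inside the tube
#' meets itself around the hole and must merge.
#'
#' @param size volume dimensions.
#' @param center torus centre.
#' @param R_major spine-circle radius, pixels.
#' @param r_minor tube radius, pixels.
#' @param thickness shell thickness.
#' @param noise_sigma,seed optional additive noise.
#' @return An [image3d()].
#' @export
phantom_torus <- function(size = c(100, 100, 100), center = (size - 1) / 2,
                          R_major = 28, r_minor = 12, thickness = 2,
                          noise_sigma = 0, seed = 1L) {
  size <- as.integer(size)
  if (R_major + r_minor + thickness / 2 + 2 > min(size[1], size[2]) / 2)
    stop("torus does not fit in the volume with a 2-voxel margin")
  gx <- (seq_len(size[1]) - 1) - center[1]
  gy <- (seq_len(size[2]) - 1) - center[2]
  gz <- (seq_len(size[3]) - 1) - center[3]
  rho <- sqrt(outer(gx^2, gy^2, `+`))            # radial distance in xy
  a <- (rho - R_major)^2                         # nx x ny
  d <- sqrt(outer(a, gz^2, `+`))                 # distance to spine circle
  vol <- array(0, size)
  vol[d >= r_minor - thickness / 2 & d <= r_minor + thickness / 2] <- 1
  image3d(.phantom_noise(vol, noise_sigma, seed))
}

#' Two disjoint sphere shells
#'
#' The fission test geometry: one enclosing seed deflating under negative
#' pressure must split into two surfaces, one per shell.
#'
#' @param size volume dimensions.
#' @param centers 2 x 3 matrix of sphere centres.
#' @param radii length-2 vector of shell radii.
#' @param thickness shell thickness.
#' @param noise_sigma,seed optional additive noise.
#' @return An [image3d()].
#' @export
phantom_two_spheres <- function(size = c(100, 100, 100),
                                centers = rbind(c(28, 49.5, 49.5),
                                                c(71, 49.5, 49.5)),
                                radii = c(16, 16), thickness = 2,
                                noise_sigma = 0, seed = 1L) {
  size <- as.integer(size)
  centers <- as.matrix(centers)
  gap <- sqrt(sum((centers[1, ] - centers[2, ])^2))
  if (gap <= radii[1] + radii[2] + thickness)
    stop("spheres overlap; the fission phantom needs disjoint shells")
  vol <- array(0, size)
  for (s in 1:2) {
    d <- sqrt(.dist_grid(size, centers[s, ]))
    vol[d >= radii[s] - thickness / 2 & d <= radii[s] + thickness / 2] <- 1
  }
  image3d(.phantom_noise(vol, noise_sigma, seed))
}
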