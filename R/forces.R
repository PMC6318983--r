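## Surfel-surfel pair interactions and image forces.
##
## All forces are displacements per integration step in units of d0 (the
## update rule multiplies the resulting force by d0). Three pair terms act
## between same-object neighbors:
##   F_dist  -- distance-restoring force along the inter-surfel unit vector u:
##              harmonic repulsion below d0, breakable-bond attraction above
##              (zero at d0 and at infinity), scaled by the stiffness k_dist;
##   F_plane -- co-planarity force k_plane * (u . (n_i + n_j)) n_i;
##   T_tilt  -- normal-alignment increment -k_tilt * (n_i . u) u, which
##              relaxes the normal towards the local surface plane (removes
##              the component of n_i along u).
## Surfels of different objects interact only through the repulsive branch of
## F_dist (pure surface exclusion).

#' Signed distance-force profile
#'
#' The scalar profile `f(x)` with `x = d / d0`, applied along the unit
#' vector from surfel i to surfel j; negative values repel, positive values
#' attract. Below the equilibrium distance the force is harmonic,
#' `x - 1`; above it, the bond is breakable:
#' `(x - 1) * exp(-(x - 1)^2 / w^2)`, vanishing at `x = 1` and as
#' `x -> Inf`. The default width `w = 0.4` makes the bond negligible near
#' the sphere-of-influence cutoff `x = alpha = 1.75`.
#'
#' @param x positive numeric vector of scaled distances `d / d0`.
#' @param w attractive-branch width, units of `d0`.
#' @return Signed magnitudes, same length as `x`.
#' @examples
#' f_dist_profile(c(0.5, 1, 1.4))
#' @export
f_dist_profile <- function(x, w = 0.4) {
  x <- as.numeric(x)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("scaled distance must be > 0 (coincident surfels must be jittered)")
  e <- x - 1
  ifelse(x < 1, e, e * exp(-e^2 / w^2))
}

#' Pair interaction between two same-object surfels
#'
#' @param si,sj [make_surfel()] objects (distinct positions).
#' @param p a [surf_params()] object.
#' @return A list with the three interaction vectors acting on `si`:
#'   `F_dist` (parallel to the inter-surfel unit vector `u`), `F_plane`
#'   (parallel to `n_i`), `T_tilt` (parallel to `u`), plus `u` and the
#'   distance `d`.
#' @export
pair_interaction <- function(si, sj, p) {
  dp <- sj$position - si$position
  d <- sqrt(sum(dp^2))
  if (d == 0) stop("coincident surfels")
  u <- dp / d
  fd <- p$k_dist * f_dist_profile(d / p$d0, p$profile_w)
  list(F_dist = fd * u,
       F_plane = p$k_plane * sum(u * (si$normal + sj$normal)) * si$normal,
       T_tilt = -p$k_tilt * sum(si$normal * u) * u,
       u = u, d = d)
}

#' Pair interaction between surfels of different objects
#'
#' Cross-object surfels are not neighbors: only the repulsive branch of
#' `F_dist` is kept, so distinct surfaces exclude each other without
#' co-planarity or tilt coupling.
#'
#' @inheritParams pair_interaction
#' @return Same shape as [pair_interaction()]; `F_plane` and `T_tilt` are
#'   zero, and `F_dist` is zero beyond `d0`.
#' @export
pair_interaction_repulsive_only <- function(si, sj, p) {
  if (si$object_id == sj$object_id)
    stop("repulsive-only interaction requires distinct object ids")
  dp <- sj$position - si$position
  d <- sqrt(sum(dp^2))
  if (d == 0) stop("coincident surfels")
  u <- dp / d
  x <- d / p$d0
  fd <- if (x < 1) p$k_dist * (x - 1) else 0
  list(F_dist = fd * u, F_plane = c(0, 0, 0), T_tilt = c(0, 0, 0),
       u = u, d = d)
}

#' Offset of the local image maximum along a surfel normal
#'
#' Samples the image by trilinear interpolation at `p + s * n` for `s` on a
#' uniform grid spanning `[-band, band]` (step 0.5 px; under anisotropic
#' spacing the direction is normalised in physical space so the band is
#' physically isotropic) and returns the signed offset of the maximum
#' sample. A plateau of equal maxima (e.g. inside a thick bright shell)
#' returns the plateau centroid. Returns `NA` when the profile is flat
#' (max - min below `1e-6`) or entirely outside the volume; out-of-volume
#' samples rank below every in-volume intensity.
#'
#' @param img an [image3d()].
#' @param position 3-vector or n x 3 matrix of voxel coordinates.
#' @param normal matching 3-vector or n x 3 matrix of unit normals.
#' @param band half-width of the search, pixels.
#' @return Signed offsets (NA = no usable maximum), one per row.
#' @export
local_max_offset <- function(img, position, normal, band) {
  stopifnot(inherits(img, "image3d"), band > 0)
  pos <- if (is.matrix(position)) position else matrix(as.numeric(position), 1)
  nrm <- if (is.matrix(normal)) normal else matrix(as.numeric(normal), 1)
  cpp_profile_max(as.vector(img$voxels), dim(img$voxels), pos, nrm,
                  band, 0.5, img$spacing, 1e-6)
}

#' Image force on a surfel
#'
#' Combines the constant-norm data-attachment force
#' `F_signal = sign(s*) * f_signal * n` (pointing towards the nearest local
#' intensity maximum along the normal) with the balloon force
#' `F_pressure = f_pressure * n`. A surfel within half a sampling step
#' (0.5 px) of the maximum is "at the maximum": both terms become null and
#' the surfel is held in place by its neighbors alone. When no maximum
#' exists along the profile (flat signal) only the pressure acts.
#'
#' @param s a [make_surfel()] object.
#' @param img an [image3d()].
#' @param p a [surf_params()] object.
#' @return A list with `F_total` (3-vector) and `at_maximum` (logical).
#' @export
image_force <- function(s, img, p) {
  off <- local_max_offset(img, s$position, s$normal, p$search_band)
  if (is.na(off)) {
    list(F_total = p$f_pressure * s$normal, at_maximum = FALSE)
  } else if (abs(off) <= 0.5) {
    list(F_total = c(0, 0, 0), at_maximum = TRUE)
  } else {
    list(F_total = (sign(off) * p$f_signal + p$f_pressure) * s$normal,
         at_maximum = FALSE)
  }
}

## Internal vectorised image-force magnitudes for a whole system.
## Returns the scalar coefficient of n per surfel.
.image_force_scalars <- function(pos, nrm, img, p) {
  if (is.null(img)) return(rep(p$f_pressure, nrow(pos)))
  off <- cpp_profile_max(as.vector(img$voxels), dim(img$voxels), pos, nrm,
                         p$search_band, 0.5, img$spacing, 1e-6)
  out <- rep(p$f_pressure, nrow(pos))
  at_max <- !is.na(off) & abs(off) <= 0.5
  push <- !is.na(off) & abs(off) > 0.5
  out[at_max] <- 0
  out[push] <- sign(off[push]) * p$f_signal + p$f_pressure
  out
}
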