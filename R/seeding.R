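## Seed construction: every segmentation starts from a surfel system that
## already delimits a closed surface. Seeds are spheres (Fibonacci
## tessellation at spacing ~ d0), generalized cylinders interpolated through
## a stack of planar ROIs ("skeleton" seeds for non-spherical objects), or
## pre-existing oriented clouds (e.g. the output of the previous time frame).

#' Spherical seed
#'
#' Tessellates a sphere with a Fibonacci lattice whose point count
#' `n = round(4 pi R^2 / ((sqrt(3)/2) d0^2))` gives nearest-neighbor
#' spacing close to `d0` (one hexagonal tile of side `d0` per surfel).
#' Normals point radially outward.
#'
#' @param center 3-vector, voxel coordinates.
#' @param radius sphere radius, pixels; must be at least `d0`.
#' @param d0 target inter-surfel spacing, pixels.
#' @param object_id object identifier for all surfels of this seed.
#' @return A list of [make_surfel()] objects.
#' @export
sphere_seed <- function(center, radius, d0, object_id = 0L) {
  if (radius < d0)
    stop("seed radius (", radius, ") must be at least d0 (", d0,
         "): coarser seeds cannot be tessellated at spacing d0")
  center <- as.numeric(center)
  n <- max(4L, round(4 * pi * radius^2 / (sqrt(3) / 2 * d0^2)))
  pts <- fibonacci_sphere(n)
  lapply(seq_len(n), function(i)
    make_surfel(center + radius * pts[i, ], pts[i, ], object_id))
}

#' Fibonacci lattice on the unit sphere
#'
#' @param n number of points.
#' @return An `n x 3` matrix of unit vectors, near-uniformly distributed.
#' @export
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i          # golden-angle longitudes
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Skeleton seed from a stack of planar ROIs
#'
#' Builds a generalized-cylinder surface through closed polygons drawn on
#' distinct z slices: consecutive outlines are put in correspondence by
#' normalized arc length and linearly interpolated at a z pitch of ~ `d0`,
#' each intermediate ring is resampled at arc spacing ~ `d0`, and the two
#' ends are capped with flat disks. Normals point outward (away from the
#' local ring centroid; caps point along -z / +z).
#'
#' @param rois a list of `list(z = slice, polygon = k x 2 matrix)` entries,
#'   at least two, at distinct z; polygons are closed implicitly (do not
#'   repeat the first vertex) and must not self-intersect.
#' @param d0 target spacing, pixels.
#' @param object_id object identifier.
#' @return A list of [make_surfel()] objects.
#' @export
skeleton_seed <- function(rois, d0, object_id = 0L) {
  if (!is.list(rois) || length(rois) < 2)
    stop("a skeleton seed needs at least 2 ROIs at distinct z")
  zs <- vapply(rois, function(r) as.numeric(r$z), numeric(1))
  if (anyDuplicated(zs)) stop("ROI z slices must be distinct")
  rois <- rois[order(zs)]
  zs <- sort(zs)
  polys <- lapply(rois, function(r) {
    pg <- as.matrix(r$polygon)
    if (nrow(pg) < 3 || ncol(pg) != 2) stop("degenerate polygon in ROI")
    pg
  })
  ## common angular sampling count from the largest outline
  perim <- vapply(polys, .poly_perimeter, numeric(1))
  m <- max(8L, round(max(perim) / d0))
  rings <- lapply(polys, .resample_polygon, m = m)

  surfels <- list()
  add_ring <- function(ring2d, z, normal_z = 0) {
    ctr <- colMeans(ring2d)
    for (k in seq_len(nrow(ring2d))) {
      radial <- c(ring2d[k, ] - ctr, 0)
      nr <- sqrt(sum(radial^2))
      nvec <- if (normal_z != 0) c(0, 0, normal_z)
              else if (nr > 1e-9) radial / nr else c(0, 0, 1)
      surfels[[length(surfels) + 1L]] <<-
        make_surfel(c(ring2d[k, ], z), nvec, object_id)
    }
  }
  ## walls: interpolate between consecutive ROIs at pitch ~ d0
  for (s in seq_len(length(rings) - 1)) {
    dz <- zs[s + 1] - zs[s]
    nstep <- max(1L, round(dz / d0))
    for (t in seq(0, 1, length.out = nstep + 1)) {
      if (s > 1 && t == 0) next                 # shared ring already emitted
      ring <- (1 - t) * rings[[s]] + t * rings[[s + 1]]
      add_ring(ring, zs[s] + t * dz)
    }
  }
  ## caps: concentric shrunken copies of the end outlines, normals +-z
  for (end in c(1L, length(rings))) {
    ring <- rings[[end]]
    ctr <- colMeans(ring)
    rad <- max(sqrt(rowSums(sweep(ring, 2, ctr)^2)))
    nring <- max(0L, floor(rad / d0) - 1L)
    nz <- if (end == 1L) -1 else 1
    if (nring >= 1)
      for (f in seq_len(nring) / (nring + 1)) {
        shr <- sweep(sweep(ring, 2, ctr) * (1 - f), 2, ctr, `+`)
        keep <- unique(round(seq(1, nrow(shr),
                                 length.out = max(4, round(nrow(shr) * (1 - f))))))
        add_ring(shr[keep, , drop = FALSE], zs[end], normal_z = nz)
      }
    surfels[[length(surfels) + 1L]] <-
      make_surfel(c(ctr, zs[end]), c(0, 0, nz), object_id)
  }
  surfels
}

.poly_perimeter <- function(pg) {
  pg2 <- rbind(pg, pg[1, ])
  sum(sqrt(rowSums(diff(pg2)^2)))
}

## resample a closed polygon at m points equally spaced in arc length
.resample_polygon <- function(pg, m) {
  pg2 <- rbind(pg, pg[1, ])
  seg <- sqrt(rowSums(diff(pg2)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) stop("degenerate polygon (zero perimeter)")
  s <- seq(0, total, length.out = m + 1)[-(m + 1)]
  x <- stats::approx(cum, pg2[, 1], xout = s)$y
  y <- stats::approx(cum, pg2[, 2], xout = s)$y
  cbind(x, y)
}

#' Seed from an existing oriented point cloud
#'
#' Wraps a cloud (e.g. a previous frame's output, or an imported PLY) as
#' mature active surfels, ready to resume evolving.
#'
#' @param points an `oriented_cloud` / data frame with columns
#'   `x, y, z, nx, ny, nz`, or an `n x 6` matrix.
#' @param object_id object identifier; defaults to the cloud's own
#'   `object_id` column when present.
#' @return A list of [make_surfel()] objects.
#' @export
cloud_seed <- function(points, object_id = NULL) {
  if (is.matrix(points))
    points <- data.frame(x = points[, 1], y = points[, 2], z = points[, 3],
                         nx = points[, 4], ny = points[, 5], nz = points[, 6])
  if (nrow(points) == 0) stop("empty point cloud")
  ids <- if (!is.null(object_id)) rep(as.integer(object_id), nrow(points))
         else if (!is.null(points$object_id)) as.integer(points$object_id)
         else rep(0L, nrow(points))
  lapply(seq_len(nrow(points)), function(i)
    make_surfel(c(points$x[i], points$y[i], points$z[i]),
                c(points$nx[i], points$ny[i], points$nz[i]), ids[i]))
}

#' Read a seed specification file
#'
#' A YAML list of seed entries. Each entry has `kind` (`sphere`,
#' `skeleton` or `cloud`) and `object_id`, plus `center`/`radius` for
#' spheres, `rois` (each with `z` and `polygon`, a list of `[x, y]`
#' vertices) for skeletons, or `path` to a PLY file for clouds.
#'
#' @param path YAML file path.
#' @param d0 spacing used to tessellate sphere and skeleton seeds.
#' @return A list of [make_surfel()] objects combining all seeds.
#' @export
read_seeds <- function(path, d0) {
  spec <- yaml::read_yaml(path)
  if (!is.list(spec) || length(spec) == 0) stop("empty seed specification")
  out <- list()
  for (entry in spec) {
    oid <- as.integer(entry$object_id %||% 0L)
    s <- switch(entry$kind,
      sphere = sphere_seed(as.numeric(entry$center), as.numeric(entry$radius),
                           d0, oid),
      skeleton = skeleton_seed(lapply(entry$rois, function(r)
        list(z = r$z, polygon = do.call(rbind, r$polygon))), d0, oid),
      cloud = cloud_seed(import_ply(entry$path), oid),
      stop("unknown seed kind: ", entry$kind))
    out <- c(out, s)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
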