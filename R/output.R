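## Export and shape analysis of oriented point clouds.
## The cloud itself is the segmentation result; measurements treat each
## surfel as one hexagonal tile of side ~ d0 and integrate over the closed
## surface (volume by the divergence theorem).

#' Export an oriented cloud as ASCII PLY
#'
#' Properties, in order: `x y z nx ny nz object_id` (float, float ... int32).
#' The file re-imports losslessly at single-float printed precision.
#'
#' @param cloud an `oriented_cloud` (see [as_cloud()]), or anything
#'   coercible by `as_cloud`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_ply <- function(cloud, path) {
  cloud <- as_cloud(cloud)
  if (nrow(cloud) == 0) stop("cannot export an empty cloud")
  con <- file(path, "wb")  # binary connection: LF line endings on any OS
  on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0",
           "comment oriented surfel cloud",
           paste("element vertex", nrow(cloud)),
           "property float x", "property float y", "property float z",
           "property float nx", "property float ny", "property float nz",
           "property int object_id",
           "end_header")
  writeLines(hdr, con, sep = "\n")
  lines <- sprintf("%.8g %.8g %.8g %.8g %.8g %.8g %d",
                   cloud$x, cloud$y, cloud$z,
                   cloud$nx, cloud$ny, cloud$nz, as.integer(cloud$object_id))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Import an ASCII PLY oriented cloud
#'
#' Reads vertices with `x y z nx ny nz` properties (and `object_id` when
#' present) as written by [export_ply()].
#'
#' @param path PLY file path.
#' @return An `oriented_cloud` data frame.
#' @export
import_ply <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || lines[1] != "ply") stop("not a PLY file: ", path)
  if (!grepl("^format ascii", lines[2])) stop("only ASCII PLY is supported")
  endh <- match("end_header", lines)
  if (is.na(endh)) stop("malformed PLY: no end_header")
  vline <- grep("^element vertex ", lines[seq_len(endh)], value = TRUE)
  if (!length(vline)) stop("malformed PLY: no vertex element")
  nv <- as.integer(sub("^element vertex ", "", vline[1]))
  props <- sub("^property \\S+ ", "",
               grep("^property ", lines[seq_len(endh)], value = TRUE))
  need <- c("x", "y", "z", "nx", "ny", "nz")
  if (!all(need %in% props))
    stop("PLY must provide properties: ", paste(need, collapse = ", "))
  body <- lines[endh + seq_len(nv)]
  vals <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  df <- as.data.frame(vals)
  names(df) <- props[seq_len(ncol(df))]
  if (is.null(df$object_id)) df$object_id <- 0L
  df$object_id <- as.integer(df$object_id)
  as_cloud(df[, c("x", "y", "z", "nx", "ny", "nz", "object_id")])
}

#' Shape measurements from an oriented cloud
#'
#' Each surfel stands for one ideal hexagonal tile of area
#' `a = (sqrt(3)/2) d0^2` (converged surfaces sit near that packing), so
#' `surface_area = n * a`; the enclosed volume follows from the divergence
#' theorem, `V = (1/3) sum a * (p . n)`, which is origin-independent for a
#' closed surface; the centre of mass is the (area-weighted) mean surfel
#' position. With anisotropic `spacing` the positions are mapped to
#' physical coordinates and the per-surfel tile is scaled by the geometric
#' mean spacing (an approximation that is exact for isotropic data).
#'
#' @param cloud an `oriented_cloud` (one object; pass a subset for
#'   multi-object fits) or anything [as_cloud()] accepts.
#' @param d0 inter-surfel spacing used for the tile area, pixels.
#' @param spacing physical units per voxel (default 1).
#' @return A list with `volume`, `surface_area`, `center_of_mass`, and
#'   `flipped` (`TRUE` when the signed volume came out negative — inward
#'   normals or an open surface — in which case the absolute value is
#'   returned with a warning).
#' @export
measure <- function(cloud, d0, spacing = c(1, 1, 1)) {
  cloud <- as_cloud(cloud)
  if (nrow(cloud) == 0) stop("cannot measure an empty cloud")
  spacing <- as.numeric(spacing)
  sbar <- prod(spacing)^(1 / 3)
  p <- cbind(cloud$x * spacing[1], cloud$y * spacing[2], cloud$z * spacing[3])
  nrm <- cbind(cloud$nx / spacing[1], cloud$ny / spacing[2],
               cloud$nz / spacing[3])
  nrm <- nrm / sqrt(rowSums(nrm^2))
  a <- sqrt(3) / 2 * (d0 * sbar)^2
  ## centroid-referenced divergence-theorem volume: identical to the raw
  ## sum for a closed cloud, but exactly translation invariant even when
  ## the discrete area-weighted normals do not cancel perfectly
  ctr <- colMeans(p)
  pc <- sweep(p, 2, ctr)
  vol <- sum(a * rowSums(pc * nrm)) / 3
  flipped <- vol < 0
  if (flipped)
    warning("negative signed volume (inward normals or open surface); returning |V|",
            call. = FALSE)
  list(volume = abs(vol), surface_area = a * nrow(cloud),
       center_of_mass = colMeans(p), flipped = flipped)
}

#' RMS distance of a cloud to a target sphere
#'
#' The segmentation score of the noise benchmark: the root mean square of
#' the surfel distances to the target sphere surface, in pixels.
#'
#' @param cloud an `oriented_cloud`.
#' @param center target sphere centre.
#' @param radius target sphere radius.
#' @return A single number, pixels.
#' @export
rms_to_sphere <- function(cloud, center, radius) {
  cloud <- as_cloud(cloud)
  if (nrow(cloud) == 0) stop("empty cloud")
  center <- as.numeric(center)
  r <- sqrt((cloud$x - center[1])^2 + (cloud$y - center[2])^2 +
              (cloud$z - center[3])^2)
  sqrt(mean((r - radius)^2))
}

#' Connected components of the surfel proximity graph
#'
#' Links surfels of the same object closer than `link_radius` and counts
#' connected components, summed over objects. Fusion and fission tests use
#' this to count distinct segmented surfaces.
#'
#' @param cloud an `oriented_cloud`.
#' @param link_radius linking distance (default `alpha * d0` given `d0`).
#' @param d0 used only for the default `link_radius = 1.75 * d0`.
#' @return Integer component count.
#' @export
connected_components <- function(cloud, link_radius = NULL, d0 = NULL) {
  cloud <- as_cloud(cloud)
  if (is.null(link_radius)) {
    if (is.null(d0)) stop("provide link_radius or d0")
    link_radius <- 1.75 * d0
  }
  stopifnot(link_radius > 0)
  total <- 0L
  for (oid in unique(cloud$object_id)) {
    sub <- cloud[cloud$object_id == oid, , drop = FALSE]
    pos <- as.matrix(sub[, c("x", "y", "z")])
    idx <- build_index(pos, cell_size = link_radius)
    pr <- index_pairs(idx, link_radius)
    g <- igraph::graph_from_edgelist(cbind(pr$i, pr$j), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, nrow(pos) - igraph::vcount(g)))
    total <- total + as.integer(igraph::components(g)$no)
  }
  total
}
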