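## Fixed-radius near neighbor search over surfel positions.
## A uniform hash grid with cell edge alpha * d0 answers closed-ball queries
## exactly from a 27-cell neighborhood, provided the query radius does not
## exceed the cell size (enforced). The index is rebuilt from scratch at the
## start of every integration step.

#' Build a spatial index over the surfels of a system
#'
#' @param system a `surfel_system`, or a numeric n x 3 position matrix.
#' @param cell_size grid cell edge, pixels; defaults to `alpha * d0` of the
#'   system parameters (the sphere-of-influence radius).
#' @return An object of class `neighbor_index`.
#' @export
build_index <- function(system, cell_size = NULL) {
  if (inherits(system, "surfel_system")) {
    pos <- system$pos
    if (is.null(cell_size)) cell_size <- system$params$alpha * system$params$d0
  } else {
    pos <- as.matrix(system)
    if (is.null(cell_size)) stop("cell_size is required for a raw position matrix")
  }
  if (nrow(pos) && any(!is.finite(pos))) {
    bad <- which(!is.finite(rowSums(pos)))[1]
    stop("non-finite position for surfel ", bad)
  }
  idx <- list(ptr = cpp_grid_build(pos, cell_size), cell_size = cell_size,
              n = nrow(pos))
  class(idx) <- "neighbor_index"
  idx
}

#' Closed-ball fixed-radius query
#'
#' Returns exactly the indices whose Euclidean distance to `center` is
#' `<= radius` (ties at the radius are included). The radius must not exceed
#' the index cell size: that contract is what makes the 27-cell scan exact.
#'
#' @param index a `neighbor_index` from [build_index()].
#' @param center numeric 3-vector.
#' @param radius query radius, `<= index$cell_size`.
#' @param exclude_id optional 1-based index to omit (typically the query
#'   surfel itself).
#' @return Sorted integer vector of matching indices.
#' @export
query_radius <- function(index, center, radius, exclude_id = NULL) {
  stopifnot(inherits(index, "neighbor_index"))
  if (radius > index$cell_size + 1e-12)
    stop("radius (", radius, ") exceeds index cell_size (", index$cell_size, ")")
  cpp_grid_query(index$ptr, as.numeric(center), radius,
                 if (is.null(exclude_id)) 0L else as.integer(exclude_id))
}

#' All surfel pairs within a radius
#'
#' @param index a `neighbor_index`.
#' @param radius pair cutoff, `<= cell_size`.
#' @return A list with integer vectors `i`, `j` (1-based, `i < j`, ascending)
#'   and numeric `d` of pair distances.
#' @export
index_pairs <- function(index, radius = index$cell_size) {
  stopifnot(inherits(index, "neighbor_index"))
  cpp_grid_pairs(index$ptr, radius)
}

#' @export
print.neighbor_index <- function(x, ...) {
  cat(sprintf("neighbor index: %d points, cell size %g px\n", x$n, x$cell_size))
  invisible(x)
}
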