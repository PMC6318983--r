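## Surfel and surfel-system containers.
## A surfel system is stored columnar (matrices / vectors) so that each
## integration step is vectorised; individual surfels are lightweight lists.

STATE_ACTIVE <- 0L
STATE_CONVERGED <- 1L
STATE_LOCKED <- 2L

.state_names <- c("active", "converged", "locked")

#' Create one surfel
#'
#' A surfel (SURFace ELement) is an oriented particle: a continuous
#' (sub-voxel) position, a unit normal, and the identifier of the
#' segmentation object it belongs to. The stored normal is always
#' renormalised to unit length.
#'
#' @param position numeric 3-vector, voxel coordinates.
#' @param normal numeric 3-vector, any non-zero length.
#' @param object_id integer object identifier.
#' @return An object of class `surfel` with fields `position`, `normal`
#'   (unit length), `object_id`, `state` (`"active"`), `age` and
#'   `still_counter` (both 0).
#' @examples
#' s <- make_surfel(c(0, 0, 0), c(0, 0, 2), 0L)
#' s$normal   # (0, 0, 1)
#' @export
make_surfel <- function(position, normal, object_id = 0L) {
  position <- as.numeric(position)
  normal <- as.numeric(normal)
  stopifnot(length(position) == 3, length(normal) == 3)
  nn <- sqrt(sum(normal^2))
  if (!is.finite(nn) || nn == 0) stop("surfel normal must be non-zero")
  structure(list(position = position, normal = normal / nn,
                 object_id = as.integer(object_id), state = "active",
                 age = 0L, still_counter = 0L),
            class = "surfel")
}

#' Assemble a surfel system
#'
#' Bundles a set of surfels with the run parameters into the evolving
#' container consumed by [step_system()] and [run_system()].
#'
#' @param surfels a list of [make_surfel()] objects, or a data frame /
#'   oriented cloud with columns `x, y, z, nx, ny, nz, object_id`
#'   (as produced by [as_cloud()] or [import_ply()]).
#' @param params a [surf_params()] object.
#' @param age initial age assigned to the surfels (mature by default so
#'   seeds take part in density adaptation immediately).
#' @return An object of class `surfel_system`.
#' @export
surfel_system <- function(surfels, params = surf_params(),
                          age = params$balance_period + 1L) {
  params <- validate_params(params)
  if (is.data.frame(surfels)) {
    pos <- as.matrix(surfels[, c("x", "y", "z")])
    nrm <- as.matrix(surfels[, c("nx", "ny", "nz")])
    obj <- as.integer(surfels$object_id)
  } else {
    stopifnot(is.list(surfels), length(surfels) > 0)
    pos <- do.call(rbind, lapply(surfels, `[[`, "position"))
    nrm <- do.call(rbind, lapply(surfels, `[[`, "normal"))
    obj <- vapply(surfels, `[[`, integer(1), "object_id")
  }
  n <- nrow(pos)
  if (n == 0) stop("a surfel system needs at least one surfel")
  nn <- sqrt(rowSums(nrm^2))
  if (any(!is.finite(nn)) || any(nn == 0)) stop("all normals must be non-zero")
  nrm <- nrm / nn
  dimnames(pos) <- dimnames(nrm) <- NULL
  sys <- list(pos = pos, nrm = nrm, id = seq_len(n), object = obj,
              state = rep(STATE_ACTIVE, n), age = rep(as.integer(age), n),
              still = rep(0L, n), ref_pos = pos, ref_nrm = nrm,
              params = params, step_count = 0L, next_id = n + 1L)
  class(sys) <- "surfel_system"
  sys
}

#' @export
print.surfel_system <- function(x, ...) {
  tab <- tabulate(x$state + 1L, nbins = 3L)
  cat(sprintf("surfel system: %d surfels (%d active, %d converged, %d locked), %d object(s), step %d\n",
              nrow(x$pos), tab[1], tab[2], tab[3],
              length(unique(x$object)), x$step_count))
  invisible(x)
}

#' Number of surfels in a system
#' @param sys a `surfel_system`.
#' @return integer count.
#' @export
n_surfels <- function(sys) nrow(sys$pos)

#' Extract the oriented point cloud of a system or fit
#'
#' @param x a `surfel_system` or `surfseg` fit.
#' @param ... unused.
#' @return A data frame of class `oriented_cloud` with columns
#'   `x, y, z, nx, ny, nz, object_id`.
#' @export
as_cloud <- function(x, ...) UseMethod("as_cloud")

#' @export
as_cloud.surfel_system <- function(x, ...) {
  out <- data.frame(x = x$pos[, 1], y = x$pos[, 2], z = x$pos[, 3],
                    nx = x$nrm[, 1], ny = x$nrm[, 2], nz = x$nrm[, 3],
                    object_id = x$object)
  class(out) <- c("oriented_cloud", "data.frame")
  out
}

#' @export
as_cloud.data.frame <- function(x, ...) {
  stopifnot(all(c("x", "y", "z", "nx", "ny", "nz") %in% names(x)))
  if (is.null(x$object_id)) x$object_id <- 0L
  class(x) <- c("oriented_cloud", "data.frame")
  x
}

## internal: states as factor-ish character vector
.states <- function(sys) .state_names[sys$state + 1L]
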