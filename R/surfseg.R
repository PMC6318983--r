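#' Fit a surfel surface to a 3D image
#'
#' The main entry point: evolves one or more seed surfaces under the
#' oriented-particle membrane dynamics until every surfel is locked or
#' `max_steps` is reached, and returns the converged oriented point cloud
#' together with the run trace. Seeds of different `object_id` segment
#' different objects simultaneously and interact only through surface
#' repulsion.
#'
#' @param image an [image3d()] (or a path to a multi-page TIFF), or `NULL`
#'   for a force-field-only evolution.
#' @param seeds a list of [make_surfel()] objects, e.g. from
#'   [sphere_seed()], [skeleton_seed()], [cloud_seed()] or [read_seeds()];
#'   several seeds are concatenated with `c()`.
#' @param d0 equilibrium inter-surfel distance, pixels.
#' @param f_pressure balloon force (positive inflates, negative deflates).
#' @param params full parameter set; overrides `d0` / `f_pressure` when
#'   given.
#' @param max_steps iteration cap.
#' @param report_every progress-log period in steps (0 = silent).
#' @param ... further arguments passed to [surf_params()].
#' @return An object of class `surfseg`: a list with the final `system`,
#'   the oriented `cloud`, per-step `reports`, `converged`, `steps` and the
#'   matched `call`. Use [summary()] for shape measurements, [plot()] for a
#'   projection, [as_cloud()] / [export_ply()] for the result cloud.
#' @examples
#' img <- phantom_sphere_shell(size = c(48, 48, 48), radius = 15)
#' fit <- surfseg(img, sphere_seed(c(23.5, 23.5, 23.5), 7, 3),
#'                d0 = 3, f_pressure = 0.02, max_steps = 400)
#' fit
#' @export
surfseg <- function(image, seeds, d0 = 3, f_pressure = 0.01, params = NULL,
                    max_steps = NULL, report_every = 0L, ...) {
  if (is.character(image)) image <- load_volume(image)
  if (!is.null(image)) stopifnot(inherits(image, "image3d"))
  if (is.null(params))
    params <- surf_params(d0 = d0, f_pressure = f_pressure, ...)
  params <- validate_params(params)
  sys <- surfel_system(seeds, params)
  run <- run_system(sys, image,
                    max_steps = if (is.null(max_steps)) params$max_steps
                                else max_steps,
                    report_every = report_every)
  structure(list(system = run$system, cloud = as_cloud(run$system),
                 reports = run$reports, converged = run$converged,
                 steps = run$steps_run, params = params,
                 spacing = if (is.null(image)) c(1, 1, 1) else image$spacing,
                 call = match.call()),
            class = "surfseg")
}

#' @export
print.surfseg <- function(x, ...) {
  cat("surfel segmentation fit\n")
  cat("  call: ", deparse(x$call), "\n", sep = "")
  tab <- tabulate(x$system$state + 1L, nbins = 3L)
  cat(sprintf("  %d surfels over %d object(s) after %d steps (%s)\n",
              nrow(x$cloud), length(unique(x$cloud$object_id)), x$steps,
              if (x$converged) "all locked" else "step cap reached"))
  cat(sprintf("  states: %d active, %d converged, %d locked\n",
              tab[1], tab[2], tab[3]))
  invisible(x)
}

#' @export
summary.surfseg <- function(object, ...) {
  objs <- sort(unique(object$cloud$object_id))
  rows <- lapply(objs, function(oid) {
    sub <- object$cloud[object$cloud$object_id == oid, , drop = FALSE]
    m <- suppressWarnings(measure(sub, object$params$d0, object$spacing))
    data.frame(object_id = oid, n_surfels = nrow(sub),
               components = connected_components(sub, d0 = object$params$d0),
               volume = m$volume, surface_area = m$surface_area,
               com_x = m$center_of_mass[1], com_y = m$center_of_mass[2],
               com_z = m$center_of_mass[3])
  })
  out <- list(fit = object, objects = do.call(rbind, rows))
  class(out) <- "summary.surfseg"
  out
}

#' @export
print.summary.surfseg <- function(x, ...) {
  print(x$fit)
  cat("\nper-object shape measurements (physical units):\n")
  print(x$objects, row.names = FALSE, digits = 5)
  invisible(x)
}

#' @export
plot.surfseg <- function(x, plane = c("xy", "xz", "yz"), ...) {
  plane <- match.arg(plane)
  cl <- x$cloud
  ax <- switch(plane, xy = c("x", "y"), xz = c("x", "z"), yz = c("y", "z"))
  cols <- grDevices::hcl.colors(max(2L, length(unique(cl$object_id))), "Dark 3")
  graphics::plot(cl[[ax[1]]], cl[[ax[2]]], asp = 1, pch = 16, cex = 0.4,
                 col = cols[match(cl$object_id, sort(unique(cl$object_id)))],
                 xlab = ax[1], ylab = ax[2],
                 main = sprintf("surfel cloud (%s projection)", plane), ...)
  invisible(x)
}

#' @export
as_cloud.surfseg <- function(x, ...) x$cloud
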