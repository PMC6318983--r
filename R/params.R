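#' Parameter set for a surfel segmentation run
#'
#' Collects every tunable of the oriented-particle surface. Only two
#' parameters normally need attention: `d0`, the equilibrium inter-surfel
#' distance in pixels (the minimum feature size the surface can resolve),
#' and `f_pressure`, the balloon force biasing the surface towards
#' inflation (positive) or deflation (negative). Like every force in the
#' method, `f_pressure` is a displacement per integration step in units of
#' `d0`; values outside `[-0.04, 0.04]` destabilise the particle system and
#' trigger a warning.
#'
#' @param d0 equilibrium inter-surfel distance, pixels. Typical range 1-20.
#' @param f_pressure balloon force, displacement per step in units of `d0`.
#' @param alpha sphere-of-influence radius factor: neighbors are surfels
#'   within `alpha * d0`; the same radius defines the density count.
#' @param f_signal constant norm of the image-attachment force.
#' @param k_dist stiffness of the distance-restoring pair force (scales
#'   [f_dist_profile()]).
#' @param k_plane stiffness of the co-planarity force.
#' @param k_tilt stiffness of the normal-alignment torque.
#' @param n_create create a surfel when the neighbor count is `<= n_create`.
#' @param n_remove remove a surfel when the neighbor count is `> n_remove`.
#' @param n_isolated remove a surfel when the neighbor count is `< n_isolated`.
#' @param balance_period steps after creation during which a surfel can
#'   neither die nor spawn.
#' @param search_band half-width, in pixels, of the maximum search along the
#'   normal. Defaults to `d0`.
#' @param conv_window length, in steps, of the convergence observation
#'   window; a surfel whose net motion over a full window stays below the
#'   tolerances counts as converged.
#' @param conv_disp_tol net displacement tolerance over one window, as a
#'   fraction of `d0`. The default 0.25 sits above the bounded sawtooth a
#'   surfel trapped at the image maximum performs (its net drift cancels)
#'   but below the net advance of the slowest sanctioned inflation
#'   (`d0 * 0.005 * conv_window = 0.5 d0`).
#' @param conv_rot_tol net rotation tolerance over one window, radians.
#' @param max_steps default iteration cap for [run_system()].
#' @param rng_seed integer seed driving all creation jitter.
#' @param profile_w width of the attractive branch of the distance force,
#'   in units of `d0` (the bond effectively breaks near `alpha`).
#' @return A validated object of class `surf_params`.
#' @seealso [validate_params()], [read_params()], [write_params()]
#' @examples
#' p <- surf_params(d0 = 5, f_pressure = 0.01)
#' p$d0
#' @export
surf_params <- function(d0 = 3, f_pressure = 0.01, alpha = 1.75,
                        f_signal = 0.02, k_dist = 0.05, k_plane = 0.02,
                        k_tilt = 0.05,
                        n_create = 6L, n_remove = 13L, n_isolated = 3L,
                        balance_period = 10L, search_band = d0,
                        conv_window = 100L, conv_disp_tol = 0.25,
                        conv_rot_tol = 0.05, max_steps = 2000L,
                        rng_seed = 1L, profile_w = 0.4) {
  p <- list(d0 = as.numeric(d0), f_pressure = as.numeric(f_pressure),
            alpha = as.numeric(alpha), f_signal = as.numeric(f_signal),
            k_dist = as.numeric(k_dist),
            k_plane = as.numeric(k_plane), k_tilt = as.numeric(k_tilt),
            n_create = as.integer(n_create), n_remove = as.integer(n_remove),
            n_isolated = as.integer(n_isolated),
            balance_period = as.integer(balance_period),
            search_band = as.numeric(search_band),
            conv_window = as.integer(conv_window),
            conv_disp_tol = as.numeric(conv_disp_tol),
            conv_rot_tol = as.numeric(conv_rot_tol),
            max_steps = as.integer(max_steps),
            rng_seed = as.integer(rng_seed),
            profile_w = as.numeric(profile_w))
  class(p) <- "surf_params"
  validate_params(p)
}

#' Validate a parameter set
#'
#' Hard invariants (positivity of `d0`, `alpha > 1`, ordering of the density
#' limits) raise an error; soft stability bounds (`|f_pressure| <= 0.04`,
#' `d0` in `[1, 20]`) only warn, since the method still runs outside them.
#'
#' @param p a `surf_params` object (or a plain named list with its fields).
#' @return `p`, unchanged, invisibly classed as `surf_params`.
#' @export
validate_params <- function(p) {
  stopifnot(is.list(p))
  if (!is.numeric(p$d0) || length(p$d0) != 1 || is.na(p$d0) || p$d0 <= 0)
    stop("d0 must be a single positive number")
  if (p$alpha <= 1)
    stop("alpha must exceed 1 (sphere of influence must reach past d0)")
  if (!(p$n_isolated < p$n_create && p$n_create < p$n_remove))
    stop("density limits must satisfy n_isolated < n_create < n_remove")
  if (p$f_signal <= 0) stop("f_signal must be > 0")
  if (p$k_dist <= 0 || p$k_plane <= 0 || p$k_tilt <= 0)
    stop("stiffnesses must be > 0")
  if (p$search_band <= 0) stop("search_band must be > 0")
  if (p$conv_window < 1L || p$balance_period < 0L)
    stop("conv_window must be >= 1 and balance_period >= 0")
  if (abs(p$f_pressure) > 0.04)
    warning("f_pressure outside [-0.04, 0.04]; the particle system may be unstable",
            call. = FALSE)
  if (p$d0 < 1 || p$d0 > 20)
    warning("d0 outside the typical 1-20 pixel range", call. = FALSE)
  class(p) <- "surf_params"
  p
}

#' @export
print.surf_params <- function(x, ...) {
  cat("surfel segmentation parameters\n")
  cat(sprintf("  d0 = %g px, f_pressure = %g, f_signal = %g, alpha = %g\n",
              x$d0, x$f_pressure, x$f_signal, x$alpha))
  cat(sprintf("  density limits: isolated < %d, create <= %d, remove > %d; balance %d steps\n",
              x$n_isolated, x$n_create, x$n_remove, x$balance_period))
  cat(sprintf("  convergence: window %d steps, disp tol %g d0, rot tol %g rad\n",
              x$conv_window, x$conv_disp_tol, x$conv_rot_tol))
  invisible(x)
}

#' Read or write a parameter set as a flat YAML file
#'
#' Keys are named exactly as the fields of [surf_params()]; unknown keys are
#' rejected so typos do not silently fall back to defaults.
#'
#' @param path file path.
#' @return `read_params` returns a `surf_params` object; `write_params`
#'   returns `path` invisibly.
#' @export
read_params <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(surf_params))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown parameter field(s): ", paste(bad, collapse = ", "))
  do.call(surf_params, vals)
}

#' @rdname read_params
#' @param p a `surf_params` object.
#' @export
write_params <- function(p, path) {
  p <- validate_params(p)
  yaml::write_yaml(unclass(p), path)
  invisible(path)
}
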