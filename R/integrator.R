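## Explicit Euler integration of the surfel system.
##
## Dynamics are purely viscous: each step, every non-locked surfel moves by
## d0 times its resulting force,
##   p(t+1) = p(t) + d0 * [ sum_j (F_dist + F_plane) + F_pressure + F_signal ]
## and its normal is incremented by the summed tilt torques and
## renormalised. Forces are therefore displacements per step in units of
## d0: a constant force of 0.01 with d0 = 15 moves a surfel 0.15 px per
## step, i.e. 100 steps for 15 px.
##
## Two-stage convergence: a surfel that stays below the motion tolerances
## for conv_window consecutive steps is flagged converged; once all its
## same-object neighbors are converged too, it is locked. Locked surfels
## are never updated again within a run (they still exert forces on active
## neighbors), which restricts computation to the actively segmenting
## frontier.

#' One integration step
#'
#' Performs a full iteration: rebuild the neighbor index, accumulate pair
#' forces, run the density-driven population adaptation, apply image and
#' pressure forces, update positions and normals of all non-locked surfels,
#' and refresh the convergence/locking flags.
#'
#' @param system a `surfel_system`.
#' @param img an [image3d()], or `NULL` for force-field-only evolution
#'   (pressure and pair forces only).
#' @return A list with the updated `system` and a `report` (step index,
#'   population counts per state, maximum displacement, adaptation events).
#' @export
step_system <- function(system, img = NULL) {
  p <- system$params
  n <- n_surfels(system)
  r_inf <- p$alpha * p$d0
  idx <- build_index(system)
  pr <- index_pairs(idx, r_inf)
  pf <- cpp_pair_forces(system$pos, system$nrm, pr$i, pr$j, pr$d,
                        system$object, system$state, p$d0, p$k_dist,
                        p$k_plane, p$k_tilt, p$profile_w)

  ## population adaptation on the pre-step census (applied atomically)
  same <- system$object[pr$i] == system$object[pr$j]
  events <- adapt_population(system, pf$count,
                             neighbor_pairs = list(i = pr$i[same],
                                                   j = pr$j[same]))
  drop <- events$surfel[events$kind != "created"]
  keep <- if (length(drop)) setdiff(seq_len(n), drop) else seq_len(n)
  sys2 <- .apply_events(system, events)
  if (n_surfels(sys2) == 0)
    stop("population collapse: all surfels removed at step ",
         system$step_count + 1,
         "; consider a different f_pressure or seed", call. = FALSE)

  ## forces at time t for the surviving surfels (created surfels skip their
  ## creation step); image force only where it can move something
  nk <- length(keep)
  old_pos <- system$pos[keep, , drop = FALSE]
  old_nrm <- system$nrm[keep, , drop = FALSE]
  state_k <- system$state[keep]
  movable <- state_k != STATE_LOCKED
  fimg <- rep(0, nk)
  if (any(movable))
    fimg[movable] <- .image_force_scalars(old_pos[movable, , drop = FALSE],
                                          old_nrm[movable, , drop = FALSE],
                                          img, p)
  Ftot <- pf$F[keep, , drop = FALSE] + fimg * old_nrm
  Tacc <- pf$T[keep, , drop = FALSE]

  new_pos <- old_pos
  new_nrm <- old_nrm
  new_pos[movable, ] <- old_pos[movable, ] + p$d0 * Ftot[movable, ]
  nr <- old_nrm[movable, , drop = FALSE] + Tacc[movable, , drop = FALSE]
  nl <- sqrt(rowSums(nr^2))
  if (any(nl < 1e-12))
    stop("degenerate normal update at step ", system$step_count + 1)
  new_nrm[movable, ] <- nr / nl
  if (any(!is.finite(new_pos))) {
    bad <- which(!is.finite(rowSums(new_pos)))[1]
    stop("non-finite position update for surfel id ", sys2$id[bad],
         " at step ", system$step_count + 1,
         " (force blow-up; reduce f_pressure or check parameters)",
         call. = FALSE)
  }

  disp <- rep(0, nk)
  disp[movable] <- sqrt(rowSums((new_pos - old_pos)[movable, , drop = FALSE]^2))
  sys2$pos[seq_len(nk), ] <- new_pos
  sys2$nrm[seq_len(nk), ] <- new_nrm

  sys2$age[seq_len(nk)] <- sys2$age[seq_len(nk)] + 1L
  sys2$step_count <- system$step_count + 1L

  ## convergence checkpoint at the window cadence: net motion over the
  ## completed window decides converged/active, then the locking pass runs
  if (sys2$step_count %% p$conv_window == 0L)
    sys2 <- update_convergence(sys2)

  tab <- tabulate(sys2$state + 1L, nbins = 3L)
  report <- list(step_index = sys2$step_count, n_active = tab[1],
                 n_converged = tab[2], n_locked = tab[3],
                 max_displacement = if (nk) max(disp) else 0,
                 events = events)
  list(system = sys2, report = report)
}

#' Convergence checkpoint: flag converged surfels and lock quiet regions
#'
#' Compares every non-locked surfel with its reference state recorded at
#' the previous checkpoint. A surfel whose net displacement stayed below
#' `conv_disp_tol * d0` and whose net rotation stayed below `conv_rot_tol`
#' over the window is flagged converged (a trapped surfel's bounded
#' oscillation around the image maximum cancels out; genuine advance does
#' not); any other surfel reverts to active. A converged surfel whose
#' same-object neighbors have all converged (or are locked) is locked:
#' its position and normal are frozen for the rest of the run, though it
#' keeps exerting forces on active neighbors. Finally the reference state
#' is reset to the current one. [step_system()] calls this every
#' `conv_window` steps; it can also be invoked directly.
#'
#' @param system a `surfel_system`.
#' @return The updated system.
#' @export
update_convergence <- function(system) {
  p <- system$params
  n <- n_surfels(system)
  movable <- system$state != STATE_LOCKED
  net_disp <- sqrt(rowSums((system$pos - system$ref_pos)^2))
  dotn <- rowSums(system$nrm * system$ref_nrm)
  net_rot <- acos(pmin(1, pmax(-1, dotn)))
  quiet <- net_disp <= p$conv_disp_tol * p$d0 & net_rot <= p$conv_rot_tol
  system$still[movable & quiet] <- system$still[movable & quiet] + 1L
  system$still[movable & !quiet] <- 0L
  system$state[movable & quiet] <- STATE_CONVERGED
  system$state[movable & !quiet] <- STATE_ACTIVE
  idx <- build_index(system)
  pr <- index_pairs(idx)
  has_active <- rep(FALSE, n)
  if (length(pr$i)) {
    same <- system$object[pr$i] == system$object[pr$j]
    oi <- pr$i[same]; oj <- pr$j[same]
    blocked <- c(oi[system$state[oj] == STATE_ACTIVE],
                 oj[system$state[oi] == STATE_ACTIVE])
    has_active[unique(blocked)] <- TRUE
  }
  system$state[system$state == STATE_CONVERGED & !has_active] <- STATE_LOCKED
  system$ref_pos <- system$pos
  system$ref_nrm <- system$nrm
  system
}

#' Run the segmentation loop
#'
#' Iterates [step_system()] until every surfel is locked, `max_steps` is
#' reached, or `stop_when` returns `TRUE`. All randomness (creation jitter,
#' symmetric-fallback directions) flows from a seed derived from
#' `params$rng_seed` and the current step count, so identical inputs give
#' identical runs; the caller's RNG state is restored on exit.
#'
#' @param system a `surfel_system` with at least one surfel.
#' @param img an [image3d()] or `NULL`.
#' @param max_steps iteration cap (default from the system parameters).
#' @param stop_when optional predicate `function(system)`; the loop exits
#'   as soon as it returns `TRUE` (used e.g. by benchmark sweeps to detect
#'   a surface crossing a landmark).
#' @param report_every log one progress line every this many steps
#'   (0 = silent).
#' @return A list of class `surfseg_run` with the final `system`, a
#'   `reports` data frame (one row per step), `converged` (all locked) and
#'   `stopped_early`.
#' @export
run_system <- function(system, img = NULL, max_steps = system$params$max_steps,
                       stop_when = NULL, report_every = 0L) {
  stopifnot(inherits(system, "surfel_system"), n_surfels(system) >= 1)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(system$params$rng_seed + system$step_count)
  reports <- vector("list", max_steps)
  converged <- all(system$state == STATE_LOCKED)
  stopped <- FALSE
  nsteps <- 0L
  while (!converged && nsteps < max_steps) {
    out <- step_system(system, img)
    system <- out$system
    nsteps <- nsteps + 1L
    rp <- out$report
    reports[[nsteps]] <- data.frame(step = rp$step_index,
                                    n_active = rp$n_active,
                                    n_converged = rp$n_converged,
                                    n_locked = rp$n_locked,
                                    max_displacement = rp$max_displacement,
                                    n_events = nrow(rp$events))
    if (report_every > 0 && nsteps %% report_every == 0)
      message(sprintf("step %d: %d surfels (%d active, %d converged, %d locked), max disp %.4g px",
                      rp$step_index, with(rp, n_active + n_converged + n_locked),
                      rp$n_active, rp$n_converged, rp$n_locked,
                      rp$max_displacement))
    converged <- all(system$state == STATE_LOCKED)
    if (!is.null(stop_when) && isTRUE(stop_when(system))) {
      stopped <- TRUE
      break
    }
  }
  structure(list(system = system,
                 reports = do.call(rbind, reports[seq_len(nsteps)]),
                 converged = converged, stopped_early = stopped,
                 steps_run = nsteps),
            class = "surfseg_run")
}

#' Resume a run with (possibly) new parameters
#'
#' Reverts every surfel to the active state, clears the still-counters and
#' swaps in the new parameter set, supporting the refinement workflow of
#' re-running a converged segmentation with a smaller `d0`.
#'
#' @param system a `surfel_system` (or the `system` of a `surfseg_run`).
#' @param params new [surf_params()]; defaults to keeping the old ones.
#' @return The reactivated system.
#' @export
resume_system <- function(system, params = system$params) {
  if (inherits(system, "surfseg_run")) system <- system$system
  system$params <- validate_params(params)
  system$state <- rep(STATE_ACTIVE, n_surfels(system))
  system$still <- rep(0L, n_surfels(system))
  system
}
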