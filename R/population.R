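## Surfel number adaptation.
## The particle count is not conserved: overcrowded surfels remove
## themselves, sparse (but not isolated) surfels spawn a new surfel at the
## position of lowest local density, and isolated surfels are cleared as
## spurious surface. A balance period after creation keeps fresh surfels
## from dying or spawning immediately, which stabilises the frontier.

#' Position of lowest local surfel density
#'
#' Estimates where a new surfel should be placed around `s` by summing
#' repulsions from its neighbors (weight decaying linearly to zero at the
#' sphere-of-influence radius), taking the opposite direction, projecting it
#' onto the local tangent plane of `s`, and stepping `d0` along it. A small
#' jitter (0.01 d0, from the session RNG) prevents exact coincidences. A
#' perfectly symmetric neighborhood (zero net repulsion) falls back to a
#' random tangent direction.
#'
#' @param s a [make_surfel()] object.
#' @param neighbors non-empty list of neighboring surfels (same object).
#' @param p a [surf_params()] object.
#' @return A 3-vector position.
#' @export
lowest_density_position <- function(s, neighbors, p) {
  stopifnot(length(neighbors) > 0)
  npos <- do.call(rbind, lapply(neighbors, `[[`, "position"))
  .lowest_density_position(s$position, s$normal, npos, p)
}

## internal workhorse on raw vectors
.lowest_density_position <- function(pos, nrm, npos, p) {
  dp <- sweep(npos, 2, pos)            # vectors to neighbors
  d <- sqrt(rowSums(dp^2))
  keep <- d > 0
  r <- c(0, 0, 0)
  if (any(keep)) {
    wgt <- pmax(0, 1 - d[keep] / (p$alpha * p$d0)) / d[keep]
    r <- -colSums(dp[keep, , drop = FALSE] * wgt)   # away from the crowd
  }
  t_vec <- r - sum(r * nrm) * nrm      # project on tangent plane
  tn <- sqrt(sum(t_vec^2))
  if (tn < 1e-12) {                    # symmetric neighborhood: random tangent
    repeat {
      v <- stats::rnorm(3)
      t_vec <- v - sum(v * nrm) * nrm
      tn <- sqrt(sum(t_vec^2))
      if (tn > 1e-8) break
    }
  }
  jit <- stats::rnorm(3)
  jit <- jit / sqrt(sum(jit^2)) * 0.01 * p$d0
  pos + p$d0 * t_vec / tn + jit
}

#' Density-driven population adaptation
#'
#' Applies the adaptation rules to every active surfel past its balance
#' period, given same-object neighbor counts at radius `alpha * d0`:
#' a count above `n_remove` removes the surfel (overcrowding); a count
#' between `n_isolated` and `n_create` (inclusive) spawns one new surfel at
#' the position of lowest density (inheriting normal and object id, age 0);
#' a count below `n_isolated` removes the surfel as spurious isolated
#' surface. Events are gathered over a full scan in ascending surfel order
#' and returned for atomic application, so within-step order cannot cascade.
#'
#' @param system a `surfel_system`.
#' @param neighbor_counts integer vector of same-object neighbor counts,
#'   one per surfel.
#' @param neighbor_pairs optional pair list (`i`, `j`) from [index_pairs()]
#'   restricted to same-object pairs; required to place created surfels.
#' @return A data frame of events with columns `kind`
#'   (`created` / `removed_crowded` / `removed_isolated`), `surfel` (row
#'   index), and `x, y, z` (new position, `NA` for removals).
#' @export
adapt_population <- function(system, neighbor_counts, neighbor_pairs = NULL) {
  p <- system$params
  n <- n_surfels(system)
  stopifnot(length(neighbor_counts) == n)
  eligible <- system$state == STATE_ACTIVE & system$age > p$balance_period
  crowd <- which(eligible & neighbor_counts > p$n_remove)
  spawn <- which(eligible & neighbor_counts <= p$n_create &
                   neighbor_counts >= p$n_isolated)
  lone <- which(eligible & neighbor_counts < p$n_isolated)
  kind <- c(rep("removed_crowded", length(crowd)),
            rep("created", length(spawn)),
            rep("removed_isolated", length(lone)))
  who <- c(crowd, spawn, lone)
  ev <- data.frame(kind = kind, surfel = who,
                   x = rep(NA_real_, length(who)),
                   y = rep(NA_real_, length(who)),
                   z = rep(NA_real_, length(who)))
  ev <- ev[order(ev$surfel, ev$kind), , drop = FALSE]
  rownames(ev) <- NULL
  if (length(spawn)) {
    ## neighbor lists for the spawning surfels only
    if (is.null(neighbor_pairs)) {
      idx <- build_index(system)
      pr <- index_pairs(idx)
      same <- system$object[pr$i] == system$object[pr$j]
      neighbor_pairs <- list(i = pr$i[same], j = pr$j[same])
    }
    is_sp <- logical(n); is_sp[spawn] <- TRUE
    pi <- neighbor_pairs$i; pj <- neighbor_pairs$j
    a <- c(pi[is_sp[pi]], pj[is_sp[pj]])   # spawner side
    b <- c(pj[is_sp[pi]], pi[is_sp[pj]])   # its neighbor
    nb <- split(b, a)
    rows <- which(ev$kind == "created")
    rows <- rows[order(ev$surfel[rows])]
    for (r in rows) {
      s_i <- ev$surfel[r]
      nbs <- nb[[as.character(s_i)]]
      if (is.null(nbs) || length(nbs) == 0) {
        next  # cannot place without neighbors; event dropped below
      }
      newp <- .lowest_density_position(system$pos[s_i, ], system$nrm[s_i, ],
                                       system$pos[nbs, , drop = FALSE], p)
      ev$x[r] <- newp[1]; ev$y[r] <- newp[2]; ev$z[r] <- newp[3]
    }
    ev <- ev[!(ev$kind == "created" & is.na(ev$x)), , drop = FALSE]
    rownames(ev) <- NULL
  }
  ev
}

## Apply an event list atomically; returns the updated system.
.apply_events <- function(system, events) {
  if (nrow(events) == 0) return(system)
  drop <- events$surfel[events$kind != "created"]
  created <- events[events$kind == "created", , drop = FALSE]
  keep <- setdiff(seq_len(n_surfels(system)), drop)
  newn <- nrow(created)
  new_pos <- as.matrix(created[, c("x", "y", "z")])
  new_nrm <- system$nrm[created$surfel, , drop = FALSE]   # inherit parent normal
  system$object <- c(system$object[keep], system$object[created$surfel])
  system$pos <- rbind(system$pos[keep, , drop = FALSE], new_pos)
  system$nrm <- rbind(system$nrm[keep, , drop = FALSE], new_nrm)
  system$id <- c(system$id[keep],
                 if (newn) seq(system$next_id, length.out = newn) else integer(0))
  system$state <- c(system$state[keep], rep(STATE_ACTIVE, newn))
  system$age <- c(system$age[keep], rep(0L, newn))
  system$still <- c(system$still[keep], rep(0L, newn))
  system$ref_pos <- rbind(system$ref_pos[keep, , drop = FALSE], new_pos)
  system$ref_nrm <- rbind(system$ref_nrm[keep, , drop = FALSE], new_nrm)
  system$next_id <- system$next_id + newn
  dimnames(system$pos) <- dimnames(system$nrm) <- NULL
  system
}
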