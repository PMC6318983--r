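## Shared test fixtures and brute-force oracles.

## O(n^2) closed-ball radius query: the oracle the grid index must match.
brute_radius <- function(pos, center, radius, exclude = 0L) {
  d2 <- (pos[, 1] - center[1])^2 + (pos[, 2] - center[2])^2 +
    (pos[, 3] - center[3])^2
  hits <- which(d2 <= radius^2)
  sort(setdiff(hits, exclude))
}

## O(n^2) pair scan (i < j, distance <= radius), as a sorted key vector.
brute_pairs <- function(pos, radius) {
  n <- nrow(pos)
  if (n < 2) return(character(0))
  d <- as.matrix(stats::dist(pos))
  idx <- which(upper.tri(d) & d <= radius, arr.ind = TRUE)
  sort(paste(idx[, 1], idx[, 2]))
}

## 7-surfel flat hexagonal patch at spacing d0, normals +z; center first.
hex_patch <- function(d0) {
  ang <- (0:5) * pi / 3
  pos <- rbind(c(0, 0, 0), cbind(d0 * cos(ang), d0 * sin(ang), 0))
  list(pos = pos, nrm = matrix(rep(c(0, 0, 1), 7), ncol = 3, byrow = TRUE))
}

## surfel_system from raw position/normal matrices.
mat_system <- function(pos, nrm, params = surf_params(), object_id = 0L,
                       age = params$balance_period + 1L) {
  surfels <- lapply(seq_len(nrow(pos)), function(i)
    make_surfel(pos[i, ], nrm[i, ], object_id))
  surfel_system(surfels, params, age = age)
}

## random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

## parameters that disable population adaptation (negative density limits
## keep the ordering invariant while matching no neighbor count)
no_adapt_params <- function(...) {
  surf_params(n_isolated = -2L, n_create = -1L, n_remove = 999L, ...)
}
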