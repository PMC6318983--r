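test_that("f_dist_profile matches its defining points", {
  expect_identical(f_dist_profile(1), 0)
  expect_equal(f_dist_profile(0.5), -0.5)
  expect_lt(abs(f_dist_profile(10)), 1e-10)
  expect_equal(f_dist_profile(c(0.2, 1, 2))[1], -0.8)
  expect_error(f_dist_profile(0), "> 0")
  expect_error(f_dist_profile(-1), "> 0")
})

test_that("f_dist_profile is repulsive below d0, attractive above, bond breaks", {
  x <- seq(0.1, 0.99, by = 0.05)
  expect_true(all(f_dist_profile(x) < 0))
  x <- seq(1.01, 1.7, by = 0.05)
  expect_true(all(f_dist_profile(x) > 0))
  ## bond effectively broken near the sphere-of-influence cutoff
  expect_lt(f_dist_profile(1.75), f_dist_profile(1.4))
})

test_that("pair interaction vanishes at equilibrium with tangent normals", {
  p <- surf_params(d0 = 3)
  si <- make_surfel(c(0, 0, 0), c(0, 0, 1))
  sj <- make_surfel(c(3, 0, 0), c(0, 0, 1))   # u = +x, both normals ⊥ u
  pi_ <- pair_interaction(si, sj, p)
  expect_equal(pi_$F_dist, c(0, 0, 0))
  expect_equal(pi_$F_plane, c(0, 0, 0))
  expect_equal(pi_$T_tilt, c(0, 0, 0))
  expect_equal(pi_$d, 3)
  expect_equal(pi_$u, c(1, 0, 0))
})

test_that("pair interaction terms follow their formulas", {
  p <- surf_params(d0 = 3)
  ## n_i parallel to u, n_j perpendicular: F_dist = 0,
  ## F_plane = k_plane (u.(n_i+n_j)) n_i = k_plane u,
  ## T_tilt restores: -k_tilt (n_i.u) u = -k_tilt u
  si <- make_surfel(c(0, 0, 0), c(1, 0, 0))
  sj <- make_surfel(c(3, 0, 0), c(0, 0, 1))
  pi_ <- pair_interaction(si, sj, p)
  expect_equal(pi_$F_dist, c(0, 0, 0))
  expect_equal(pi_$F_plane, p$k_plane * c(1, 0, 0))
  expect_equal(pi_$T_tilt, -p$k_tilt * c(1, 0, 0))
  ## T_tilt removes the component of n_i along u after the normal update
  n_new <- si$normal + pi_$T_tilt
  expect_lt(abs(sum(n_new * pi_$u)), abs(sum(si$normal * pi_$u)))
})

test_that("F_dist is antisymmetric under the pair swap", {
  set.seed(5)
  p <- surf_params(d0 = 2)
  for (k in 1:20) {
    si <- make_surfel(rnorm(3), rnorm(3))
    sj <- make_surfel(si$position + rnorm(3, sd = 2), rnorm(3))
    expect_equal(pair_interaction(si, sj, p)$F_dist,
                 -pair_interaction(sj, si, p)$F_dist, tolerance = 1e-12)
  }
})

test_that("pair interaction is rotation equivariant", {
  set.seed(6)
  p <- surf_params(d0 = 2)
  for (k in 1:10) {
    R <- random_rotation()
    pi_ <- make_surfel(rnorm(3), rnorm(3))
    pj <- make_surfel(pi_$position + rnorm(3, sd = 1.5), rnorm(3))
    a <- pair_interaction(pi_, pj, p)
    b <- pair_interaction(
      make_surfel(c(R %*% pi_$position), c(R %*% pi_$normal)),
      make_surfel(c(R %*% pj$position), c(R %*% pj$normal)), p)
    expect_equal(b$F_dist, c(R %*% a$F_dist), tolerance = 1e-12)
    expect_equal(b$F_plane, c(R %*% a$F_plane), tolerance = 1e-12)
    expect_equal(b$T_tilt, c(R %*% a$T_tilt), tolerance = 1e-12)
  }
})

test_that("coincident surfels are rejected", {
  p <- surf_params()
  s <- make_surfel(c(1, 1, 1), c(0, 0, 1))
  expect_error(pair_interaction(s, s, p), "oincident")
})

test_that("cross-object interaction keeps only sub-d0 repulsion", {
  p <- surf_params(d0 = 4)
  si <- make_surfel(c(0, 0, 0), c(0, 0, 1), 0L)
  far <- make_surfel(c(6, 0, 0), c(0, 0, 1), 1L)      # 1.5 d0
  near <- make_surfel(c(2, 0, 0), c(1, 1, 0), 1L)     # 0.5 d0
  a <- pair_interaction_repulsive_only(si, far, p)
  expect_equal(a$F_dist, c(0, 0, 0))
  b <- pair_interaction_repulsive_only(si, near, p)
  expect_equal(b$F_dist, p$k_dist * -0.5 * c(1, 0, 0))
  expect_equal(b$F_plane, c(0, 0, 0))
  expect_equal(b$T_tilt, c(0, 0, 0))
  same <- make_surfel(c(2, 0, 0), c(0, 0, 1), 0L)
  expect_error(pair_interaction_repulsive_only(si, same, p), "object id")
})

test_that("hexagonal patch is a fixed point of the pair interactions", {
  p <- surf_params(d0 = 3)
  hp <- hex_patch(3)
  center <- make_surfel(hp$pos[1, ], c(0, 0, 1))
  Fnet <- c(0, 0, 0); Tnet <- c(0, 0, 0)
  for (k in 2:7) {
    pi_ <- pair_interaction(center, make_surfel(hp$pos[k, ], c(0, 0, 1)), p)
    Fnet <- Fnet + pi_$F_dist + pi_$F_plane
    Tnet <- Tnet + pi_$T_tilt
  }
  expect_lt(max(abs(Fnet)), 1e-12)
  expect_lt(max(abs(Tnet)), 1e-12)
})

test_that("the vectorised engine agrees with the reference pair functions", {
  set.seed(31)
  p <- surf_params(d0 = 2.5)
  n <- 40
  pos <- matrix(runif(3 * n, 0, 12), n)
  nrm <- matrix(rnorm(3 * n), n); nrm <- nrm / sqrt(rowSums(nrm^2))
  obj <- rep(c(0L, 1L), length.out = n)
  sys <- surfel_system(data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                                  nx = nrm[, 1], ny = nrm[, 2], nz = nrm[, 3],
                                  object_id = obj), p)
  idx <- build_index(sys)
  pr <- index_pairs(idx, p$alpha * p$d0)
  pf <- surfseg:::cpp_pair_forces(sys$pos, sys$nrm, pr$i, pr$j, pr$d,
                                  sys$object, sys$state, p$d0, p$k_dist,
                                  p$k_plane, p$k_tilt, p$profile_w)
  Fref <- matrix(0, n, 3); Tref <- matrix(0, n, 3); cnt <- integer(n)
  for (k in seq_along(pr$i)) {
    i <- pr$i[k]; j <- pr$j[k]
    si <- make_surfel(sys$pos[i, ], sys$nrm[i, ], sys$object[i])
    sj <- make_surfel(sys$pos[j, ], sys$nrm[j, ], sys$object[j])
    if (sys$object[i] == sys$object[j]) {
      a <- pair_interaction(si, sj, p); b <- pair_interaction(sj, si, p)
      cnt[i] <- cnt[i] + 1L; cnt[j] <- cnt[j] + 1L
    } else {
      a <- pair_interaction_repulsive_only(si, sj, p)
      b <- pair_interaction_repulsive_only(sj, si, p)
    }
    Fref[i, ] <- Fref[i, ] + a$F_dist + a$F_plane
    Fref[j, ] <- Fref[j, ] + b$F_dist + b$F_plane
    Tref[i, ] <- Tref[i, ] + a$T_tilt
    Tref[j, ] <- Tref[j, ] + b$T_tilt
  }
  expect_equal(pf$F, Fref, tolerance = 1e-12)
  expect_equal(pf$T, Tref, tolerance = 1e-12)
  expect_equal(pf$count, cnt)
})

test_that("local_max_offset finds ramp and shell maxima", {
  ## ramp along +x: maximum at the far end of the band
  ramp <- image3d(array(rep(seq_len(40), times = 40 * 40), c(40, 40, 40)))
  off <- local_max_offset(ramp, c(20, 20, 20), c(1, 0, 0), band = 5)
  expect_equal(off, 5)
  off2 <- local_max_offset(ramp, c(20, 20, 20), c(-1, 0, 0), band = 5)
  expect_equal(off2, -5)

  ## surfel 3 px inside a sphere shell, outward normal: offset ~ +3
  img <- phantom_sphere_shell(size = c(64, 64, 64), radius = 20)
  ctr <- c(31.5, 31.5, 31.5)
  off3 <- local_max_offset(img, ctr + c(17, 0, 0), c(1, 0, 0), band = 6)
  expect_lt(abs(off3 - 3), 0.75)
})

test_that("flat profiles and fully-outside positions return NA", {
  flat <- image3d(array(0.7, c(10, 10, 10)))
  expect_true(is.na(local_max_offset(flat, c(5, 5, 5), c(0, 0, 1), band = 3)))
  img <- phantom_sphere_shell(size = c(32, 32, 32), radius = 10)
  expect_true(is.na(local_max_offset(img, c(500, 500, 500), c(0, 0, 1),
                                     band = 3)))
})

test_that("out-of-volume samples rank below in-volume intensities", {
  ## dim 20: surfel near the face; the only bright voxel is inside
  vol <- array(0, c(20, 20, 20)); vol[10, 10, 10] <- 1
  img <- image3d(vol)
  ## normal pointing out of the volume: maximum must be found inward
  off <- local_max_offset(img, c(12, 9, 9), c(1, 0, 0), band = 12)
  expect_equal(off, -3)
})

test_that("image force respects the trap window and constant norm", {
  p <- surf_params(d0 = 3, f_signal = 0.02, f_pressure = 0)
  img <- phantom_sphere_shell(size = c(64, 64, 64), radius = 20)
  ctr <- c(31.5, 31.5, 31.5)
  inside <- make_surfel(ctr + c(18, 0, 0), c(1, 0, 0))
  fi <- image_force(inside, img, p)
  expect_false(fi$at_maximum)
  expect_equal(sqrt(sum(fi$F_total^2)), p$f_signal)   # constant norm
  expect_gt(sum(fi$F_total * inside$normal), 0)       # towards the shell

  on_shell <- make_surfel(ctr + c(20, 0, 0), c(1, 0, 0))
  fo <- image_force(on_shell, img, p)
  expect_true(fo$at_maximum)
  expect_equal(fo$F_total, c(0, 0, 0))                # both forces null

  outside <- make_surfel(ctr + c(22, 0, 0), c(1, 0, 0))
  fb <- image_force(outside, img, p)
  expect_lt(sum(fb$F_total * outside$normal), 0)      # pulled back
})

test_that("flat image leaves pressure only", {
  p <- surf_params(f_pressure = -0.02)
  flat <- image3d(array(0.3, c(8, 8, 8)))
  s <- make_surfel(c(4, 4, 4), c(0, 1, 0))
  f <- image_force(s, flat, p)
  expect_false(f$at_maximum)
  expect_equal(f$F_total, -0.02 * s$normal)
})

test_that("anisotropic spacing keeps the search band physically isotropic", {
  ## bright plane at z-index 10 = physical z 30 with spacing (1,1,3)
  vol <- array(0, c(24, 24, 20)); vol[, , 11] <- 1
  img <- image3d(vol, spacing = c(1, 1, 3))
  ## surfel at z-index 8 (physical 24), normal +z: maximum 6 physical units
  ## ahead; with an isotropic band of 8 physical px it must be found
  off <- local_max_offset(img, c(12, 12, 8), c(0, 0, 1), band = 8)
  expect_false(is.na(off))
  expect_lt(abs(off - 6), 0.75)
})
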