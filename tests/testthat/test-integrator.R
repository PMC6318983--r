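test_that("a constant force moves a surfel by d0 times the force per step", {
  p <- no_adapt_params(d0 = 15, f_pressure = 0.01)
  sys <- surfel_system(list(make_surfel(c(0, 0, 0), c(0, 0, 1))), p)
  out <- step_system(sys, NULL)
  expect_equal(out$system$pos[1, 3], 0.15, tolerance = 1e-12)
  expect_equal(out$report$max_displacement, 0.15, tolerance = 1e-12)
})

test_that("a quiet hexagonal patch is a fixed point of step_system", {
  hp <- hex_patch(3)
  sys <- mat_system(hp$pos, hp$nrm, no_adapt_params(d0 = 3, f_pressure = 0.01))
  ## the center surfel is in pairwise equilibrium, so pressure alone acts
  ## on it: it moves exactly d0 * f along +z and nothing else. All normals
  ## stay aligned (coplanar patch exerts zero tilt torque), so every
  ## surfel takes exactly the same z step. Ring surfels may drift slightly
  ## in-plane (next-nearest-neighbor attraction), which is not asserted.
  out <- step_system(sys, NULL)$system
  expect_equal(out$pos[1, ] - hp$pos[1, ], c(0, 0, 0.03), tolerance = 1e-12)
  expect_lt(max(abs(out$nrm - hp$nrm)), 1e-12)
  expect_equal(out$pos[, 3] - hp$pos[, 3], rep(0.03, nrow(hp$pos)),
               tolerance = 1e-12)
})

test_that("sub-d0 same-object surfels separate after one step", {
  p <- no_adapt_params(d0 = 4, f_pressure = 0)
  pos <- rbind(c(0, 0, 0), c(2, 0, 0))   # 0.5 d0 apart
  nrm <- rbind(c(0, 0, 1), c(0, 0, 1))
  sys <- mat_system(pos, nrm, p)
  out <- step_system(sys, NULL)$system
  expect_gt(abs(diff(out$pos[, 1])), 2)
})

test_that("force blow-up aborts naming the surfel and step", {
  p <- suppressWarnings(no_adapt_params(d0 = 3, f_pressure = 1e308))
  sys <- suppressWarnings(
    surfel_system(list(make_surfel(c(0, 0, 0), c(0, 0, 1))), p))
  expect_error(step_system(sys, NULL), "surfel id 1.*step 1")
})

test_that("population collapse is reported with advice", {
  p <- surf_params(d0 = 3)
  pos <- rbind(c(0, 0, 0), c(50, 50, 50))   # both isolated, mature
  nrm <- rbind(c(0, 0, 1), c(0, 0, 1))
  sys <- mat_system(pos, nrm, p)
  expect_error(step_system(sys, NULL), "population collapse")
})

test_that("update_convergence applies the window and locking rules", {
  ## A - B - C collinear at d0 = 3: A-B and B-C are neighbors, A-C are not
  p <- surf_params(d0 = 3)
  pos <- rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0))
  nrm <- matrix(rep(c(0, 0, 1), 3), ncol = 3, byrow = TRUE)
  sys <- mat_system(pos, nrm, p)
  ## C moved beyond the net-displacement tolerance since the last checkpoint
  sys$pos[3, ] <- sys$pos[3, ] + c(0, 0, 2)   # 2 > 0.25 * 3
  sys <- update_convergence(sys)
  expect_identical(sys$state, c(surfseg:::STATE_LOCKED,
                                surfseg:::STATE_CONVERGED,
                                surfseg:::STATE_ACTIVE))
  ## references were reset: a second immediate checkpoint locks everything
  sys <- update_convergence(sys)
  expect_true(all(sys$state == surfseg:::STATE_LOCKED))
})

test_that("rotation beyond the tolerance prevents convergence", {
  p <- surf_params(d0 = 3)
  hp <- hex_patch(3)
  sys <- mat_system(hp$pos, hp$nrm, p)
  th <- 2 * p$conv_rot_tol
  sys$nrm[1, ] <- c(sin(th), 0, cos(th))
  sys <- update_convergence(sys)
  expect_identical(sys$state[1], surfseg:::STATE_ACTIVE)
})

test_that("a pre-locked system runs zero steps", {
  hp <- hex_patch(3)
  sys <- mat_system(hp$pos, hp$nrm, surf_params(d0 = 3))
  sys$state <- rep(surfseg:::STATE_LOCKED, 7)
  run <- run_system(sys, NULL, max_steps = 50)
  expect_identical(run$steps_run, 0L)
  expect_true(run$converged)
})

test_that("the locked set never shrinks and locked surfels stay bitwise fixed", {
  img <- phantom_sphere_shell(size = c(64, 64, 64), radius = 20)
  sys <- surfel_system(sphere_seed(c(31.5, 31.5, 31.5), 8, 3),
                       surf_params(d0 = 3, f_pressure = 0.02, rng_seed = 3))
  run <- run_system(sys, img, max_steps = 900)
  expect_true(run$converged)
  expect_true(all(diff(run$reports$n_locked) >= 0))
  ## restart from a snapshot mid-run and check a locked surfel stays put
  sys2 <- surfel_system(sphere_seed(c(31.5, 31.5, 31.5), 8, 3),
                        surf_params(d0 = 3, f_pressure = 0.02, rng_seed = 3))
  for (i in seq_len(run$steps_run)) {
    sys2 <- step_system(sys2, img)$system
    if (any(sys2$state == surfseg:::STATE_LOCKED)) break
  }
  locked <- which(sys2$state == surfseg:::STATE_LOCKED)
  snap_pos <- sys2$pos[locked, , drop = FALSE]
  snap_id <- sys2$id[locked]
  for (i in 1:50) sys2 <- step_system(sys2, img)$system
  expect_identical(sys2$pos[match(snap_id, sys2$id), , drop = FALSE], snap_pos)
})

test_that("report population counts always sum to the total", {
  img <- phantom_sphere_shell(size = c(48, 48, 48), radius = 15)
  sys <- surfel_system(sphere_seed(c(23.5, 23.5, 23.5), 7, 3),
                       surf_params(d0 = 3, f_pressure = 0.02, rng_seed = 5))
  for (i in 1:120) {
    out <- step_system(sys, img)
    sys <- out$system
    rp <- out$report
    expect_identical(rp$n_active + rp$n_converged + rp$n_locked,
                     n_surfels(sys))
  }
})

test_that("pressure-only inflation follows the growth law", {
  ## mean radius grows by ~ d0 * f_pressure per step while curvature
  ## effects are small (R >> d0)
  p <- surf_params(d0 = 3, f_pressure = 0.02, rng_seed = 7)
  sys <- surfel_system(sphere_seed(c(0, 0, 0), 50, 3), p)
  r0 <- mean(sqrt(rowSums(sys$pos^2)))
  run <- run_system(sys, NULL, max_steps = 50)
  r1 <- mean(sqrt(rowSums(run$system$pos^2)))
  rate <- (r1 - r0) / 50
  expect_equal(rate, p$d0 * p$f_pressure, tolerance = 0.1)
})

test_that("deflation mirrors inflation", {
  p <- surf_params(d0 = 3, f_pressure = -0.02, rng_seed = 7)
  sys <- surfel_system(sphere_seed(c(0, 0, 0), 50, 3), p)
  r0 <- mean(sqrt(rowSums(sys$pos^2)))
  run <- run_system(sys, NULL, max_steps = 50)
  r1 <- mean(sqrt(rowSums(run$system$pos^2)))
  expect_lt(r1, r0 - 2)
})

test_that("run_system restores the caller's RNG state", {
  set.seed(1234)
  before <- .Random.seed
  sys <- surfel_system(sphere_seed(c(0, 0, 0), 10, 3),
                       surf_params(d0 = 3, f_pressure = 0.01))
  invisible(run_system(sys, NULL, max_steps = 30))
  expect_identical(.Random.seed, before)
})

test_that("resume reactivates all surfels and accepts new parameters", {
  hp <- hex_patch(3)
  sys <- mat_system(hp$pos, hp$nrm, surf_params(d0 = 3))
  sys$state <- rep(surfseg:::STATE_LOCKED, 7)
  sys$still <- rep(3L, 7)
  res <- resume_system(sys, surf_params(d0 = 1.5))
  expect_true(all(res$state == surfseg:::STATE_ACTIVE))
  expect_true(all(res$still == 0L))
  expect_equal(res$params$d0, 1.5)
})

test_that("the surfseg() fit object carries methods and measurements", {
  img <- phantom_sphere_shell(size = c(48, 48, 48), radius = 15)
  fit <- surfseg(img, sphere_seed(c(23.5, 23.5, 23.5), 7, 3),
                 d0 = 3, f_pressure = 0.02, rng_seed = 6)
  expect_s3_class(fit, "surfseg")
  expect_true(fit$converged)
  out <- capture.output(print(fit))
  expect_match(out, "all locked", all = FALSE)
  sm <- summary(fit)
  expect_s3_class(sm, "summary.surfseg")
  expect_equal(sm$objects$volume, 4 / 3 * pi * 15^3, tolerance = 0.12)
  expect_equal(sm$objects$components, 1L)
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
  expect_s3_class(as_cloud(fit), "oriented_cloud")
})
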