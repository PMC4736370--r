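test_that("tracking parameter validation enforces the documented ranges", {
  p <- tracking_params()
  expect_equal(p$n_per_voxel, 500L)
  expect_equal(p$max_steps, 2000L)
  expect_equal(p$step_length, 0.5)
  expect_equal(p$curvature_threshold, 0.2)
  expect_error(tracking_params(n_per_voxel = 0), "n_per_voxel")
  expect_error(tracking_params(step_length = 0), "step_length")
  expect_error(tracking_params(curvature_threshold = 1.2), "curvature")
})

test_that("Watson sampling matches a numerical integration of the density", {
  # E[(mu.x)^2] under f(t) propto exp(kappa t^2) on [-1, 1]
  for (kappa in c(5, 50)) {
    num <- integrate(function(t) t^2 * exp(kappa * t^2), -1, 1,
                     rel.tol = 1e-10)$value
    den <- integrate(function(t) exp(kappa * t^2), -1, 1,
                     rel.tol = 1e-10)$value
    expected <- num / den
    x <- watson_sample(1e4, c(0, 0, 1), kappa, seed = 8)
    t2 <- x[, 3]^2
    expect_lt(abs(mean(t2) - expected) / expected, 0.02)
    expect_lt(max(abs(rowSums(x^2) - 1)), 1e-12)
  }
  # kappa -> Inf returns the mean axis exactly
  xi <- watson_sample(5, c(1, 1, 0), Inf, seed = 1)
  expect_equal(xi, matrix(1 / sqrt(2) * c(1, 1, 0), 5, 3, byrow = TRUE))
})

test_that("kappa = 0 voxels sample uniformly on the sphere", {
  x <- watson_sample(1e4, c(0, 0, 1), 0, seed = 3)
  # each coordinate of a uniform spherical point is Uniform(-1, 1)
  for (j in 1:3) {
    ks <- suppressWarnings(ks.test(x[, j], "punif", -1, 1))
    expect_gt(ks$p.value, 0.001)
  }
  # same behaviour through the R-level sampler used by sample_direction
  mv <- list(mu = matrix(c(0, 0, 1), 1), kappa = 0, frac = 1)
  set.seed(4)
  y <- sample_direction(mv, n = 1e4)
  ks <- suppressWarnings(ks.test(y[, 3], "punif", -1, 1))
  expect_gt(ks$p.value, 0.001)
})

test_that("sample_direction honours fractions and sign alignment", {
  mv <- list(mu = rbind(c(1, 0, 0), c(0, 1, 0)), kappa = c(Inf, Inf),
             frac = c(0.5, 0.5))
  set.seed(9)
  x <- sample_direction(mv, previous_direction = c(1, 1, 0) / sqrt(2),
                        n = 1e4)
  # compartment choice is a fair coin within binomial 3 sigma
  n1 <- sum(x[, 1] > 0.5)
  expect_lt(abs(n1 - 5000), 3 * sqrt(1e4 * 0.25))
  # all draws aligned with the previous direction
  expect_true(all(x %*% (c(1, 1, 0) / sqrt(2)) >= 0))
})

test_that("the deterministic limit reproduces eigenvector tracking exactly", {
  ph <- tube_phantom(grid = c(16, 9, 9))
  om <- orientation_model_from_compartments(ph, kappa = Inf)
  mask <- ph$tract_masks[[1]]
  seed_pt <- drop(voxel_to_world(mask, c(8, 4, 4)))
  pars <- tracking_params(n_per_voxel = 1, seed = 6)
  got <- track_streamline(om, mask, seed_pt, pars)
  axis_fun <- function(v) {
    e <- which(ph$compartments$vox_id ==
                 v[1] + 16 * (v[2] + 9 * v[3]) + 1)[1]
    ph$compartments$orientation[e, ]
  }
  want <- oracle_deterministic_track(axis_fun, mask, seed_pt,
                                     pars$step_length, pars$max_steps)
  expect_equal(unname(got), unname(want), tolerance = 1e-12)
  # spans the tube: in-mask steps of 0.5 mm per direction
  expect_equal(nrow(got), length(unique(got[, 1])))
  expect_true(all(diff(got[, 1]) == 0.5))
})

test_that("every streamline satisfies the curvature-cosine constraint", {
  ph <- tube_phantom(grid = c(12, 9, 9), sigma = 5)
  tf <- fit_tensor_lls(ph$dwi, mask = ph$mask)
  om <- orientation_model_from_tensor(tf, kappa_max = 15)
  ws <- whole_brain_tracking(om, ph$mask,
                             tracking_params(n_per_voxel = 3, seed = 2))
  mc <- vapply(unclass(ws), min_step_cosine, 0)
  expect_true(all(mc >= 0.2 - 1e-12))
  # and no point leaves the mask (stronger than the one-step-length bound)
  Ainv <- solve(ph$mask$affine)
  for (s in unclass(ws)[seq(1, length(ws), by = 97)]) {
    idx <- round(world_to_voxel(ph$mask$affine, s))
    expect_true(all(idx >= 0 & idx < rep(dim(ph$mask$data),
                                         each = nrow(idx))))
  }
})

test_that("a single-voxel mask terminates tracking within bounds", {
  ph <- tube_phantom(grid = c(8, 7, 7))
  m <- array(0L, dim(ph$mask$data)); m[4, 4, 4] <- 1L
  mask1 <- mask_volume(m, ph$mask$affine)
  om <- orientation_model_from_compartments(ph, kappa = 50)
  pars <- tracking_params(n_per_voxel = 1, max_steps = 20, seed = 3)
  sl <- track_streamline(om, mask1, drop(voxel_to_world(mask1, c(3, 3, 3))),
                         pars)
  expect_lte(nrow(sl), 2 * pars$max_steps + 1)
  idx <- round(world_to_voxel(mask1$affine, sl))
  expect_true(all(idx[, 1] == 3 & idx[, 2] == 3 & idx[, 3] == 3))
  # seeding outside the mask is an error
  expect_error(track_streamline(om, mask1, c(0, 0, 0), pars), "outside")
})

test_that("whole-brain tracking yields seeds-per-voxel streamlines, reproducibly", {
  ph <- tube_phantom(grid = c(10, 5, 5))
  om <- orientation_model_from_compartments(ph, kappa = 30)
  m <- array(0L, dim(ph$mask$data)); m[3:7, 2:3, 2:3] <- 1L
  mask <- mask_volume(m, ph$mask$affine)
  pars <- tracking_params(n_per_voxel = 7, seed = 11)
  a <- whole_brain_tracking(om, mask, pars)
  expect_equal(length(a), 7L * sum(mask$data))
  b <- whole_brain_tracking(om, mask, pars)
  expect_identical(unclass(a), unclass(b))
  # one seed, one streamline
  m1 <- array(0L, dim(ph$mask$data)); m1[5, 2, 2] <- 1L
  one <- whole_brain_tracking(om, mask_volume(m1, ph$mask$affine),
                              tracking_params(n_per_voxel = 1, seed = 1))
  expect_equal(length(one), 1L)
})

test_that("ACM reproducibility improves with the number of seeds per voxel", {
  ph <- tube_phantom(grid = c(12, 8, 8), sigma = 5)
  tf <- fit_tensor_lls(ph$dwi, mask = ph$mask)
  om <- orientation_model_from_tensor(tf)
  run <- function(n, s)
    whole_brain_tracking(om, ph$mask,
                         tracking_params(n_per_voxel = n, seed = s),
                         keep_streamlines = FALSE,
                         count_mask = ph$mask)$counts
  cors <- sapply(c(5, 25, 125), function(n)
    cor(as.vector(run(n, 1)), as.vector(run(n, 2))))
  expect_true(all(diff(cors) > 0))
})
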