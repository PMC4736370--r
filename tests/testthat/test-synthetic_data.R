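test_that("direction sets are deterministic, valid, and near-optimally spread", {
  sch <- make_gradient_scheme(61, 1500, 10, seed = 7)
  expect_identical(sch, make_gradient_scheme(61, 1500, 10, seed = 7))
  expect_equal(n_volumes(sch), 71)
  expect_error(make_gradient_scheme(5, 1000, 1), "at least 6")
  expect_equal(n_volumes(make_gradient_scheme(6, 1000, 1, seed = 1)), 7)

  # independent long-run repulsion oracle: naive tangential force descent
  # with a slow step decay, run far longer than the package optimiser
  X <- with_seed(99, {
    x <- matrix(rnorm(3 * 61), 3)
    x / rep(sqrt(colSums(x^2)), each = 3)
  })
  for (it in 1:4000) {
    eta <- 0.05 / (1 + 0.002 * it)
    G <- matrix(0, 3, 61)
    for (j in 1:61) {
      d1 <- X - X[, j]; d2 <- X + X[, j]
      r1 <- colSums(d1^2)^1.5; r1[j] <- Inf
      r2 <- colSums(d2^2)^1.5; r2[r2 < 1e-12] <- Inf
      G <- G + d1 / rep(r1, each = 3) + d2 / rep(r2, each = 3)
    }
    G <- G - X * rep(colSums(G * X), each = 3)
    gn <- sqrt(colSums(G^2)); gn[gn < 1e-12] <- 1
    X <- X + eta * G / rep(gn, each = 3)
    X <- X / rep(sqrt(colSums(X^2)), each = 3)
  }
  oracle_angle <- min_pairwise_angle(X)
  ours <- min_pairwise_angle(sch$bvecs[, sch$bvals > 0])
  expect_gte(ours, 0.95 * oracle_angle)
})

test_that("the forward signal model obeys its closed forms", {
  sch <- light_scheme()
  b <- sch$bvals
  # any compartment: b=0 volumes give exactly S0
  cmp <- fibre_compartment(c(1, 1, 0), 1.7e-3, 0.3e-3, 0.7)
  s <- simulate_signal(cmp, sch, S0 = 123)
  expect_equal(s[b == 0], rep(123, sum(b == 0)))
  # purely isotropic: S = S0 exp(-b d) in every direction
  s_iso <- simulate_signal(list(), sch, S0 = 100, iso_diffusivity = 1.1e-3)
  expect_equal(s_iso, 100 * exp(-b * 1.1e-3), tolerance = 1e-12)
  # gradient perpendicular to the fibre: S = S0 exp(-b lambda_perp)
  sch_perp <- gradient_scheme(c(0, 1500), cbind(c(0, 0, 0), c(0, 1, 0)))
  s_perp <- simulate_signal(fibre_compartment(c(1, 0, 0), 1.7e-3, 0.3e-3, 1),
                            sch_perp, S0 = 100)
  expect_equal(s_perp[2], 100 * exp(-1500 * 0.3e-3), tolerance = 1e-12)
  # invalid compartments are rejected
  expect_error(fibre_compartment(c(1, 0, 0), 1e-3, -1e-4), "lambda")
  expect_error(simulate_signal(list(
    fibre_compartment(c(1, 0, 0), fraction = 0.7),
    fibre_compartment(c(0, 1, 0), fraction = 0.7)), sch), "sum above 1")
  expect_true(all(s >= 0) && all(s_iso >= 0))
})

test_that("Rician noise has the Rayleigh mean and second-moment structure", {
  s <- rep(50, 2e4)
  expect_identical(add_rician_noise(s, 0), s)
  expect_identical(add_rician_noise(s, 3, seed = 5),
                   add_rician_noise(s, 3, seed = 5))
  # S = 0: mean = sigma * sqrt(pi/2) (Rayleigh)
  sigma <- 4
  m0 <- add_rician_noise(rep(0, 2e4), sigma, seed = 11)
  se <- sd(m0) / sqrt(length(m0))
  expect_lt(abs(mean(m0) - sigma * sqrt(pi / 2)), 3 * se)
  # any S: E[M^2] = S^2 + 2 sigma^2
  m <- add_rician_noise(s, sigma, seed = 12)
  se2 <- sd(m^2) / sqrt(length(m))
  expect_lt(abs(mean(m^2) - (50^2 + 2 * sigma^2)), 3 * se2)
  expect_true(all(m >= 0))
})

test_that("tube phantoms carry the constructed fibre geometry", {
  ph <- tube_phantom(grid = c(12, 9, 9))
  pd <- principal_direction(ph$truth)
  inside <- which(ph$tract_masks[[1]]$data == 1)
  for (v in inside[c(1, 5, 20)])
    expect_equal(abs(pd$direction[v, ]), c(1, 0, 0), tolerance = 1e-12)
  # noiseless phantom signal equals the forward model of the ground truth
  v <- inside[1]
  cmp_idx <- which(ph$compartments$vox_id == v)
  sig <- simulate_signal(
    fibre_compartment(ph$compartments$orientation[cmp_idx, ],
                      ph$compartments$lambda_par[cmp_idx],
                      ph$compartments$lambda_perp[cmp_idx],
                      ph$compartments$fraction[cmp_idx]),
    ph$dwi$scheme, S0 = ph$spec$S0,
    iso_diffusivity = ph$spec$background_adc)
  ijk <- arrayInd(v, dim(ph$mask$data))
  expect_equal(as.numeric(ph$dwi$data[ijk[1], ijk[2], ijk[3], ]), sig,
               tolerance = 1e-10)
  # tube outside the grid is rejected
  expect_error(phantom_spec(grid_dim = c(10, 10, 10), voxel_size = 2,
                            tracts = list(straight_tube(c(0, 9, 9),
                                                        c(40, 9, 9), 2))),
               "outside the grid")
})

test_that("two orthogonal tubes create two-compartment crossing voxels", {
  vs <- 2
  spec <- phantom_spec(
    grid_dim = c(11, 11, 5), voxel_size = vs,
    tracts = list(
      straight_tube(c(0, 10, 4), c(20, 10, 4), radius = 2.2),
      straight_tube(c(10, 0, 4), c(10, 20, 4), radius = 2.2)),
    scheme = light_scheme(), sigma = 0)
  ph <- build_phantom(spec, seed = 1)
  both <- which(ph$tract_masks[[1]]$data == 1 & ph$tract_masks[[2]]$data == 1)
  expect_gt(length(both), 0)
  v <- both[1]
  e <- which(ph$compartments$vox_id == v)
  expect_equal(length(e), 2L)
  expect_equal(ph$compartments$fraction[e], c(0.5, 0.5))
  ang <- abs(sum(ph$compartments$orientation[e[1], ] *
                   ph$compartments$orientation[e[2], ]))
  expect_lt(ang, 1e-12)   # 90 degrees
})

test_that("a lesion lowers ground-truth FA by the closed-form margin", {
  lesion <- list(center = c(9, 8, 8), radius = 5, rd_multiplier = 2)
  ph <- tube_phantom(grid = c(16, 9, 9), lesion = lesion)
  sc <- tensor_scalars(ph$truth)
  les <- ph$lesion_mask$data == 1 & ph$tract_masks[[1]]$data == 1
  healthy <- ph$lesion_mask$data == 0 & ph$tract_masks[[1]]$data == 1
  fa_les <- oracle_scalars(1.7e-3, 0.6e-3, 0.6e-3)$FA
  fa_healthy <- oracle_scalars(1.7e-3, 0.3e-3, 0.3e-3)$FA
  expect_equal(mean(sc$FA$data[les]), fa_les, tolerance = 1e-10)
  expect_equal(mean(sc$FA$data[healthy]), fa_healthy, tolerance = 1e-10)
  expect_equal(fa_healthy, 0.799, tolerance = 1e-3)
})

test_that("cohorts are reproducible and carry the designed group effect", {
  spec <- study_cohort_spec(base_seed = 5, grid_dim = c(10, 8, 8),
                            groups = list(NS = list(n = 2, rd_multiplier = 1),
                                          CB = list(n = 2, rd_multiplier = 2)))
  co1 <- make_cohort(spec)
  co2 <- make_cohort(spec)
  expect_identical(co1$subjects$CB01$phantom$dwi$data,
                   co2$subjects$CB01$phantom$dwi$data)
  expect_identical(co1$design, co2$design)
  expect_s3_class(co1$design, "cohort_design")

  # ground-truth (pre-noise) FA inside the lesion ROI is lower for the
  # lesioned group by about the analytic margin (eigenvalue jitter aside)
  roi <- co1$subjects$CB01$phantom$lesion_mask
  tube <- co1$subjects$CB01$phantom$tract_masks[[1]]
  sel <- roi$data == 1 & tube$data == 1
  fa_g <- sapply(co1$subjects, function(s)
    mean(tensor_scalars(s$phantom$truth)$FA$data[sel]))
  grp <- sapply(co1$subjects, `[[`, "group")
  margin <- oracle_scalars(1.7e-3, 0.3e-3, 0.3e-3)$FA -
    oracle_scalars(1.7e-3, 0.6e-3, 0.6e-3)$FA
  observed <- mean(fa_g[grp == "NS"]) - mean(fa_g[grp == "CB"])
  expect_gt(observed, 0.5 * margin)
  expect_lt(abs(observed - margin), 0.25 * margin)

  expect_error(cohort_spec(study_cohort_spec()$base_spec,
                           groups = list(A = list(n = 1), B = list(n = 3))),
               "n >= 2")
})
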