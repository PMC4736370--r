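make_design <- function(groups, age = NULL, gender = NULL, mv = NULL) {
  n <- length(groups)
  cohort_design(data.frame(
    id = sprintf("s%02d", seq_len(n)), group = groups,
    age = if (is.null(age)) seq(30, 60, length.out = n) else age,
    gender = if (is.null(gender)) rep_len(0:1, n) else gender,
    mask_voxels = if (is.null(mv)) 1000 + (seq_len(n) * 37) %% 11 else mv))
}

test_that("Gaussian smoothing conserves mass and reproduces the kernel", {
  aff <- diag(c(2, 2, 2, 1))
  const <- scalar_map(array(3.7, c(13, 13, 13)), aff)
  sm <- smooth_map(const, 4)
  # voxels more than a kernel radius from the boundary are unchanged
  expect_equal(sm$data[6:8, 6:8, 6:8], const$data[6:8, 6:8, 6:8],
               tolerance = 1e-9)
  # identity at fwhm 0
  expect_identical(smooth_map(const, 0), const)
  # unit impulse: centre value equals the discrete 3-D kernel normalisation
  imp <- array(0, c(15, 15, 15)); imp[8, 8, 8] <- 1
  sm2 <- smooth_map(scalar_map(imp, aff), 4)
  sig_vox <- (4 / (2 * sqrt(2 * log(2)))) / 2   # sigma in voxels
  r <- max(1, ceiling(4 * sig_vox))
  k1 <- dnorm(-r:r, sd = sig_vox); k1 <- k1 / sum(k1)
  expect_equal(sm2$data[8, 8, 8], k1[r + 1]^3, tolerance = 1e-12)
  # mass conserved away from boundaries
  expect_equal(sum(sm2$data), 1, tolerance = 1e-6)
  expect_error(smooth_map(const, -1), ">= 0")
})

test_that("GLM t and F maps match closed-form oracles", {
  x <- c(1, 2, 3); y <- c(2, 3, 4)
  d <- make_design(rep(c("A", "B"), each = 3))
  dm <- design_matrix(d, covariates = character())
  Y <- matrix(c(x, y), ncol = 1)
  st <- glm_stat(Y, dm, "A>B")
  expect_equal(st$stat, oracle_pooled_t(x, y), tolerance = 1e-12)
  expect_equal(st$stat, -sqrt(3 / 2), tolerance = 1e-12)
  # three groups: omnibus F equals the one-way ANOVA F
  vals <- c(1, 2, 3, 4, 2, 5, 6, 7, 1, 9)
  grp <- rep(c("A", "B", "C"), c(3, 3, 4))
  dm3 <- design_matrix(make_design(grp), covariates = character())
  stF <- glm_stat(matrix(vals, ncol = 1), dm3, "group")
  expect_equal(stF$stat, oracle_anova_f(vals, grp), tolerance = 1e-12)
  # cross-check against the installed linear-model machinery
  expect_equal(stF$stat,
               unname(summary(lm(vals ~ factor(grp)))$fstatistic["value"]),
               tolerance = 1e-10)
})

test_that("contrasts on covariates orthogonal to the data give statistic 0", {
  d <- make_design(rep(c("A", "B"), each = 4))
  dm <- design_matrix(d)
  set.seed(2)
  # orthogonalise the response against the partialled age column, so the
  # age contrast has exactly zero estimated effect
  X <- dm$X
  j <- match("age", colnames(X))
  a_perp <- stats::resid(stats::lm.fit(X[, -j, drop = FALSE], X[, j]))
  Y <- matrix(rnorm(8 * 3), 8, 3)
  Y <- Y - a_perp %*% (crossprod(a_perp, Y) / sum(a_perp^2))
  cvec <- numeric(ncol(X)); cvec[j] <- 1
  st <- glm_stat(Y, dm, cvec)
  expect_true(all(abs(st$stat) < 1e-8))
})

test_that("rank-deficient designs fail naming the collinear columns", {
  d <- make_design(rep(c("A", "B"), each = 3), age = rep(40, 6),
                   gender = rep(1, 6))
  # constant age (centred to 0) and constant gender are collinear
  expect_error(design_matrix(d), "collinear")
  err <- tryCatch(design_matrix(d), error = conditionMessage)
  expect_match(err, "age|gender")
})

test_that("location shifts common to all subjects leave statistics unchanged", {
  d <- make_design(rep(c("A", "B", "C"), each = 4))
  dm <- design_matrix(d)
  set.seed(3)
  Y <- matrix(rnorm(12 * 20), 12, 20)
  s1 <- glm_stat(Y, dm, "A>B")$stat
  s2 <- glm_stat(Y + 17.3, dm, "A>B")$stat
  expect_equal(s1, s2, tolerance = 1e-9)
  f1 <- glm_stat(Y, dm, "group")$stat
  f2 <- glm_stat(Y + 17.3, dm, "group")$stat
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("TFCE equals brute-force threshold integration on random maps", {
  set.seed(6)
  for (conn in c(6L, 26L)) {
    arr <- array(pmax(0, rnorm(10 * 10 * 10, 0.3, 1)), c(10, 10, 10))
    expect_lt(max(abs(tfce(arr, connectivity = conn) -
                        oracle_tfce(arr, conn = conn))), 1e-10)
  }
  # fixed dh and non-default exponents
  arr <- array(pmax(0, rnorm(6^3, 0.5, 1)), c(6, 6, 6))
  expect_lt(max(abs(tfce(arr, E = 1, H = 1, dh = 0.05) -
                      oracle_tfce(arr, E = 1, H = 1, dh = 0.05))), 1e-10)
})

test_that("TFCE handles degenerate input and scales monotonically", {
  z <- array(0, c(5, 5, 5))
  expect_equal(tfce(z), z)
  expect_error(tfce(array(1, c(3, 3, 3)), dh = 0), "dh")
  set.seed(7)
  arr <- array(pmax(0, rnorm(6^3, 0.4, 1)), c(6, 6, 6))
  for (cc in c(1.5, 3)) {
    expect_true(all(tfce(arr * cc) >= tfce(arr) - 1e-12))
  }
  # uniform-height cluster closed form
  u <- array(0, c(6, 6, 6)); u[2:3, 2:3, 2] <- 2
  hs <- seq(0.02, 2, by = 0.02)
  expect_equal(tfce(u, dh = 0.02)[2, 2, 2], 4^0.5 * sum(hs^2 * 0.02),
               tolerance = 1e-10)
})

test_that("permutation p-values respect their attainable bounds and grid", {
  mask <- mask_volume(array(1L, c(4, 4, 2)), diag(c(2, 2, 2, 1)))
  d <- make_design(rep(c("A", "B"), each = 5),
                   age = round(rnorm(10, 45, 10)), mv = rnorm(10, 1000, 30))
  set.seed(8)
  Y <- matrix(rnorm(10 * 32), 10, 32)
  pr <- permutation_test(Y, mask, d, "A>B", n_perm = 150, seed = 1)
  p <- pr$p_fwe[pr$mask_idx]
  expect_true(all(p >= 1 / 151 & p <= 1))
  expect_true(all(abs(p * 151 - round(p * 151)) < 1e-9))
  # under the null, FWE p-values of the minimum are not systematically tiny
  expect_gt(min(p), 1 / 151 - 1e-12)
})

test_that("permutation null p-values are uniform on the attainable grid", {
  # one-voxel 'map': the corrected p at a single voxel is the uncorrected
  # permutation p, which must be uniform under exchangeability
  mask <- mask_volume(array(1L, c(1, 1, 1)), diag(4))
  d <- make_design(rep(c("A", "B"), each = 4))
  set.seed(9)
  ps <- replicate(120, {
    Y <- matrix(rnorm(8), 8, 1)
    pr <- permutation_test(Y, mask, d, "A>B", n_perm = 100, tfce_on = FALSE,
                           seed = sample.int(1e6, 1), keep_null = FALSE)
    pr$p_fwe[1]
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("small-volume correction sharpens but never contradicts global FWE", {
  mask <- mask_volume(array(1L, c(5, 5, 2)), diag(c(2, 2, 2, 1)))
  d <- make_design(rep(c("A", "B"), each = 5))
  set.seed(10)
  Y <- matrix(rnorm(10 * 50), 10, 50)
  Y[d$group == "A", 12] <- Y[d$group == "A", 12] + 2.5   # planted effect
  pr <- permutation_test(Y, mask, d, "A>B", n_perm = 200, seed = 3)
  # roi = whole mask reproduces the global result
  svc_all <- small_volume_correct(pr, mask)
  expect_equal(svc_all$p_svc$roi[pr$mask_idx], pr$p_fwe[pr$mask_idx],
               tolerance = 1e-12)
  # strict sub-roi: p <= global everywhere inside
  m <- array(0L, c(5, 5, 2)); m[2:3, 2:3, 1] <- 1L
  roi <- mask_volume(m, mask$affine)
  svc <- small_volume_correct(pr, roi)
  lin <- which(roi$data == 1L)
  expect_true(all(svc$p_svc$roi[lin] <= pr$p_fwe[lin] + 1e-12))
  expect_named(svc$summary,
               c("roi", "n_voxels", "p_fwe_peak",
                 "peak_x", "peak_y", "peak_z"))
  # one-voxel roi: p equals that voxel's uncorrected permutation p
  m1 <- array(0L, c(5, 5, 2)); m1[2, 2, 1] <- 1L
  v <- which(m1 == 1L)
  svc1 <- small_volume_correct(pr, mask_volume(m1, mask$affine))
  pos <- match(v, pr$mask_idx)
  p_unc <- (1 + sum(pr$null_enhanced[, pos] >= pr$enhanced[v])) /
    (pr$n_perm + 1)
  expect_equal(svc1$p_svc$roi[v], p_unc)
  # an roi reaching outside the analysis mask is rejected
  expect_error(small_volume_correct(
    permutation_test(Y[, 1:8], mask_volume(array(1L, c(2, 2, 2)),
                                           mask$affine),
                     d, "A>B", n_perm = 200, seed = 3),
    roi), "outside")
})

test_that("few exchangeable subjects fall back to full enumeration", {
  mask <- mask_volume(array(1L, c(2, 2, 1)), diag(4))
  d <- make_design(rep(c("A", "B"), each = 2))
  dm <- design_matrix(d, covariates = character())
  Y <- matrix(rnorm(4 * 4), 4, 4)
  expect_warning(
    pr <- permutation_test(Y, mask, dm, "A>B", n_perm = 100, seed = 1),
    "enumerating")
  expect_equal(pr$n_perm, factorial(4))
})

test_that("the Lilliefors check is calibrated and detects heavy tails", {
  mask <- mask_volume(array(1L, c(10, 10, 4)), diag(4))
  d <- make_design(rep(c("A", "B"), each = 10))
  set.seed(12)
  n_vox <- 400
  Yg <- matrix(rnorm(20 * n_vox), 20, n_vox)
  rg <- residual_normality_check(Yg, mask, d)
  expect_lt(abs(rg$rejection_fraction - 0.05), 3 * sqrt(0.05 * 0.95 / n_vox))
  Yt <- matrix(rt(20 * n_vox, df = 3), 20, n_vox)
  rt3 <- residual_normality_check(Yt, mask, d)
  expect_gt(rt3$rejection_fraction, 0.05 + 3 * sqrt(0.05 * 0.95 / n_vox))
  # constant residuals are flagged as degenerate, not tested
  Yc <- Yg; Yc[, 1] <- rep(c(1, 2), each = 10)[seq_len(20)]
  rc <- residual_normality_check(Yc, mask, d)
  expect_gte(rc$n_degenerate, 1L)
  dm4 <- design_matrix(make_design(c("A", "A", "B", "B")),
                       covariates = character())
  expect_error(residual_normality_check(Yg[1:4, ],
               mask_volume(array(1L, c(10, 10, 4)), diag(4)), dm4),
               "at least 5")
})

test_that("ICV correlation reproduces closed-form Pearson values", {
  aff <- diag(4)
  roi <- mask_volume(array(1L, c(2, 2, 1)), aff)
  mk_map <- function(v) scalar_map(array(v, c(2, 2, 1)), aff)
  # perfectly linear pairs -> r = 1
  icv <- c(10, 20, 30, 40)
  maps <- lapply(icv, function(i) mk_map(2 * i + 1))
  out <- icv_correlation(maps, roi, icv, rep("NS", 4))
  expect_equal(out$r, 1, tolerance = 1e-12)
  # the 6-pair reference set against the hand formula
  x <- c(1, 2, 3, 4, 5, 6); y <- c(2, 4, 5, 4, 5, 7)
  maps6 <- lapply(y, mk_map)
  out6 <- icv_correlation(maps6, roi, x, rep("CB", 6))
  expect_equal(out6$r, oracle_pearson(x, y), tolerance = 1e-12)
  expect_equal(out6$r, 0.87831, tolerance = 1e-4)
  expect_equal(out6$p,
               cor.test(x, y)$p.value, tolerance = 1e-12)
  # permuting the pairing shrinks |r| in expectation
  set.seed(13)
  rs <- replicate(200, {
    yy <- sample(y)
    abs(oracle_pearson(x, yy))
  })
  expect_lt(mean(rs), abs(out6$r))
  # degenerate inputs
  expect_error(icv_correlation(maps6, roi, rep(1, 6), rep("CB", 6)),
               "zero variance")
  expect_error(icv_correlation(maps6[1:2], roi, x[1:2], rep("CB", 2)),
               "fewer than 3")
})
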