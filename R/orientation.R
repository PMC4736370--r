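#' Per-voxel Watson orientation model
#'
#' The tracker's stand-in for a sampled fibre-orientation posterior: each
#' voxel carries up to K compartments, each with a mean axis, a Watson
#' concentration kappa (kappa = 0 is uniform on the sphere, kappa = Inf is
#' deterministic) and a mixture fraction; fractions sum to 1 over the
#' compartments of a voxel. The parametric form is isolated behind this
#' class so that a bootstrap or MCMC orientation backend could be swapped in.
#'
#' @param mu array `c(dims, K, 3)` of unit mean axes.
#' @param kappa array `c(dims, K)` of concentrations (>= 0, may be Inf).
#' @param frac array `c(dims, K)` of fractions.
#' @param ncomp integer array `dims`: number of valid compartments per voxel.
#' @param dims grid dimensions.
#' @param affine voxel-to-world transform.
#' @export
orientation_model <- function(mu, kappa, frac, ncomp, dims, affine) {
  dims <- as.integer(dims)
  K <- dim(kappa)[4]
  stopifnot(all(dim(mu) == c(dims, K, 3)), all(dim(frac) == c(dims, K)),
            all(dim(ncomp) == dims))
  structure(list(mu = mu, kappa = kappa, frac = frac,
                 ncomp = array(as.integer(ncomp), dims),
                 dims = dims, K = K, affine = affine),
            class = "orientation_model")
}

#' @export
print.orientation_model <- function(x, ...) {
  cat(sprintf("<orientation_model> %s grid, up to %d compartments/voxel\n",
              paste(x$dims, collapse = "x"), x$K))
  invisible(x)
}

#' Orientation model from a fitted tensor field
#'
#' One compartment per voxel: mean = principal eigenvector, concentration
#' kappa = `kappa_rule(FA)`. The default rule `kappa_max * FA^2` makes
#' tracking nearly deterministic in coherent white matter and nearly uniform
#' in isotropic tissue; voxels with undefined FA get an isotropic entry
#' (kappa = 0).
#'
#' @param tf a `tensor_field`.
#' @param kappa_rule function FA -> kappa; default `kappa_max * FA^2`.
#' @param kappa_max scale of the default rule (default 200).
#' @export
orientation_model_from_tensor <- function(tf, kappa_rule = NULL,
                                          kappa_max = 200) {
  if (is.null(kappa_rule)) kappa_rule <- function(fa) kappa_max * fa^2
  pd <- principal_direction(tf)
  nv <- prod(tf$dims)
  mu <- matrix(0, nv, 3); mu[, 1] <- 1
  kap <- rep(0, nv)
  ok <- which(tf$valid & !is.na(pd$fa))
  mu[ok, ] <- pd$direction[ok, , drop = FALSE]
  kap[ok] <- kappa_rule(pd$fa[ok])
  orientation_model(array(mu, c(tf$dims, 1, 3)),
                    array(kap, c(tf$dims, 1)),
                    array(1, c(tf$dims, 1)),
                    array(1L, tf$dims), tf$dims, tf$affine)
}

#' Orientation model from known phantom compartments
#'
#' Builds the model directly from ground-truth fibre compartments (the
#' crossing-aware constructor used with synthetic phantoms): one entry per
#' compartment, fractions renormalised to sum to 1 within each voxel, and a
#' common concentration `kappa` (scalar, possibly Inf for the deterministic
#' limit). Voxels without compartments get an isotropic entry.
#'
#' @param phantom result of [build_phantom()] (or a compatible list with
#'   `compartments`, `mask`, `spec`).
#' @param kappa Watson concentration for every fibre entry.
#' @export
orientation_model_from_compartments <- function(phantom, kappa = 200) {
  ct <- phantom$compartments
  dims <- dim(phantom$mask$data)
  nv <- prod(dims)
  K <- if (length(ct$vox_id)) max(table(ct$vox_id)) else 1L
  K <- max(K, 1L)
  mu <- array(0, c(nv, K, 3)); mu[, , 1] <- 1
  kap <- matrix(0, nv, K)
  frac <- matrix(0, nv, K); frac[, 1] <- 1
  ncomp <- rep(1L, nv)
  if (length(ct$vox_id)) {
    ord <- order(ct$vox_id)
    vid <- ct$vox_id[ord]
    slot <- stats::ave(seq_along(vid), vid, FUN = seq_along)
    for (e in seq_along(vid)) {
      v <- vid[e]; s <- slot[e]
      mu[v, s, ] <- ct$orientation[ord[e], ]
      kap[v, s] <- kappa
      frac[v, s] <- ct$fraction[ord[e]]
    }
    for (v in unique(vid)) {
      n <- sum(vid == v)
      ncomp[v] <- n
      frac[v, 1:n] <- frac[v, 1:n] / sum(frac[v, 1:n])
      if (n < K) frac[v, (n + 1):K] <- 0
    }
  }
  orientation_model(array(mu, c(dims, K, 3)), array(kap, c(dims, K)),
                    array(frac, c(dims, K)), array(ncomp, dims),
                    dims, phantom$mask$affine)
}

#' Sample fibre directions at one voxel
#'
#' Chooses a compartment with probability proportional to its fraction and
#' draws an axis from the Watson distribution about its mean; if
#' `previous_direction` is given, the sign is aligned so the dot product is
#' non-negative. Uses R's RNG stream (seed with `set.seed()`).
#'
#' @param model_voxel list with `mu` (K x 3), `kappa` (K), `frac` (K).
#' @param previous_direction unit 3-vector or `NULL` for the first step.
#' @param n number of draws.
#' @return n x 3 matrix of unit vectors.
#' @export
sample_direction <- function(model_voxel, previous_direction = NULL, n = 1L) {
  mu <- matrix(model_voxel$mu, ncol = 3)
  kappa <- model_voxel$kappa
  frac <- model_voxel$frac / sum(model_voxel$frac)
  K <- nrow(mu)
  comp <- if (K == 1L) rep(1L, n) else
    sample.int(K, n, replace = TRUE, prob = frac)
  out <- matrix(0, n, 3)
  for (c in seq_len(K)) {
    idx <- which(comp == c)
    if (!length(idx)) next
    out[idx, ] <- r_watson(length(idx), mu[c, ], kappa[c])
  }
  if (!is.null(previous_direction)) {
    flip <- drop(out %*% previous_direction) < 0
    out[flip, ] <- -out[flip, , drop = FALSE]
  }
  out
}

# Watson draws about mu using R's RNG: rejection from an exponential envelope
# on t = mu.x in [0,1], random sign, uniform azimuth
r_watson <- function(n, mu, kappa) {
  mu <- mu / sqrt(sum(mu^2))
  if (is.infinite(kappa)) return(matrix(mu, n, 3, byrow = TRUE))
  t <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    m <- length(need)
    tt <- if (kappa <= 0) stats::runif(m) else
      log1p(stats::runif(m) * expm1(kappa)) / kappa
    acc <- if (kappa <= 0) rep(TRUE, m) else
      stats::runif(m) < exp(kappa * (tt^2 - tt))
    t[need[acc]] <- tt[acc]
    need <- need[!acc]
  }
  t <- t * sign(stats::runif(n) - 0.5)
  a <- if (abs(mu[1]) > 0.9) c(0, 1, 0) else c(1, 0, 0)
  e1 <- c(mu[2] * a[3] - mu[3] * a[2], mu[3] * a[1] - mu[1] * a[3],
          mu[1] * a[2] - mu[2] * a[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(mu[2] * e1[3] - mu[3] * e1[2], mu[3] * e1[1] - mu[1] * e1[3],
          mu[1] * e1[2] - mu[2] * e1[1])
  phi <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - t^2))
  t %o% mu + (r * cos(phi)) %o% e1 + (r * sin(phi)) %o% e2
}

#' Watson-distribution draws (tracker RNG)
#'
#' Samples axes from the bipolar Watson distribution with the same
#' counter-seeded generator the streamline tracker uses, so the tracker's
#' angular distribution can be checked directly.
#'
#' @param n number of draws.
#' @param mean_dir unit mean axis.
#' @param kappa concentration (>= 0; Inf returns the mean).
#' @param seed integer RNG seed.
#' @return n x 3 matrix of unit vectors.
#' @export
watson_sample <- function(n, mean_dir, kappa, seed = 1L) {
  mean_dir <- mean_dir / sqrt(sum(mean_dir^2))
  t(cpp_watson_sample(mean_dir, kappa, n, seed))
}
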