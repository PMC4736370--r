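#' Gradient scheme (b-values and diffusion directions)
#'
#' Per-volume diffusion weightings and unit gradient directions. Directions of
#' diffusion-weighted volumes (b > 0) must have unit Euclidean norm within
#' 1e-6; b = 0 volumes carry the zero vector.
#'
#' @param bvals numeric vector of b-values in s/mm^2.
#' @param bvecs 3 x n matrix of gradient directions (columns).
#' @return an object of class `gradient_scheme`.
#' @export
gradient_scheme <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L)
    stop("bvecs must be a 3 x n matrix (FSL dialect)")
  if (ncol(bvecs) != length(bvals))
    stop(sprintf("bvals (%d) and bvecs (%d columns) differ in length",
                 length(bvals), ncol(bvecs)))
  if (any(bvals < 0)) stop("negative b-value")
  nrm <- sqrt(colSums(bvecs^2))
  dw <- bvals > 0
  if (any(abs(nrm[dw] - 1) > 1e-6))
    stop("b > 0 gradient direction with non-unit norm (tolerance 1e-6)")
  if (any(nrm[!dw] > 1e-6))
    stop("b = 0 volume with non-zero gradient direction")
  structure(list(bvals = bvals, bvecs = bvecs), class = "gradient_scheme")
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf("<gradient_scheme> %d volumes: %d b=0, %d diffusion-weighted (b = %s)\n",
              n_volumes(x), sum(x$bvals == 0), sum(x$bvals > 0),
              paste(unique(x$bvals[x$bvals > 0]), collapse = ", ")))
  invisible(x)
}

#' Number of volumes in a gradient scheme
#' @param scheme a `gradient_scheme`.
#' @export
n_volumes <- function(scheme) length(scheme$bvals)

# minimal pairwise angle (degrees) between direction axes, antipodally
# symmetric: the quantity maximised by electrostatic-repulsion designs
#' Minimal pairwise angle of a direction set
#'
#' Smallest angle (degrees) between any two distinct gradient axes, treating
#' directions as axes (v and -v identical).
#' @param bvecs 3 x n matrix of unit directions.
#' @export
min_pairwise_angle <- function(bvecs) {
  g <- abs(crossprod(bvecs))
  diag(g) <- -Inf
  acos(min(1, max(g))) * 180 / pi
}

#' Generate an approximately uniform diffusion gradient scheme
#'
#' Places `n_directions` unit vectors approximately uniformly on the
#' half-sphere by electrostatic-repulsion refinement of a random start: each
#' direction is repelled by every other direction and its antipode with an
#' inverse-square Coulomb force, projected onto the sphere tangent, with a
#' decaying step size. The result is deterministic given `seed`.
#'
#' @param n_directions number of diffusion-weighted directions (>= 6; the
#'   tensor has 6 independent elements).
#' @param b_value diffusion weighting in s/mm^2 for the weighted volumes.
#' @param n_b0 number of unweighted (b = 0) volumes, placed first.
#' @param seed integer seed for the random initialisation.
#' @param n_starts random restarts; the lowest-energy solution is kept.
#' @return a [gradient_scheme()] of `n_b0 + n_directions` volumes.
#' @export
make_gradient_scheme <- function(n_directions, b_value = 1500, n_b0 = 10,
                                 seed = 1L, n_starts = 4L) {
  if (n_directions < 6)
    stop("at least 6 directions are required (tensor under-determined)")
  if (n_b0 < 0) stop("n_b0 must be >= 0")
  best <- NULL
  for (s in seq_len(n_starts)) {
    X0 <- with_seed(seed + (s - 1L) * 101L, {
      x <- matrix(stats::rnorm(3 * n_directions), nrow = 3)
      x / rep(sqrt(colSums(x^2)), each = 3)
    })
    fit <- repel_directions(X0)
    if (is.null(best) || fit$energy < best$energy) best <- fit
  }
  bvals <- c(rep(0, n_b0), rep(b_value, n_directions))
  bvecs <- cbind(matrix(0, 3, n_b0), best$X)
  out <- gradient_scheme(bvals, bvecs)
  attr(out, "seed") <- as.integer(seed)   # lets configs regenerate the set
  out
}

# Minimise the antipodally symmetric Coulomb energy
#   E = sum_{i<j} 1/|x_i - x_j| + 1/|x_i + x_j|
# over spherical coordinates with BFGS and an analytic gradient.
repel_directions <- function(X0) {
  n <- ncol(X0)
  eg <- function(par, want) {
    th <- par[1:n]; ph <- par[(n + 1):(2 * n)]
    st <- sin(th); ct <- cos(th)
    X <- rbind(st * cos(ph), st * sin(ph), ct)
    C <- crossprod(X)
    Dm <- sqrt(pmax(2 - 2 * C, 0))
    Dp <- sqrt(2 + 2 * C)
    if (want == "E") {
      iu <- upper.tri(C)
      return(sum(1 / Dm[iu]) + sum(1 / Dp[iu]))
    }
    Am <- 1 / Dm^3; diag(Am) <- 0
    Ap <- 1 / Dp^3
    Gx <- -(X * rep(colSums(Am), each = 3) - X %*% Am) -
      (X * rep(colSums(Ap), each = 3) + X %*% Ap)
    dth <- rbind(ct * cos(ph), ct * sin(ph), -st)
    dph <- rbind(-st * sin(ph), st * cos(ph), 0 * st)
    c(colSums(Gx * dth), colSums(Gx * dph))
  }
  par0 <- c(acos(pmin(1, pmax(-1, X0[3, ]))), atan2(X0[2, ], X0[1, ]))
  opt <- stats::optim(par0, fn = function(p) eg(p, "E"),
                      gr = function(p) eg(p, "g"), method = "BFGS",
                      control = list(maxit = 500L, reltol = 1e-14))
  th <- opt$par[1:n]; ph <- opt$par[(n + 1):(2 * n)]
  list(X = rbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th)),
       energy = opt$value)
}
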