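#' Per-voxel diffusion tensor field
#'
#' Stores the 6 unique elements of the symmetric tensor per voxel (order
#' Dxx, Dyy, Dzz, Dxy, Dxz, Dyz; mm^2/s) together with the fitted baseline
#' S0, a validity flag, and (for the nonlinear fit) a convergence flag.
#'
#' @param D n_voxel x 6 matrix of tensor elements.
#' @param S0 baseline signal per voxel.
#' @param dims grid dimensions.
#' @param affine voxel-to-world transform.
#' @param valid logical per voxel.
#' @param converged logical per voxel (`NA` for linear fits).
#' @export
tensor_field_from_matrix <- function(D, S0, dims, affine,
                                     valid = rep(TRUE, nrow(D)),
                                     converged = rep(NA, nrow(D))) {
  stopifnot(ncol(D) == 6L, nrow(D) == prod(dims))
  structure(list(D = D, S0 = S0, dims = as.integer(dims), affine = affine,
                 valid = valid, converged = converged),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("<tensor_field> %s grid, %d/%d valid voxels\n",
              paste(x$dims, collapse = "x"), sum(x$valid), length(x$valid)))
  invisible(x)
}

# eigen-decomposition of every valid voxel; values descending
tensor_eigen <- function(tf, vectors = FALSE) {
  nv <- nrow(tf$D)
  vals <- matrix(NA_real_, nv, 3)
  vecs <- if (vectors) matrix(NA_real_, nv, 3) else NULL
  for (v in which(tf$valid)) {
    d <- tf$D[v, ]
    M <- matrix(c(d[1], d[4], d[5],
                  d[4], d[2], d[6],
                  d[5], d[6], d[3]), 3, 3)
    e <- eigen(M, symmetric = TRUE)
    vals[v, ] <- e$values
    if (vectors) vecs[v, ] <- e$vectors[, 1]
  }
  list(values = vals, vectors = vecs)
}

# log-linear design: log S = log S0 - b g^T D g, row per volume
tensor_design <- function(scheme) {
  b <- scheme$bvals
  g <- scheme$bvecs
  cbind(1,
        -b * g[1, ]^2, -b * g[2, ]^2, -b * g[3, ]^2,
        -2 * b * g[1, ] * g[2, ], -2 * b * g[1, ] * g[3, ],
        -2 * b * g[2, ] * g[3, ])
}

check_scheme_for_fit <- function(scheme) {
  if (sum(scheme$bvals == 0) < 1L)
    stop("tensor fitting needs at least one b = 0 volume")
  dirs <- scheme$bvecs[, scheme$bvals > 0, drop = FALSE]
  if (nrow(unique(t(round(dirs, 8)))) < 6L)
    stop("tensor fitting needs at least 6 distinct b > 0 directions")
}

#' Log-linear (least squares) diffusion tensor fit
#'
#' Ordinary least squares on \eqn{\log S = \log S_0 - b g^T D g} per masked
#' voxel. Non-positive samples are excluded voxel-wise; a voxel with fewer
#' than 7 usable samples is flagged invalid.
#'
#' @param dwi 4-D [image_volume()] with attached scheme.
#' @param scheme optional [gradient_scheme()] overriding `dwi$scheme`.
#' @param mask [mask_volume()] of voxels to fit.
#' @return a `tensor_field`.
#' @export
fit_tensor_lls <- function(dwi, scheme = NULL, mask = NULL) {
  if (is.null(scheme)) scheme <- dwi$scheme
  if (is.null(scheme)) stop("no gradient scheme supplied")
  check_scheme_for_fit(scheme)
  dm <- dim(dwi$data)[1:3]
  nv <- prod(dm)
  if (is.null(mask)) mask <- mask_volume(array(1L, dm), dwi$affine)
  X <- tensor_design(scheme)
  Y <- matrix(dwi$data, nv, n_volumes(scheme))   # voxel x volume
  sel <- which(as.logical(mask$data))
  D <- matrix(NA_real_, nv, 6)
  S0 <- rep(NA_real_, nv)
  valid <- rep(FALSE, nv)

  ok_all <- sel[rowSums(Y[sel, , drop = FALSE] <= 0) == 0L]
  if (length(ok_all)) {
    beta <- qr.coef(qr(X), t(log(Y[ok_all, , drop = FALSE])))
    S0[ok_all] <- exp(beta[1, ])
    D[ok_all, ] <- t(beta[-1, , drop = FALSE])
    valid[ok_all] <- TRUE
  }
  partial <- setdiff(sel, ok_all)
  for (v in partial) {
    use <- Y[v, ] > 0
    if (sum(use) < 7L || qr(X[use, , drop = FALSE])$rank < 7L) next
    beta <- qr.coef(qr(X[use, , drop = FALSE]), log(Y[v, use]))
    S0[v] <- exp(beta[1])
    D[v, ] <- beta[-1]
    valid[v] <- TRUE
  }
  tensor_field_from_matrix(D, S0, dm, dwi$affine, valid)
}

#' Nonlinear least-squares diffusion tensor fit
#'
#' Minimises \eqn{\sum_i (S_i - S_0 e^{-b_i g_i^T D g_i})^2} per voxel with
#' damped Gauss-Newton (Levenberg-Marquardt) steps and an analytic Jacobian,
#' initialised from the log-linear fit. Voxels that fail to converge within
#' `max_iter` iterations fall back to the initial estimate and are flagged.
#'
#' @inheritParams fit_tensor_lls
#' @param init optional `tensor_field` used as starting point (defaults to
#'   [fit_tensor_lls()]).
#' @param max_iter iteration cap (default 100).
#' @param ftol objective tolerance (default 1e-10).
#' @export
fit_tensor_nls <- function(dwi, scheme = NULL, mask = NULL, init = NULL,
                           max_iter = 100L, ftol = 1e-10) {
  if (is.null(scheme)) scheme <- dwi$scheme
  if (is.null(scheme)) stop("no gradient scheme supplied")
  check_scheme_for_fit(scheme)
  if (is.null(init)) init <- fit_tensor_lls(dwi, scheme, mask)
  dm <- dim(dwi$data)[1:3]
  nv <- prod(dm)
  if (is.null(mask)) mask <- mask_volume(array(1L, dm), dwi$affine)
  Xd <- tensor_design(scheme)[, -1, drop = FALSE]
  Y <- matrix(dwi$data, nv, n_volumes(scheme))
  D <- init$D; S0 <- init$S0
  valid <- init$valid & as.logical(mask$data)
  converged <- rep(NA, nv)
  for (v in which(valid)) {
    y <- Y[v, ]
    th0 <- c(log(max(S0[v], 1e-12)), D[v, ])
    fit <- minpack.lm::nls.lm(
      par = th0,
      fn = function(th) y - exp(th[1] + drop(Xd %*% th[-1])),
      jac = function(th) {
        mhat <- exp(th[1] + drop(Xd %*% th[-1]))
        -mhat * cbind(1, Xd)
      },
      control = minpack.lm::nls.lm.control(
        maxiter = max_iter, ftol = ftol, ptol = 1e-12))
    if (fit$info %in% 1:4) {
      S0[v] <- exp(fit$par[1])
      D[v, ] <- fit$par[-1]
      converged[v] <- TRUE
    } else {
      converged[v] <- FALSE       # keep the initial (log-linear) estimate
    }
  }
  tensor_field_from_matrix(D, S0, dm, dwi$affine, valid, converged)
}

#' Scalar indices from sorted eigenvalues
#'
#' Standard definitions: MD = (l1+l2+l3)/3, AD = l1, RD = (l2+l3)/2,
#' FA = sqrt(3/2) * sqrt(sum((l - MD)^2)) / sqrt(sum(l^2)). Eigenvalues are
#' clamped below at 1e-12 mm^2/s first, which keeps FA within [0,1]; an
#' all-zero tensor gets FA = 0 by convention.
#'
#' @param lambda n x 3 matrix of eigenvalues (any order).
#' @return data frame with columns FA, MD, RD, AD.
#' @export
diffusion_scalars <- function(lambda) {
  lambda <- matrix(lambda, ncol = 3)
  lambda <- t(apply(lambda, 1, sort, decreasing = TRUE))
  lambda[lambda < 1e-12] <- 1e-12
  md <- rowMeans(lambda)
  num <- sqrt(rowSums((lambda - md)^2))
  den <- sqrt(rowSums(lambda^2))
  fa <- ifelse(den > 0, sqrt(1.5) * num / den, 0)
  fa[num < 1e-300] <- 0
  data.frame(FA = pmin(fa, 1), MD = md, RD = (lambda[, 2] + lambda[, 3]) / 2,
             AD = lambda[, 1])
}

#' DTI scalar maps (FA, MD, RD, AD) from a tensor field
#'
#' @param tf a `tensor_field`.
#' @return named list of four [scalar_map()]s; invalid voxels are 0.
#' @export
tensor_scalars <- function(tf) {
  eg <- tensor_eigen(tf)
  nv <- nrow(tf$D)
  sc <- matrix(0, nv, 4, dimnames = list(NULL, c("FA", "MD", "RD", "AD")))
  ok <- which(tf$valid)
  if (length(ok))
    sc[ok, ] <- as.matrix(diffusion_scalars(eg$values[ok, , drop = FALSE]))
  out <- lapply(colnames(sc), function(k) {
    scalar_map(array(sc[, k], tf$dims), tf$affine, kind = k,
               units = if (k == "FA") "dimensionless" else "mm^2/s")
  })
  names(out) <- colnames(sc)
  out
}

#' Principal diffusion direction and FA per voxel
#'
#' @param tf a `tensor_field`.
#' @return list with `direction` (n x 3 unit vectors, NA where invalid) and
#'   `fa` (vector).
#' @export
principal_direction <- function(tf) {
  eg <- tensor_eigen(tf, vectors = TRUE)
  nv <- nrow(tf$D)
  fa <- rep(NA_real_, nv)
  ok <- which(tf$valid)
  if (length(ok))
    fa[ok] <- diffusion_scalars(eg$values[ok, , drop = FALSE])$FA
  list(direction = eg$vectors, fa = fa)
}
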