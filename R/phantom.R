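#' Tube tract geometry
#'
#' A tract is a polyline in world mm swept by a tube of fixed radius; every
#' voxel whose centre lies within `radius` of the polyline belongs to the
#' tract, with the fibre orientation given by the local tangent.
#'
#' @param points n x 3 matrix of polyline vertices (world mm), n >= 2.
#' @param radius tube radius in mm.
#' @param lambda_par,lambda_perp compartment eigenvalues (mm^2/s).
#' @param fraction total fibre volume fraction carried by the tract.
#' @export
tract_tube <- function(points, radius, lambda_par = 1.7e-3,
                       lambda_perp = 0.3e-3, fraction = 1) {
  points <- as.matrix(points)
  if (ncol(points) != 3L || nrow(points) < 2L)
    stop("tract polyline needs an n x 3 matrix with n >= 2")
  if (radius <= 0) stop("radius must be positive")
  structure(list(points = points, radius = radius, lambda_par = lambda_par,
                 lambda_perp = lambda_perp, fraction = fraction),
            class = "tract_tube")
}

#' @rdname tract_tube
#' @param from,to straight tube endpoints (world mm).
#' @export
straight_tube <- function(from, to, radius, ...) {
  tract_tube(rbind(from, to), radius, ...)
}

#' Phantom specification
#'
#' Describes a synthetic DWI subject: the grid, the acquisition, the tube
#' tracts, the isotropic background, an optional spherical "lesion" that
#' multiplies the radial diffusivity (lambda_perp) of fibre compartments
#' inside it by `rd_multiplier >= 1` (producing the FA-down / RD-up / MD-up /
#' AD-unchanged signature of a demyelinating-type insult), and the Rician
#' noise level.
#'
#' @param grid_dim integer 3-vector of voxel counts (default 20^3).
#' @param voxel_size voxel edge length(s) in mm (default 2 mm isotropic).
#' @param tracts list of [tract_tube()]s; must lie inside the grid.
#' @param scheme a [gradient_scheme()]; defaults to 61 directions at
#'   b = 1500 s/mm^2 plus 10 b = 0 volumes.
#' @param background_adc isotropic background diffusivity (mm^2/s).
#' @param lesion `NULL` or `list(center = <world mm>, radius = <mm>,
#'   rd_multiplier = f >= 1)`; `f = 1` means no lesion.
#' @param S0 baseline signal.
#' @param sigma Rician noise sd; the default `S0/20` gives SNR 20 on b = 0,
#'   typical for b = 1500 acquisitions.
#' @export
phantom_spec <- function(grid_dim = c(20L, 20L, 20L), voxel_size = 2,
                         tracts = list(), scheme = NULL,
                         background_adc = 0.8e-3, lesion = NULL,
                         S0 = 100, sigma = S0 / 20) {
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (sigma < 0) stop("sigma must be >= 0")
  if (!is.null(lesion)) {
    stopifnot(all(c("center", "radius", "rd_multiplier") %in% names(lesion)))
    if (lesion$rd_multiplier < 1)
      stop("lesion rd_multiplier must be >= 1")
  }
  if (is.null(scheme)) scheme <- make_gradient_scheme(61, 1500, 10, seed = 42)
  affine <- diag(c(voxel_size, 1))
  extent_lo <- -0.5 * voxel_size
  extent_hi <- (grid_dim - 0.5) * voxel_size
  for (tr in tracts) {
    stopifnot(inherits(tr, "tract_tube"))
    if (any(t(tr$points) < extent_lo - 1e-9) ||
        any(t(tr$points) > extent_hi + 1e-9))
      stop("tract polyline extends outside the grid")
  }
  structure(list(grid_dim = as.integer(grid_dim), voxel_size = voxel_size,
                 affine = affine, tracts = tracts, scheme = scheme,
                 background_adc = background_adc, lesion = lesion,
                 S0 = S0, sigma = sigma),
            class = "phantom_spec")
}

# assign tube membership: for each voxel centre, nearest point on a finely
# resampled polyline and the tangent there
tube_membership <- function(centres, tube, voxel_size) {
  P <- tube$points
  seg <- diff(P)
  lens <- sqrt(rowSums(seg^2))
  step <- min(voxel_size) / 4
  samp <- list(); tang <- list()
  for (s in seq_len(nrow(seg))) {
    n <- max(2L, ceiling(lens[s] / step) + 1L)
    tt <- seq(0, 1, length.out = n)
    samp[[s]] <- cbind(P[s, 1] + tt * seg[s, 1], P[s, 2] + tt * seg[s, 2],
                       P[s, 3] + tt * seg[s, 3])
    tang[[s]] <- matrix(seg[s, ] / lens[s], n, 3, byrow = TRUE)
  }
  S <- do.call(rbind, samp)
  Tg <- do.call(rbind, tang)
  # squared distances voxel-centres x samples, blocked to bound memory
  n_c <- nrow(centres)
  nearest <- integer(n_c); d2min <- numeric(n_c)
  block <- 4096L
  for (b0 in seq(1L, n_c, by = block)) {
    idx <- b0:min(n_c, b0 + block - 1L)
    d2 <- outer(rowSums(centres[idx, , drop = FALSE]^2), rowSums(S^2), "+") -
      2 * centres[idx, , drop = FALSE] %*% t(S)
    nearest[idx] <- max.col(-d2, ties.method = "first")
    d2min[idx] <- d2[cbind(seq_along(idx), nearest[idx])]
  }
  inside <- d2min <= tube$radius^2 + 1e-12
  list(inside = inside, tangent = Tg[nearest, , drop = FALSE])
}

#' Build a DWI phantom with known ground truth
#'
#' Voxels inside a single tube carry one fibre compartment along the local
#' tube tangent; voxels inside several tubes carry one compartment per tube
#' with the tract fraction split equally (crossing-fibre voxels); all other
#' voxels are isotropic background. Lesion voxels have their compartments'
#' lambda_perp multiplied by the lesion's `rd_multiplier`. The returned
#' ground truth is the mixture-weighted mean tensor per voxel (equal to the
#' compartment tensor wherever a single full-fraction compartment lives),
#' plus the compartment table itself for orientation-model construction.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed for the Rician noise.
#' @return a list with elements `dwi` ([image_volume()] with scheme),
#'   `mask` (brain mask covering the grid), `truth` (a `tensor_field` of
#'   ground-truth tensors), `compartments` (per-voxel list), `tract_masks`,
#'   `lesion_mask` and `spec`.
#' @export
build_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$grid_dim
  nv <- prod(dm)
  ijk <- as.matrix(expand.grid(i = 0:(dm[1] - 1), j = 0:(dm[2] - 1),
                               k = 0:(dm[3] - 1)))
  centres <- voxel_to_world(spec$affine, ijk)

  # per-voxel compartment table
  n_tr <- length(spec$tracts)
  member <- vector("list", n_tr)
  for (t in seq_len(n_tr))
    member[[t]] <- tube_membership(centres, spec$tracts[[t]], spec$voxel_size)
  n_in <- if (n_tr) Reduce(`+`, lapply(member, function(m) m$inside))
          else integer(nv)

  lesion_vox <- rep(FALSE, nv)
  if (!is.null(spec$lesion)) {
    d2 <- rowSums((centres - matrix(spec$lesion$center, nv, 3,
                                    byrow = TRUE))^2)
    lesion_vox <- d2 <= spec$lesion$radius^2
  }

  # flatten compartments for vectorised signal synthesis
  vox_id <- integer(0); orient <- NULL
  lpar <- numeric(0); lperp <- numeric(0); frac <- numeric(0)
  for (t in seq_len(n_tr)) {
    m <- member[[t]]
    sel <- which(m$inside)
    if (!length(sel)) next
    tr <- spec$tracts[[t]]
    lp <- rep(tr$lambda_perp, length(sel))
    f_mult <- if (!is.null(spec$lesion)) spec$lesion$rd_multiplier else 1
    lp[lesion_vox[sel]] <- lp[lesion_vox[sel]] * f_mult
    lp <- pmin(lp, tr$lambda_par)   # lesion cannot exceed lambda_par
    vox_id <- c(vox_id, sel)
    orient <- rbind(orient, m$tangent[sel, , drop = FALSE])
    lpar <- c(lpar, rep(tr$lambda_par, length(sel)))
    lperp <- c(lperp, lp)
    frac <- c(frac, tr$fraction / n_in[sel])
  }

  b <- spec$scheme$bvals
  G <- spec$scheme$bvecs
  n_vol <- n_volumes(spec$scheme)
  S <- matrix(exp(-outer(b, rep(spec$background_adc, nv))), n_vol, nv)
  if (length(vox_id)) {
    # replace the isotropic remainder voxel-by-voxel where fibres live
    ftot <- rowsum(frac, vox_id)
    fv <- as.integer(rownames(ftot))
    S[, fv] <- exp(-b %o% rep(spec$background_adc, length(fv))) *
      rep(1 - ftot[, 1], each = n_vol)
    Q <- (crossprod(G, t(orient)))^2          # n_vol x n_entries
    adc <- rep(lperp, each = n_vol) + rep(lpar - lperp, each = n_vol) * Q
    att <- exp(-b * adc) * rep(frac, each = n_vol)
    for (e in seq_along(vox_id)) S[, vox_id[e]] <- S[, vox_id[e]] + att[, e]
  }
  S <- spec$S0 * S
  noisy <- add_rician_noise(S, spec$sigma, seed = seed)

  data <- array(t(noisy), dim = c(dm, n_vol))
  dwi <- image_volume(data, spec$affine, units = "signal",
                      scheme = spec$scheme)
  mask <- mask_volume(array(1L, dim = dm), spec$affine)

  # ground-truth mixture-mean tensors, lower-triangular order
  D6 <- matrix(0, nv, 6)
  iso <- spec$background_adc
  D6[, 1:3] <- iso
  if (length(vox_id)) {
    fv <- as.integer(rownames(rowsum(frac, vox_id)))
    ftot_v <- rowsum(frac, vox_id)[, 1]
    D6[fv, 1:3] <- (1 - ftot_v) * iso
    for (e in seq_along(vox_id)) {
      v <- vox_id[e]; u <- orient[e, ]
      Dc <- lperp[e] * diag(3) + (lpar[e] - lperp[e]) * tcrossprod(u)
      D6[v, ] <- D6[v, ] + frac[e] *
        c(Dc[1, 1], Dc[2, 2], Dc[3, 3], Dc[1, 2], Dc[1, 3], Dc[2, 3])
    }
  }
  truth <- tensor_field_from_matrix(D6, rep(spec$S0, nv), dm, spec$affine)

  comp_table <- list(vox_id = vox_id, orientation = orient, lambda_par = lpar,
                     lambda_perp = lperp, fraction = frac)
  tract_masks <- lapply(seq_len(n_tr), function(t) {
    m <- array(0L, dm); m[member[[t]]$inside] <- 1L
    if (!any(m == 1L)) NULL else mask_volume(m, spec$affine)
  })
  lesion_mask <- if (any(lesion_vox)) {
    m <- array(0L, dm); m[lesion_vox] <- 1L
    mask_volume(m, spec$affine)
  } else NULL

  list(dwi = dwi, mask = mask, truth = truth, compartments = comp_table,
       tract_masks = tract_masks, lesion_mask = lesion_mask, spec = spec)
}
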