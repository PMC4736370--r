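#' Spatial image volume
#'
#' A minimal spatial data model shared by every stage of the pipeline: a 3-D
#' scalar lattice or 4-D intensity lattice together with a 4x4 voxel-to-world
#' affine. Voxel indices are 0-based, so the world position of voxel
#' \eqn{(i,j,k)} is \eqn{A [i,j,k,1]^T} in mm. Streamlines and all tracking
#' geometry live in world mm, which keeps them independent of grid resolution.
#'
#' @param data numeric array, 3-D or 4-D.
#' @param affine invertible 4x4 voxel-index-to-world-mm matrix. Defaults to
#'   identity spacing (1 mm isotropic, corner origin).
#' @param units free-text intensity units.
#' @param scheme optional [gradient_scheme()]; if supplied, the length of the
#'   4th data axis must equal the number of scheme volumes.
#' @return an object of class `image_volume`.
#' @export
image_volume <- function(data, affine = diag(4), units = "a.u.",
                         scheme = NULL) {
  data <- as.array(data)
  nd <- length(dim(data))
  if (nd != 3L && nd != 4L)
    stop("image data must be a 3-D or 4-D array")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("affine must be 4x4")
  if (abs(det(affine)) < .Machine$double.eps)
    stop("affine must be invertible")
  if (!is.null(scheme)) {
    stopifnot(inherits(scheme, "gradient_scheme"))
    if (nd != 4L || dim(data)[4] != n_volumes(scheme))
      stop(sprintf(
        "4th image axis (%s) does not match gradient scheme length (%d)",
        if (nd == 4L) dim(data)[4] else "absent", n_volumes(scheme)))
  }
  structure(list(data = data, affine = affine, units = units,
                 scheme = scheme),
            class = "image_volume")
}

#' Binary mask volume
#'
#' @param data 3-D array coercible to 0/1; must contain at least one 1.
#' @inheritParams image_volume
#' @return an object of class `mask_volume` (also an `image_volume`).
#' @export
mask_volume <- function(data, affine = diag(4)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("mask must be 3-D")
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1))) stop("mask values must be 0/1")
  if (!any(data == 1)) stop("mask is empty")
  storage.mode(data) <- "integer"
  v <- image_volume(data, affine, units = "binary")
  class(v) <- c("mask_volume", class(v))
  v
}

#' Scalar map (FA, MD, RD, AD or ACM lattice)
#'
#' A 3-D [image_volume()] carrying a `kind` tag. Values are defined inside the
#' mask the map was computed on and 0 elsewhere.
#'
#' @inheritParams image_volume
#' @param kind one of `"FA"`, `"MD"`, `"RD"`, `"AD"`, `"ACM"`, or another
#'   descriptive tag.
#' @export
scalar_map <- function(data, affine = diag(4), kind = "scalar",
                       units = "a.u.") {
  v <- image_volume(as.array(data), affine, units = units)
  if (length(dim(v$data)) != 3L) stop("scalar map must be 3-D")
  v$kind <- kind
  class(v) <- c("scalar_map", class(v))
  v
}

#' Voxel-index / world-mm coordinate transforms
#'
#' @param vol an `image_volume` (or its 4x4 affine).
#' @param ijk n x 3 matrix of 0-based voxel indices (may be fractional).
#' @return n x 3 matrix of world-mm points.
#' @export
voxel_to_world <- function(vol, ijk) {
  A <- if (is.matrix(vol)) vol else vol$affine
  ijk <- matrix(ijk, ncol = 3L)
  t(A %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
}

#' @rdname voxel_to_world
#' @param xyz n x 3 matrix of world-mm points.
#' @return for `world_to_voxel`, n x 3 matrix of fractional 0-based indices.
#' @export
world_to_voxel <- function(vol, xyz) {
  A <- if (is.matrix(vol)) vol else vol$affine
  xyz <- matrix(xyz, ncol = 3L)
  t(solve(A) %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %s, voxel %s mm\n",
              class(x)[1], paste(d, collapse = "x"),
              paste(signif(voxel_size(x), 4), collapse = "x")))
  invisible(x)
}

#' Voxel edge lengths in mm
#' @param vol an `image_volume` or 4x4 affine.
#' @export
voxel_size <- function(vol) {
  A <- if (is.matrix(vol)) vol else vol$affine
  sqrt(colSums(A[1:3, 1:3]^2))
}

# evaluate a seeded computation without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, globalenv())
    })
    set.seed(seed)
  }
  force(code)
}
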