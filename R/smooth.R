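#' Gaussian smoothing of a scalar map
#'
#' Separable isotropic Gaussian convolution with kernel standard deviation
#' sigma = fwhm / (2 sqrt(2 ln 2)) per axis, expressed in mm and converted to
#' voxels through the affine. The discrete kernel is normalised to sum 1
#' (mass-conserving away from boundaries; zero padding at the edges).
#' `fwhm_mm = 0` returns the map unchanged.
#'
#' @param map a [scalar_map()] (or any 3-D [image_volume()]).
#' @param fwhm_mm full width at half maximum in mm (>= 0).
#' @export
smooth_map <- function(map, fwhm_mm) {
  if (fwhm_mm < 0) stop("fwhm must be >= 0")
  if (fwhm_mm == 0) return(map)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  vs <- voxel_size(map)
  arr <- map$data
  for (ax in 1:3) {
    sig <- sigma_mm / vs[ax]
    r <- max(1L, ceiling(4 * sig))
    k <- stats::dnorm(-r:r, sd = sig)
    k <- k / sum(k)
    arr <- conv_axis(arr, k, ax)
  }
  out <- map
  out$data <- arr
  out
}

# 1-D convolution along one axis via a banded matrix, zero padding
conv_axis <- function(arr, k, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  n <- d[axis]
  r <- (length(k) - 1L) / 2L
  K <- matrix(0, n, n)
  for (o in -r:r) {
    i <- seq_len(n)
    j <- i + o
    ok <- j >= 1 & j <= n
    K[cbind(i[ok], j[ok])] <- k[o + r + 1L]
  }
  m <- K %*% matrix(a, n)
  aperm(array(m, d[perm]), order(perm))
}
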