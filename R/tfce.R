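#' Threshold-free cluster enhancement
#'
#' Discrete threshold integration
#' \deqn{TFCE(v) = \sum_{h = dh, 2dh, \dots}^{stat(v)} e_h(v)^E \, h^H \, dh}
#' where \eqn{e_h(v)} is the extent (voxel count) of the connected component
#' of the supra-threshold set containing v at height h. Defaults E = 0.5,
#' H = 2, 26-connectivity and 100 integration steps (dh = max(stat)/100).
#' Only positive values are enhanced; for two-tailed use the negated map is
#' enhanced separately (see `two_sided`).
#'
#' @param stat_map 3-D numeric array (or [scalar_map()]) of statistics.
#' @param E extent exponent.
#' @param H height exponent.
#' @param dh integration step; default `max(stat)/100` (must be > 0).
#' @param connectivity 6, 18 or 26.
#' @param two_sided if TRUE, returns `tfce(max(map,0)) - tfce(max(-map,0))`.
#' @return array of the same shape with non-negative enhanced values (signed
#'   when `two_sided`).
#' @export
tfce <- function(stat_map, E = 0.5, H = 2, dh = NULL, connectivity = 26L,
                 two_sided = FALSE) {
  arr <- if (inherits(stat_map, "image_volume")) stat_map$data else stat_map
  stopifnot(length(dim(arr)) == 3L)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  if (!is.null(dh) && dh <= 0) stop("dh must be positive")
  pos <- pmax(arr, 0)
  enh <- tfce_half(pos, E, H, dh, connectivity)
  if (two_sided) {
    neg <- pmax(-arr, 0)
    enh <- enh - tfce_half(neg, E, H, dh, connectivity)
  }
  enh
}

tfce_half <- function(pos, E, H, dh, connectivity) {
  mx <- max(pos)
  if (mx <= 0) return(array(0, dim(pos)))
  step <- if (is.null(dh)) mx / 100 else dh
  out <- cpp_tfce(as.numeric(pos), as.integer(dim(pos)), E, H, step,
                  as.integer(connectivity))
  array(out, dim(pos))
}
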