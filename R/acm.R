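#' Anatomical Connectivity Map from a streamline set
#'
#' Counts, per voxel of `mask`, the number of streamlines that traverse it.
#' Counting is unique-visitation: a streamline that passes through (or loops
#' back into) a voxel increments it at most once. Traversal is determined by
#' sampling each streamline segment at intervals of at most half the smallest
#' voxel edge; an exact 3-D line--voxel intersection walk is available with
#' `method = "exact"` (slower; used as an oracle).
#'
#' @param streamlines a [streamline_set()] (world mm). If it carries an
#'   `affine` attribute it must match the mask affine.
#' @param mask a [mask_volume()]; voxels outside it are ignored.
#' @param method `"sampled"` (default) or `"exact"`.
#' @return an `acm_map`: a [scalar_map()] of kind `"ACM"` with integer counts
#'   and a `provenance` attribute.
#' @export
acm_from_streamlines <- function(streamlines, mask,
                                 method = c("sampled", "exact")) {
  method <- match.arg(method)
  saff <- attr(streamlines, "affine")
  if (!is.null(saff) && max(abs(saff - mask$affine)) > 1e-6)
    stop("streamline reference affine does not match the mask affine")
  dims <- dim(mask$data)
  if (method == "sampled") {
    counts <- cpp_count_visits(unclass(streamlines), solve(mask$affine),
                               as.integer(dims), as.integer(mask$data),
                               min(voxel_size(mask$affine)) / 2)
    counts <- array(counts, dims)
  } else {
    counts <- array(0L, dims)
    for (s in unclass(streamlines)) {
      vox <- exact_traversed_voxels(s, mask$affine, dims)
      if (nrow(vox)) {
        lin <- vox[, 1] + dims[1] * (vox[, 2] + dims[2] * vox[, 3]) + 1L
        lin <- lin[mask$data[lin] == 1L]
        counts[unique(lin)] <- counts[unique(lin)] + 1L
      }
    }
  }
  out <- scalar_map(counts, mask$affine, kind = "ACM", units = "streamlines")
  attr(out, "provenance") <- attr(streamlines, "provenance")
  class(out) <- c("acm_map", class(out))
  out
}

# exact voxel traversal of one polyline: walk each segment in continuous
# voxel coordinates, crossing half-integer planes (voxel boundaries) in order
exact_traversed_voxels <- function(points, affine, dims) {
  idx <- world_to_voxel(affine, points)
  out <- list()
  # nearest-voxel convention matching the tracker: halves round away from 0
  round <- function(x) sign(x) * floor(abs(x) + 0.5)
  cur <- round(idx[1, ])
  add <- function(v) {
    if (all(v >= 0) && all(v < dims)) out[[length(out) + 1L]] <<- v
  }
  add(cur)
  if (nrow(idx) > 1) for (s in 1:(nrow(idx) - 1)) {
    a <- idx[s, ]; b <- idx[s + 1, ]
    d <- b - a
    # parametric crossings of the planes x_j = n + 1/2 between a and b
    ts <- numeric(0)
    for (j in 1:3) if (abs(d[j]) > 1e-12) {
      lo <- min(a[j], b[j]); hi <- max(a[j], b[j])
      planes <- seq(floor(lo - 0.5) + 0.5, ceiling(hi + 0.5) - 0.5, by = 1)
      planes <- planes[planes > lo & planes < hi]
      ts <- c(ts, (planes - a[j]) / d[j])
    }
    for (t in sort(unique(ts))) {
      p <- a + (t + 1e-9) * d       # just past the boundary
      add(round(p))
    }
    add(round(b))
  }
  if (!length(out)) return(matrix(integer(), 0, 3))
  m <- do.call(rbind, out)
  storage.mode(m) <- "integer"
  m
}

#' One-shot ACM pipeline
#'
#' Tensor fit, orientation model, whole-brain tracking and unique-visitation
#' counting in one reproducible call. Tracking and counting are fused so the
#' full streamline set is never materialised. Seed and count masks are
#' separate arguments (they may legitimately differ, e.g. seeding from a
#' grey+white mask while counting in white matter only); by default both are
#' `mask`.
#'
#' @param dwi 4-D [image_volume()] with scheme.
#' @param mask seed [mask_volume()].
#' @param params a [tracking_params()].
#' @param scheme optional scheme override.
#' @param count_mask optional counting mask (default: `mask`).
#' @param model optional pre-built [orientation_model()]; when supplied the
#'   tensor stage is skipped.
#' @param fit_method `"lls"` or `"nls"` for the tensor stage.
#' @param kappa_max concentration scale of the FA-to-kappa rule.
#' @return an `acm_map`.
#' @export
acm_pipeline <- function(dwi, mask, params = tracking_params(),
                         scheme = NULL, count_mask = NULL, model = NULL,
                         fit_method = c("lls", "nls"), kappa_max = 200) {
  fit_method <- match.arg(fit_method)
  if (is.null(model)) {
    tf <- if (fit_method == "lls") fit_tensor_lls(dwi, scheme, mask)
          else fit_tensor_nls(dwi, scheme, mask)
    model <- orientation_model_from_tensor(tf, kappa_max = kappa_max)
  }
  if (is.null(count_mask)) count_mask <- mask
  res <- whole_brain_tracking(model, mask, params, keep_streamlines = FALSE,
                              count_mask = count_mask)
  out <- scalar_map(res$counts, mask$affine, kind = "ACM",
                    units = "streamlines")
  attr(out, "provenance") <- res$provenance
  class(out) <- c("acm_map", class(out))
  out
}
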