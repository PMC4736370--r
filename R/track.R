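#' Probabilistic tracking parameters
#'
#' Defaults follow common whole-brain probabilistic tractography practice:
#' 500 streamlines initiated per seed voxel, up to 2000 Euler steps per
#' direction, 0.5 mm step length, and a curvature threshold of 0.2 expressed
#' as the minimum cosine between successive steps (about 78.5 degrees).
#'
#' @param n_per_voxel streamlines initiated per masked voxel (>= 1).
#' @param max_steps step cap per tracking direction.
#' @param step_length Euler step in mm (> 0).
#' @param curvature_threshold minimum cosine between successive unit steps,
#'   in (0, 1); a sampled step below it terminates the streamline.
#' @param seed integer seed; per-voxel RNG streams are derived from
#'   `(seed, voxel index, streamline index)` so results are independent of
#'   iteration order.
#' @export
tracking_params <- function(n_per_voxel = 500L, max_steps = 2000L,
                            step_length = 0.5, curvature_threshold = 0.2,
                            seed = 1L) {
  if (n_per_voxel < 1) stop("n_per_voxel must be >= 1")
  if (step_length <= 0) stop("step_length must be positive")
  if (curvature_threshold <= 0 || curvature_threshold >= 1)
    stop("curvature_threshold must be in (0, 1)")
  if (max_steps < 1) stop("max_steps must be >= 1")
  structure(list(n_per_voxel = as.integer(n_per_voxel),
                 max_steps = as.integer(max_steps),
                 step_length = step_length,
                 curvature_threshold = curvature_threshold,
                 seed = as.integer(seed)),
            class = "tracking_params")
}

model_arrays <- function(model) {
  list(mu = as.numeric(model$mu), kappa = as.numeric(model$kappa),
       frac = as.numeric(model$frac), ncomp = as.integer(model$ncomp),
       dims = model$dims, K = model$K)
}

#' Track a single streamline
#'
#' Euler propagation from `seed_point` (world mm): a first direction is drawn
#' at the seed voxel, the streamline is tracked in both directions and the
#' reversed first half is concatenated with the second. Each step samples a
#' direction from the Watson model of the containing voxel, sign-aligned with
#' the previous step; the streamline terminates on leaving the mask, when the
#' direction cosine falls below the curvature threshold, or at `max_steps`
#' per direction.
#'
#' @param model an [orientation_model()].
#' @param mask a [mask_volume()].
#' @param seed_point world-mm 3-vector (must fall inside the mask).
#' @param params a [tracking_params()].
#' @param stream_key index distinguishing repeated draws from one seed.
#' @return an n x 3 matrix of world-mm points.
#' @export
track_streamline <- function(model, mask, seed_point, params = tracking_params(),
                             stream_key = 0L) {
  ma <- model_arrays(model)
  ijk <- round(world_to_voxel(model$affine, seed_point))
  vlin <- ijk[1] + model$dims[1] * (ijk[2] + model$dims[2] * ijk[3])
  cpp_track_one(ma$mu, ma$kappa, ma$frac, ma$ncomp, ma$dims, ma$K,
                as.integer(mask$data), solve(model$affine),
                as.numeric(seed_point), params$max_steps, params$step_length,
                params$curvature_threshold, params$seed, vlin, stream_key)
}

#' Whole-brain tractography
#'
#' Initiates exactly `n_per_voxel` streamlines from the centre of every
#' masked voxel. Per-voxel RNG streams are derived from
#' `(seed, voxel index, streamline index)`, so the result is bit-identical
#' across runs and iteration orders given one seed.
#'
#' @inheritParams track_streamline
#' @param keep_streamlines return the streamlines themselves (set `FALSE`
#'   when only visit counts are needed; see [acm_pipeline()]).
#' @param count_mask optional [mask_volume()] in which to count unique
#'   streamline visits while tracking (avoids materialising large sets).
#' @return a [streamline_set()] with attributes `affine` and `provenance`,
#'   or (when `keep_streamlines = FALSE`) a list with the visit-count array.
#' @export
whole_brain_tracking <- function(model, mask, params = tracking_params(),
                                 keep_streamlines = TRUE, count_mask = NULL) {
  if (!any(mask$data == 1L)) stop("empty seed mask")
  ma <- model_arrays(model)
  sel <- which(as.logical(mask$data)) - 1L
  dims <- model$dims
  seeds <- cbind(sel %% dims[1],
                 (sel %/% dims[1]) %% dims[2],
                 sel %/% (dims[1] * dims[2]))
  storage.mode(seeds) <- "integer"
  do_count <- !is.null(count_mask)
  cm <- if (do_count) as.integer(count_mask$data) else as.integer(mask$data)
  res <- cpp_whole_brain_track(
    ma$mu, ma$kappa, ma$frac, ma$ncomp, ma$dims, ma$K,
    as.integer(mask$data), model$affine, solve(model$affine), seeds,
    params$n_per_voxel, params$max_steps, params$step_length,
    params$curvature_threshold, params$seed, keep_streamlines, do_count, cm,
    min(voxel_size(model$affine)) / 2)
  prov <- list(params = params, n_seeds = nrow(seeds),
               n_streamlines = res$n_streamlines)
  if (keep_streamlines) {
    out <- streamline_set(res$streamlines)
    attr(out, "affine") <- model$affine
    attr(out, "provenance") <- prov
    return(out)
  }
  list(counts = array(res$acm, dims), provenance = prov)
}
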