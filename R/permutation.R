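#' Nonparametric voxelwise inference with TFCE and FWE correction
#'
#' Freedman-Lane permutation of the GLM: the nuisance covariates are
#' regressed out, the residualised data are permuted over subjects, the full
#' model is refitted, and the maximum of the (optionally TFCE-enhanced)
#' statistic over the analysis mask (or over `roi`, for small-volume
#' correction at source) forms the null distribution. Corrected p-values are
#' \deqn{p(v) = (1 + \#\{perm max \ge observed(v)\}) / (n_{perm} + 1),}
#' so the observed labelling always counts and the smallest attainable p is
#' 1/(n_perm + 1). When fewer distinct subject permutations exist than
#' `n_perm`, all of them are enumerated (with a warning).
#'
#' For one-tailed t contrasts only positive statistics are enhanced; with
#' `tail = "two.sided"` both signs are enhanced separately and the larger
#' magnitude is used.
#'
#' @param maps list of per-subject [scalar_map()]s (or an n x V matrix over
#'   mask voxels).
#' @param mask analysis [mask_volume()].
#' @param design a `cohort_design` or prebuilt [design_matrix()].
#' @param contrast contrast specification (see [parse_contrast()]).
#' @param n_perm number of permutations (>= 100).
#' @param tfce_on apply TFCE before forming the max-statistic null.
#' @param tail `"greater"` (default for t) or `"two.sided"`; ignored for F.
#' @param roi optional [mask_volume()] restricting the max-statistic null
#'   (small-volume correction at source); must lie within `mask`.
#' @param E,H,connectivity TFCE parameters (defaults 0.5, 2, 26).
#' @param seed integer RNG seed for the permutations.
#' @param keep_null keep the per-permutation enhanced null maps so that
#'   [small_volume_correct()] can be applied afterwards (default TRUE).
#' @return an object of class `stat_maps`: arrays `stat`, `enhanced`, `p_fwe`
#'   (1 outside the mask), the null maxima, and metadata.
#' @export
permutation_test <- function(maps, mask, design, contrast, n_perm = 500L,
                             tfce_on = TRUE, tail = NULL, roi = NULL,
                             E = 0.5, H = 2, connectivity = 26L, seed = 1L,
                             keep_null = TRUE) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  dm <- if (inherits(design, "design_matrix")) design else design_matrix(design)
  Y <- if (is.matrix(maps)) maps else stack_maps(maps, mask)
  n <- nrow(Y)
  stopifnot(n == nrow(dm$X))
  ct <- parse_contrast(dm, contrast)
  if (is.null(tail)) tail <- if (ct$type == "t") "greater" else NA_character_
  mask_idx <- which(mask$data == 1L)
  stopifnot(length(mask_idx) == ncol(Y))
  roi_lin <- NULL
  if (!is.null(roi)) {
    if (any(roi$data == 1L & mask$data != 1L))
      stop("roi must lie within the analysis mask")
    roi_lin <- match(which(roi$data == 1L), mask_idx)
  }

  # permutation schedule (subject relabellings); identity is the observed one
  perms <- draw_permutations(n, n_perm, seed)
  n_perm <- nrow(perms)

  # Freedman-Lane: residualise against nuisance (covariates + a mean term)
  Z <- cbind(`(intercept)` = 1, dm$X[, dm$nuisance_cols, drop = FALSE])
  Hz <- Z %*% solve(crossprod(Z), t(Z))
  fitted_z <- Hz %*% Y
  Ez <- Y - fitted_z

  dims <- dim(mask$data)
  enhance <- function(stat_vec) {
    if (!tfce_on) return(stat_vec)
    arr <- array(0, dims)
    arr[mask_idx] <- stat_vec
    if (identical(tail, "two.sided")) {
      ep <- tfce(arr, E, H, connectivity = connectivity)
      en <- tfce(-arr, E, H, connectivity = connectivity)
      pmax(ep, en)[mask_idx]
    } else {
      tfce(arr, E, H, connectivity = connectivity)[mask_idx]
    }
  }

  obs <- glm_stat(Y, dm, contrast)
  obs_enh <- enhance(obs$stat)

  null_idx <- if (is.null(roi_lin)) seq_along(mask_idx) else roi_lin
  null_max <- numeric(n_perm)
  null_enh <- if (keep_null) matrix(NA_real_, n_perm, length(mask_idx)) else NULL
  for (j in seq_len(n_perm)) {
    Yp <- fitted_z + Ez[perms[j, ], , drop = FALSE]
    st <- glm_stat(Yp, dm, contrast)$stat
    en <- enhance(st)
    null_max[j] <- max(en[null_idx])
    if (keep_null) null_enh[j, ] <- en
  }

  cmp <- if (identical(tail, "two.sided")) abs(obs_enh) else obs_enh
  p <- (1 + colSums(outer(null_max, cmp, `>=`))) / (n_perm + 1)

  stat_arr <- array(NA_real_, dims); stat_arr[mask_idx] <- obs$stat
  enh_arr <- array(NA_real_, dims); enh_arr[mask_idx] <- obs_enh
  p_arr <- array(1, dims); p_arr[mask_idx] <- p
  structure(list(stat = stat_arr, enhanced = enh_arr, p_fwe = p_arr,
                 null_max = null_max, null_enhanced = null_enh,
                 mask_idx = mask_idx, dims = dims, affine = mask$affine,
                 n_perm = n_perm, contrast = contrast, type = obs$type,
                 tail = tail, tfce_on = tfce_on,
                 roi = !is.null(roi)),
            class = "stat_maps")
}

#' @export
print.stat_maps <- function(x, ...) {
  cat(sprintf(
    "<stat_maps> %s statistic, %d permutations%s; min FWE p = %.4g, %d voxels with p < 0.05\n",
    x$type, x$n_perm, if (x$tfce_on) " with TFCE" else "",
    min(x$p_fwe[x$mask_idx]), sum(x$p_fwe[x$mask_idx] < 0.05)))
  invisible(x)
}

# subject permutation schedule: identity-free random draws, or full
# enumeration when n! <= n_perm
draw_permutations <- function(n, n_perm, seed) {
  total <- factorial(n)
  if (total <= n_perm) {
    warning(sprintf(
      "only %d distinct permutations exist; enumerating all of them",
      as.integer(total)))
    return(do.call(rbind, all_permutations(n)))
  }
  with_seed(seed, t(replicate(n_perm, sample.int(n))))
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- list()
  for (p in sub)
    for (pos in 0:(n - 1L))
      out[[length(out) + 1L]] <- append(p, n, after = pos)
  out
}

#' Small-volume correction of a permutation result
#'
#' Re-forms the max-statistic null over an a-priori region of interest, using
#' the per-permutation enhanced maps retained by [permutation_test()]. ROI
#' p-values are never larger than the global FWE p-values. The summary table
#' reports, per ROI, the number of surviving voxels at `alpha`, the peak
#' (smallest) corrected p and the world-mm coordinate of the peak enhanced
#' statistic.
#'
#' @param perm_result a `stat_maps` from [permutation_test()] run with
#'   `keep_null = TRUE`.
#' @param roi_mask a [mask_volume()] inside the analysis mask (or a named
#'   list of them).
#' @param alpha significance level for the surviving-voxel count.
#' @return an object of class `svc_result`: per-ROI corrected p arrays and a
#'   `summary` data frame with columns roi, n_voxels, p_fwe_peak,
#'   peak_x, peak_y, peak_z.
#' @export
small_volume_correct <- function(perm_result, roi_mask, alpha = 0.05) {
  stopifnot(inherits(perm_result, "stat_maps"))
  if (is.null(perm_result$null_enhanced))
    stop("permutation_test must be run with keep_null = TRUE for SVC")
  rois <- if (inherits(roi_mask, "mask_volume")) list(roi = roi_mask) else roi_mask
  res <- list(); tab <- list()
  for (nm in names(rois)) {
    roi <- rois[[nm]]
    lin <- which(roi$data == 1L)
    if (!length(lin)) stop("empty roi: ", nm)
    pos <- match(lin, perm_result$mask_idx)
    if (anyNA(pos)) stop("roi extends outside the analysis mask: ", nm)
    null_max_roi <- apply(perm_result$null_enhanced[, pos, drop = FALSE], 1, max)
    obs <- perm_result$enhanced[lin]
    cmp <- if (identical(perm_result$tail, "two.sided")) abs(obs) else obs
    p <- (1 + colSums(outer(null_max_roi, cmp, `>=`))) /
      (perm_result$n_perm + 1)
    p_arr <- array(1, perm_result$dims)
    p_arr[lin] <- p
    peak <- which.max(cmp)
    ijk <- arrayInd(lin[peak], perm_result$dims) - 1L
    xyz <- voxel_to_world(perm_result$affine, ijk)
    res[[nm]] <- p_arr
    tab[[nm]] <- data.frame(roi = nm, n_voxels = sum(p < alpha),
                            p_fwe_peak = min(p),
                            peak_x = xyz[1], peak_y = xyz[2], peak_z = xyz[3])
  }
  structure(list(p_svc = res, summary = do.call(rbind, tab),
                 alpha = alpha),
            class = "svc_result")
}

#' @export
print.svc_result <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  invisible(x)
}
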