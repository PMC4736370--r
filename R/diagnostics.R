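#' Voxelwise residual normality check (Lilliefors test)
#'
#' Fits the GLM at every masked voxel and applies the Lilliefors
#' (Kolmogorov-Smirnov with estimated mean and sd) test to the residuals.
#' A high fraction of rejections motivates the nonparametric permutation
#' route over parametric GLM inference.
#'
#' @param maps list of per-subject [scalar_map()]s or an n x V matrix.
#' @param mask analysis [mask_volume()].
#' @param design a `cohort_design` or [design_matrix()].
#' @param alpha rejection level for the summary fraction (default 0.05).
#' @return list with arrays `statistic` and `p`, the `rejection_fraction`,
#'   and `n_degenerate` (voxels with (near-)constant residuals, flagged and
#'   excluded from the fraction).
#' @export
residual_normality_check <- function(maps, mask, design, alpha = 0.05) {
  dm <- if (inherits(design, "design_matrix")) design else design_matrix(design)
  Y <- if (is.matrix(maps)) maps else stack_maps(maps, mask)
  n <- nrow(Y)
  if (n < 5) stop("at least 5 subjects are required for the Lilliefors test")
  X <- dm$X
  beta <- solve(crossprod(X), crossprod(X, Y))
  R <- Y - X %*% beta
  mask_idx <- which(mask$data == 1L)
  dims <- dim(mask$data)
  stat_arr <- array(NA_real_, dims)
  p_arr <- array(NA_real_, dims)
  degen <- 0L
  for (v in seq_len(ncol(R))) {
    r <- R[, v]
    if (stats::sd(r) < 1e-12 * (abs(mean(r)) + 1)) {
      degen <- degen + 1L
      next
    }
    lt <- nortest::lillie.test(r)
    stat_arr[mask_idx[v]] <- unname(lt$statistic)
    p_arr[mask_idx[v]] <- lt$p.value
  }
  pv <- p_arr[mask_idx]
  list(statistic = stat_arr, p = p_arr,
       rejection_fraction = mean(pv < alpha, na.rm = TRUE),
       n_degenerate = degen)
}

#' Does ACM depend linearly on intracranial volume?
#'
#' Per group, the Pearson correlation between the per-subject mean ACM inside
#' an ROI and the subject's intracranial (brain-mask) volume, with the
#' two-sided t-based p-value. A strong linear dependence would mark brain
#' size, rather than connectivity, as the driver of group ACM differences.
#'
#' @param acm_maps list of per-subject ACM [scalar_map()]s.
#' @param roi_mask [mask_volume()] in which to average the ACM.
#' @param icv_values numeric vector of intracranial volumes (one per subject).
#' @param group_labels factor/character of group membership per subject.
#' @return data frame with columns group, n, r, p.
#' @export
icv_correlation <- function(acm_maps, roi_mask, icv_values, group_labels) {
  stopifnot(length(acm_maps) == length(icv_values),
            length(acm_maps) == length(group_labels))
  idx <- which(roi_mask$data == 1L)
  mean_acm <- vapply(acm_maps, function(m) mean(m$data[idx]), 0)
  out <- list()
  for (g in unique(group_labels)) {
    sel <- group_labels == g
    if (sum(sel) < 3) stop("group ", g, " has fewer than 3 subjects")
    if (stats::sd(mean_acm[sel]) == 0 || stats::sd(icv_values[sel]) == 0)
      stop("zero variance in group ", g)
    ct <- stats::cor.test(mean_acm[sel], icv_values[sel], method = "pearson")
    out[[g]] <- data.frame(group = g, n = sum(sel),
                           r = unname(ct$estimate), p = ct$p.value)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
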