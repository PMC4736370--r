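#' Canonical synthetic study cohort
#'
#' The package's reference study conditions: a 20^3 voxel (2 mm isotropic)
#' phantom head with one straight white-matter tract along x (tube radius
#' 3 mm, lambda_par = 1.7e-3, lambda_perp = 0.3e-3 mm^2/s) crossing an
#' anterior spherical lesion ROI (radius 4.5 mm), acquired with 61 diffusion
#' directions at b = 1500 s/mm^2 plus 10 b = 0 volumes at SNR 20, and three
#' groups mirroring a sighted / late-onset / congenital structure: NS
#' (n = 15, no lesion), LB (n = 15, radial diffusivity multiplier 1.5) and
#' CB (n = 12, multiplier 2.0). The multipliers raise lambda_perp inside the
#' lesion only, lowering FA and raising RD and MD while leaving AD unchanged.
#'
#' @param base_seed integer seed for the cohort.
#' @param grid_dim grid size (default `c(20, 20, 20)`).
#' @param groups group definitions, as in [cohort_spec()].
#' @param sigma noise sd (default 5 = S0/20).
#' @return a [cohort_spec()].
#' @export
study_cohort_spec <- function(base_seed = 1L, grid_dim = c(20L, 20L, 20L),
                              groups = list(
                                NS = list(n = 15, rd_multiplier = 1),
                                LB = list(n = 15, rd_multiplier = 1.5,
                                          age_mean = 52, age_sd = 15),
                                CB = list(n = 12, rd_multiplier = 2,
                                          age_mean = 42, age_sd = 13)),
                              sigma = 5) {
  vs <- 2
  ymid <- (grid_dim[2] - 1) * vs / 2
  zmid <- (grid_dim[3] - 1) * vs / 2
  xmax <- (grid_dim[1] - 1) * vs
  base <- phantom_spec(
    grid_dim = grid_dim, voxel_size = vs,
    tracts = list(straight_tube(c(0, ymid, zmid), c(xmax, ymid, zmid),
                                radius = 3)),
    scheme = make_gradient_scheme(61, 1500, 10, seed = 42),
    lesion = list(center = c(0.225 * xmax, ymid, zmid), radius = 4.5,
                  rd_multiplier = 1),
    sigma = sigma)
  cohort_spec(base, groups = groups, base_seed = base_seed)
}

#' Per-subject scalar and connectivity maps for group analysis
#'
#' For every cohort subject: tensor fit, the four DTI scalar maps, the ACM
#' from the one-shot tracking pipeline, and Gaussian smoothing — the
#' map-preparation stage preceding voxelwise group statistics.
#'
#' Tracking uses `n_per_voxel` streamlines per seed and an FA-to-kappa
#' concentration scale of `kappa_max`; the default `kappa_max = 15` is
#' deliberately lower than the single-subject tracking default so that
#' orientation dispersion in partially damaged tissue translates into
#' streamline loss along the tract (the regime in which connectivity mapping
#' carries information beyond local microstructure; see the vignette).
#'
#' @param cohort result of [make_cohort()].
#' @param measures subset of `c("FA", "MD", "RD", "AD", "ACM")`.
#' @param n_per_voxel streamlines per seed voxel for the ACM (default 50).
#' @param kappa_max concentration scale for cohort tracking (default 15).
#' @param fwhm smoothing kernel FWHM in mm (default 4; 0 disables).
#' @param fit_method tensor fit for the scalar maps (`"lls"` or `"nls"`).
#' @param seed base seed for tracking RNG streams.
#' @return named list (by subject id) of named lists of [scalar_map()]s.
#' @export
cohort_maps <- function(cohort, measures = c("FA", "MD", "RD", "AD", "ACM"),
                        n_per_voxel = 50L, kappa_max = 15, fwhm = 4,
                        fit_method = "lls", seed = 1L) {
  out <- list()
  for (s in names(cohort$subjects)) {
    ph <- cohort$subjects[[s]]$phantom
    tf <- if (fit_method == "nls") fit_tensor_nls(ph$dwi, mask = ph$mask)
          else fit_tensor_lls(ph$dwi, mask = ph$mask)
    maps <- list()
    if (any(measures != "ACM")) {
      sc <- tensor_scalars(tf)
      for (m in intersect(measures, names(sc))) maps[[m]] <- sc[[m]]
    }
    if ("ACM" %in% measures) {
      model <- orientation_model_from_tensor(tf, kappa_max = kappa_max)
      pars <- tracking_params(n_per_voxel = n_per_voxel,
                              seed = seed + match(s, names(cohort$subjects)))
      maps$ACM <- acm_pipeline(ph$dwi, ph$mask, pars, model = model)
    }
    if (fwhm > 0) maps <- lapply(maps, smooth_map, fwhm_mm = fwhm)
    out[[s]] <- maps
  }
  out
}
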