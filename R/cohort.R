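#' Cohort specification
#'
#' Describes a synthetic study population built from per-subject phantoms.
#' Each group shares the base [phantom_spec()] but applies its own lesion
#' radial-diffusivity multiplier (`rd_multiplier = 1` in the control group
#' means no lesion). Between-subject variability is a multiplicative
#' log-normal jitter on the compartment eigenvalues and background
#' diffusivity. Age and gender covariates are drawn from per-group
#' distributions loosely matched to a blind-vs-sighted study population
#' (means 42-52 years, sd 13-15); the native brain-mask voxel count emulates
#' intracranial-volume variation as a log-normal jitter of the true grid
#' count. Everything is reproducible from `base_seed`, with distinct derived
#' seeds per subject.
#'
#' @param base_spec a [phantom_spec()] that must carry a lesion definition
#'   whenever any group has `rd_multiplier > 1`.
#' @param groups named list; each element is
#'   `list(n = <int >= 2>, rd_multiplier = <f >= 1>, age_mean, age_sd)`.
#'   Defaults mirror a three-group sighted/late/congenital structure:
#'   NS (n = 15, f = 1), LB (n = 15, f = 1.25), CB (n = 12, f = 1.5).
#' @param jitter_scale sd of the log-normal eigenvalue jitter (default 0.05).
#' @param icv_jitter sd of the log-normal brain-mask-size jitter (default
#'   0.03).
#' @param base_seed integer seed for the whole cohort.
#' @export
cohort_spec <- function(base_spec,
                        groups = list(
                          NS = list(n = 15, rd_multiplier = 1),
                          LB = list(n = 15, rd_multiplier = 1.25,
                                    age_mean = 52, age_sd = 15),
                          CB = list(n = 12, rd_multiplier = 1.5,
                                    age_mean = 42, age_sd = 13)),
                        jitter_scale = 0.05, icv_jitter = 0.03,
                        base_seed = 1L) {
  stopifnot(inherits(base_spec, "phantom_spec"))
  if (length(groups) < 2L) stop("at least two groups are required")
  for (g in names(groups)) {
    gr <- groups[[g]]
    if (is.null(gr$n) || gr$n < 2)
      stop("each group needs n >= 2 subjects")
    if (is.null(gr$rd_multiplier)) groups[[g]]$rd_multiplier <- 1
    if (groups[[g]]$rd_multiplier < 1) stop("rd_multiplier must be >= 1")
    if (is.null(gr$age_mean)) groups[[g]]$age_mean <- 46
    if (is.null(gr$age_sd)) groups[[g]]$age_sd <- 13
  }
  lesioned <- any(vapply(groups, function(g) g$rd_multiplier > 1, TRUE))
  if (lesioned && is.null(base_spec$lesion))
    stop("base_spec needs a lesion definition when a group has rd_multiplier > 1")
  structure(list(base_spec = base_spec, groups = groups,
                 jitter_scale = jitter_scale, icv_jitter = icv_jitter,
                 base_seed = as.integer(base_seed)),
            class = "cohort_spec")
}

# per-subject spec: group lesion multiplier + log-normal eigenvalue jitter
subject_spec <- function(base, rd_multiplier, jitter_scale, subj_seed) {
  sp <- base
  jit <- with_seed(subj_seed, exp(stats::rnorm(3, 0, jitter_scale)))
  for (t in seq_along(sp$tracts)) {
    sp$tracts[[t]]$lambda_par <- sp$tracts[[t]]$lambda_par * jit[1]
    sp$tracts[[t]]$lambda_perp <- min(sp$tracts[[t]]$lambda_perp * jit[2],
                                      sp$tracts[[t]]$lambda_par)
  }
  sp$background_adc <- sp$background_adc * jit[3]
  if (!is.null(sp$lesion)) {
    sp$lesion$rd_multiplier <- rd_multiplier
    if (rd_multiplier == 1) sp$lesion <- NULL
  }
  sp
}

#' Generate a synthetic cohort of DWI phantoms
#'
#' @param spec a [cohort_spec()].
#' @return a list with `subjects` (per subject: `id`, `group`, `phantom` as
#'   returned by [build_phantom()]) and `design` (a `cohort_design` with
#'   covariates age, gender and mask_voxels).
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  subjects <- list()
  rows <- list()
  sid <- 0L
  for (g in names(spec$groups)) {
    gr <- spec$groups[[g]]
    for (i in seq_len(gr$n)) {
      sid <- sid + 1L
      # derived seeds stay in 32-bit integer range
      subj_seed <- (spec$base_seed * 1009L + sid * 7919L) %% 2147483629L
      sp <- subject_spec(spec$base_spec, gr$rd_multiplier,
                         spec$jitter_scale, subj_seed)
      ph <- build_phantom(sp, seed = subj_seed + 1L)
      covs <- with_seed(subj_seed + 2L, list(
        age = round(stats::rnorm(1, gr$age_mean, gr$age_sd), 1),
        gender = stats::rbinom(1, 1, 0.5),
        mask_voxels = round(sum(ph$mask$data) *
                              exp(stats::rnorm(1, 0, spec$icv_jitter)))))
      id <- sprintf("%s%02d", g, i)
      subjects[[id]] <- list(id = id, group = g, phantom = ph)
      rows[[id]] <- data.frame(id = id, group = g, age = covs$age,
                               gender = covs$gender,
                               mask_voxels = covs$mask_voxels)
    }
  }
  design <- cohort_design(do.call(rbind, c(rows, make.row.names = FALSE)))
  list(subjects = subjects, design = design)
}
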