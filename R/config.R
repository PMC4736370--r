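#' Serialise phantom specifications to and from YAML
#'
#' A plain-text round-trip for [phantom_spec()] so that phantom cohorts can
#' be described in a single configuration file. The gradient scheme is stored
#' by its generating parameters (n_directions, b_value, n_b0, seed), not by
#' its realised direction table.
#'
#' @param spec a [phantom_spec()].
#' @param path YAML file path.
#' @export
write_phantom_yaml <- function(spec, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required for configuration files")
  sch <- spec$scheme
  cfg <- list(
    grid_dim = as.integer(spec$grid_dim),
    voxel_size = spec$voxel_size,
    background_adc = spec$background_adc,
    S0 = spec$S0, sigma = spec$sigma,
    scheme = list(n_directions = sum(sch$bvals > 0),
                  b_value = max(sch$bvals),
                  n_b0 = sum(sch$bvals == 0),
                  seed = attr(sch, "seed") %||% 42L),
    tracts = lapply(spec$tracts, function(tr) list(
      points = apply(tr$points, 1, function(p) as.list(p), simplify = FALSE),
      radius = tr$radius, lambda_par = tr$lambda_par,
      lambda_perp = tr$lambda_perp, fraction = tr$fraction)),
    lesion = spec$lesion)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_phantom_yaml
#' @export
read_phantom_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required for configuration files")
  cfg <- yaml::read_yaml(path)
  scheme <- make_gradient_scheme(cfg$scheme$n_directions, cfg$scheme$b_value,
                                 cfg$scheme$n_b0, seed = cfg$scheme$seed)
  tracts <- lapply(cfg$tracts, function(tr)
    tract_tube(do.call(rbind, lapply(tr$points, unlist)), tr$radius,
               tr$lambda_par, tr$lambda_perp, tr$fraction))
  phantom_spec(grid_dim = unlist(cfg$grid_dim),
               voxel_size = unlist(cfg$voxel_size), tracts = tracts,
               scheme = scheme, background_adc = cfg$background_adc,
               lesion = if (!is.null(cfg$lesion))
                 list(center = unlist(cfg$lesion$center),
                      radius = cfg$lesion$radius,
                      rd_multiplier = cfg$lesion$rd_multiplier),
               S0 = cfg$S0, sigma = cfg$sigma)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
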