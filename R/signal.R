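#' Fibre compartment
#'
#' An axially symmetric diffusion compartment: unit mean orientation,
#' eigenvalues (lambda_par, lambda_perp, lambda_perp) in mm^2/s and a volume
#' fraction. Within a voxel, fractions over compartments must sum to <= 1;
#' the remainder is modelled as isotropic.
#'
#' @param orientation 3-vector (normalised internally).
#' @param lambda_par,lambda_perp parallel / perpendicular diffusivity
#'   (mm^2/s); `lambda_par >= lambda_perp > 0`.
#' @param fraction volume fraction in `[0, 1]`.
#' @export
fibre_compartment <- function(orientation, lambda_par = 1.7e-3,
                              lambda_perp = 0.3e-3, fraction = 1) {
  if (lambda_perp <= 0 || lambda_par < lambda_perp)
    stop("need lambda_par >= lambda_perp > 0")
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0,1]")
  n <- sqrt(sum(orientation^2))
  if (n < .Machine$double.eps) stop("orientation must be non-zero")
  structure(list(orientation = orientation / n, lambda_par = lambda_par,
                 lambda_perp = lambda_perp, fraction = fraction),
            class = "fibre_compartment")
}

#' Multi-compartment diffusion signal forward model
#'
#' \deqn{S(g, b) = S_0 (\sum_c f_c e^{-b g^T D_c g} + f_{iso} e^{-b d_{iso}})}
#' with \eqn{D_c = \lambda_\perp I + (\lambda_\parallel - \lambda_\perp)
#' v v^T} for each axially symmetric compartment and the fraction remainder
#' \eqn{f_{iso} = 1 - \sum_c f_c} isotropic with diffusivity `iso_diffusivity`.
#' At b = 0 the signal is exactly `S0`.
#'
#' @param compartments list of [fibre_compartment()]s (possibly empty for a
#'   purely isotropic voxel).
#' @param scheme a [gradient_scheme()].
#' @param S0 baseline (unweighted) signal.
#' @param iso_diffusivity diffusivity of the isotropic remainder (mm^2/s).
#' @return numeric vector of non-negative signals, one per scheme volume.
#' @export
simulate_signal <- function(compartments, scheme, S0 = 100,
                            iso_diffusivity = 0.8e-3) {
  if (inherits(compartments, "fibre_compartment"))
    compartments <- list(compartments)
  fsum <- 0
  att <- numeric(n_volumes(scheme))
  b <- scheme$bvals
  for (cmp in compartments) {
    stopifnot(inherits(cmp, "fibre_compartment"))
    fsum <- fsum + cmp$fraction
    gv2 <- as.vector(crossprod(scheme$bvecs, cmp$orientation))^2
    adc <- cmp$lambda_perp + (cmp$lambda_par - cmp$lambda_perp) * gv2
    att <- att + cmp$fraction * exp(-b * adc)
  }
  if (fsum > 1 + 1e-9) stop("compartment fractions sum above 1")
  att <- att + (1 - fsum) * exp(-b * iso_diffusivity)
  S0 * att
}

#' Rician (magnitude-MRI) noise
#'
#' Adds complex Gaussian noise and takes the magnitude:
#' \eqn{M = |(S + n_1) + i n_2|}, \eqn{n_1, n_2 \sim N(0, \sigma^2)}.
#' With `sigma = 0` the signal is returned unchanged. Deterministic given
#' `seed`; the caller's RNG stream is left untouched.
#'
#' @param signal numeric vector/array of noise-free magnitudes.
#' @param sigma noise standard deviation per channel (>= 0).
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @export
add_rician_noise <- function(signal, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(signal)
  with_seed(seed, {
    n <- length(signal)
    noisy <- sqrt((signal + stats::rnorm(n, 0, sigma))^2 +
                    stats::rnorm(n, 0, sigma)^2)
    if (!is.null(dim(signal))) dim(noisy) <- dim(signal)
    noisy
  })
}
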