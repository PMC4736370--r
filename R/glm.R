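#' Design matrix for voxelwise group GLMs
#'
#' Cell-means coding: one indicator column per group (no intercept) plus the
#' nuisance covariates. Continuous covariates (age, mask_voxels) are
#' mean-centred by default so that group-column contrasts compare adjusted
#' group means; gender stays 0/1. The matrix must be of full column rank;
#' collinear columns are named in the error.
#'
#' @param design a `cohort_design` (see [read_design()]).
#' @param covariates covariate column names to include.
#' @param center mean-centre non-binary covariates (default TRUE).
#' @return an object of class `design_matrix`.
#' @export
design_matrix <- function(design,
                          covariates = c("age", "gender", "mask_voxels"),
                          center = TRUE) {
  groups <- sort(unique(design$group))
  G <- sapply(groups, function(g) as.numeric(design$group == g))
  colnames(G) <- groups
  Z <- NULL
  if (length(covariates)) {
    Z <- as.matrix(design[, covariates, drop = FALSE])
    if (center)
      for (j in seq_len(ncol(Z)))
        if (length(unique(Z[, j])) > 2L) Z[, j] <- Z[, j] - mean(Z[, j])
  }
  X <- cbind(G, Z)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  structure(list(X = X, groups = groups,
                 group_cols = seq_along(groups),
                 nuisance_cols = if (is.null(Z)) integer() else
                   length(groups) + seq_len(ncol(Z)),
                 ids = design$id),
            class = "design_matrix")
}

#' Parse a contrast specification
#'
#' `"A>B"` / `"A<B"` give one-tailed two-sample t contrasts on the group
#' columns; `"group"` gives the omnibus F contrast over all group
#' differences. A numeric vector (t) or matrix (F) over the design columns is
#' passed through.
#'
#' @param dm a [design_matrix()].
#' @param contrast character specification or numeric vector/matrix.
#' @return list with `type` ("t"/"F"), `C` (vector or matrix), `tail`.
#' @export
parse_contrast <- function(dm, contrast) {
  p <- ncol(dm$X)
  if (is.character(contrast)) {
    if (identical(contrast, "group")) {
      k <- length(dm$groups)
      C <- matrix(0, k - 1, p)
      for (r in seq_len(k - 1)) {
        C[r, r] <- 1
        C[r, k] <- -1
      }
      return(list(type = "F", C = C, tail = NA_character_))
    }
    m <- regmatches(contrast, regexec("^([^<>]+)([<>])([^<>]+)$", contrast))[[1]]
    if (length(m) != 4)
      stop("cannot parse contrast: ", contrast)
    a <- trimws(m[2]); b <- trimws(m[4])
    if (!a %in% dm$groups || !b %in% dm$groups)
      stop("unknown group in contrast: ", contrast)
    cvec <- numeric(p)
    s <- if (m[3] == ">") 1 else -1
    cvec[match(a, dm$groups)] <- s
    cvec[match(b, dm$groups)] <- -s
    return(list(type = "t", C = cvec, tail = "greater"))
  }
  if (is.matrix(contrast)) {
    stopifnot(ncol(contrast) == p)
    return(list(type = "F", C = contrast, tail = NA_character_))
  }
  stopifnot(length(contrast) == p)
  list(type = "t", C = as.numeric(contrast), tail = "greater")
}

#' Voxelwise GLM statistic map
#'
#' Ordinary least squares per voxel; t statistics for vector contrasts,
#' partial F statistics for matrix contrasts.
#'
#' @param Y n_subject x n_voxel matrix of responses (see [stack_maps()]).
#' @param dm a [design_matrix()].
#' @param contrast see [parse_contrast()].
#' @return list with `stat` (length n_voxel), `type`, `df`.
#' @export
glm_stat <- function(Y, dm, contrast) {
  ct <- parse_contrast(dm, contrast)
  X <- dm$X
  n <- nrow(X); p <- ncol(X)
  XtXi <- solve(crossprod(X))
  beta <- XtXi %*% crossprod(X, Y)
  resid <- Y - X %*% beta
  df <- n - p
  sigma2 <- colSums(resid^2) / df
  if (ct$type == "t") {
    num <- drop(ct$C %*% beta)
    v <- drop(t(ct$C) %*% XtXi %*% ct$C)
    den <- sqrt(sigma2 * v)
    stat <- ifelse(den > 0, num / den, 0)
    stat[abs(num) < 1e-300 & den == 0] <- 0
    list(stat = stat, type = "t", df = df)
  } else {
    C <- ct$C
    q <- nrow(C)
    M <- C %*% XtXi %*% t(C)
    CB <- C %*% beta
    quad <- colSums(CB * solve(M, CB))
    stat <- ifelse(sigma2 > 0, quad / (q * sigma2), 0)
    list(stat = stat, type = "F", df = c(q, df))
  }
}

#' Stack subject maps into a response matrix
#'
#' @param maps list of aligned [scalar_map()]s, one per subject.
#' @param mask analysis [mask_volume()].
#' @return n_subject x n_masked_voxel matrix.
#' @export
stack_maps <- function(maps, mask) {
  idx <- which(mask$data == 1L)
  t(vapply(maps, function(m) {
    if (!all(dim(m$data) == dim(mask$data)))
      stop("subject map and mask dimensions differ")
    as.numeric(m$data[idx])
  }, numeric(length(idx))))
}
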