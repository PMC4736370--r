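#' Read a diffusion-weighted dataset (NIfTI + FSL bval/bvec)
#'
#' @param image_path path to a 4-D NIfTI volume (.nii or .nii.gz).
#' @param bval_path path to a whitespace-separated b-value file (1 x n).
#' @param bvec_path path to a whitespace-separated direction file (3 rows x
#'   n columns, FSL dialect).
#' @return an [image_volume()] with the [gradient_scheme()] attached.
#' @export
read_dwi <- function(image_path, bval_path, bvec_path) {
  img <- RNifti::readNifti(image_path)
  scheme <- read_gradient_scheme(bval_path, bvec_path)
  data <- as.array(img)
  if (length(dim(data)) != 4L)
    stop("DWI image must be 4-D")
  if (dim(data)[4] != n_volumes(scheme))
    stop(sprintf("image has %d volumes but the gradient scheme lists %d",
                 dim(data)[4], n_volumes(scheme)))
  image_volume(data, affine = unclass(RNifti::xform(img)),
               units = "signal", scheme = scheme)
}

#' @rdname read_dwi
#' @param vol an [image_volume()] with attached scheme.
#' @export
write_dwi <- function(vol, image_path, bval_path, bvec_path) {
  stopifnot(inherits(vol, "image_volume"), !is.null(vol$scheme))
  write_nifti_volume(vol, image_path)
  write_gradient_scheme(vol$scheme, bval_path, bvec_path)
  invisible(image_path)
}

#' Read / write FSL-dialect gradient tables
#'
#' @param bval_path,bvec_path whitespace-separated text files; bvec has 3 rows.
#' @export
read_gradient_scheme <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, what = numeric(), quiet = TRUE)
  bv <- as.matrix(utils::read.table(bvec_path))
  if (nrow(bv) != 3L && ncol(bv) == 3L) bv <- t(bv)
  if (nrow(bv) != 3L)
    stop("bvec file must have 3 rows (FSL dialect)")
  gradient_scheme(bvals, bv)
}

#' @rdname read_gradient_scheme
#' @param scheme a [gradient_scheme()].
#' @export
write_gradient_scheme <- function(scheme, bval_path, bvec_path) {
  cat(paste(format(scheme$bvals, trim = TRUE, scientific = FALSE),
            collapse = " "), "\n", sep = "", file = bval_path)
  write.table(format(scheme$bvecs, digits = 17, trim = TRUE,
                     scientific = FALSE),
              bvec_path, row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(bval_path)
}

#' Read / write 3-D volumes and masks as NIfTI
#'
#' @param path NIfTI file path (.nii or .nii.gz).
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  image_volume(as.array(img), affine = unclass(RNifti::xform(img)))
}

#' @rdname read_nifti_volume
#' @param vol an [image_volume()], [mask_volume()] or [scalar_map()].
#' @export
write_nifti_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_nifti_volume
#' @export
read_mask <- function(path) {
  v <- read_nifti_volume(path)
  mask_volume(v$data != 0, v$affine)
}

#' Read a cohort design table
#'
#' A delimited table (comma or tab) with header columns `id`, `group`, `age`,
#' `gender`, `mask_voxels`: one row per subject, the group label as the main
#' factor and age (years), gender (0/1) and native-space brain-mask voxel
#' count as nuisance covariates.
#'
#' @param table_path CSV/TSV path.
#' @return a validated `cohort_design` data frame.
#' @export
read_design <- function(table_path) {
  first <- readLines(table_path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(table_path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  cohort_design(df)
}

#' @rdname read_design
#' @param design a `cohort_design`.
#' @export
write_design <- function(design, table_path) {
  utils::write.csv(as.data.frame(design), table_path, row.names = FALSE)
  invisible(table_path)
}

#' Validate a cohort design
#'
#' @param df data frame with columns `id`, `group`, `age`, `gender`,
#'   `mask_voxels`.
#' @export
cohort_design <- function(df) {
  need <- c("id", "group", "age", "gender", "mask_voxels")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("design table is missing columns: ", paste(miss, collapse = ", "))
  cov <- df[, c("age", "gender", "mask_voxels")]
  if (anyNA(cov) || anyNA(df$group) || anyNA(df$id))
    stop("design table has missing values")
  if (!all(df$gender %in% c(0, 1)))
    stop("gender must be coded 0/1")
  tab <- table(df$group)
  if (length(tab) < 2L)
    stop("at least two groups are required")
  small <- names(tab)[tab < 2L]
  if (length(small))
    stop("each group needs >= 2 subjects; too small: ",
         paste(small, collapse = ", "))
  df <- as.data.frame(df)
  class(df) <- c("cohort_design", "data.frame")
  df
}
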