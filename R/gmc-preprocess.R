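#' Mask and flatten image volumes to a subjects-by-voxel matrix
#'
#' Each subject's 3-D volume is restricted to the `TRUE` voxels of `mask`
#' and laid out as one row; column `j` is the `j`-th in-mask voxel in R's
#' native column-major array scan order, so the operation is invertible
#' (out-of-mask voxels restore to 0, see [unflatten_gmc()]).
#'
#' @param volumes a 4-D array (x, y, z, subject) or a list of 3-D arrays.
#' @param mask logical 3-D array.
#' @param voxel_size,affine grid geometry carried into the result.
#' @param subject_ids optional identifiers.
#' @return A [gmc_matrix()].
#' @export
mask_and_flatten <- function(volumes, mask, voxel_size = c(2, 2, 2),
                             affine = NULL, subject_ids = NULL) {
  mask <- array(as.logical(mask), dim = dim(mask))
  if (is.list(volumes)) {
    volumes <- array(unlist(volumes),
                     dim = c(dim(volumes[[1]]), length(volumes)))
  }
  dv <- dim(volumes)
  if (length(dv) == 3L) { dv <- c(dv, 1L); dim(volumes) <- dv }
  if (!identical(dv[1:3], dim(mask)))
    stopf("volume grid %s does not match mask grid %s",
          paste(dv[1:3], collapse = "x"), paste(dim(mask), collapse = "x"))
  idx <- which(mask)
  vmat <- matrix(volumes, prod(dv[1:3]), dv[4])[idx, , drop = FALSE]
  gmc_matrix(t(vmat), mask, voxel_size = voxel_size, affine = affine,
             subject_ids = subject_ids)
}

#' Restore a flattened row (or matrix) to volume form
#'
#' @param x a [gmc_matrix()], or a numeric vector/matrix of in-mask values.
#' @param mask required when `x` is not a `gmc_matrix`.
#' @return A 3-D array (single row) or 4-D array, zero outside the mask.
#' @export
unflatten_gmc <- function(x, mask = NULL) {
  if (inherits(x, "gmc_matrix")) { mask <- x$mask; x <- x$values }
  if (is.null(mask)) stopf("mask required")
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  idx <- which(mask)
  flat <- matrix(0, prod(dim(mask)), nrow(x))
  flat[idx, ] <- t(x)
  if (nrow(x) == 1L) array(flat[, 1L], dim = dim(mask))
  else array(flat, dim = c(dim(mask), nrow(x)))
}

# Build the nuisance design: intercept, age, sex, L-1 site dummies
# (reference level = first site), plus any extra numeric columns.
.nuisance_design <- function(covariates, extra = NULL) {
  stopifnot(all(c("age", "sex", "site") %in% names(covariates)))
  if (anyNA(covariates[c("age", "sex", "site")]))
    stopf("missing covariate values; complete cases required")
  site <- factor(covariates$site)
  df <- data.frame(age = as.numeric(covariates$age),
                   sex = as.numeric(covariates$sex), site = site)
  form <- ~ age + sex + site
  x <- stats::model.matrix(form, df)
  if (!is.null(extra)) x <- cbind(x, as.matrix(extra))
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1L):ncol(x)]]
    stopf("rank-deficient nuisance design; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  x
}

#' Voxelwise nuisance regression of age, sex and site
#'
#' Fits, at every voxel, ordinary least squares on an intercept, age, sex,
#' and dummy-coded site (L levels give L-1 dummies, so 50 sites contribute
#' 49 columns), and returns the residuals with the per-voxel intercept added
#' back so values stay on a concentration-like scale.  Each residual voxel
#' is orthogonal to every covariate column.
#'
#' @param gmc a [gmc_matrix()].
#' @param covariates data frame with `age`, `sex`, `site` (and optionally
#'   more) rows aligned to the GMC subjects.
#' @param extra optional additional numeric design columns (e.g. MDS
#'   factors).
#' @param keep_intercept add the fitted intercept back (default `TRUE`);
#'   `FALSE` returns plain residuals.
#' @return A `gmc_matrix` of residualized values.
#' @export
residualize_voxels <- function(gmc, covariates, extra = NULL,
                               keep_intercept = TRUE) {
  stopifnot(inherits(gmc, "gmc_matrix"))
  if (nrow(covariates) != nrow(gmc$values))
    stopf("covariates rows (%d) != GMC subjects (%d)",
          nrow(covariates), nrow(gmc$values))
  x <- .nuisance_design(covariates, extra)
  fit <- stats::lm.fit(x, gmc$values)
  res <- fit$residuals
  if (keep_intercept)
    res <- sweep(res, 2L, fit$coefficients["(Intercept)", ], "+")
  gmc_matrix(res, gmc$mask, gmc$voxel_size, gmc$affine, gmc$subject_ids)
}
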