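#' Clinical table constructor
#'
#' A per-subject table of the seven clinical measures with direction
#' metadata: for TMTA/TMTB (seconds) and the UHDRS total motor score, higher
#' is worse; for SDMT and the Stroop conditions (correct counts), higher is
#' better.  Per-measure missingness is allowed (analyses are complete-case
#' per measure).
#'
#' @param df data frame of clinical measures (and optionally `subject_id`).
#' @param directions named character vector mapping measure names to
#'   `"higher_worse"` or `"higher_better"`; defaults to
#'   [clinical_directions()] for the standard battery.
#' @return `df` with a `directions` attribute, class `clinical_table`.
#' @export
clinical_table <- function(df, directions = NULL) {
  directions <- directions %||% attr(df, "directions") %||%
    clinical_directions()
  measures <- setdiff(names(df), "subject_id")
  miss <- setdiff(measures, names(directions))
  if (length(miss))
    stopf("no direction metadata for measure(s): %s",
          paste(miss, collapse = ", "))
  bad <- !directions[measures] %in% c("higher_worse", "higher_better")
  if (any(bad)) stopf("directions must be 'higher_worse'/'higher_better'")
  attr(df, "directions") <- directions
  class(df) <- unique(c("clinical_table", class(df)))
  df
}

#' Bonferroni adjustment
#'
#' `p' = min(1, m * p)`; monotone and order-preserving.  The family size may
#' exceed the number of supplied p-values.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @param m family size; defaults to `length(p_values)`.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stopf("p-values must lie in [0, 1]")
  if (m < length(p_values))
    stopf("family size m = %d smaller than the number of tests", m)
  pmin(1, m * p_values)
}

#' Associate clinical measures with a covariate
#'
#' For each clinical measure, fits ordinary least squares of the measure on
#' an intercept plus the covariate (component loading or SNP dosage) and any
#' adjusters, complete-case per measure, and reports the F test of the
#' covariate (`df1 = 1`, so `F = t^2`), the Bonferroni-adjusted p-value over
#' the measure family, and a direction call: the coefficient sign is mapped
#' through the measure's direction metadata to `protective` (higher
#' covariate predicts better performance) or `deleterious`, with `n.s.` when
#' the raw p-value is at or above `alpha`.
#'
#' @param clinical a [clinical_table()] (or data frame with direction
#'   attribute).
#' @param covariate numeric subject vector aligned to the clinical rows.
#' @param adjusters optional data frame / matrix of additional columns.
#' @param covariate_name label for the output.
#' @param family_m Bonferroni family size; defaults to the number of
#'   measures.
#' @param alpha significance level for the direction call.
#' @return Data frame with one row per measure: `measure`, `covariate`,
#'   `f_stat`, `df1`, `df2`, `p_raw`, `p_bonferroni`, `beta`,
#'   `direction_call`.
#' @export
glm_clinical <- function(clinical, covariate, adjusters = NULL,
                         covariate_name = "covariate", family_m = NULL,
                         alpha = 0.05) {
  clinical <- clinical_table(as.data.frame(clinical),
                             attr(clinical, "directions"))
  directions <- attr(clinical, "directions")
  measures <- setdiff(names(clinical), "subject_id")
  n <- nrow(clinical)
  if (length(covariate) != n)
    stopf("covariate length %d != %d clinical rows", length(covariate), n)
  if (stats::sd(covariate, na.rm = TRUE) == 0) stopf("constant covariate")
  family_m <- family_m %||% length(measures)
  adj <- if (!is.null(adjusters)) as.matrix(adjusters) else NULL
  rows <- lapply(measures, function(m) {
    y <- clinical[[m]]
    ok <- !is.na(y) & !is.na(covariate)
    if (!is.null(adj)) ok <- ok & stats::complete.cases(adj)
    x <- cbind(1, covariate, adj)[ok, , drop = FALSE]
    npar <- ncol(x)
    if (sum(ok) < npar + 2)
      stopf("measure '%s': %d complete cases for %d parameters",
            m, sum(ok), npar)
    fit <- stats::lm.fit(x, y[ok])
    df2 <- sum(ok) - npar
    sigma2 <- sum(fit$residuals^2) / df2
    xtx_inv <- chol2inv(chol(crossprod(x)))
    beta <- fit$coefficients[2L]
    se <- sqrt(sigma2 * xtx_inv[2L, 2L])
    tval <- beta / se
    f <- tval^2
    p <- 2 * stats::pt(-abs(tval), df2)
    better <- if (directions[[m]] == "higher_worse") beta < 0 else beta > 0
    call <- if (p >= alpha) "n.s." else if (better) "protective"
            else "deleterious"
    data.frame(measure = m, covariate = covariate_name, f_stat = f,
               df1 = 1L, df2 = df2, p_raw = p,
               p_bonferroni = bonferroni(p, family_m), beta = beta,
               direction_call = call, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Associate clinical measures with a single SNP's dosage
#'
#' Extracts the dosage column for `snp_id` (a continuous covariate between 0
#' and 2, missing calls mean-imputed), verifies it is polymorphic, and runs
#' [glm_clinical()].  `direction_call = "protective"` means greater minor
#' allele dosage predicts better performance given the measure's direction
#' metadata.
#'
#' @param geno a [genotype_matrix()] (post-QC).
#' @param snp_id SNP identifier present in `geno$snp_meta$id`.
#' @param clinical a [clinical_table()].
#' @param ... passed to [glm_clinical()].
#' @return As [glm_clinical()].
#' @export
snp_dose_association <- function(geno, snp_id, clinical, ...) {
  stopifnot(inherits(geno, "genotype_matrix"))
  j <- match(snp_id, geno$snp_meta$id)
  if (is.na(j)) stopf("SNP '%s' not found", snp_id)
  dose <- geno$dosages[, j]
  if (anyNA(dose)) dose[is.na(dose)] <- mean(dose, na.rm = TRUE)
  if (stats::sd(dose) == 0) stopf("SNP '%s' is monomorphic in sample", snp_id)
  if (any(dose < 0 | dose > 2)) stopf("dosages outside [0, 2]")
  glm_clinical(clinical, dose, covariate_name = snp_id, ...)
}
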