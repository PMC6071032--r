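#' Select the maximally correlated component pair
#'
#' Computes all `n1 x n2` Pearson correlations between the two modalities'
#' subject-loading columns and returns the pair with the largest `|r|`,
#' together with a two-tailed p-value from the t transform at
#' `df = subjects - 2`.  The full correlation table is attached for
#' family-wise (Bonferroni, family size `n1 * n2`) correction; argmax ties
#' break to the lower index pair.
#'
#' @param result a `decomposition_result` from [run_picar()], or a list with
#'   loading matrices `a1` and `a2`.
#' @return An object of class `pair_stat` with fields `comp_1`, `comp_2`,
#'   `r`, `p`, `df`, `n_pairs`, and attribute `cor_table`.
#' @export
select_max_pair <- function(result) {
  a1 <- result$a1; a2 <- result$a2
  stopifnot(ncol(a1) >= 1L, ncol(a2) >= 1L, nrow(a1) == nrow(a2))
  cm <- suppressWarnings(stats::cor(a1, a2))
  cm[is.na(cm)] <- 0
  best <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2])[1L], , drop = TRUE]
  pair_stat(best[1], best[2], cm[best[1], best[2]], nrow(a1),
            n_pairs = length(cm), cor_table = cm)
}

#' Correlation statistic for one component pair
#'
#' @param comp_1,comp_2 component indices in modalities 1 and 2.
#' @param r Pearson correlation of the two loading columns.
#' @param n number of subjects.
#' @param n_pairs family size for Bonferroni correction.
#' @param cor_table optional full correlation table.
#' @return A `pair_stat` object with two-tailed `p` at `df = n - 2`.
#' @export
pair_stat <- function(comp_1, comp_2, r, n, n_pairs = 1L, cor_table = NULL) {
  stopifnot(abs(r) <= 1 + 1e-12, n > 2)
  df <- n - 2L
  r <- max(min(r, 1), -1)
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df)
  structure(list(comp_1 = as.integer(comp_1), comp_2 = as.integer(comp_2),
                 r = r, p = p, df = df, n_pairs = as.integer(n_pairs),
                 p_bonferroni = min(1, p * n_pairs)),
            cor_table = cor_table, class = "pair_stat")
}

#' @export
print.pair_stat <- function(x, ...) {
  cat(sprintf("pair_stat: components (%d, %d), r(%d) = %.3f, p = %.3g (Bonferroni %.3g over %d pairs)\n",
              x$comp_1, x$comp_2, x$df, x$r, x$p, x$p_bonferroni, x$n_pairs))
  invisible(x)
}

#' Z-score a component row
#'
#' Standardizes a component weight vector to mean 0, SD 1 for thresholded
#' reporting (the conventional display threshold is `|Z| >= 2.5`).
#'
#' @param s numeric vector (one component's weights); must be nonconstant.
#' @return The standardized vector.
#' @export
zscore_component <- function(s) {
  sdv <- stats::sd(s)
  if (!is.finite(sdv) || sdv == 0) stopf("constant component row")
  (s - mean(s)) / sdv
}

#' Select top contributing SNPs by logistic-distribution fit
#'
#' Fits the SNP component weights to a logistic distribution by maximum
#' likelihood and selects SNPs whose weights lie more than `k_sd` standard
#' deviations (`SD = scale * pi / sqrt(3)`) from the fitted location.  The
#' default multiplier is 4.25.  If the ML fit fails, a moment-based fit
#' (median location, SD-matched scale) is used with a warning.
#'
#' @param weights numeric vector of component weights (at least 30).
#' @param k_sd SD multiplier.
#' @return An object of class `top_snp_set`: `indices`, `weights`,
#'   `fit_location`, `fit_scale`, `k_sd`, `n_selected`.
#' @export
select_top_snps <- function(weights, k_sd = 4.25) {
  stopifnot(length(weights) >= 30L)
  fit <- tryCatch(
    suppressWarnings(MASS::fitdistr(weights, "logistic")),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("logistic ML fit failed; using moment-based fallback")
    location <- stats::median(weights)
    scale <- stats::sd(weights) * sqrt(3) / pi
  } else {
    location <- fit$estimate[["location"]]
    scale <- fit$estimate[["scale"]]
  }
  sdv <- scale * pi / sqrt(3)
  sel <- which(abs(weights - location) > k_sd * sdv)
  structure(list(indices = sel, weights = weights[sel],
                 fit_location = location, fit_scale = scale,
                 k_sd = k_sd, n_selected = length(sel)),
            class = "top_snp_set")
}

#' @export
print.top_snp_set <- function(x, ...) {
  cat(sprintf("top_snp_set: %d SNPs beyond %.2f SD (logistic location %.4g, scale %.4g)\n",
              x$n_selected, x$k_sd, x$fit_location, x$fit_scale))
  invisible(x)
}

#' Restricted subject loadings from the top contributing SNPs
#'
#' Multiplies the selected SNPs' component weights by the participants'
#' dosages: `loading_i = sum_j weight_j * dosage_ij` (missing dosages
#' mean-imputed per SNP).  When the full-component loadings are supplied,
#' their Pearson correlation with the restricted loadings is attached.
#'
#' @param top a [select_top_snps()] result (nonempty).
#' @param geno a [genotype_matrix()].
#' @param full_loadings optional full-component subject loading vector.
#' @return Numeric subject loading vector; attribute `cor_full` when
#'   `full_loadings` is given.
#' @export
restricted_loadings <- function(top, geno, full_loadings = NULL) {
  stopifnot(inherits(top, "top_snp_set"), inherits(geno, "genotype_matrix"))
  if (top$n_selected == 0L) stopf("empty top SNP set")
  if (max(top$indices) > ncol(geno$dosages))
    stopf("top SNP indices exceed genotype columns")
  d <- geno$dosages[, top$indices, drop = FALSE]
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  out <- as.numeric(d %*% top$weights)
  names(out) <- geno$subject_ids
  if (!is.null(full_loadings))
    attr(out, "cor_full") <- stats::cor(out, full_loadings)
  out
}
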