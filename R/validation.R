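#' Permutation test of the maximal component-pair correlation
#'
#' Shuffles the subject rows of the genomic modality, reruns the full
#' coupled decomposition on the mismatched data, and records the maximal
#' absolute loading-pair correlation, `n_perm` times.  The reported
#' `ratio_above` is the fraction of null values at or above the observed
#' maximum (the observed run excluded; `smoothed = TRUE` applies the
#' add-one convention instead).
#'
#' Row-permuting a column-centered matrix leaves its subject-space
#' covariance -- hence its whitened representation -- unchanged; only the
#' loading-recovery map is row-permuted.  Both modalities are therefore
#' whitened once and each permutation reruns the full optimizer with the
#' genomic dewhitener rows shuffled, which is algebraically identical to
#' rerunning from the raw shuffled matrix.
#'
#' @param x1,x2,ref,config as in [run_picar()].
#' @param n_perm number of permutations (>= 1); the study-scale convention
#'   is 1000, scaled-down values are accepted.
#' @param seed master seed for the permutation draws; per-permutation
#'   optimizer seeds are derived from it.
#' @param mode `"full"` reruns the decomposition per permutation (the
#'   faithful procedure); `"fixed"` keeps the observed decomposition and
#'   only re-correlates the shuffled loadings -- a fast approximation.
#' @param smoothed use `(count + 1) / (n_perm + 1)` for the ratio.
#' @return An object of class `permutation_result`: `observed_r`,
#'   `null_rs`, `n_perm`, `ratio_above`, `seed`, `mode`.
#' @export
permutation_test <- function(x1, x2, ref = NULL, config = picar_config(),
                             n_perm = 1000, seed = 1L,
                             mode = c("full", "fixed"), smoothed = FALSE) {
  if (!is_count(n_perm)) stopf("n_perm must be a positive integer")
  mode <- match.arg(mode)
  m1 <- .as_modality_matrix(x1)
  m2 <- .as_modality_matrix(x2, genomic = TRUE)
  wh1 <- whiten(m1, config$n_components_1)
  wh2 <- whiten(m2, config$n_components_2)
  observed <- .picar_engine(wh1, wh2, ref, config)
  obs_pair <- select_max_pair(observed)
  n <- nrow(m1)
  null_rs <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    perm <- with_seed(derive_seed(seed, 200000L + b), sample.int(n))
    if (mode == "full") {
      wh2p <- wh2
      wh2p$dewhitener <- wh2$dewhitener[perm, , drop = FALSE]
      cfg <- config
      cfg$seed <- derive_seed(seed, 300000L + b)
      res <- .picar_engine(wh1, wh2p, ref, cfg)
      null_rs[b] <- abs(select_max_pair(res)$r)
    } else {
      cm <- suppressWarnings(stats::cor(observed$a1,
                                        observed$a2[perm, , drop = FALSE]))
      cm[is.na(cm)] <- 0
      null_rs[b] <- max(abs(cm))
    }
  }
  cnt <- sum(null_rs >= abs(obs_pair$r))
  ratio <- if (smoothed) (cnt + 1) / (n_perm + 1) else cnt / n_perm
  structure(list(observed_r = obs_pair$r, observed_pair = obs_pair,
                 null_rs = null_rs, n_perm = as.integer(n_perm),
                 ratio_above = ratio, seed = as.integer(seed), mode = mode),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation_result: observed |r| = %.3f, ratio_above = %.4g (%d perms, %s mode)\n",
              abs(x$observed_r), x$ratio_above, x$n_perm, x$mode))
  invisible(x)
}

#' Leave-N-subjects-out (k-fold) replication of the component pair
#'
#' Partitions subjects into `folds` groups, reruns the decomposition on each
#' complement (90% of the sample for 10 folds), matches the full-run
#' components to the best-correlated fold-run components (by component
#' weight-vector correlation, sign-invariant), and tests whether the matched
#' pair's loading correlation is significant at `alpha` after Bonferroni
#' correction over the pair family.  A tail-driven effect is expected to
#' replicate less often in folds that exclude many tail subjects.
#'
#' @param x1,x2,ref,config as in [run_picar()].
#' @param folds number of folds (>= 2).
#' @param seed partition seed.
#' @param alpha significance level for the replication call.
#' @return A data frame, one row per fold: `fold_id`, `n_subjects_used`,
#'   `comp_1`, `comp_2`, `r`, `p`, `p_bonferroni`, `replicated`,
#'   `similarity_1`, `similarity_2`, `n_tail_excluded` (when the inputs
#'   carry a `tail_subjects` attribute).
#' @export
kfold_validation <- function(x1, x2, ref = NULL, config = picar_config(),
                             folds = 10, seed = 1L, alpha = 0.05) {
  stopifnot(is_count(folds), folds >= 2)
  m1 <- .as_modality_matrix(x1)
  n <- nrow(m1)
  if (n < 2 * folds) stopf("not enough subjects for %d folds", folds)
  full <- run_picar(x1, x2, ref, config)
  full_pair <- select_max_pair(full)
  assignment <- with_seed(derive_seed(seed, 400000L),
                          sample(rep_len(seq_len(folds), n)))
  tails <- attr(x1, "tail_subjects") %||% attr(x2, "tail_subjects") %||%
    integer(0)
  out <- vector("list", folds)
  for (f in seq_len(folds)) {
    use <- which(assignment != f)
    sub1 <- if (inherits(x1, "gmc_matrix")) subset_gmc(x1, use)
            else m1[use, , drop = FALSE]
    sub2 <- if (inherits(x2, "genotype_matrix")) subset_genotypes(x2, use)
            else .as_modality_matrix(x2, TRUE)[use, , drop = FALSE]
    cfg <- config
    cfg$seed <- derive_seed(seed, 500000L + f)
    res <- run_picar(sub1, sub2, ref, cfg)
    # match the full run's max pair to fold components by the loading
    # correlation over the shared subjects (robust when a component's
    # active loci are a small fraction of the panel); the weight-vector
    # similarity of the matched maps is reported alongside
    m1 <- abs(stats::cor(full$a1[use, full_pair$comp_1], res$a1))
    m2 <- abs(stats::cor(full$a2[use, full_pair$comp_2], res$a2))
    i <- which.max(m1); j <- which.max(m2)
    sim1 <- abs(stats::cor(full$s1[full_pair$comp_1, ], res$s1[i, ]))
    sim2 <- abs(stats::cor(full$s2[full_pair$comp_2, ], res$s2[j, ]))
    ps <- pair_stat(i, j, stats::cor(res$a1[, i], res$a2[, j]),
                    length(use), n_pairs = nrow(res$s1) * nrow(res$s2))
    out[[f]] <- data.frame(fold_id = f, n_subjects_used = length(use),
                           comp_1 = i, comp_2 = j, r = ps$r, p = ps$p,
                           p_bonferroni = ps$p_bonferroni,
                           replicated = ps$p_bonferroni < alpha,
                           similarity_1 = sim1,
                           similarity_2 = sim2,
                           n_tail_excluded = sum(assignment[tails] == f))
  }
  do.call(rbind, out)
}

#' Regression influence diagnostics for a loading-pair association
#'
#' Fits the simple regression `y ~ x` of the imaging loading on the genomic
#' loading and reports, per subject, the hat (leverage) value, the
#' externally studentized residual, and Cook's distance, plus the subject's
#' x z-score.  A subject is flagged as a driver of the association when its
#' Cook's distance exceeds `cooks_threshold` (default `4/n`) and its
#' leverage exceeds `leverage_factor` times the mean hat value -- the
#' two-axis rule of the studentized-residual-by-hat influence plot, which
#' confines flags to genuinely high-leverage subjects.
#'
#' @param x_loadings genomic (SNP) component subject loadings.
#' @param y_loadings imaging (GMC) component subject loadings.
#' @param cooks_threshold Cook's distance cutoff; `NULL` uses `4/n`.
#' @param leverage_factor multiple of the mean hat value a flagged subject
#'   must exceed; with the default 3, flagged subjects necessarily have
#'   `|x z-score|` above about 2.2.
#' @param subject_ids optional identifiers.
#' @return A data frame: `subject_id`, `hat`, `studentized_residual`,
#'   `cooks_d`, `snp_loading_z`, `flagged`.
#' @export
influence_analysis <- function(x_loadings, y_loadings,
                               cooks_threshold = NULL, leverage_factor = 3,
                               subject_ids = NULL) {
  n <- length(x_loadings)
  stopifnot(n >= 4L, length(y_loadings) == n)
  if (stats::sd(x_loadings) == 0) stopf("zero variance in x loadings")
  fit <- stats::lm(y_loadings ~ x_loadings)
  hat <- stats::hatvalues(fit)
  rst <- stats::rstudent(fit)
  cd <- stats::cooks.distance(fit)
  cooks_threshold <- cooks_threshold %||% (4 / n)
  flagged <- cd > cooks_threshold & hat > leverage_factor * mean(hat)
  data.frame(subject_id = subject_ids %||% seq_len(n),
             hat = as.numeric(hat),
             studentized_residual = as.numeric(rst),
             cooks_d = as.numeric(cd),
             snp_loading_z = as.numeric(scale(x_loadings)),
             flagged = as.logical(flagged))
}
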