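#' @name genotype_qc
#' @title Genotype quality control
#' @description Missingness filtering, MAF filtering, windowed LD pruning,
#'   method-of-moments relatedness exclusion, and classical-MDS ancestry
#'   factors, mirroring a PLINK-style preprocessing chain for dosage data.
NULL

.qc_report <- function(n_snps_in, n_snps_out, n_subj_in, n_subj_out,
                       dropped_snps = character(0),
                       dropped_subjects = character(0),
                       snp_reasons = character(0),
                       subject_reasons = character(0),
                       parameters = list()) {
  stopifnot(n_snps_out <= n_snps_in, n_subj_out <= n_subj_in)
  structure(list(n_snps_in = n_snps_in, n_snps_out = n_snps_out,
                 n_subjects_in = n_subj_in, n_subjects_out = n_subj_out,
                 dropped_snps = data.frame(id = dropped_snps,
                                           reason = snp_reasons,
                                           stringsAsFactors = FALSE),
                 dropped_subjects = data.frame(id = dropped_subjects,
                                               reason = subject_reasons,
                                               stringsAsFactors = FALSE),
                 parameters = parameters),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: SNPs %d -> %d, subjects %d -> %d\n",
              x$n_snps_in, x$n_snps_out, x$n_subjects_in, x$n_subjects_out))
  invisible(x)
}

#' Filter SNPs and subjects by missingness
#'
#' Iteratively drops SNPs whose missing-call fraction exceeds `max_rate`,
#' then subjects, repeating until stable, so every surviving row and column
#' missing rate is at most `max_rate`.  The default 5% threshold is the
#' conventional per-sample and per-SNP cutoff.
#'
#' @param geno a [genotype_matrix()].
#' @param max_rate maximum tolerated missing fraction in `[0, 1)`.
#' @return `list(genotypes, report)`.
#' @export
filter_missingness <- function(geno, max_rate = 0.05) {
  stopifnot(inherits(geno, "genotype_matrix"),
            max_rate >= 0, max_rate < 1)
  d <- geno$dosages
  keep_snp <- rep(TRUE, ncol(d)); keep_subj <- rep(TRUE, nrow(d))
  repeat {
    m <- is.na(d[keep_subj, keep_snp, drop = FALSE])
    if (!any(dim(m))) stopf("missingness filter removed all data")
    snp_rate <- colMeans(m)
    drop_s <- snp_rate > max_rate
    if (any(drop_s)) {
      keep_snp[keep_snp][drop_s] <- FALSE
      next_m <- is.na(d[keep_subj, keep_snp, drop = FALSE])
    } else next_m <- m
    subj_rate <- rowMeans(next_m)
    drop_u <- subj_rate > max_rate
    if (any(drop_u)) keep_subj[keep_subj][drop_u] <- FALSE
    if (!any(drop_s) && !any(drop_u)) break
    if (!any(keep_snp) || !any(keep_subj))
      stopf("missingness filter removed all data")
  }
  out <- subset_genotypes(geno, which(keep_subj), which(keep_snp))
  rep <- .qc_report(ncol(d), sum(keep_snp), nrow(d), sum(keep_subj),
                    dropped_snps = geno$snp_meta$id[!keep_snp],
                    snp_reasons = rep("missingness", sum(!keep_snp)),
                    dropped_subjects = geno$subject_ids[!keep_subj],
                    subject_reasons = rep("missingness", sum(!keep_subj)),
                    parameters = list(max_rate = max_rate))
  list(genotypes = out, report = rep)
}

#' Filter SNPs by minor allele frequency
#'
#' Keeps SNPs with MAF strictly greater than `min_maf` (so a SNP at exactly
#' the threshold is dropped).  MAF is computed over non-missing calls.
#'
#' @param geno a [genotype_matrix()].
#' @param min_maf threshold in `[0, 0.5)`; default 0.05.
#' @return `list(genotypes, report)`.
#' @export
filter_maf <- function(geno, min_maf = 0.05) {
  stopifnot(inherits(geno, "genotype_matrix"),
            min_maf >= 0, min_maf < 0.5)
  maf <- snp_maf(geno)
  keep <- !is.na(maf) & maf > min_maf
  if (!any(keep)) warning("MAF filter removed every SNP")
  out <- subset_genotypes(geno, snps = which(keep))
  rep <- .qc_report(ncol(geno$dosages), sum(keep),
                    nrow(geno$dosages), nrow(geno$dosages),
                    dropped_snps = geno$snp_meta$id[!keep],
                    snp_reasons = rep("maf", sum(!keep)),
                    parameters = list(min_maf = min_maf))
  list(genotypes = out, report = rep)
}

#' Greedy windowed linkage-disequilibrium pruning
#'
#' Slides a window of `window` SNPs by `step` along each chromosome
#' (windows never span chromosomes).  Within a window, while any retained
#' pair has squared dosage correlation above `r2_max`, the member of the
#' worst pair with the lower MAF is dropped (tie broken by dropping the
#' later position).  After pruning, no retained pair within a window has
#' r-squared above `r2_max`.
#'
#' @param geno a [genotype_matrix()] with SNPs sorted by (chr, pos).
#' @param r2_max squared-correlation ceiling; default 0.5.
#' @param window,step window size and slide, in SNP counts (the PLINK
#'   `--indep-pairwise` convention).
#' @return `list(kept, report)` where `kept` is the index vector of
#'   retained SNPs (relative to the input).
#' @export
ld_prune <- function(geno, r2_max = 0.5, window = 50, step = 5) {
  stopifnot(inherits(geno, "genotype_matrix"))
  meta <- geno$snp_meta
  o <- order(meta$chr, meta$pos)
  if (any(o != seq_along(o)))
    stopf("SNPs must be sorted by (chromosome, position) before LD pruning")
  d <- geno$dosages
  maf <- snp_maf(geno)
  keep <- rep(TRUE, ncol(d))
  for (ch in unique(meta$chr)) {
    idx <- which(meta$chr == ch)
    start <- 1L
    repeat {
      win <- idx[start:min(start + window - 1L, length(idx))]
      win_kept <- win[keep[win]]
      if (length(win_kept) > 1L) {
        r2 <- suppressWarnings(
          stats::cor(d[, win_kept, drop = FALSE],
                     use = "pairwise.complete.obs"))^2
        diag(r2) <- 0
        r2[is.na(r2)] <- 0
        while (max(r2) > r2_max) {
          worst <- which(r2 == max(r2), arr.ind = TRUE)[1L, ]
          a <- win_kept[worst[1]]; b <- win_kept[worst[2]]
          drop <- if (maf[a] < maf[b]) a
                  else if (maf[b] < maf[a]) b
                  else max(a, b)                 # tie: later position
          keep[drop] <- FALSE
          at <- which(win_kept == drop)
          r2[at, ] <- 0; r2[, at] <- 0
        }
      }
      if (start + window - 1L >= length(idx)) break
      start <- start + step
    }
  }
  rep <- .qc_report(ncol(d), sum(keep), nrow(d), nrow(d),
                    dropped_snps = meta$id[!keep],
                    snp_reasons = rep("ld", sum(!keep)),
                    parameters = list(r2_max = r2_max, window = window,
                                      step = step))
  list(kept = which(keep), report = rep)
}

# Per-pair IBS counts via indicator-matrix products; missing calls drop out
# of all indicators, so counts cover co-observed loci only.
.ibs_counts <- function(d) {
  g0 <- (!is.na(d) & d == 0) * 1
  g1 <- (!is.na(d) & d == 1) * 1
  g2 <- (!is.na(d) & d == 2) * 1
  m <- g0 + g1 + g2
  ibs2 <- tcrossprod(g0) + tcrossprod(g1) + tcrossprod(g2)
  ibs0 <- tcrossprod(g0, g2) + tcrossprod(g2, g0)
  tt <- tcrossprod(m)
  list(ibs0 = ibs0, ibs1 = tt - ibs2 - ibs0, ibs2 = ibs2, total = tt)
}

#' Method-of-moments relatedness estimation and exclusion
#'
#' Estimates the identity-by-descent proportion (PI-HAT-style) for every
#' subject pair from identity-by-state counts and allele frequencies:
#' expected IBS rates under IBD states 0/1/2 are accumulated over loci, the
#' IBD state proportions are solved by moments, and `pi_hat = z1/2 + z2`.
#' Pairs above `threshold` are grouped into families and one member per
#' family (the first in subject order) is retained.
#'
#' @param geno a [genotype_matrix()] (post-QC).
#' @param threshold relatedness cutoff; the conventional 0.18.
#' @return `list(pairs, keep)` -- a data frame of all pairs with their
#'   statistic, and a logical keep mask over subjects.
#' @export
estimate_relatedness <- function(geno, threshold = 0.18) {
  stopifnot(inherits(geno, "genotype_matrix"))
  d <- geno$dosages
  n <- nrow(d)
  if (n < 2L)
    return(list(pairs = data.frame(i = integer(0), j = integer(0),
                                   pi_hat = numeric(0)),
                keep = rep(TRUE, n)))
  p <- colMeans(d, na.rm = TRUE) / 2
  q <- 1 - p
  # expected per-locus IBS probabilities conditional on IBD state
  s_ibs0_z0 <- sum(2 * p^2 * q^2)
  s_ibs1_z0 <- sum(4 * p^3 * q + 4 * p * q^3)
  s_ibs1_z1 <- sum(2 * p * q)
  cnt <- .ibs_counts(d)
  ut <- upper.tri(cnt$total)
  frac <- cnt$total[ut] / ncol(d)          # co-observed scaling
  z0 <- cnt$ibs0[ut] / (frac * s_ibs0_z0)
  z1 <- (cnt$ibs1[ut] - z0 * frac * s_ibs1_z0) / (frac * s_ibs1_z1)
  z0 <- pmin(pmax(z0, 0), 1)
  z1 <- pmin(pmax(z1, 0), 1 - z0)
  z2 <- 1 - z0 - z1
  pi_hat <- z1 / 2 + z2
  ij <- which(ut, arr.ind = TRUE)
  pairs <- data.frame(i = ij[, 1], j = ij[, 2], pi_hat = pi_hat)
  keep <- rep(TRUE, n)
  rel <- pairs[pairs$pi_hat > threshold, , drop = FALSE]
  if (nrow(rel)) {
    # union-find family grouping; keep the first member by subject order
    fam <- seq_len(n)
    find <- function(x) { while (fam[x] != x) x <- fam[x]; x }
    for (r in seq_len(nrow(rel))) {
      a <- find(rel$i[r]); b <- find(rel$j[r])
      fam[max(a, b)] <- min(a, b)
    }
    roots <- vapply(seq_len(n), find, integer(1))
    in_family <- roots %in% roots[c(rel$i, rel$j)]
    keep <- !(in_family & seq_len(n) != roots)
  }
  list(pairs = pairs, keep = keep)
}

#' Classical multidimensional-scaling ancestry factors
#'
#' Double-centred eigendecomposition (classical MDS via [stats::cmdscale()])
#' of the pairwise allele-sharing distance matrix
#' `1 - (IBS2 + IBS1/2)/loci`.  Columns are ordered by eigenvalue and are
#' deterministic up to sign; the conventional top 10 factors are the
#' population-structure covariates.
#'
#' @param geno a [genotype_matrix()].
#' @param k number of factors; must be at most `subjects - 1`.
#' @return Subjects-by-`k` coordinate matrix.
#' @export
mds_factors <- function(geno, k = 10) {
  stopifnot(inherits(geno, "genotype_matrix"), is_count(k))
  n <- nrow(geno$dosages)
  if (k > n - 1L) stopf("k = %d exceeds subjects - 1 = %d", k, n - 1L)
  cnt <- .ibs_counts(geno$dosages)
  sim <- (cnt$ibs2 + 0.5 * cnt$ibs1) / pmax(cnt$total, 1)
  dmat <- 1 - sim
  diag(dmat) <- 0
  coords <- stats::cmdscale(stats::as.dist(dmat), k = k)
  if (ncol(coords) < k)   # degenerate geometry: pad with zero coordinates
    coords <- cbind(coords, matrix(0, n, k - ncol(coords)))
  rownames(coords) <- geno$subject_ids
  coords
}

#' Run the full genotype QC chain
#'
#' Missingness (SNP-level then sample-level), MAF, LD pruning, relatedness
#' exclusion -- the PLINK-conventional ordering.
#'
#' @param geno a [genotype_matrix()].
#' @param max_missing,min_maf,ld_r2,ld_window,ld_step,relatedness stage
#'   thresholds.
#' @param mds_k number of MDS factors to compute (0 to skip).
#' @return `list(genotypes, mds, reports)` where `reports` is a named list
#'   of per-stage [print.qc_report()] objects.
#' @export
genotype_qc_pipeline <- function(geno, max_missing = 0.05, min_maf = 0.05,
                                 ld_r2 = 0.5, ld_window = 50, ld_step = 5,
                                 relatedness = 0.18, mds_k = 10) {
  st1 <- filter_missingness(geno, max_missing)
  st2 <- filter_maf(st1$genotypes, min_maf)
  st3 <- ld_prune(st2$genotypes, ld_r2, ld_window, ld_step)
  g <- subset_genotypes(st2$genotypes, snps = st3$kept)
  rel <- estimate_relatedness(g, relatedness)
  g2 <- subset_genotypes(g, subjects = which(rel$keep))
  mds <- if (mds_k > 0) mds_factors(g2, min(mds_k, nrow(g2$dosages) - 1L))
         else NULL
  list(genotypes = g2, mds = mds,
       reports = list(missingness = st1$report, maf = st2$report,
                      ld = st3$report,
                      relatedness = list(pairs = rel$pairs,
                                         kept = which(rel$keep))))
}
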