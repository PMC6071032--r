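# Small hand-constructable genotype fixtures.
toy_geno <- function(d, chr = NULL, pos = NULL) {
  p <- ncol(d)
  genotype_matrix(d, data.frame(id = sprintf("s%03d", seq_len(p)),
                                chr = chr %||% rep(1L, p),
                                pos = pos %||% seq_len(p) * 1000L,
                                a1 = "A", a2 = "G"))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("missingness filter drops offenders and matches an exhaustive oracle", {
  set.seed(42)
  d <- matrix(sample(0:2, 20 * 30, TRUE), 20, 30)
  d[1, sample(30, 2)] <- NA              # subject 1: 6.7% missing
  d[, 5][sample(20, 3)] <- NA            # SNP 5: 15% missing
  g <- toy_geno(d)
  res <- filter_missingness(g, 0.05)
  m <- is.na(res$genotypes$dosages)
  expect_true(all(colMeans(m) <= 0.05))
  expect_true(all(rowMeans(m) <= 0.05))
  # oracle: recompute rates on the survivors against the original matrix
  kept_snps <- match(res$genotypes$snp_meta$id, g$snp_meta$id)
  kept_subj <- match(res$genotypes$subject_ids, g$subject_ids)
  expect_true(all(colMeans(is.na(d[kept_subj, kept_snps])) <= 0.05))
  expect_false("s005" %in% res$genotypes$snp_meta$id)
})

test_that("a subject missing 6% of calls is dropped at the 5% threshold", {
  set.seed(1)
  d <- matrix(sample(0:2, 50 * 100, TRUE), 50, 100)
  d[7, 1:6] <- NA
  res <- filter_missingness(toy_geno(d), 0.05)
  expect_false("S0007" %in% res$genotypes$subject_ids)
  expect_identical(res$report$n_subjects_out, 49L)
})

test_that("missingness filter is the identity on complete data and idempotent", {
  set.seed(2)
  g <- toy_geno(matrix(sample(0:2, 200, TRUE), 10, 20))
  res <- filter_missingness(g, 0.05)
  expect_identical(res$genotypes$dosages, g$dosages)
  d <- matrix(sample(0:2, 600, TRUE), 20, 30)
  d[sample(600, 60)] <- NA
  once <- filter_missingness(toy_geno(d), 0.1)
  twice <- filter_missingness(once$genotypes, 0.1)
  expect_identical(once$genotypes$dosages, twice$genotypes$dosages)
})

test_that("MAF filter uses a strict threshold and hand-counted frequencies", {
  d <- matrix(0L, 10, 3)
  d[1, 2] <- 1L                     # SNP 2: 1 minor allele / 20 = MAF 0.05
  d[, 3] <- rep(c(0L, 1L), 5)       # SNP 3: MAF 0.25
  res <- filter_maf(toy_geno(d), 0.05)
  expect_identical(res$genotypes$snp_meta$id, "s003")  # monomorphic + 0.05 dropped
  expect_setequal(res$report$dropped_snps$id, c("s001", "s002"))
  expect_true(filter_maf(toy_geno(d), 0.04)$report$n_snps_out == 2L)
})

test_that("MAF filter is idempotent and never increases counts", {
  co <- small_cohort()
  once <- filter_maf(co$genotypes, 0.2)
  twice <- filter_maf(once$genotypes, 0.2)
  expect_identical(once$genotypes$dosages, twice$genotypes$dosages)
  expect_lte(once$report$n_snps_out, once$report$n_snps_in)
})

test_that("LD pruning keeps one of a duplicated pair and all independent SNPs", {
  set.seed(3)
  x <- sample(0:2, 200, TRUE, prob = c(.49, .42, .09))
  d <- cbind(x, x, sample(0:2, 200, TRUE), sample(0:2, 200, TRUE))
  res <- ld_prune(toy_geno(d), 0.5, window = 10, step = 2)
  expect_identical(length(res$kept), 3L)
  expect_true(3 %in% res$kept && 4 %in% res$kept)
  set.seed(4)
  ind <- matrix(sample(0:2, 100 * 10, TRUE), 100, 10)
  expect_identical(ld_prune(toy_geno(ind), 0.5, 10, 2)$kept, 1:10)
})

test_that("pruned sets pass a brute-force all-pairs r-squared scan", {
  sp <- cohort_spec(n_subjects = 300, n_snps = 50, ld_block_size = 5,
                    ld_block_rho = 0.9, missing_rate = 0.01,
                    n_related_pairs = 0, n_voxels = 27,
                    grid_shape = c(3, 3, 3), seed = 6)
  g <- generate_genotypes(sp)
  res <- ld_prune(g, 0.5, window = 50, step = 5)
  kept <- g$dosages[, res$kept, drop = FALSE]
  r2 <- suppressWarnings(cor(kept, use = "pairwise.complete.obs"))^2
  diag(r2) <- 0
  expect_lte(max(r2, na.rm = TRUE), 0.5)
  # pruning an already pruned panel changes nothing
  g2 <- subset_genotypes(g, snps = res$kept)
  expect_identical(ld_prune(g2, 0.5, 50, 5)$kept, seq_along(res$kept))
})

test_that("LD pruning rejects unsorted input", {
  d <- matrix(sample(0:2, 40, TRUE), 10, 4)
  g <- toy_geno(d, pos = c(4000L, 1000L, 2000L, 3000L))
  expect_error(ld_prune(g, 0.5), "sorted")
})

test_that("a duplicated subject is detected as related and one copy kept", {
  set.seed(5)
  d <- matrix(sample(0:2, 40 * 500, TRUE, prob = c(.36, .48, .16)), 40, 500)
  d[2, ] <- d[1, ]
  rel <- estimate_relatedness(toy_geno(d), 0.18)
  dup <- rel$pairs[rel$pairs$i == 1 & rel$pairs$j == 2, ]
  expect_gt(dup$pi_hat, 0.9)
  expect_true(rel$keep[1])
  expect_false(rel$keep[2])
})

test_that("relatedness statistics of independent subjects stay below 0.18", {
  sp <- cohort_spec(n_subjects = 200, n_snps = 3000, ld_block_rho = 0,
                    missing_rate = 0, n_related_pairs = 0, n_voxels = 27,
                    grid_shape = c(3, 3, 3), seed = 7)
  g <- generate_genotypes(sp)
  rel <- estimate_relatedness(g, 0.18)
  expect_lt(quantile(rel$pairs$pi_hat, 0.999), 0.18)
  expect_true(all(rel$keep))
})

test_that("planted related pairs are removed by the QC chain", {
  co <- small_cohort()
  qc <- genotype_qc_pipeline(co$genotypes, mds_k = 0)
  rel <- co$related_pairs
  kept <- qc$genotypes$subject_ids
  for (r in seq_len(nrow(rel)))
    expect_lt(sum(co$genotypes$subject_ids[rel[r, ]] %in% kept), 2L)
})

test_that("MDS factor 1 separates planted subpopulations", {
  set.seed(8)
  n <- 80; p <- 600
  pop <- rep(0:1, each = n / 2)
  maf <- cbind(runif(p, 0.05, 0.5), runif(p, 0.05, 0.5))
  d <- sapply(seq_len(p), function(j)
    rbinom(n, 2, maf[j, pop + 1]))
  coords <- mds_factors(toy_geno(d), 2)
  expect_gt(abs(cor(coords[, 1], pop)), 0.9)
})

test_that("identical subjects receive identical MDS coordinates", {
  set.seed(9)
  d <- matrix(sample(0:2, 30 * 200, TRUE), 30, 200)
  d[4, ] <- d[3, ]
  coords <- mds_factors(toy_geno(d), 3)
  expect_equal(coords[3, ], coords[4, ], tolerance = 1e-8)
  expect_error(mds_factors(toy_geno(d), 30), "exceeds")
})

test_that("the QC chain never increases SNP or subject counts", {
  co <- small_cohort()
  qc <- genotype_qc_pipeline(co$genotypes)
  expect_lte(ncol(qc$genotypes$dosages), ncol(co$genotypes$dosages))
  expect_lte(nrow(qc$genotypes$dosages), nrow(co$genotypes$dosages))
  expect_identical(ncol(qc$mds), 10L)
})
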