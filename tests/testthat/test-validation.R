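# Tiny cohorts sized so that full decompositions rerun quickly inside
# permutation and fold loops.
tiny_spec <- function(seed, rho = 0.5, ...) {
  cohort_spec(n_subjects = 70, n_snps = 160, n_voxels = 180,
              n_components_snp = 3, n_components_gmc = 3, n_sites = 3,
              n_tail_subjects = 7, n_related_pairs = 0,
              coupled_pair_rho = rho, seed = seed, ...)
}
tiny_config <- function(seed = 1, max_iter = 50, ...) {
  picar_config(n_components_1 = 3, n_components_2 = 3, max_iter = max_iter,
               seed = seed, ...)
}

test_that("permutation ratio is the fraction of null values at or above the observed", {
  co <- generate_coupled_cohort(tiny_spec(31))
  pt <- permutation_test(co$gmc, co$genotypes, NULL, tiny_config(),
                         n_perm = 30, seed = 2)
  expect_identical(pt$ratio_above,
                   mean(pt$null_rs >= abs(pt$observed_r)))
  expect_length(pt$null_rs, 30L)
  sm <- permutation_test(co$gmc, co$genotypes, NULL, tiny_config(),
                         n_perm = 10, seed = 2, mode = "fixed",
                         smoothed = TRUE)
  expect_identical(sm$ratio_above,
                   (sum(sm$null_rs >= abs(sm$observed_r)) + 1) / 11)
})

test_that("a strong embedded coupling is never matched by mismatched subjects", {
  co <- generate_coupled_cohort(tiny_spec(32, rho = 0.8))
  pt <- permutation_test(co$gmc, co$genotypes, NULL, tiny_config(),
                         n_perm = 40, seed = 3)
  expect_gt(abs(pt$observed_r), 0.5)
  expect_identical(pt$ratio_above, 0)
})

test_that("permuting either modality yields comparable null distributions", {
  co <- generate_coupled_cohort(tiny_spec(33, rho = 0))
  cfg <- tiny_config()
  pt2 <- permutation_test(co$gmc, co$genotypes, NULL, cfg,
                          n_perm = 60, seed = 4, mode = "fixed")
  # permute modality 1 instead: swap the roles of the two modalities
  pt1 <- permutation_test(co$genotypes, co$gmc, NULL, cfg,
                          n_perm = 60, seed = 5, mode = "fixed")
  ks <- suppressWarnings(ks.test(pt1$null_rs, pt2$null_rs))
  expect_gt(ks$p.value, 0.01)
})

test_that("permutation p-values are uniform under the null", {
  # 16 independent no-effect cohorts; empirical p from 40 permutations each
  pvals <- vapply(1:16, function(s) {
    co <- generate_coupled_cohort(tiny_spec(100 + s, rho = 0))
    pt <- permutation_test(co$gmc, co$genotypes, NULL,
                           tiny_config(seed = s), n_perm = 40,
                           seed = 50 + s, smoothed = TRUE)
    pt$ratio_above
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  # type-I control at alpha = 0.1: few rejections across null cohorts
  expect_lte(mean(pvals <= 0.1), 0.35)
})

test_that("k-fold arithmetic uses the complement of each fold", {
  co <- generate_coupled_cohort(tiny_spec(34, rho = 0.6))
  # folds = 2 on an even cohort: each run uses exactly half the subjects
  fr <- kfold_validation(co$gmc, co$genotypes, NULL, tiny_config(),
                         folds = 2, seed = 6)
  expect_identical(fr$n_subjects_used, rep(35L, 2))
  fr10 <- kfold_validation(co$gmc, co$genotypes, NULL, tiny_config(),
                           folds = 10, seed = 6)
  expect_true(all(abs(fr10$n_subjects_used - 0.9 * 70) <= 1))
})

test_that("a strong bulk (non-tail) effect replicates in every fold", {
  sp <- cohort_spec(n_subjects = 220, n_snps = 600, n_voxels = 600,
                    n_components_snp = 3, n_components_gmc = 3,
                    n_sites = 4, n_related_pairs = 0,
                    coupled_pair_rho = 0.7, tail_driven = FALSE, seed = 35)
  co <- generate_coupled_cohort(sp)
  gmc_r <- residualize_voxels(co$gmc, co$covariates)
  fr <- kfold_validation(gmc_r, co$genotypes, NULL,
                         tiny_config(max_iter = 150), folds = 5, seed = 7)
  expect_true(all(fr$replicated))
})

test_that("tail-driven effects weaken in folds that shed tail subjects", {
  sp <- cohort_spec(n_subjects = 200, n_snps = 300, n_voxels = 300,
                    n_components_snp = 3, n_components_gmc = 3,
                    n_sites = 4, n_tail_subjects = 20, n_related_pairs = 0,
                    coupled_pair_rho = 0.35, seed = 36)
  co <- generate_coupled_cohort(sp)
  x1 <- residualize_voxels(co$gmc, co$covariates)
  attr(x1, "tail_subjects") <- co$tail_subjects
  fr <- kfold_validation(x1, co$genotypes, NULL,
                         tiny_config(max_iter = 150), folds = 10, seed = 8)
  lo <- fr$n_tail_excluded <= median(fr$n_tail_excluded)
  expect_gt(mean(abs(fr$r[lo])), mean(abs(fr$r[!lo])))
})

test_that("hat values follow the closed form and sum to the parameter count", {
  set.seed(37)
  x <- rnorm(25); x[1] <- mean(x[-1]) * (25 - 0) / 24  # put subject 1 at the mean
  x[1] <- (sum(x[-1])) / 24  # x1 = mean of others => x1 = xbar
  y <- 0.5 * x + rnorm(25)
  inf <- influence_analysis(x, y)
  expect_equal(sum(inf$hat), 2, tolerance = 1e-12)
  expect_lte(max(inf$hat), 1)
  hand <- 1 / 25 + (x - mean(x))^2 / sum((x - mean(x))^2)
  expect_equal(inf$hat, hand, tolerance = 1e-12)
  expect_equal(inf$hat[1], 1 / 25, tolerance = 1e-12)
})

test_that("Cook's distance equals the delete-one refit oracle", {
  set.seed(38)
  n <- 30
  x <- rnorm(n); y <- 1 + 0.4 * x + rnorm(n)
  inf <- influence_analysis(x, y)
  fit <- lm(y ~ x)
  mse <- sum(residuals(fit)^2) / (n - 2)
  oracle <- vapply(seq_len(n), function(i) {
    f2 <- lm(y[-i] ~ x[-i])
    yhat_full <- fitted(fit)
    yhat_drop <- cbind(1, x) %*% coef(f2)
    sum((yhat_full - yhat_drop)^2) / (2 * mse)
  }, numeric(1))
  expect_equal(inf$cooks_d, oracle, tolerance = 1e-10)
})

test_that("flagged influence subjects on the tail-driven preset are tail subjects", {
  sp <- predict_hd_spec(seed = 9, n_snps = 60, n_voxels = 27,
                        grid_shape = c(3, 3, 3))
  co <- generate_coupled_cohort(sp)
  inf <- influence_analysis(co$truth_a2[, 1], co$truth_a1[, 1])
  expect_gt(sum(inf$flagged), 0L)
  expect_true(all(abs(inf$snp_loading_z[inf$flagged]) >= 2))
  expect_error(influence_analysis(rep(1, 10), rnorm(10)), "variance")
})
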