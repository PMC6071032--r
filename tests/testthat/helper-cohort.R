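# Shared fixtures, generated in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# A small but structurally complete cohort for module tests.
small_spec <- function(seed = 3, coupled_pair_rho = 0.45, ...) {
  cohort_spec(n_subjects = 120, n_snps = 400, n_voxels = 500,
              n_components_snp = 4, n_components_gmc = 4,
              n_sites = 6, n_tail_subjects = 10, n_related_pairs = 2,
              coupled_pair_rho = coupled_pair_rho, seed = seed, ...)
}

small_cohort <- function(seed = 3) {
  cached(paste0("small_cohort_", seed), generate_coupled_cohort(small_spec(seed)))
}

# Config sized for small cohorts.
small_config <- function(seed = 5, ...) {
  picar_config(n_components_1 = 4, n_components_2 = 4,
               max_iter = 120, seed = seed, ...)
}

# Amari index between an estimated and a true source set, computed from the
# cross-correlation of the component rows (permutation- and scale-invariant).
amari_index <- function(s_est, s_true) {
  p <- abs(stats::cor(t(s_est), t(s_true)))
  k <- nrow(p)
  ri <- sum(sweep(p, 1L, apply(p, 1L, max), "/")) - k
  ci <- sum(sweep(p, 2L, apply(p, 2L, max), "/")) - k
  (ri + ci) / (2 * k * (k - 1))
}

# Super-Gaussian random sources (Laplace-like) for recovery tests.
supergaussian_sources <- function(k, p) {
  matrix(stats::rexp(k * p) * sample(c(-1, 1), k * p, TRUE), k, p)
}

# The study-emulation analysis chain: generate, QC, residualize, decompose.
preset_analysis <- function(seed, n_snps = 5000, n_voxels = 8000,
                            config = NULL) {
  sp <- predict_hd_spec(seed = seed, n_snps = n_snps, n_voxels = n_voxels)
  co <- generate_coupled_cohort(sp)
  qc <- genotype_qc_pipeline(co$genotypes, mds_k = 0)
  subj <- match(qc$genotypes$subject_ids, co$covariates$subject_id)
  gmc_r <- residualize_voxels(subset_gmc(co$gmc, subj),
                              co$covariates[subj, , drop = FALSE])
  ref <- remap_reference(cohort_reference(co),
                         co$genotypes$snp_meta$id,
                         qc$genotypes$snp_meta$id)
  cfg <- config %||% picar_config(seed = seed)
  cfg$seed <- seed
  list(cohort = co, qc = qc, gmc = gmc_r, ref = ref, config = cfg,
       subjects = subj)
}

# Five-seed coupled-pair recovery on the full preset, cached so the
# recovery and significance checks share one computation.
preset_recovery <- function() {
  cached("preset_recovery", {
    lapply(1:5, function(s) {
      an <- preset_analysis(s)
      dec <- run_picar(an$gmc, an$qc$genotypes, an$ref, an$config)
      select_max_pair(dec)
    })
  })
}
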