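#' Specification of a synthetic imaging-genetics cohort
#'
#' Collects every knob of the generator: cohort size, genotype structure
#' (MAF range, LD blocks, relatedness, missingness), the embedded coupled
#' component pair (target loading correlation, tail-driven mixture), scanner
#' sites, clinical effect sizes and the CAG-repeat distribution.  Defaults
#' are the `predict_hd` study-emulation preset values; see
#' [predict_hd_spec()].
#'
#' @param n_subjects,n_snps,n_voxels cohort dimensions.
#' @param n_components_snp,n_components_gmc number of latent components
#'   planted per modality.
#' @param coupled_pair_rho target Pearson correlation between the coupled
#'   pair of subject-loading columns, in `[-1, 1]`.
#' @param tail_driven if `TRUE`, the coupling is carried entirely by
#'   `n_tail_subjects` subjects with extreme SNP-loading values; the bulk of
#'   the cohort is uncorrelated by construction.
#' @param n_tail_subjects number of tail subjects.
#' @param tail_z_range interval (in SD units) from which tail SNP-loading
#'   magnitudes are drawn.  The lower bound is kept slightly above 2 so that
#'   after standardization the planted tails are exactly the subjects with
#'   `|z| >= 2`.
#' @param maf_range interval in `(0, 0.5]` for per-SNP minor allele
#'   frequencies.
#' @param ld_block_size,ld_block_rho SNPs per LD block and the latent
#'   within-block correlation.
#' @param n_sites number of site/scanner combinations.
#' @param n_related_pairs number of planted related subject pairs (latent
#'   genotype background copied with small perturbation).
#' @param missing_rate fraction of genotype calls set missing.
#' @param clinical_effect_f target F-statistic for the linear dependence of
#'   each clinical measure on the coupled GMC loading.
#' @param clinical_missing_rate per-measure missingness fraction.
#' @param cag_mean,cag_sd,cag_min CAG-repeat distribution (normal truncated
#'   at `cag_min`, rounded to integers).
#' @param grid_shape 3-D voxel grid dimensions; derived from `n_voxels` when
#'   `NULL` (scaled from a 30 x 36 x 30 grid holding 8,000 in-mask voxels).
#' @param gmc_baseline,gmc_signal_sd,gmc_noise_sd GMC signal model scales:
#'   baseline concentration, component amplitude, and additive noise SD.
#' @param snp_signal_var mean share of a signal SNP's latent variance
#'   carried by the planted components.
#' @param n_active_coupled,n_active_other number of nonzero SNP weights in
#'   the coupled and the remaining SNP components; `NULL` scales them with
#'   the panel (4% and 3% of `n_snps`).
#' @param seed integer master seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 715, n_snps = 5000, n_voxels = 8000,
                        n_components_snp = 8, n_components_gmc = 8,
                        coupled_pair_rho = 0.17, tail_driven = TRUE,
                        n_tail_subjects = 28, tail_z_range = c(2.3, 4.0),
                        maf_range = c(0.10, 0.50),
                        ld_block_size = 10, ld_block_rho = 0.30,
                        n_sites = 50, n_related_pairs = 4,
                        missing_rate = 0.01,
                        clinical_effect_f = 5.5,
                        clinical_missing_rate = 0.057,
                        cag_mean = 42.5, cag_sd = 2.5, cag_min = 36,
                        grid_shape = NULL,
                        gmc_baseline = 0.55, gmc_signal_sd = 0.08,
                        gmc_noise_sd = 0.03,
                        snp_signal_var = 0.45,
                        n_active_coupled = NULL, n_active_other = NULL,
                        seed = 1L) {
  for (nm in c("n_subjects", "n_snps", "n_voxels", "n_components_snp",
               "n_components_gmc", "n_sites"))
    if (!is_count(get(nm))) stopf("%s must be a positive integer", nm)
  if (abs(coupled_pair_rho) > 1) stopf("coupled_pair_rho must be in [-1, 1]")
  if (n_tail_subjects > n_subjects)
    stopf("n_tail_subjects (%d) exceeds n_subjects (%d)",
          n_tail_subjects, n_subjects)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stopf("maf_range must lie within (0, 0.5]")
  if (missing_rate < 0 || missing_rate >= 1) stopf("missing_rate in [0, 1)")
  if (is.null(grid_shape)) {
    sc <- (n_voxels / 8000)^(1 / 3)
    grid_shape <- pmax(4L, as.integer(ceiling(c(30, 36, 30) * sc)))
  }
  if (prod(grid_shape) < n_voxels)
    stopf("grid %s holds fewer voxels than n_voxels = %d",
          paste(grid_shape, collapse = "x"), n_voxels)
  # active SNP counts scale with the panel so the component eigenvalue gap
  # and the fraction of structured columns stay constant across desk scales
  n_active_coupled <- n_active_coupled %||% max(20L, round(0.04 * n_snps))
  n_active_other <- n_active_other %||% max(15L, round(0.03 * n_snps))
  spec <- list(n_subjects = as.integer(n_subjects),
               n_snps = as.integer(n_snps), n_voxels = as.integer(n_voxels),
               n_components_snp = as.integer(n_components_snp),
               n_components_gmc = as.integer(n_components_gmc),
               coupled_pair_rho = coupled_pair_rho,
               tail_driven = isTRUE(tail_driven),
               n_tail_subjects = as.integer(n_tail_subjects),
               tail_z_range = tail_z_range, maf_range = maf_range,
               ld_block_size = as.integer(ld_block_size),
               ld_block_rho = ld_block_rho, n_sites = as.integer(n_sites),
               n_related_pairs = as.integer(n_related_pairs),
               missing_rate = missing_rate,
               clinical_effect_f = clinical_effect_f,
               clinical_missing_rate = clinical_missing_rate,
               cag_mean = cag_mean, cag_sd = cag_sd, cag_min = cag_min,
               grid_shape = as.integer(grid_shape),
               gmc_baseline = gmc_baseline, gmc_signal_sd = gmc_signal_sd,
               gmc_noise_sd = gmc_noise_sd, snp_signal_var = snp_signal_var,
               n_active_coupled = as.integer(n_active_coupled),
               n_active_other = as.integer(n_active_other),
               seed = as.integer(seed))
  structure(spec, class = "cohort_spec")
}

#' The prodromal Huntington disease study-emulation preset
#'
#' Fixes the cohort structure to the published study sample: 715
#' expansion-positive subjects scanned under 50 site/scanner combinations,
#' a tail-driven coupled SNP-GMC component pair with loading correlation
#' 0.17 carried by 28 subjects with SNP-component values 2-4 SD from the
#' mean, and CAG repeats ~ N(42.5, 2.5^2) truncated at 36.
#'
#' @param seed master seed.
#' @param n_snps,n_voxels desk-scale dimensions (defaults 5,000 SNPs and
#'   8,000 in-mask voxels; reduce for faster runs).
#' @param ... further overrides passed to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
predict_hd_spec <- function(seed = 1L, n_snps = 5000, n_voxels = 8000, ...) {
  cohort_spec(n_subjects = 715, n_snps = n_snps, n_voxels = n_voxels,
              coupled_pair_rho = 0.17, tail_driven = TRUE,
              n_tail_subjects = 28, n_sites = 50,
              cag_mean = 42.5, cag_sd = 2.5, cag_min = 36,
              seed = seed, ...)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0("cohort_spec: %d subjects, %d SNPs, %d voxels, ",
                     "rho = %.2f (%s), seed = %d\n"),
              x$n_subjects, x$n_snps, x$n_voxels, x$coupled_pair_rho,
              if (x$tail_driven) sprintf("tail-driven, %d tails",
                                         x$n_tail_subjects) else "bulk",
              x$seed))
  invisible(x)
}

# ---- internal generator pieces ---------------------------------------------

# SNP map: chromosome, position, LD block id.
.snp_map <- function(spec) {
  p <- spec$n_snps
  # spread SNPs over up to 22 chromosomes, but never so thinly that LD
  # blocks are broken up on small panels
  per_chr <- max(spec$ld_block_size * 5L, ceiling(p / 22))
  chr <- ceiling(seq_len(p) / per_chr)
  within <- seq_len(p) - (chr - 1L) * per_chr
  pos <- within * 5000L + 100000L
  # LD blocks never span chromosomes
  block <- (within - 1L) %/% spec$ld_block_size
  block <- as.integer(factor(paste(chr, block)))
  data.frame(id = sprintf("rs%07d", seq_len(p)), chr = chr, pos = pos,
             a1 = "A", a2 = "G", block = block,
             stringsAsFactors = FALSE)
}

# Latent Gaussian genotype background with LD-block structure, relatedness
# copies applied; per-SNP MAF drawn from maf_range.  Stream 1 of the seed.
.latent_background <- function(spec) {
  n <- spec$n_subjects; p <- spec$n_snps
  map <- .snp_map(spec)
  with_seed(derive_seed(spec$seed, 1L), {
    maf <- stats::runif(p, spec$maf_range[1], spec$maf_range[2])
    rho <- spec$ld_block_rho
    z <- matrix(stats::rnorm(n * p), n, p)
    if (rho > 0) {
      u <- matrix(stats::rnorm(n * max(map$block)), n)
      z <- sqrt(rho) * u[, map$block, drop = FALSE] + sqrt(1 - rho) * z
    }
    related <- NULL
    if (spec$n_related_pairs > 0 && n >= 2 * spec$n_related_pairs + 2) {
      k <- spec$n_related_pairs
      src <- n - 2L * seq_len(k) + 1L
      rel <- src + 1L
      rr <- 0.95
      z[rel, ] <- rr * z[src, ] +
        sqrt(1 - rr^2) * matrix(stats::rnorm(k * p), k, p)
      related <- cbind(source = src, relative = rel)
    }
    list(latent = z, maf = maf, map = map, related_pairs = related)
  })
}

# Hardy-Weinberg thresholding of a unit-variance latent to 0/1/2 dosages.
.threshold_dosages <- function(latent, maf) {
  q0 <- stats::qnorm((1 - maf)^2)      # below: major homozygote (dosage 0)
  q1 <- stats::qnorm(1 - maf^2)        # above: minor homozygote (dosage 2)
  d <- sweep(latent, 2L, q0, ">") + sweep(latent, 2L, q1, ">")
  storage.mode(d) <- "integer"
  d
}

# Missingness mask, stream 2: depends only on dimensions and rate.
.plant_missing <- function(d, spec) {
  if (spec$missing_rate <= 0) return(d)
  with_seed(derive_seed(spec$seed, 2L), {
    idx <- which(stats::runif(length(d)) < spec$missing_rate)
    d[idx] <- NA_integer_
    d
  })
}

#' Generate a genotype matrix with LD-block and Hardy-Weinberg structure
#'
#' Dosages are drawn per LD block: a latent Gaussian with within-block
#' correlation `ld_block_rho` is thresholded at the Hardy-Weinberg genotype
#' frequencies of a per-SNP MAF drawn uniformly from `maf_range`.  Related
#' pairs copy a subject's latent vector with small perturbation; missing
#' calls are planted at `missing_rate`.
#'
#' @param spec a [cohort_spec()].
#' @return A [genotype_matrix()] with a `related_pairs` attribute.
#' @export
generate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  bg <- .latent_background(spec)
  d <- .plant_missing(.threshold_dosages(bg$latent, bg$maf), spec)
  g <- genotype_matrix(d, bg$map[c("id", "chr", "pos", "a1", "a2")])
  attr(g, "related_pairs") <- bg$related_pairs
  attr(g, "maf_drawn") <- bg$maf
  g
}

# Place the nine reference genes as contiguous, non-overlapping SNP runs.
# Counts are scaled down proportionally when the SNP panel is small.
.place_reference_genes <- function(spec) {
  counts <- reference_gene_counts()
  if (spec$n_snps < 4L * sum(counts)) {
    scaled <- pmax(1L, as.integer(round(counts * spec$n_snps /
                                          (4 * sum(counts)))))
    names(scaled) <- names(counts)
    counts <- scaled
  }
  with_seed(derive_seed(spec$seed, 4L), {
    p <- spec$n_snps
    taken <- logical(p)
    genes <- list()
    for (nm in names(counts)) {
      m <- counts[[nm]]
      repeat {
        start <- sample.int(p - m + 1L, 1L)
        idx <- start:(start + m - 1L)
        if (!any(taken[idx])) break
      }
      taken[idx] <- TRUE
      genes[[nm]] <- idx
    }
    genes
  })
}

# Sparse heavy-tailed SNP component weights (stream 4, after gene placement
# which shares the stream deterministically via a fresh derive).
.build_snp_components <- function(spec, genes) {
  k <- spec$n_components_snp; p <- spec$n_snps
  with_seed(derive_seed(spec$seed, 5L), {
    s2 <- matrix(0, k, p)
    ntrk2 <- genes[["NTRK2"]]
    n_act <- min(spec$n_active_coupled, p)
    mags <- sort(0.8 + stats::rexp(n_act, rate = 2.5), decreasing = TRUE)
    # four reference-gene SNPs among the ten largest |weights|
    ref_ranks <- c(2L, 3L, 7L, 9L)
    ref_snps <- if (length(ntrk2) >= 4L) sample(ntrk2, 4L) else ntrk2
    ref_ranks <- ref_ranks[seq_along(ref_snps)]
    other_ranks <- setdiff(seq_len(n_act), ref_ranks)
    pool <- setdiff(seq_len(p), unlist(genes))
    other_snps <- sample(pool, length(other_ranks))
    active <- integer(n_act)
    active[ref_ranks] <- ref_snps
    active[other_ranks] <- other_snps
    signs <- c(rep(1, min(10L, n_act)),
               sample(c(-1, 1), max(0L, n_act - 10L), replace = TRUE))
    s2[1L, active] <- signs * mags
    for (j in seq_len(k)[-1]) {
      na <- min(spec$n_active_other, p)
      idx <- sample(pool, na)
      s2[j, idx] <- sample(c(-1, 1), na, TRUE) * (0.8 + stats::rexp(na, 3))
    }
    # scale so an active SNP carries snp_signal_var of its latent variance
    for (j in seq_len(k)) {
      act <- s2[j, ] != 0
      if (any(act)) {
        sc <- sqrt(spec$snp_signal_var / mean(s2[j, act]^2))
        s2[j, ] <- s2[j, ] * sc
      }
    }
    # cap total per-SNP signal variance
    v <- colSums(s2^2)
    over <- v > 0.75
    if (any(over))
      s2[, over] <- sweep(s2[, over, drop = FALSE], 2L,
                          sqrt(0.75 / v[over]), "*")
    list(s2 = s2, coupled_active = active, reference_top = ref_snps)
  })
}

# Subject loadings with the coupled pair at the target correlation
# (stream 3).  Tail-driven: coupling carried only by the tail subjects;
# bulk residuals are orthogonalized so removing the tails removes the
# correlation by construction.
.build_loadings <- function(spec) {
  n <- spec$n_subjects
  k1 <- spec$n_components_gmc; k2 <- spec$n_components_snp
  with_seed(derive_seed(spec$seed, 3L), {
    a2 <- matrix(stats::rnorm(n * k2), n, k2)
    tail_idx <- integer(0)
    if (spec$tail_driven && spec$n_tail_subjects > 0) {
      nt <- spec$n_tail_subjects
      tail_idx <- sort(sample.int(n, nt))
      zr <- spec$tail_z_range
      bulk <- setdiff(seq_len(n), tail_idx)
      # bulk truncated inside +/-1.8 SD, tails outside; after column
      # standardization the planted tails are exactly the |z| >= 2 subjects
      a2[bulk, 1L] <- rtruncnorm(length(bulk), lower = -1.8, upper = 1.8)
      a2[tail_idx, 1L] <- sample(c(-1, 1), nt, TRUE) *
        stats::runif(nt, zr[1], zr[2])
    }
    a2 <- standardize_cols(a2)
    a1 <- matrix(stats::rnorm(n * k1), n, k1)
    e <- a1[, 1L]
    t_vec <- a2[, 1L]
    if (spec$tail_driven && length(tail_idx)) {
      t_vec <- ifelse(seq_len(n) %in% tail_idx, a2[, 1L], 0)
      bulk <- setdiff(seq_len(n), tail_idx)
      xb <- a2[bulk, 1L]
      e[bulk] <- e[bulk] - xb * sum(e[bulk] * xb) / sum(xb^2)
    }
    f <- function(g) stats::cor(g * t_vec + e, a2[, 1L]) - spec$coupled_pair_rho
    lo <- -100; hi <- 100
    if (f(lo) * f(hi) > 0)
      stopf(paste("target coupled_pair_rho = %.3f unreachable with the",
                  "given tail configuration (attainable range [%.3f, %.3f])"),
            spec$coupled_pair_rho,
            min(f(lo), f(hi)) + spec$coupled_pair_rho,
            max(f(lo), f(hi)) + spec$coupled_pair_rho)
    g <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
    a1[, 1L] <- g * t_vec + e
    a1 <- standardize_cols(a1)
    list(a1 = a1, a2 = a2, tail_subjects = tail_idx)
  })
}

# Smooth spatial component maps: sums of Gaussian blobs on the voxel grid,
# evaluated at the in-mask coordinates, unit variance per row (stream 6).
.build_gmc_components <- function(spec, coords) {
  k <- spec$n_components_gmc
  # blob width scales with the grid so map sparsity (hence source
  # non-Gaussianity) is invariant across desk scales
  gsc <- (spec$n_voxels / 8000)^(1 / 3)
  with_seed(derive_seed(spec$seed, 6L), {
    s1 <- matrix(0, k, nrow(coords))
    # primary blob centers are spread maximin-greedily so the k spatial
    # networks are anatomically distinct (near-coincident primary peaks
    # make the sources nearly collinear)
    centers <- matrix(NA_real_, k, 3)
    cand_n <- min(64L, nrow(coords))
    for (j in seq_len(k)) {
      cand <- coords[sample.int(nrow(coords), cand_n), , drop = FALSE]
      if (j == 1L) {
        centers[1, ] <- cand[1, ]
      } else {
        dmin <- apply(cand, 1L, function(x)
          min(rowSums(sweep(centers[seq_len(j - 1), , drop = FALSE],
                            2L, x, "-")^2)))
        centers[j, ] <- cand[which.max(dmin), ]
      }
    }
    for (j in seq_len(k)) {
      for (b in seq_len(3L)) {
        ctr <- if (b == 1L) centers[j, ]
               else coords[sample.int(nrow(coords), 1L), ]
        sig <- stats::runif(1, 2, 4) * gsc
        amp <- if (b == 1L) 1 else 0.6 * sample(c(-1, 1), 1L)
        d2 <- (coords[, 1] - ctr[1])^2 + (coords[, 2] - ctr[2])^2 +
          (coords[, 3] - ctr[3])^2
        s1[j, ] <- s1[j, ] + amp * exp(-d2 / (2 * sig^2))
      }
      s1[j, ] <- s1[j, ] / stats::sd(s1[j, ])
    }
    s1
  })
}

# Ellipsoidal brain-like mask with exactly n_voxels TRUE voxels.
.build_mask <- function(spec) {
  gs <- spec$grid_shape
  u <- lapply(1:3, function(a) (seq_len(gs[a]) - (gs[a] + 1) / 2) / (gs[a] / 2))
  r2 <- outer(outer(u[[1]]^2, u[[2]]^2, "+"), u[[3]]^2, "+")
  cut <- sort(as.vector(r2))[spec$n_voxels]
  mask <- array(FALSE, gs)
  ord <- order(as.vector(r2))[seq_len(spec$n_voxels)]
  mask[ord] <- TRUE
  mask
}

# Demographics and acquisition covariates (stream 7).
.build_covariates <- function(spec) {
  n <- spec$n_subjects
  with_seed(derive_seed(spec$seed, 7L), {
    age <- round(rtruncnorm(n, 45, 12, 18, 82), 1)
    sex <- stats::rbinom(n, 1, 448 / 715)          # 1 = female
    ns <- spec$n_sites
    base_rep <- min(3L, n %/% ns)
    site <- c(rep(seq_len(ns), base_rep),
              sample.int(ns, n - base_rep * ns, replace = TRUE))
    site <- sample(site, n)
    education <- round(rtruncnorm(n, 14, 2.5, 8, 20))
    cag <- round(rtruncnorm(n, spec$cag_mean, spec$cag_sd,
                            lower = spec$cag_min))
    data.frame(subject_id = sprintf("S%04d", seq_len(n)), age = age,
               sex = sex, site = site, education = education, cag = cag,
               stringsAsFactors = FALSE)
  })
}

#' Clinical measure direction metadata
#'
#' For timed tests (TMTA, TMTB) and the UHDRS total motor score, higher
#' scores mean poorer performance; for SDMT and the Stroop conditions
#' (correct counts), higher scores mean better performance.
#'
#' @return Named character vector, values `"higher_worse"`/`"higher_better"`.
#' @export
clinical_directions <- function() {
  c(tmta = "higher_worse", tmtb = "higher_worse", tms = "higher_worse",
    sdmt = "higher_better", stroop_color = "higher_better",
    stroop_word = "higher_better", stroop_interference = "higher_better")
}

# Clinical variables weakly linear in the coupled GMC loading (stream 8).
.build_clinical <- function(spec, gmc_loading) {
  n <- spec$n_subjects
  scales <- list(tmta = c(24, 8), tmtb = c(60, 25), sdmt = c(50, 10),
                 stroop_color = c(80, 13), stroop_word = c(100, 16),
                 stroop_interference = c(45, 10), tms = c(6, 5))
  dirs <- clinical_directions()
  n_complete <- round(n * (1 - spec$clinical_missing_rate))
  x <- as.numeric(scale(gmc_loading))
  with_seed(derive_seed(spec$seed, 8L), {
    out <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                      stringsAsFactors = FALSE)
    for (m in names(scales)) {
      mu <- scales[[m]][1]; sigma <- scales[[m]][2]
      # noncentrality F - 1 makes the expected F statistic equal the target
      beta <- sigma * sqrt(max(spec$clinical_effect_f - 1, 0) /
                             max(n_complete - 1, 1))
      sgn <- if (dirs[[m]] == "higher_worse") -1 else 1
      y <- mu + sgn * beta * x + sigma * stats::rnorm(n)
      y <- if (m %in% c("tmta", "tmtb")) round(pmax(y, 1), 1)
           else pmax(round(y), 0)
      y[stats::runif(n) < spec$clinical_missing_rate] <- NA
      out[[m]] <- y
    }
    attr(out, "directions") <- dirs
    out
  })
}

#' Generate a full synthetic cohort with an embedded coupled component pair
#'
#' Builds sparse heavy-tailed SNP components (four reference-gene SNPs among
#' the ten largest coupled-component weights), smooth Gaussian-blob GMC
#' maps, subject loadings whose coupled pair realizes `coupled_pair_rho`
#' exactly on the generated sample (tail-driven mixture when flagged),
#' injects the signal additively (`X = A S` plus Gaussian noise; for
#' genotypes into the latent scale before Hardy-Weinberg thresholding), adds
#' age/sex/site effects to the GMC voxels, and draws clinical variables
#' linearly related to the coupled GMC loading.
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `synthetic_cohort` with elements `genotypes`,
#'   `gmc`, `covariates`, `clinical`, `truth_s1`, `truth_s2`, `truth_a1`,
#'   `truth_a2`, `reference_snp_indices`, `tail_subjects`, `coupled`
#'   (component indices of the planted pair, both 1), and `spec`.
#' @export
generate_coupled_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  if (spec$n_components_snp >= n || spec$n_components_gmc >= n)
    stopf("component counts must be smaller than n_subjects")

  load <- .build_loadings(spec)
  genes <- .place_reference_genes(spec)
  snpc <- .build_snp_components(spec, genes)

  # genotypes: signal injected into the latent scale before thresholding
  bg <- .latent_background(spec)
  signal <- load$a2 %*% snpc$s2
  v <- colSums(snpc$s2^2)
  latent <- sweep(bg$latent, 2L, sqrt(pmax(1 - v, 0.05)), "*") + signal
  dos <- .plant_missing(.threshold_dosages(latent, bg$maf), spec)
  geno <- genotype_matrix(dos, bg$map[c("id", "chr", "pos", "a1", "a2")])
  attr(geno, "related_pairs") <- bg$related_pairs

  # GMC: X1 = baseline + A1 S1 + covariate effects + noise
  mask <- .build_mask(spec)
  coords <- which(mask, arr.ind = TRUE)
  s1 <- .build_gmc_components(spec, coords)
  covs <- .build_covariates(spec)
  x1 <- with_seed(derive_seed(spec$seed, 9L), {
    eff_age <- .smooth_map(coords, 2L) * 0.003
    eff_sex <- .smooth_map(coords, 2L) * 0.02
    site_map <- .smooth_map(coords, 2L)
    site_off <- stats::rnorm(spec$n_sites, 0, 0.03)
    noise <- matrix(stats::rnorm(n * spec$n_voxels), n, spec$n_voxels)
    spec$gmc_baseline +
      spec$gmc_signal_sd * (load$a1 %*% s1) +
      outer(covs$age - mean(covs$age), eff_age) +
      outer(as.numeric(covs$sex), eff_sex) +
      outer(site_off[covs$site], site_map) +
      spec$gmc_noise_sd * noise
  })
  gmc <- gmc_matrix(x1, mask, subject_ids = covs$subject_id)

  clinical <- .build_clinical(spec, load$a1[, 1L])

  structure(list(genotypes = geno, gmc = gmc, covariates = covs,
                 clinical = clinical,
                 truth_s1 = s1, truth_s2 = snpc$s2,
                 truth_a1 = load$a1, truth_a2 = load$a2,
                 reference_snp_indices = genes,
                 coupled = c(gmc = 1L, snp = 1L),
                 tail_subjects = load$tail_subjects,
                 related_pairs = bg$related_pairs,
                 spec = spec),
            class = "synthetic_cohort")
}

# One smooth random blob map over the in-mask coordinates, unit variance.
.smooth_map <- function(coords, n_blobs = 2L) {
  m <- rep(0, nrow(coords))
  for (b in seq_len(n_blobs)) {
    ctr <- coords[sample.int(nrow(coords), 1L), ]
    sig <- stats::runif(1, 3, 6)
    d2 <- (coords[, 1] - ctr[1])^2 + (coords[, 2] - ctr[2])^2 +
      (coords[, 3] - ctr[3])^2
    m <- m + sample(c(-1, 1), 1L) * exp(-d2 / (2 * sig^2))
  }
  as.numeric(m / stats::sd(m))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("synthetic_cohort: %d subjects, %d SNPs, %d voxels; ",
                     "embedded |r| = %.3f%s\n"),
              nrow(x$genotypes$dosages), ncol(x$genotypes$dosages),
              ncol(x$gmc$values),
              abs(stats::cor(x$truth_a1[, x$coupled["gmc"]],
                             x$truth_a2[, x$coupled["snp"]])),
              if (length(x$tail_subjects))
                sprintf(" (%d tail subjects)", length(x$tail_subjects))
              else ""))
  invisible(x)
}

#' Build the reference matrix of a synthetic cohort
#'
#' Uniform unit-norm weights over each planted reference gene's SNP indices.
#'
#' @param cohort a [generate_coupled_cohort()] result.
#' @return A [reference_matrix()].
#' @export
cohort_reference <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  reference_matrix(cohort$reference_snp_indices,
                   n_snps = ncol(cohort$genotypes$dosages))
}

#' Write a synthetic cohort to disk as standard-format files
#'
#' Emits PLINK BED/BIM/FAM, a 4-D GMC NIfTI stack plus binary mask NIfTI,
#' covariate and clinical TSV tables (with a JSON sidecar of measure
#' directions), ground-truth loading/component TSVs, and a JSON sidecar of
#' reference indices and tail subjects.  Files round-trip losslessly through
#' [read_plink()] and [read_gmc()].
#'
#' @param cohort a `synthetic_cohort`.
#' @param directory output directory (created if needed).
#' @return Invisibly, the named vector of written file paths.
#' @export
write_fixture <- function(cohort, directory) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    bed = write_plink(cohort$genotypes, file.path(directory, "genotypes")),
    gmc = write_gmc(cohort$gmc, file.path(directory, "gmc.nii.gz"),
                    file.path(directory, "mask.nii.gz"))["volumes"])
  cov_path <- file.path(directory, "covariates.tsv")
  write_tsv(cohort$covariates, cov_path)
  clin_path <- file.path(directory, "clinical.tsv")
  write_tsv(cohort$clinical, clin_path)
  jsonlite::write_json(as.list(attr(cohort$clinical, "directions")),
                       file.path(directory, "clinical_directions.json"),
                       auto_unbox = TRUE)
  for (nm in c("truth_s1", "truth_s2", "truth_a1", "truth_a2"))
    write_tsv(as.data.frame(cohort[[nm]]), file.path(directory,
                                                     paste0(nm, ".tsv")))
  jsonlite::write_json(list(reference_snp_indices =
                              cohort$reference_snp_indices,
                            tail_subjects = cohort$tail_subjects,
                            coupled = as.list(cohort$coupled),
                            seed = cohort$spec$seed),
                       file.path(directory, "truth.json"))
  invisible(c(paths, covariates = cov_path, clinical = clin_path))
}
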