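#' Genotype matrix container
#'
#' Subjects-by-SNPs minor-allele dosage matrix (values 0/1/2, `NA` allowed)
#' with per-SNP metadata.  Dosages count copies of the minor allele
#' (`allele1` in the PLINK BIM convention used throughout).
#'
#' @param dosages numeric/integer matrix, subjects in rows, SNPs in columns;
#'   entries must be 0, 1, 2 or `NA`.
#' @param snp_meta data frame with columns `id`, `chr`, `pos` (1-based bp),
#'   `a1`, `a2`; one row per SNP column.
#' @param subject_ids character vector, one per row of `dosages`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, snp_meta, subject_ids = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(subject_ids)) {
    subject_ids <- rownames(dosages) %||% sprintf("S%04d", seq_len(nrow(dosages)))
  }
  if (ncol(dosages) != nrow(snp_meta))
    stopf("snp_meta has %d rows but dosages has %d columns",
          nrow(snp_meta), ncol(dosages))
  if (nrow(dosages) != length(subject_ids))
    stopf("subject_ids length %d != %d subjects", length(subject_ids),
          nrow(dosages))
  need <- c("id", "chr", "pos", "a1", "a2")
  miss <- setdiff(need, names(snp_meta))
  if (length(miss)) stopf("snp_meta lacks column(s): %s",
                          paste(miss, collapse = ", "))
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) stopf("%d dosage entries outside {0,1,2,NA}", sum(bad))
  dimnames(dosages) <- list(subject_ids, snp_meta$id)
  structure(list(dosages = dosages,
                 snp_meta = as.data.frame(snp_meta, stringsAsFactors = FALSE),
                 subject_ids = as.character(subject_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d subjects x %d SNPs (%.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix
#'
#' @param x a [genotype_matrix()].
#' @param subjects row (subject) index vector; `NULL` keeps all.
#' @param snps column (SNP) index vector; `NULL` keeps all.
#' @return A `genotype_matrix` restricted to the selected rows/columns.
#' @export
subset_genotypes <- function(x, subjects = NULL, snps = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  subjects <- subjects %||% seq_len(nrow(x$dosages))
  snps <- snps %||% seq_len(ncol(x$dosages))
  genotype_matrix(x$dosages[subjects, snps, drop = FALSE],
                  x$snp_meta[snps, , drop = FALSE],
                  x$subject_ids[subjects])
}

#' Per-SNP minor allele frequency
#'
#' MAF is `min(p, 1 - p)` with `p = mean(dosage)/2` over non-missing calls.
#'
#' @param x a [genotype_matrix()] or plain dosage matrix.
#' @return Numeric vector of MAFs, one per SNP.
#' @export
snp_maf <- function(x) {
  d <- if (inherits(x, "genotype_matrix")) x$dosages else x
  p <- colMeans(d, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Gray-matter-concentration matrix container
#'
#' Subjects-by-voxel matrix restricted to a boolean 3-D mask, carrying the
#' grid geometry needed to write component maps back out as volumes.
#' Column `j` corresponds to the `j`-th `TRUE` voxel of `mask` in R's native
#' (column-major) array scan order.
#'
#' @param values numeric matrix, subjects x in-mask voxels.
#' @param mask logical 3-D array; `sum(mask)` must equal `ncol(values)`.
#' @param voxel_size numeric length-3, voxel edge lengths in mm.
#' @param affine 4x4 voxel-to-world transform.
#' @param subject_ids optional subject identifiers.
#' @return An object of class `gmc_matrix`.
#' @export
gmc_matrix <- function(values, mask, voxel_size = c(2, 2, 2),
                       affine = NULL, subject_ids = NULL) {
  values <- as.matrix(values)
  mask <- array(as.logical(mask), dim = dim(mask))
  if (length(dim(mask)) != 3L) stopf("mask must be a 3-D array")
  if (sum(mask) != ncol(values))
    stopf("mask has %d TRUE voxels but values has %d columns",
          sum(mask), ncol(values))
  if (any(!is.finite(values))) stopf("non-finite GMC values")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  subject_ids <- subject_ids %||% rownames(values) %||%
    sprintf("S%04d", seq_len(nrow(values)))
  rownames(values) <- subject_ids
  structure(list(values = values, mask = mask,
                 grid_shape = dim(mask),
                 voxel_size = as.numeric(voxel_size),
                 affine = affine,
                 subject_ids = as.character(subject_ids)),
            class = "gmc_matrix")
}

#' @export
print.gmc_matrix <- function(x, ...) {
  cat(sprintf("gmc_matrix: %d subjects x %d in-mask voxels (grid %s)\n",
              nrow(x$values), ncol(x$values),
              paste(x$grid_shape, collapse = "x")))
  invisible(x)
}

#' @export
dim.gmc_matrix <- function(x) dim(x$values)

#' Subset a GMC matrix by subject
#'
#' @param x a [gmc_matrix()].
#' @param subjects row index vector.
#' @return A `gmc_matrix` with the selected subjects.
#' @export
subset_gmc <- function(x, subjects) {
  stopifnot(inherits(x, "gmc_matrix"))
  gmc_matrix(x$values[subjects, , drop = FALSE], x$mask,
             x$voxel_size, x$affine, x$subject_ids[subjects])
}

#' Reference matrix of candidate-gene SNP weights
#'
#' Each reference is a nonnegative, unit-Euclidean-norm weight vector over a
#' set of SNP column indices, encoding prior belief that a gene's SNPs act
#' together.  Used as the similarity prior of the constrained genomic
#' Infomax objective.
#'
#' @param genes named list; each element is either an integer vector of SNP
#'   indices (weights default to uniform) or a list with `indices` and
#'   `weights` (nonnegative; renormalized to unit norm).
#' @param n_snps total SNP count used for index validation.
#' @param flank_bp base-pair padding recorded when built from annotations.
#' @return An object of class `reference_matrix`.
#' @export
reference_matrix <- function(genes, n_snps = NULL, flank_bp = 20000) {
  stopifnot(is.list(genes), length(genes) >= 1L, !is.null(names(genes)))
  out <- lapply(names(genes), function(nm) {
    g <- genes[[nm]]
    if (is.list(g)) {
      idx <- as.integer(g$indices); w <- as.numeric(g$weights)
    } else {
      idx <- as.integer(g); w <- rep(1, length(idx))
    }
    if (length(idx) == 0L) stopf("reference gene '%s' has no SNP indices", nm)
    if (any(w < 0)) stopf("reference weights for '%s' must be nonnegative", nm)
    if (!is.null(n_snps) && any(idx < 1L | idx > n_snps))
      stopf("reference gene '%s' has indices outside 1..%d", nm, n_snps)
    list(gene = nm, indices = idx, weights = w / sqrt(sum(w^2)))
  })
  names(out) <- names(genes)
  structure(list(genes = out, flank_bp = flank_bp, n_snps = n_snps),
            class = "reference_matrix")
}

#' @export
print.reference_matrix <- function(x, ...) {
  cat(sprintf("reference_matrix: %d gene(s): %s\n", length(x$genes),
              paste(vapply(x$genes, `[[`, "", "gene"), collapse = ", ")))
  invisible(x)
}

#' Default reference gene set
#'
#' Nine genes of the BDNF-signaling pathway used as pICAr references, with
#' the number of array SNPs each contributes: REST (4), SIN3A (2), RCOR1
#' (9), HAP1 (7), NTRK2 (52), NGFR (26), RILP (5), SORT1 (12), BDNF (6).
#'
#' @return Named integer vector of per-gene SNP counts.
#' @export
reference_gene_counts <- function() {
  c(REST = 4L, SIN3A = 2L, RCOR1 = 9L, HAP1 = 7L, NTRK2 = 52L,
    NGFR = 26L, RILP = 5L, SORT1 = 12L, BDNF = 6L)
}
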