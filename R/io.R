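#' Read a PLINK BED/BIM/FAM triple
#'
#' Decodes the variant-major 2-bit BED encoding into minor-allele dosages:
#' per variant, code 00 is the allele1 homozygote (dosage 2, BIM allele1
#' treated as the minor allele), 10 the heterozygote (dosage 1), 11 the
#' allele2 homozygote (dosage 0) and 01 missing.  SNP positions are 1-based
#' base pairs (PLINK convention).
#'
#' @param prefix path prefix; `<prefix>.bed/.bim/.fam` must exist.
#' @return A [genotype_matrix()].
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stopf("missing PLINK file(s): %s", paste(missing, collapse = ", "))
  bim <- utils::read.table(paths[2], header = FALSE,
                           col.names = c("chr", "id", "cm", "pos",
                                         "a1", "a2"),
                           colClasses = c("integer", "character", "numeric",
                                          "integer", "character",
                                          "character"))
  fam <- utils::read.table(paths[3], header = FALSE,
                           colClasses = "character")
  n <- nrow(fam); p <- nrow(bim)
  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stopf("not a PLINK BED file (bad magic bytes)")
  if (raw[3] == as.raw(0x00))
    stopf("sample-major BED layout is not supported")
  if (raw[3] != as.raw(0x01)) stopf("unknown BED mode byte")
  bpv <- ceiling(n / 4)
  body <- as.integer(raw[-(1:3)])
  if (length(body) != bpv * p)
    stopf("BED payload is %d bytes; expected %d", length(body), bpv * p)
  bytes <- matrix(body, nrow = bpv, ncol = p)
  # dosage by 2-bit code: 00 -> 2, 01 -> NA, 10 -> 1, 11 -> 0
  code_map <- c(2L, NA_integer_, 1L, 0L)
  d <- matrix(NA_integer_, n, p)
  for (k in 0:3) {
    subj <- seq.int(k + 1L, by = 4L, length.out = bpv)
    valid <- subj <= n
    if (!any(valid)) next
    codes <- bitwAnd(bitwShiftR(bytes[valid, , drop = FALSE], 2L * k), 3L)
    d[subj[valid], ] <- code_map[codes + 1L]
  }
  genotype_matrix(d, bim[c("id", "chr", "pos", "a1", "a2")],
                  subject_ids = fam[[2]])
}

#' Write a genotype matrix as PLINK BED/BIM/FAM
#'
#' Variant-major 2-bit encoding, with BIM allele1 as the minor allele so
#' that dosages count allele1 copies on read-back.
#'
#' @param geno a [genotype_matrix()].
#' @param prefix output path prefix.
#' @return The `.bed` path, invisibly.
#' @export
write_plink <- function(geno, prefix) {
  stopifnot(inherits(geno, "genotype_matrix"))
  d <- geno$dosages
  n <- nrow(d); p <- ncol(d)
  meta <- geno$snp_meta
  utils::write.table(data.frame(as.integer(meta$chr), meta$id, 0,
                                as.integer(meta$pos), meta$a1, meta$a2),
                     paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(geno$subject_ids, geno$subject_ids,
                                0, 0, 0, -9),
                     paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  # dosage -> 2-bit code: 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
  codes <- matrix(3L, n, p)
  codes[is.na(d)] <- 1L
  codes[!is.na(d) & d == 1] <- 2L
  codes[!is.na(d) & d == 2] <- 0L
  bpv <- ceiling(n / 4)
  padded <- matrix(0L, bpv * 4L, p)
  padded[seq_len(n), ] <- codes
  shift <- c(1L, 4L, 16L, 64L)
  bytes <- matrix(0L, bpv, p)
  for (k in 0:3)
    bytes <- bytes + shift[k + 1L] *
      padded[seq.int(k + 1L, by = 4L, length.out = bpv), , drop = FALSE]
  bed_path <- paste0(prefix, ".bed")
  con <- file(bed_path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(bed_path)
}

#' Read GMC volumes and a mask from NIfTI files
#'
#' @param volumes path to a 4-D NIfTI stack, or a character vector of
#'   per-subject 3-D volume paths.
#' @param mask path to a binary mask NIfTI on the same grid (affines must
#'   agree within `tol`).
#' @param tol affine agreement tolerance.
#' @return A [gmc_matrix()].
#' @export
read_gmc <- function(volumes, mask, tol = 1e-4) {
  mimg <- RNifti::readNifti(mask)
  mvals <- as.array(mimg)
  if (!all(mvals %in% c(0, 1)))
    stopf("mask is not binary (values outside {0, 1})")
  maff <- RNifti::xform(mimg)
  imgs <- lapply(volumes, RNifti::readNifti)
  arr <- if (length(imgs) == 1L && length(dim(imgs[[1]])) == 4L) {
    as.array(imgs[[1]])
  } else {
    array(unlist(lapply(imgs, as.array)),
          dim = c(dim(imgs[[1]]), length(imgs)))
  }
  vaff <- RNifti::xform(imgs[[1]])
  if (!identical(dim(arr)[1:3], dim(mvals)))
    stopf("volume grid %s does not match mask grid %s",
          paste(dim(arr)[1:3], collapse = "x"),
          paste(dim(mvals), collapse = "x"))
  if (max(abs(vaff - maff)) > tol)
    stopf("affine mismatch between volumes and mask:\n%s\nvs\n%s",
          paste(utils::capture.output(print(vaff)), collapse = "\n"),
          paste(utils::capture.output(print(maff)), collapse = "\n"))
  vox <- RNifti::pixdim(mimg)[1:3]
  mask_arr <- array(mvals > 0, dim = dim(mvals))
  mask_and_flatten(arr, mask_arr, voxel_size = vox, affine = maff)
}

#' Write a GMC matrix as a 4-D NIfTI stack plus mask
#'
#' @param gmc a [gmc_matrix()].
#' @param volumes_path output path for the 4-D stack (`.nii`/`.nii.gz`).
#' @param mask_path output path for the binary mask volume.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_gmc <- function(gmc, volumes_path, mask_path) {
  stopifnot(inherits(gmc, "gmc_matrix"))
  arr <- unflatten_gmc(gmc)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(gmc$voxel_size, 1)[seq_along(dim(arr))]
  RNifti::writeNifti(img, volumes_path)
  mimg <- RNifti::asNifti(array(as.integer(gmc$mask), dim = gmc$grid_shape))
  RNifti::pixdim(mimg) <- gmc$voxel_size
  RNifti::writeNifti(mimg, mask_path)
  invisible(c(volumes = volumes_path, mask = mask_path))
}

#' Write a z-scored component map as a NIfTI volume
#'
#' @param s component weight row over the in-mask voxels.
#' @param gmc the [gmc_matrix()] providing the grid.
#' @param path output NIfTI path.
#' @param zscore standardize before writing (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_component_map <- function(s, gmc, path, zscore = TRUE) {
  stopifnot(inherits(gmc, "gmc_matrix"), length(s) == ncol(gmc$values))
  if (zscore) s <- zscore_component(s)
  vol <- unflatten_gmc(s, gmc$mask)
  RNifti::writeNifti(RNifti::asNifti(vol, pixdim = gmc$voxel_size), path)
  invisible(path)
}

#' Tab-separated table helpers
#'
#' Header-row TSV with no quoting or row names; `read_tsv` preserves column
#' types via standard `read.delim` inference.
#'
#' @param df data frame to write.
#' @param path file path.
#' @return `write_tsv`: `path` invisibly; `read_tsv`: a data frame.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Re-index a reference matrix after SNP filtering
#'
#' Maps each reference gene's SNP indices from the original panel to a
#' filtered panel via SNP identifiers; genes whose SNPs were all removed are
#' dropped with a warning.
#'
#' @param ref a [reference_matrix()].
#' @param original_ids SNP identifiers of the panel the reference indexes.
#' @param new_ids SNP identifiers of the filtered panel.
#' @return A [reference_matrix()] indexed for the filtered panel.
#' @export
remap_reference <- function(ref, original_ids, new_ids) {
  stopifnot(inherits(ref, "reference_matrix"))
  genes <- list()
  for (g in ref$genes) {
    ids <- original_ids[g$indices]
    at <- match(ids, new_ids)
    keep <- !is.na(at)
    if (!any(keep)) {
      warning(sprintf("reference gene '%s' lost all SNPs in filtering",
                      g$gene))
      next
    }
    genes[[g$gene]] <- list(indices = at[keep], weights = g$weights[keep])
  }
  if (!length(genes)) stopf("no reference genes survive the filtering")
  reference_matrix(genes, n_snps = length(new_ids), flank_bp = ref$flank_bp)
}
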