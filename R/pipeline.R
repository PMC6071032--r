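#' Build and validate a pipeline run configuration
#'
#' A run configuration is a plain named list (or a YAML/JSON file holding
#' one) with the per-stage parameter blocks below; unknown keys are
#' rejected.
#'
#' \describe{
#'   \item{seed}{master seed for every stochastic stage.}
#'   \item{out_dir}{output directory.}
#'   \item{cohort}{`"predict_hd"` or a list of [cohort_spec()] arguments.}
#'   \item{qc}{[genotype_qc_pipeline()] arguments.}
#'   \item{preprocess}{`keep_intercept` flag.}
#'   \item{decompose}{[picar_config()] arguments.}
#'   \item{validate}{`run` flag plus `n_perm`, `folds`.}
#'   \item{associate}{`run` flag plus `family_m`, `alpha`.}
#'   \item{log_level}{`"quiet"` or `"info"`.}
#' }
#'
#' @param config named list or path to a YAML/JSON file.
#' @return Validated configuration list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  known <- c("seed", "out_dir", "cohort", "qc", "preprocess", "decompose",
             "validate", "associate", "log_level")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  defaults <- list(seed = 1L, out_dir = tempfile("picafuse_run_"),
                   cohort = "predict_hd",
                   qc = list(), preprocess = list(keep_intercept = TRUE),
                   decompose = list(),
                   validate = list(run = FALSE, n_perm = 100, folds = 10),
                   associate = list(run = TRUE, alpha = 0.05),
                   log_level = "info")
  out <- utils::modifyList(defaults, config)
  structure(out, class = c("run_config", "list"))
}

.pipe_log <- function(config, fmt, ...) {
  if (identical(config$log_level, "info"))
    message(sprintf(paste0("[picafuse] ", fmt), ...))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Chains simulate, genotype QC, voxelwise nuisance regression, the coupled
#' decomposition, optional permutation validation, and clinical association,
#' writing stage outputs and a manifest of checksums under `out_dir`.
#' Identical configuration and seed reproduce identical output checksums for
#' the deterministic stages.
#'
#' @param config a [run_config()] (or anything it accepts).
#' @return A list of class `run_manifest`: package version, configuration
#'   hash, per-file md5 checksums, stage summaries and timestamps.
#' @export
run_pipeline <- function(config = run_config()) {
  config <- run_config(unclass(config))
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  spec <- if (identical(config$cohort, "predict_hd")) {
    predict_hd_spec(seed = config$seed)
  } else {
    do.call(cohort_spec, utils::modifyList(as.list(config$cohort),
                                           list(seed = config$seed)))
  }
  .pipe_log(config, "simulate: %d subjects, %d SNPs, %d voxels",
            spec$n_subjects, spec$n_snps, spec$n_voxels)
  cohort <- generate_coupled_cohort(spec)

  qc <- do.call(genotype_qc_pipeline,
                c(list(geno = cohort$genotypes), config$qc))
  keep_ids <- qc$genotypes$subject_ids
  subj <- match(keep_ids, cohort$covariates$subject_id)
  .pipe_log(config, "qc: %d -> %d SNPs, %d -> %d subjects",
            ncol(cohort$genotypes$dosages), ncol(qc$genotypes$dosages),
            nrow(cohort$genotypes$dosages), nrow(qc$genotypes$dosages))

  gmc <- subset_gmc(cohort$gmc, subj)
  covs <- cohort$covariates[subj, , drop = FALSE]
  gmc_r <- residualize_voxels(gmc, covs,
                              keep_intercept =
                                isTRUE(config$preprocess$keep_intercept))

  ref <- remap_reference(cohort_reference(cohort),
                         cohort$genotypes$snp_meta$id,
                         qc$genotypes$snp_meta$id)
  pc <- do.call(picar_config, utils::modifyList(
    as.list(config$decompose), list(seed = config$seed)))
  .pipe_log(config, "decompose: %d x %d components",
            pc$n_components_1, pc$n_components_2)
  dec <- run_picar(gmc_r, qc$genotypes, ref, pc)
  pair <- select_max_pair(dec)
  .pipe_log(config, "max pair: (%d, %d), r = %.3f, p = %.3g",
            pair$comp_1, pair$comp_2, pair$r, pair$p)

  perm <- NULL
  if (isTRUE(config$validate$run)) {
    perm <- permutation_test(gmc_r, qc$genotypes, ref, pc,
                             n_perm = config$validate$n_perm,
                             seed = config$seed)
  }

  assoc <- NULL
  if (isTRUE(config$associate$run)) {
    clin <- clinical_table(cohort$clinical[subj, , drop = FALSE])
    assoc <- glm_clinical(clin, dec$a1[, pair$comp_1],
                          covariate_name = "gmc_loading",
                          alpha = config$associate$alpha %||% 0.05,
                          family_m = config$associate$family_m)
  }

  # persist stage outputs
  od <- config$out_dir
  files <- character(0)
  files["pair"] <- file.path(od, "max_pair.json")
  jsonlite::write_json(unclass(pair)[c("comp_1", "comp_2", "r", "p", "df",
                                       "p_bonferroni")],
                       files["pair"], auto_unbox = TRUE, digits = NA)
  files["loadings_gmc"] <- write_tsv(as.data.frame(dec$a1),
                                     file.path(od, "loadings_gmc.tsv"))
  files["loadings_snp"] <- write_tsv(as.data.frame(dec$a2),
                                     file.path(od, "loadings_snp.tsv"))
  snp_tab <- data.frame(id = qc$genotypes$snp_meta$id,
                        weight = dec$s2[pair$comp_2, ],
                        rank = rank(-abs(dec$s2[pair$comp_2, ]),
                                    ties.method = "first"))
  files["snp_component"] <- write_tsv(snp_tab,
                                      file.path(od, "snp_component.tsv"))
  files["gmc_component"] <- write_component_map(
    dec$s1[pair$comp_1, ], gmc_r, file.path(od, "gmc_component.nii.gz"))
  if (!is.null(assoc))
    files["associations"] <- write_tsv(assoc,
                                       file.path(od, "associations.tsv"))
  if (!is.null(perm)) {
    files["permutation"] <- file.path(od, "permutation.json")
    jsonlite::write_json(unclass(perm)[c("observed_r", "null_rs", "n_perm",
                                         "ratio_above", "seed")],
                         files["permutation"], auto_unbox = TRUE,
                         digits = NA)
  }
  cfg_path <- file.path(od, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       force = TRUE)

  manifest <- structure(
    list(tool_version = as.character(utils::packageVersion("picafuse")),
         config_hash = unname(tools::md5sum(cfg_path)),
         checksums = vapply(files, function(f) unname(tools::md5sum(f)), ""),
         qc = list(n_snps = ncol(qc$genotypes$dosages),
                   n_subjects = nrow(qc$genotypes$dosages)),
         pair = unclass(pair)[c("comp_1", "comp_2", "r", "p")],
         started = format(t0, "%Y-%m-%dT%H:%M:%S"),
         finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    class = "run_manifest")
  jsonlite::write_json(unclass(manifest), file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$result <- dec
  manifest$permutation <- perm
  manifest$associations <- assoc
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("run_manifest: picafuse %s, pair r = %.3f, %d files\n",
              x$tool_version, x$pair$r, length(x$checksums)))
  invisible(x)
}
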