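Package: picafuse
Title: Parallel Independent Component Analysis with Reference for
    Imaging-Genetics Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint decomposition of single-nucleotide-polymorphism dosage
    matrices and voxelwise gray-matter-concentration matrices by parallel
    independent component analysis with reference (pICAr): Infomax blind
    source separation per modality, a soft similarity constraint pulling
    one genomic component toward candidate-gene SNP sets, and a
    cross-modality term enhancing the correlation between subject loading
    columns.  Includes genotype quality control (missingness, minor allele
    frequency, linkage-disequilibrium pruning, relatedness exclusion,
    multidimensional-scaling ancestry factors), voxelwise nuisance
    regression, permutation and k-fold validation of component-pair
    correlations, regression influence diagnostics, top-SNP restricted
    loadings, clinical association models, and a seeded synthetic-cohort
    generator emulating a prodromal Huntington disease imaging-genetics
    sample for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
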