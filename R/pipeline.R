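#' @include permutation.R
NULL

#' Assemble a pipeline configuration
#'
#' Collects every stage threshold (defaults: IBS 0.84, sample missingness
#' 0.40, SNP call rate 0.99, HWE 1e-6, MAF 0.01 single-marker / 0.05
#' interaction), the analysis mode, and either input file paths or a
#' [CohortConfig-class] for simulation.  Can also be loaded from a YAML
#' file whose keys mirror the arguments (`simulate` holding
#' [cohortConfig()] arguments).
#'
#' @param phenoFile,genoFile,mapFile input paths (ignored when `simulate`
#'   is given).
#' @param simulate optional [CohortConfig-class]; the pipeline then starts
#'   from [simulateCohort()].
#' @param mode `"imputed"` (hot-deck imputation, exams 0--3) or
#'   `"no_imputation"` (attended-exam trait construction).
#' @param ibsThreshold,maxMissing,minCallrate,hweAlpha,minMaf,interactionMaf
#'   QC and scan thresholds.
#' @param covariateAlpha univariate covariate-retention threshold.
#' @param doInteraction run the exhaustive pair scan.
#' @param nTopPermute validate this many top single-marker hits by
#'   permutation (0 skips the stage).
#' @param nReplicates permutation replicates per validated hit.
#' @param seed pipeline seed (drives permutation; simulation uses the seed
#'   inside `simulate`).
#' @return a list of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(phenoFile = NULL, genoFile = NULL, mapFile = NULL,
                           simulate = NULL,
                           mode = c("imputed", "no_imputation"),
                           ibsThreshold = 0.84, maxMissing = 0.40,
                           minCallrate = 0.99, hweAlpha = 1e-6,
                           minMaf = 0.01, interactionMaf = 0.05,
                           covariateAlpha = 0.05,
                           doInteraction = FALSE,
                           nTopPermute = 0L, nReplicates = 1000L,
                           seed = 1L) {
  mode <- match.arg(mode)
  .stopIf(is.null(simulate) && (is.null(phenoFile) || is.null(genoFile) ||
                                  is.null(mapFile)),
          "either input files or a simulation config must be given")
  structure(list(phenoFile = phenoFile, genoFile = genoFile,
                 mapFile = mapFile, simulate = simulate, mode = mode,
                 ibsThreshold = ibsThreshold, maxMissing = maxMissing,
                 minCallrate = minCallrate, hweAlpha = hweAlpha,
                 minMaf = minMaf, interactionMaf = interactionMaf,
                 covariateAlpha = covariateAlpha,
                 doInteraction = doInteraction,
                 nTopPermute = as.integer(nTopPermute),
                 nReplicates = as.integer(nReplicates),
                 seed = as.integer(seed)),
            class = "pipelineConfig")
}

#' Load a pipeline configuration from YAML
#'
#' @param file YAML file whose top-level keys mirror the arguments of
#'   [pipelineConfig()]; a `simulate` mapping holds [cohortConfig()]
#'   arguments.
#' @return a `"pipelineConfig"` list.
#' @export
readPipelineConfig <- function(file) {
  raw <- yaml::read_yaml(file)
  if (!is.null(raw$simulate)) {
    sim <- raw$simulate
    if (!is.null(sim$plantedMain))
      sim$plantedMain <- as.data.frame(sim$plantedMain)
    if (!is.null(sim$plantedInteractions))
      sim$plantedInteractions <- as.data.frame(sim$plantedInteractions)
    raw$simulate <- do.call(cohortConfig, sim)
  }
  do.call(pipelineConfig, raw)
}

.writeTable <- function(x, dir, name) {
  path <- file.path(dir, name)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  path
}

#' Run the end-to-end progression analysis
#'
#' Stage order: simulate (or read) -> missingness diagnosis -> phenotype
#' imputation (skipped in `no_imputation` mode) -> genotype QC -> trait and
#' covariate construction -> single-marker scan with genomic control ->
#' optional interaction scan -> optional permutation validation.  Every
#' stage writes a delimited table under `outDir`, and `manifest.yaml`
#' records the parameters, seed, package version and input checksums, so
#' two runs with the same configuration produce identical outputs.
#'
#' @param config a `"pipelineConfig"` from [pipelineConfig()] or
#'   [readPipelineConfig()].
#' @param outDir output directory (created if needed).
#' @param quiet suppress per-stage messages.
#' @return invisibly, a list with every stage result (`cohort`,
#'   `mechanism`, `imputation`, `qc`, `trait`, `covariates`, `scan`,
#'   `lambda`, `interaction`, `permutation`, `outDir`).
#' @export
runPipeline <- function(config, outDir, quiet = FALSE) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    say("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0)
    out
  }

  inputs <- NULL
  if (!is.null(config$simulate)) {
    cohortSim <- stage("simulate", simulateCohort(config$simulate))
    pheno <- observedPhenotypes(cohortSim)
    geno <- genotypes(cohortSim)
    .writeTable(phenoTable(pheno), outDir, "phenotypes.tsv")
  } else {
    cohortSim <- NULL
    pheno <- stage("read", readPhenotypes(config$phenoFile))
    geno <- readGenotypes(config$genoFile, config$mapFile)
    inputs <- vapply(c(config$phenoFile, config$genoFile, config$mapFile),
                     function(f) unname(tools::md5sum(f)), character(1))
  }

  mech <- stage("diagnose", mcarJointTest(pheno))
  .writeTable(data.frame(
    key = c("p_unadjusted", "p_age_adjusted", "verdict", "n_used"),
    value = c(format(mech@pUnadjusted, digits = 6),
              format(mech@pAdjusted, digits = 6),
              mech@verdict, mech@nUsed)), outDir, "missingness.tsv")

  imputation <- NULL
  if (config$mode == "imputed") {
    imputation <- stage("impute", imputeCohort(pheno))
    traitCohort <- imputedPhenotypes(imputation)
    .writeTable(phenoTable(traitCohort), outDir, "phenotypes_imputed.tsv")
    .writeTable(imputationAudit(imputation), outDir, "imputation_audit.tsv")
    trait <- buildTrait(traitCohort, mode = "imputed")
    trait$completer <- isCompleter(pheno)[match(trait$id, individualIds(pheno))]
  } else {
    aged <- imputeAges(pheno)   # ages are always recoverable from birth year
    trait <- stage("trait", buildTrait(aged, mode = "observed"))
  }

  qc <- stage("qc", applyQc(geno, ibsThreshold = config$ibsThreshold,
                            maxMissing = config$maxMissing,
                            minCallrate = config$minCallrate,
                            hweAlpha = config$hweAlpha,
                            minMaf = config$minMaf))
  .writeTable(qc$report@snpInfo, outDir, "qc_snp_info.tsv")
  .writeTable(qc$report@samplesRemoved, outDir, "qc_samples_removed.tsv")
  .writeTable(qc$report@snpsRemoved, outDir, "qc_snps_removed.tsv")

  covariates <- stage("covariates",
                      selectCovariates(trait, alpha = config$covariateAlpha))
  .writeTable(data.frame(covariate = covariates), outDir, "covariates.tsv")
  .writeTable(trait, outDir, "trait.tsv")

  scan <- stage("scan", singleMarkerScan(trait, qc$genotypes, covariates))
  lambda <- genomicInflation(scan$p)
  .writeTable(scan[order(scan$p), ], outDir, "scan_single_marker.tsv")

  interaction <- NULL
  if (isTRUE(config$doInteraction)) {
    interaction <- stage("interact",
                         interactionScan(trait, qc$genotypes,
                                         minMaf = config$interactionMaf))
    .writeTable(interaction, outDir, "scan_interaction.tsv")
  }

  permutation <- NULL
  if (config$nTopPermute > 0L) {
    permutation <- stage("permute",
                         validateTopHits(scan, trait, qc$genotypes, covariates,
                                         nTop = config$nTopPermute,
                                         nReplicates = config$nReplicates,
                                         seed = config$seed))
    .writeTable(do.call(rbind, lapply(permutation, function(r)
      data.frame(snp = r@id, stat = r@statObserved, k = r@k,
                 n_replicates = r@nReplicates, p_mc = r@pMc,
                 p_mc_conservative = r@pMcConservative))),
      outDir, "permutation.tsv")
  }

  manifest <- list(
    package = "progwas",
    version = as.character(utils::packageVersion("progwas")),
    mode = config$mode, seed = config$seed,
    parameters = config[c("ibsThreshold", "maxMissing", "minCallrate",
                          "hweAlpha", "minMaf", "interactionMaf",
                          "covariateAlpha")],
    lambda = lambda,
    inputs = as.list(inputs),
    simulated = !is.null(config$simulate))
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))

  invisible(list(cohort = cohortSim, mechanism = mech,
                 imputation = imputation, qc = qc, trait = trait,
                 covariates = covariates, scan = scan, lambda = lambda,
                 interaction = interaction, permutation = permutation,
                 outDir = outDir))
}
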