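#' @import methods
#' @importFrom stats coef cor cor.test fisher.test lm.fit p.adjust pf
#'   prcomp pt qnorm rbinom rnorm runif sd setNames smooth.spline predict
#'   wilcox.test var complete.cases
#' @importFrom utils read.delim write.table head
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' GenotypeMatrix: additive dosages with a SNP map
#'
#' Container for a sample x SNP matrix of additive allele dosages in
#' `[0, 2]` (missing allowed) together with per-SNP metadata: identifier,
#' chromosome, 1-based position, ref/alt alleles, minor allele frequency,
#' and optional imputation INFO score and call rate used by
#' [filterGenotypes()].
#'
#' @slot dosage numeric matrix, samples in rows, SNPs in columns; values in
#'   `[0, 2]` or `NA`.
#' @slot snpMap data.frame with one row per SNP: `snp`, `chrom`, `pos`,
#'   `ref`, `alt`, `maf`, and optionally `info` and `call_rate`.
#'
#' @seealso [simulateGenotypes()], [filterGenotypes()], [scanQtl()]
#' @export
setClass("GenotypeMatrix",
  representation(dosage = "matrix", snpMap = "data.frame"))

setValidity("GenotypeMatrix", function(object) {
  d <- object@dosage
  m <- object@snpMap
  msg <- character()
  if (!is.numeric(d)) msg <- c(msg, "dosage must be a numeric matrix")
  rng <- range(d, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    msg <- c(msg, "dosages must lie in [0, 2]")
  if (!all(c("snp", "chrom", "pos") %in% names(m)))
    msg <- c(msg, "snpMap needs columns snp, chrom, pos")
  else {
    if (anyDuplicated(m$snp)) msg <- c(msg, "SNP ids must be unique")
    if (any(m$pos < 1)) msg <- c(msg, "positions must be >= 1")
  }
  if (nrow(m) != ncol(d))
    msg <- c(msg, "snpMap rows must match dosage columns")
  if (!is.null(colnames(d)) && nrow(m) > 0 &&
      !identical(colnames(d), as.character(m$snp)))
    msg <- c(msg, "dosage colnames must equal snpMap$snp")
  if (length(msg)) msg else TRUE
})

#' TraitMatrix: molecular trait values with feature coordinates
#'
#' Sample x feature matrix of methylation (M-values or beta-values) or
#' expression values, with a feature coordinate map and a scale tag.
#'
#' @slot values numeric matrix, samples in rows, features in columns.
#' @slot featureMap data.frame with columns `feature`, `chrom`, `pos`
#'   (1-based anchor; TSS for transcripts if available).
#' @slot scale character, one of `"M-value"`, `"beta"`, `"expression"`.
#'
#' @seealso [simulateCohort()], [scanQtl()], [mapEqtm()]
#' @export
setClass("TraitMatrix",
  representation(values = "matrix", featureMap = "data.frame",
                 scale = "character"))

setValidity("TraitMatrix", function(object) {
  v <- object@values
  m <- object@featureMap
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
  if (any(!is.finite(v))) msg <- c(msg, "values must be finite")
  if (!object@scale %in% c("M-value", "beta", "expression"))
    msg <- c(msg, "scale must be one of M-value, beta, expression")
  if (!all(c("feature", "chrom", "pos") %in% names(m)))
    msg <- c(msg, "featureMap needs columns feature, chrom, pos")
  else if (anyDuplicated(m$feature))
    msg <- c(msg, "feature ids must be unique")
  if (nrow(m) != ncol(v))
    msg <- c(msg, "featureMap rows must match value columns")
  if (length(msg)) msg else TRUE
})

#' SimConfig: synthetic cohort configuration
#'
#' Parameters of the synthetic-cohort generator. Defaults emulate an
#' early-arthritis methylation/expression QTL cohort: ~120 genotyped
#' patients split into a disease group and disease controls, SNPs in
#' Hardy-Weinberg proportions organised in LD blocks, CpG methylation on
#' the M-value scale, and planted SNP -> CpG -> transcript triplets under
#' the four regulatory models (causal, reactive, independent, null).
#'
#' @slot nSamples,nSnps,nCpgs,nTranscripts positive counts.
#' @slot mafRange length-2 numeric in (0, 0.5]; a per-LD-block MAF is drawn
#'   uniformly from this range.
#' @slot ldBlockSize SNPs per LD block.
#' @slot ldRho within-block haplotype copy probability in `[0, 1)`; the
#'   dosage correlation between adjacent SNPs is approximately `ldRho`.
#' @slot nChrom,chromLength number of chromosomes and their length in bp.
#' @slot plantedTriplets data.frame of planted triplets, see
#'   [plantedTriplet()].
#' @slot interactionEffects data.frame (`snp`, `cpg`, `delta`) adding a
#'   genotype-slope difference `delta` (M-value per allele) between
#'   diagnosis groups.
#' @slot diagnosisFraction proportion of samples labelled as cases.
#' @slot noiseSdMethylation,noiseSdExpression residual SDs (M-value /
#'   expression units).
#' @slot seed integer RNG seed; fixed seed gives bit-identical output.
#'
#' @seealso [simulateGenotypes()], [simulateCohort()]
#' @export
setClass("SimConfig",
  representation(
    nSamples = "numeric", nSnps = "numeric", mafRange = "numeric",
    ldBlockSize = "numeric", ldRho = "numeric",
    nCpgs = "numeric", nTranscripts = "numeric",
    nChrom = "numeric", chromLength = "numeric",
    plantedTriplets = "data.frameOrNULL",
    interactionEffects = "data.frameOrNULL",
    diagnosisFraction = "numeric",
    noiseSdMethylation = "numeric", noiseSdExpression = "numeric",
    seed = "numeric"),
  prototype(
    nSamples = 120, nSnps = 500, mafRange = c(0.05, 0.5),
    ldBlockSize = 5, ldRho = 0.8,
    nCpgs = 300, nTranscripts = 100,
    nChrom = 2, chromLength = 1e8,
    plantedTriplets = NULL, interactionEffects = NULL,
    diagnosisFraction = 0.4,
    noiseSdMethylation = 0.5, noiseSdExpression = 0.5,
    seed = 1))

setValidity("SimConfig", function(object) {
  msg <- character()
  cnt <- c(object@nSamples, object@nSnps, object@nCpgs,
           object@nTranscripts, object@ldBlockSize, object@nChrom,
           object@chromLength)
  if (any(cnt <= 0)) msg <- c(msg, "all counts must be > 0")
  mr <- object@mafRange
  if (length(mr) != 2 || any(mr <= 0) || any(mr > 0.5) || mr[1] > mr[2])
    msg <- c(msg, "mafRange must be within (0, 0.5] with low <= high")
  if (object@ldRho < 0 || object@ldRho >= 1)
    msg <- c(msg, "ldRho must be in [0, 1)")
  if (object@diagnosisFraction <= 0 || object@diagnosisFraction >= 1)
    msg <- c(msg, "diagnosisFraction must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' LdBlock: an index SNP with its LD proxies
#'
#' @slot indexSnp character, index SNP id (always among the proxies with
#'   r-squared 1).
#' @slot proxies data.frame (`snp`, `r2`) of SNPs in LD with the index at or
#'   above the threshold used to build the block.
#' @slot chrom character; \code{start}, \code{end}: 1-based inclusive
#'   interval spanning the index and all proxies.
#' @slot r2Threshold numeric, the threshold used.
#'
#' @seealso [ldBlock()], [intersectRiskLoci()]
#' @export
setClass("LdBlock",
  representation(indexSnp = "character", proxies = "data.frame",
                 chrom = "character", start = "numeric", end = "numeric",
                 r2Threshold = "numeric"))

setValidity("LdBlock", function(object) {
  msg <- character()
  if (!all(c("snp", "r2") %in% names(object@proxies)))
    msg <- c(msg, "proxies needs columns snp, r2")
  else {
    if (!object@indexSnp %in% object@proxies$snp)
      msg <- c(msg, "index SNP must be among the proxies")
    if (any(object@proxies$r2 < object@r2Threshold - 1e-12))
      msg <- c(msg, "all proxy r2 must reach the threshold")
  }
  if (object@start > object@end) msg <- c(msg, "start must be <= end")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@dosage), "samples x",
      ncol(object@dosage), "SNPs\n")
  cat("  chromosomes:",
      paste(unique(object@snpMap$chrom), collapse = ", "), "\n")
  cat("  missing dosages:", sum(is.na(object@dosage)), "\n")
})

setMethod("show", "TraitMatrix", function(object) {
  cat("TraitMatrix (", object@scale, "): ", nrow(object@values),
      " samples x ", ncol(object@values), " features\n", sep = "")
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nSamples, "samples,", object@nSnps, "SNPs,",
      object@nCpgs, "CpGs,", object@nTranscripts, "transcripts\n")
  np <- if (is.null(object@plantedTriplets)) 0L
        else nrow(object@plantedTriplets)
  cat("  planted triplets:", np, " seed:", object@seed, "\n")
})

setMethod("show", "LdBlock", function(object) {
  cat("LdBlock: index", object@indexSnp, "with",
      nrow(object@proxies), "proxies (r2 >=", object@r2Threshold, ")\n")
  cat("  interval:", object@chrom, object@start, "-", object@end, "\n")
})
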