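#' Accessors for GenotypeMatrix and TraitMatrix
#'
#' @param x a [GenotypeMatrix-class] or [TraitMatrix-class].
#' @return `dosages()` the sample x SNP dosage matrix; `snpMap()` the SNP
#'   map; `traitValues()` the sample x feature matrix; `featureMap()` the
#'   feature coordinate map; `traitScale()` the scale tag.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setGeneric("snpMap", function(x) standardGeneric("snpMap"))
#' @rdname accessors
#' @export
setGeneric("traitValues", function(x) standardGeneric("traitValues"))
#' @rdname accessors
#' @export
setGeneric("featureMap", function(x) standardGeneric("featureMap"))
#' @rdname accessors
#' @export
setGeneric("traitScale", function(x) standardGeneric("traitScale"))

#' @rdname accessors
setMethod("dosages", "GenotypeMatrix", function(x) x@dosage)
#' @rdname accessors
setMethod("snpMap", "GenotypeMatrix", function(x) x@snpMap)
#' @rdname accessors
setMethod("traitValues", "TraitMatrix", function(x) x@values)
#' @rdname accessors
setMethod("featureMap", "TraitMatrix", function(x) x@featureMap)
#' @rdname accessors
setMethod("traitScale", "TraitMatrix", function(x) x@scale)

#' Construct a GenotypeMatrix
#'
#' @param dosage sample x SNP numeric matrix (values in `[0, 2]`, `NA`
#'   allowed). Column names, if absent, are taken from `snpMap$snp`.
#' @param snpMap data.frame with columns `snp`, `chrom`, `pos` and
#'   optionally `ref`, `alt`, `maf`, `info`, `call_rate`.
#' @return a validated [GenotypeMatrix-class].
#' @export
GenotypeMatrix <- function(dosage, snpMap) {
  snpMap$snp <- as.character(snpMap$snp)
  snpMap$chrom <- as.character(snpMap$chrom)
  if (is.null(colnames(dosage))) colnames(dosage) <- snpMap$snp
  rownames(snpMap) <- NULL
  new("GenotypeMatrix", dosage = dosage, snpMap = snpMap)
}

#' Construct a TraitMatrix
#'
#' @param values sample x feature numeric matrix.
#' @param featureMap data.frame with columns `feature`, `chrom`, `pos`.
#' @param scale one of `"M-value"`, `"beta"`, `"expression"`.
#' @return a validated [TraitMatrix-class].
#' @export
TraitMatrix <- function(values, featureMap, scale = "M-value") {
  featureMap$feature <- as.character(featureMap$feature)
  featureMap$chrom <- as.character(featureMap$chrom)
  if (is.null(colnames(values))) colnames(values) <- featureMap$feature
  rownames(featureMap) <- NULL
  new("TraitMatrix", values = values, featureMap = featureMap,
      scale = scale)
}

#' Convert between beta- and M-value methylation scales
#'
#' `betaToM` computes `M = log2(beta / (1 - beta))`; `mToBeta` its inverse
#' `beta = 2^M / (2^M + 1)`.
#'
#' @param beta,m numeric vectors or matrices.
#' @return the converted values.
#' @export
betaToM <- function(beta) log2(beta / (1 - beta))

#' @rdname betaToM
#' @export
mToBeta <- function(m) 2^m / (2^m + 1)
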