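# Readers and writers for the package's TSV boundary formats and a minimal
# dosage VCF. Coordinates are 1-based in every TSV; BED tracks keep their
# native 0-based half-open frame (see assignStates).

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a simulated cohort to a directory of TSV files
#'
#' Persists the genotype matrix (samples x SNPs, header row of SNP ids),
#' methylation and expression matrices, the three coordinate maps, the
#' covariates, the truth table and a minimal VCF (`genotypes.vcf`).
#'
#' @param sim list as returned by [simulateCohort()].
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of files written.
#' @export
writeCohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gm <- sim$genotypes
  out <- c(
    genotypes = file.path(dir, "genotypes.tsv"),
    snp_map = file.path(dir, "snp_map.tsv"),
    methylation = file.path(dir, "methylation_m.tsv"),
    cpg_map = file.path(dir, "cpg_map.tsv"),
    expression = file.path(dir, "expression.tsv"),
    transcript_map = file.path(dir, "transcript_map.tsv"),
    covariates = file.path(dir, "covariates.tsv"),
    truth = file.path(dir, "truth.tsv"),
    vcf = file.path(dir, "genotypes.vcf"))
  .writeTsv(data.frame(sample = rownames(dosages(gm)), dosages(gm),
                       check.names = FALSE), out["genotypes"])
  .writeTsv(snpMap(gm), out["snp_map"])
  .writeTsv(data.frame(sample = rownames(traitValues(sim$methylation)),
                       traitValues(sim$methylation), check.names = FALSE),
            out["methylation"])
  .writeTsv(featureMap(sim$methylation), out["cpg_map"])
  .writeTsv(data.frame(sample = rownames(traitValues(sim$expression)),
                       traitValues(sim$expression), check.names = FALSE),
            out["expression"])
  .writeTsv(featureMap(sim$expression), out["transcript_map"])
  .writeTsv(sim$covariates, out["covariates"])
  .writeTsv(sim$truth, out["truth"])
  writeGenotypesVcf(gm, out["vcf"])
  invisible(out)
}

#' Write genotypes as a minimal VCF
#'
#' Emits VCFv4.2 with `GT` derived by rounding the dosage (0 -> 0/0,
#' 1 -> 0/1, 2 -> 1/1, missing -> ./.) and `DS` carrying the dosage
#' itself.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeGenotypesVcf <- function(gm, path) {
  d <- dosages(gm)
  m <- snpMap(gm)
  samples <- rownames(d)
  if (is.null(samples)) samples <- sprintf("sample%03d", seq_len(nrow(d)))
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("##FORMAT=<ID=DS,Number=1,Type=Float,",
                  "Description=\"Dosage of the ALT allele\">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  gtOf <- c("0/0", "0/1", "1/1")
  lines <- vapply(seq_len(nrow(m)), function(i) {
    ds <- d[, i]
    gt <- ifelse(is.na(ds), "./.", gtOf[pmin(pmax(round(ds), 0), 2) + 1])
    dsStr <- ifelse(is.na(ds), ".", format(ds, trim = TRUE))
    paste(c(m$chrom[i], m$pos[i], m$snp[i],
            if (is.null(m$ref)) "A" else m$ref[i],
            if (is.null(m$alt)) "G" else m$alt[i],
            ".", "PASS", ".", "GT:DS", paste0(gt, ":", dsStr)),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read genotype dosages from a VCF
#'
#' Uses the `DS` FORMAT field when present, otherwise counts ALT alleles
#' in `GT`. Computes per-SNP MAF and call rate for [filterGenotypes()].
#'
#' @param path VCF file (plain or bgzipped).
#' @param genome genome tag passed to [VariantAnnotation::readVcf()].
#' @return a [GenotypeMatrix-class] (samples x SNPs).
#' @export
readGenotypesVcf <- function(path, genome = "unknown") {
  vcf <- VariantAnnotation::readVcf(path, genome = genome)
  gen <- VariantAnnotation::geno(vcf)
  if ("DS" %in% names(gen)) {
    ds <- gen$DS
    storage.mode(ds) <- "double"
  } else if ("GT" %in% names(gen)) {
    gt <- gen$GT
    cnt <- function(x) {
      if (is.na(x) || x %in% c("./.", ".")) return(NA_real_)
      sum(as.integer(strsplit(x, "[/|]")[[1]]) > 0)
    }
    ds <- apply(gt, c(1, 2), cnt)
  } else stop("VCF carries neither DS nor GT")
  ds <- t(ds)  # VariantAnnotation is variants x samples
  rr <- SummarizedExperiment::rowRanges(vcf)
  af <- colMeans(ds, na.rm = TRUE) / 2
  alt <- vapply(as(VariantAnnotation::alt(vcf), "CharacterList"),
                paste, character(1), collapse = ",")
  map <- data.frame(
    snp = names(rr),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = unname(alt),
    maf = pmin(af, 1 - af),
    call_rate = colMeans(!is.na(ds)),
    stringsAsFactors = FALSE)
  GenotypeMatrix(ds, map)
}

#' Read a sample x feature trait matrix with its coordinate map
#'
#' @param valuesPath TSV with a leading `sample` column and one column per
#'   feature.
#' @param mapPath TSV with columns `feature`, `chrom`, `pos` (1-based).
#' @param scale scale tag, see [TraitMatrix()].
#' @return a [TraitMatrix-class].
#' @export
readTraitMatrix <- function(valuesPath, mapPath, scale = "M-value") {
  v <- read.delim(valuesPath, check.names = FALSE)
  m <- read.delim(mapPath)
  mat <- as.matrix(v[, -1, drop = FALSE])
  rownames(mat) <- v[[1]]
  TraitMatrix(mat[, m$feature, drop = FALSE], m, scale = scale)
}

#' Read a genotype dosage TSV with its SNP map
#'
#' @param dosagePath TSV with a leading `sample` column and one column per
#'   SNP.
#' @param mapPath TSV with columns `snp`, `chrom`, `pos` and optional
#'   `ref`, `alt`, `maf`, `info`, `call_rate`.
#' @return a [GenotypeMatrix-class].
#' @export
readGenotypesTsv <- function(dosagePath, mapPath) {
  v <- read.delim(dosagePath, check.names = FALSE)
  m <- read.delim(mapPath)
  mat <- as.matrix(v[, -1, drop = FALSE])
  rownames(mat) <- v[[1]]
  GenotypeMatrix(mat[, m$snp, drop = FALSE], m)
}
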