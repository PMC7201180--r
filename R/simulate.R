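# Synthetic cohort generator: genotypes with HWE + block-LD structure,
# methylation/expression with planted SNP -> CpG -> transcript triplets,
# covariates with a diagnosis label, and a ground-truth table.

# Evaluate expr under a local RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Create a synthetic-cohort configuration
#'
#' Thin constructor over [SimConfig-class]; any omitted argument keeps the
#' class default, which emulates an early-arthritis QTL cohort (120
#' patients, 40% cases, 500 SNPs in 5-SNP LD blocks, 300 CpGs, 100
#' transcripts on 2 chromosomes).
#'
#' @param nSamples,nSnps,nCpgs,nTranscripts,nChrom,chromLength counts / bp.
#' @param mafRange length-2 numeric in (0, 0.5].
#' @param ldBlockSize,ldRho LD block size and copy probability.
#' @param plantedTriplets data.frame from rows of [plantedTriplet()].
#' @param interactionEffects data.frame (`snp`, `cpg`, `delta`).
#' @param diagnosisFraction case fraction in (0, 1).
#' @param noiseSdMethylation,noiseSdExpression residual SDs.
#' @param seed integer seed.
#' @return a validated [SimConfig-class].
#' @examples
#' cfg <- simConfig(nSamples = 50, nSnps = 20, nCpgs = 10,
#'                  nTranscripts = 5, seed = 7)
#' @export
simConfig <- function(nSamples = 120, nSnps = 500, mafRange = c(0.05, 0.5),
                      ldBlockSize = 5, ldRho = 0.8, nCpgs = 300,
                      nTranscripts = 100, nChrom = 2, chromLength = 1e8,
                      plantedTriplets = NULL, interactionEffects = NULL,
                      diagnosisFraction = 0.4, noiseSdMethylation = 0.5,
                      noiseSdExpression = 0.5, seed = 1) {
  new("SimConfig", nSamples = nSamples, nSnps = nSnps, mafRange = mafRange,
      ldBlockSize = ldBlockSize, ldRho = ldRho, nCpgs = nCpgs,
      nTranscripts = nTranscripts, nChrom = nChrom,
      chromLength = chromLength, plantedTriplets = plantedTriplets,
      interactionEffects = interactionEffects,
      diagnosisFraction = diagnosisFraction,
      noiseSdMethylation = noiseSdMethylation,
      noiseSdExpression = noiseSdExpression, seed = seed)
}

#' Declare a planted SNP-CpG-transcript triplet
#'
#' One row of ground truth for the simulator under one of four regulatory
#' models: `causal` (SNP -> CpG -> transcript), `reactive`
#' (SNP -> transcript -> CpG), `independent` (SNP affects both, no
#' mediation) and `null` (no effects).
#'
#' @param snp,cpg,transcript feature ids (must exist in the generated
#'   matrices: `snp<k>`, `cg<k>`, `tx<k>`).
#' @param model one of `"causal"`, `"reactive"`, `"independent"`, `"null"`.
#' @param aLM dosage -> mediator effect (M-value per allele).
#' @param bMT mediator -> outcome effect.
#' @param cLT direct dosage -> outcome effect.
#' @return one-row data.frame.
#' @export
plantedTriplet <- function(snp, cpg, transcript,
                           model = c("causal", "reactive", "independent",
                                     "null"),
                           aLM = 0, bMT = 0, cLT = 0) {
  model <- match.arg(model)
  ok <- switch(model,
    null        = aLM == 0 && bMT == 0 && cLT == 0,
    causal      = cLT == 0 && aLM != 0 && bMT != 0,
    independent = bMT == 0 && aLM != 0 && cLT != 0,
    reactive    = aLM == 0 && bMT != 0 && cLT != 0)
  if (!ok)
    stop("effect sizes inconsistent with model '", model, "'")
  data.frame(snp = snp, cpg = cpg, transcript = transcript, model = model,
             a_LM = aLM, b_MT = bMT, c_LT = cLT,
             stringsAsFactors = FALSE)
}

# Internal generator: assumes the RNG is already seeded.
.simGenotypes <- function(config) {
  n <- config@nSamples
  s <- config@nSnps
  rho <- config@ldRho
  bs <- config@ldBlockSize
  nChrom <- config@nChrom

  # contiguous chromosome chunks; LD blocks restart at chromosome starts
  chromOf <- rep(seq_len(nChrom), each = ceiling(s / nChrom))[seq_len(s)]
  block <- integer(s)
  b <- 0L
  for (i in seq_len(s)) {
    newBlock <- i == 1L || chromOf[i] != chromOf[i - 1L] ||
      (i - 1L) %% bs == 0L
    if (newBlock) b <- b + 1L
    block[i] <- b
  }

  nBlocks <- max(block)
  blockMaf <- runif(nBlocks, config@mafRange[1], config@mafRange[2])
  maf <- blockMaf[block]

  # two haplotypes per sample; within a block each SNP copies the previous
  # SNP's allele with probability rho, else draws fresh at the block MAF
  hap1 <- matrix(0L, n, s)
  hap2 <- matrix(0L, n, s)
  for (i in seq_len(s)) {
    fresh1 <- rbinom(n, 1L, maf[i])
    fresh2 <- rbinom(n, 1L, maf[i])
    if (i > 1L && block[i] == block[i - 1L] && rho > 0) {
      keep1 <- runif(n) < rho
      keep2 <- runif(n) < rho
      hap1[, i] <- ifelse(keep1, hap1[, i - 1L], fresh1)
      hap2[, i] <- ifelse(keep2, hap2[, i - 1L], fresh2)
    } else {
      hap1[, i] <- fresh1
      hap2[, i] <- fresh2
    }
  }
  dosage <- hap1 + hap2
  storage.mode(dosage) <- "double"

  # compact physical blocks (5-25 kb SNP spacing), ordered along each
  # chromosome
  pos <- numeric(s)
  for (ch in seq_len(nChrom)) {
    idx <- which(chromOf == ch)
    blk <- unique(block[idx])
    starts <- sort(runif(length(blk), 1, config@chromLength * 0.95))
    for (k in seq_along(blk)) {
      members <- idx[block[idx] == blk[k]]
      offs <- cumsum(c(0, runif(length(members) - 1, 5e3, 2.5e4)))
      pos[members] <- round(starts[k] + offs)
    }
  }

  ids <- sprintf("snp%04d", seq_len(s))
  colnames(dosage) <- ids
  rownames(dosage) <- sprintf("sample%03d", seq_len(n))
  map <- data.frame(
    snp = ids, chrom = paste0("chr", chromOf), pos = pos,
    ref = "A", alt = "G", maf = maf,
    info = rep(1, s), call_rate = rep(1, s),
    stringsAsFactors = FALSE)
  GenotypeMatrix(dosage, map)
}

#' Simulate genotype dosages with Hardy-Weinberg and LD-block structure
#'
#' Draws two haplotypes per sample. Within each LD block every SNP copies
#' the previous SNP's allele with probability `ldRho` and otherwise draws a
#' fresh allele at the block's minor allele frequency, so adjacent-SNP
#' dosage correlation is about `ldRho` and genotypes are in Hardy-Weinberg
#' proportions marginally. SNPs get increasing 1-based positions on
#' `nChrom` chromosomes, with physically compact blocks.
#'
#' @param config a [SimConfig-class].
#' @return a [GenotypeMatrix-class]; same seed gives identical output.
#' @examples
#' gm <- simulateGenotypes(simConfig(nSamples = 20, nSnps = 10, seed = 1))
#' @export
simulateGenotypes <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  withSeed(config@seed, .simGenotypes(config))
}

#' Simulate a full cohort with planted causal structure
#'
#' Generates genotypes (or reuses `genotypes`), a diagnosis label and basic
#' covariates, methylation M-values, expression values and the ground-truth
#' table. Planted triplets follow their model:
#' causal `M = a*G + e, T = b*M + e'`; independent `M = a*G + e,
#' T = c*G + e'` with independent errors; reactive `T = c*G + e,
#' M = b*T + e'`; null is pure noise. Interaction effects add a
#' genotype-slope difference between diagnosis groups to the named CpG.
#' Non-planted features are baseline plus noise. Planted CpGs are placed
#' within 100 kb of their SNP and planted transcripts within 100 kb of
#' their CpG so that cis windows apply downstream.
#'
#' @param config a [SimConfig-class].
#' @param genotypes optional [GenotypeMatrix-class] to reuse (e.g. a second
#'   cell type on the same patients).
#' @return list with elements `genotypes`, `methylation` (M-value
#'   [TraitMatrix-class]), `methylationBeta` (paired beta-values),
#'   `expression`, `covariates` (data.frame with `age`, `sex`,
#'   `diagnosis`), `truth` (truth table data.frame).
#' @examples
#' pt <- plantedTriplet("snp0001", "cg0001", "tx0001", "causal",
#'                      aLM = 0.8, bMT = 0.8)
#' sim <- simulateCohort(simConfig(nSamples = 60, nSnps = 20, nCpgs = 10,
#'                                 nTranscripts = 5,
#'                                 plantedTriplets = pt, seed = 3))
#' @export
simulateCohort <- function(config, genotypes = NULL) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  withSeed(config@seed, {
    gm <- if (is.null(genotypes)) .simGenotypes(config) else genotypes
    .simTraits(config, gm)
  })
}

.simTraits <- function(config, gm) {
  n <- config@nSamples
  G <- dosages(gm)
  if (nrow(G) != n)
    stop("genotype matrix rows do not match nSamples")
  smap <- snpMap(gm)

  pt <- config@plantedTriplets
  if (is.null(pt))
    pt <- data.frame(snp = character(), cpg = character(),
                     transcript = character(), model = character(),
                     a_LM = numeric(), b_MT = numeric(), c_LT = numeric(),
                     stringsAsFactors = FALSE)

  cpgIds <- sprintf("cg%04d", seq_len(config@nCpgs))
  txIds <- sprintf("tx%04d", seq_len(config@nTranscripts))

  dangling <- c(setdiff(pt$snp, smap$snp), setdiff(pt$cpg, cpgIds),
                setdiff(pt$transcript, txIds))
  ie <- config@interactionEffects
  if (!is.null(ie))
    dangling <- c(dangling, setdiff(ie$snp, smap$snp),
                  setdiff(ie$cpg, cpgIds))
  if (length(dangling))
    stop("planted ids not present in generated matrices: ",
         paste(unique(dangling), collapse = ", "))

  diagnosis <- rbinom(n, 1L, config@diagnosisFraction)
  # guard degenerate single-group draws at small n
  if (length(unique(diagnosis)) == 1L) diagnosis[1:2] <- c(0L, 1L)
  covariates <- data.frame(
    sample = rownames(G),
    age = round(rnorm(n, 55, 10)),
    sex = rbinom(n, 1L, 0.7),
    diagnosis = diagnosis,
    stringsAsFactors = FALSE)

  chroms <- unique(smap$chrom)
  randCoord <- function(k) {
    data.frame(chrom = sample(chroms, k, replace = TRUE),
               pos = round(runif(k, 1, config@chromLength)))
  }
  cpgMap <- cbind(feature = cpgIds, randCoord(config@nCpgs),
                  stringsAsFactors = FALSE)
  txMap <- cbind(feature = txIds, randCoord(config@nTranscripts),
                 stringsAsFactors = FALSE)

  # co-locate planted features: CpG within 100 kb of its SNP, transcript
  # within 100 kb of the CpG
  for (i in seq_len(nrow(pt))) {
    si <- match(pt$snp[i], smap$snp)
    ci <- match(pt$cpg[i], cpgMap$feature)
    ti <- match(pt$transcript[i], txMap$feature)
    cpgMap$chrom[ci] <- smap$chrom[si]
    cpgMap$pos[ci] <- max(1, smap$pos[si] + round(runif(1, -1e5, 1e5)))
    txMap$chrom[ti] <- smap$chrom[si]
    txMap$pos[ti] <- max(1, cpgMap$pos[ci] + round(runif(1, -1e5, 1e5)))
  }

  muM <- rnorm(config@nCpgs, 0, 2)
  muT <- rnorm(config@nTranscripts, 5, 2)
  M <- matrix(rnorm(n * config@nCpgs, 0, config@noiseSdMethylation),
              n, config@nCpgs)
  M <- sweep(M, 2, muM, "+")
  TT <- matrix(rnorm(n * config@nTranscripts, 0, config@noiseSdExpression),
               n, config@nTranscripts)
  TT <- sweep(TT, 2, muT, "+")
  colnames(M) <- cpgIds
  colnames(TT) <- txIds
  rownames(M) <- rownames(TT) <- rownames(G)

  for (i in seq_len(nrow(pt))) {
    g <- G[, pt$snp[i]]
    ci <- pt$cpg[i]
    ti <- pt$transcript[i]
    switch(pt$model[i],
      causal = {
        M[, ci] <- M[, ci] + pt$a_LM[i] * g
        TT[, ti] <- TT[, ti] + pt$b_MT[i] * M[, ci]
      },
      independent = {
        M[, ci] <- M[, ci] + pt$a_LM[i] * g
        TT[, ti] <- TT[, ti] + pt$c_LT[i] * g
      },
      reactive = {
        TT[, ti] <- TT[, ti] + pt$c_LT[i] * g
        M[, ci] <- M[, ci] + pt$b_MT[i] * TT[, ti]
      },
      null = NULL)
  }

  if (!is.null(ie))
    for (i in seq_len(nrow(ie)))
      M[, ie$cpg[i]] <- M[, ie$cpg[i]] +
        ie$delta[i] * G[, ie$snp[i]] * diagnosis

  truth <- pt
  if (nrow(truth)) {
    truth$snp_chrom <- smap$chrom[match(truth$snp, smap$snp)]
    truth$snp_pos <- smap$pos[match(truth$snp, smap$snp)]
    truth$cpg_pos <- cpgMap$pos[match(truth$cpg, cpgMap$feature)]
    truth$transcript_pos <- txMap$pos[match(truth$transcript,
                                            txMap$feature)]
  }

  meth <- TraitMatrix(M, cpgMap, scale = "M-value")
  list(genotypes = gm,
       methylation = meth,
       methylationBeta = TraitMatrix(mToBeta(M), cpgMap, scale = "beta"),
       expression = TraitMatrix(TT, txMap, scale = "expression"),
       covariates = covariates,
       truth = truth)
}
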