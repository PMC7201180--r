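# End-to-end orchestration over one or more cell types
# (simulate/load -> QC -> meQTL scan -> clump -> risk-locus intersection
# -> [coloc] -> eQTM -> CIT forward/reverse -> classification -> summary)
# plus the set-algebra summary operations reported by the analysis.

#' Locus-overlap arithmetic between two cell types
#'
#' Pure set algebra on risk-locus hit sets: counts loci with meQTL
#' evidence in both cell types, in each cell type only, the total, and
#' the percentage of the union of represented loci harbouring meQTLs
#' (rounded to the nearest integer).
#'
#' @param hitsA,hitsB character vectors of meQTL-positive locus ids per
#'   cell type.
#' @param union character vector of all represented (tested) loci; every
#'   hit must belong to it.
#' @return list with `both`, `a_only`, `b_only`, `total_hit`, `union_n`,
#'   `pct`.
#' @examples
#' summarizeLocusOverlap(paste0("L", 1:32), paste0("L", c(1:24, 33:41)),
#'                       paste0("L", 1:112))
#' @export
summarizeLocusOverlap <- function(hitsA, hitsB, union) {
  hitsA <- unique(hitsA); hitsB <- unique(hitsB); union <- unique(union)
  stray <- setdiff(c(hitsA, hitsB), union)
  if (length(stray))
    stop("hit loci absent from the union: ",
         paste(stray, collapse = ", "))
  both <- length(intersect(hitsA, hitsB))
  aOnly <- length(setdiff(hitsA, hitsB))
  bOnly <- length(setdiff(hitsB, hitsA))
  total <- both + aOnly + bOnly
  list(both = both, a_only = aOnly, b_only = bOnly, total_hit = total,
       union_n = length(union),
       pct = round(100 * total / length(union)))
}

#' Percentage of a locus set shared with another
#'
#' @param shared count (or vector) of loci shared across traits.
#' @param total count (or vector) of all loci in the reference set.
#' @return integer percentage, rounded to the nearest integer.
#' @export
sharedLocusPct <- function(shared, total) {
  s <- if (length(shared) > 1) length(unique(shared)) else shared
  t <- if (length(total) > 1) length(unique(total)) else total
  round(100 * s / t)
}

#' Venn partition counts over up to four gene sets
#'
#' @param geneSets named list (one element per trait/cell combination) of
#'   character vectors.
#' @return data.frame with one row per non-empty trait combination
#'   (`region`, ampersand-joined set names) and the count of genes in
#'   exactly those sets.
#' @export
crossDiseaseOverlap <- function(geneSets) {
  stopifnot(length(geneSets) >= 1, length(geneSets) <= 4)
  nm <- names(geneSets)
  allGenes <- unique(unlist(geneSets))
  member <- vapply(geneSets, function(s) allGenes %in% s,
                   logical(length(allGenes)))
  if (length(allGenes) == 1) member <- matrix(member, nrow = 1)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(nm)))
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  out <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- as.logical(combos[i, ])
    inRegion <- if (length(allGenes))
      rowSums(member[, sel, drop = FALSE]) == sum(sel) &
      rowSums(member[, !sel, drop = FALSE]) == 0
    else logical(0)
    data.frame(region = paste(nm[sel], collapse = "&"),
               count = sum(inRegion), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Distinct risk loci passing the CIT permutation-FDR filter
#'
#' @param citTable data.frame with columns `locus` and `perm_fdr` (e.g. a
#'   per-cell CIT result table).
#' @param fdrThreshold threshold on the permutation FDR.
#' @return sorted character vector of distinct loci with at least one
#'   passing row.
#' @export
mediatedLoci <- function(citTable, fdrThreshold = 0.05) {
  sort(unique(citTable$locus[citTable$perm_fdr < fdrThreshold]))
}

.defaultParams <- function() {
  list(cisWindow = 1e6, meqtlFdr = 0.05, clumpR2 = 0.8,
       clumpWindowBp = 1e6, eqtmWindowBp = 5e5, eqtmFdr = 0.01,
       citFdr = 0.05, nPermComponent = 1000, nPermFdr = 1000,
       pp4Min = 0.75, pp4Pp3RatioMin = 5, colocPriorSd = 0.15,
       inferCovariatesK = 0)
}

#' Run the integrated meQTL -> eQTM -> CIT pipeline
#'
#' Stages, per cell type: simulate (or load) the cohort; SNP QC filters;
#' additive meQTL scan with covariates and BH FDR; greedy clumping of
#' significant associations; LD-block construction around each risk
#' variant and risk-locus intersection; optional Bayesian colocalization
#' against supplied GWAS summary statistics; windowed Spearman eQTM
#' mapping at risk-associated CpGs; forward and reverse CIT with
#' permutation FDR on all (risk SNP, CpG, transcript) triplets showing
#' both cis-meQTL and cis-eQTM evidence; triplet classification. Then a
#' cross-cell summary (locus overlap arithmetic, mediated gene sets).
#' Identical config and seeds give identical outputs.
#'
#' @param config named list or path to a YAML file with components
#'   `seed`, `cells` (vector of labels), `simulate` (arguments of
#'   [simConfig()]; planted triplets as a data.frame or list of rows),
#'   optional `riskLoci` (data.frame `locus`/`trait`/`variant`; default:
#'   one locus per planted non-null triplet SNP), optional `gwas`
#'   (data.frame `variant`/`beta`/`se` of disease summary statistics),
#'   and `parameters` overriding any analysis default (cis window 1 Mb,
#'   meQTL FDR 0.05, clump r2 0.8 / 1 Mb, eQTM window 500 kb / FDR 0.01,
#'   CIT FDR 0.05, PP4 > 0.75 with PP4/PP3 > 5, ABF prior SD 0.15).
#' @param outDir optional directory; when given, every stage table is
#'   persisted as TSV together with a YAML provenance log (stage
#'   parameters and seeds).
#' @return list with per-cell stage outputs (`cells`) and the summary
#'   report (`summary`).
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  params <- utils::modifyList(.defaultParams(),
                              config$parameters %||% list())
  seed <- config$seed %||% 1
  cells <- config$cells %||% "cellA"
  simArgs <- config$simulate %||% list()
  if (!is.null(simArgs$plantedTriplets) &&
      !is.data.frame(simArgs$plantedTriplets))
    simArgs$plantedTriplets <-
      do.call(rbind, lapply(simArgs$plantedTriplets, as.data.frame))

  if (!is.null(outDir))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  persist <- function(df, name) {
    if (!is.null(outDir) && is.data.frame(df))
      .writeTsv(df, file.path(outDir, paste0(name, ".tsv")))
  }

  genotypes <- NULL
  cellOut <- list()
  for (ci in seq_along(cells)) {
    cell <- cells[ci]
    cfg <- do.call(simConfig, c(simArgs, list(seed = seed + ci - 1)))
    sim <- simulateCohort(cfg, genotypes = genotypes)
    if (is.null(genotypes)) genotypes <- sim$genotypes

    gm <- filterGenotypes(sim$genotypes)
    cov <- sim$covariates
    if (params$inferCovariatesK > 0)
      cov <- inferCovariates(sim$methylation, cov,
                             k = params$inferCovariatesK)

    meqtl <- scanQtl(gm, sim$methylation, cov,
                     cisWindow = params$cisWindow)
    sig <- meqtl[meqtl$q < params$meqtlFdr, , drop = FALSE]
    clumps <- if (nrow(sig))
      clumpAssociations(sig, gm, params$clumpR2, params$clumpWindowBp)
    else sig

    riskLoci <- config$riskLoci
    if (is.null(riskLoci)) {
      pt <- sim$truth
      pt <- pt[pt$model != "null", , drop = FALSE]
      riskLoci <- if (nrow(pt))
        data.frame(locus = paste0("locus_", unique(pt$snp)),
                   trait = "RA", variant = unique(pt$snp),
                   stringsAsFactors = FALSE)
      else data.frame(locus = character(), trait = character(),
                      variant = character())
    }
    keepLoci <- riskLoci$variant %in% snpMap(gm)$snp
    riskLoci <- riskLoci[keepLoci, , drop = FALSE]
    blocks <- lapply(riskLoci$variant, ldBlock, gm = gm,
                     r2Threshold = params$clumpR2,
                     windowBp = params$clumpWindowBp)
    names(blocks) <- riskLoci$locus
    lociHits <- if (nrow(riskLoci) && nrow(clumps))
      intersectRiskLoci(clumps, riskLoci, blocks)
    else data.frame(locus = character(), trait = character(),
                    variant = character(), hit = logical(),
                    n_pairs = integer(), cpgs = character(),
                    lead_snps = character())

    coloc <- NULL
    if (!is.null(config$gwas) && nrow(lociHits)) {
      gwas <- config$gwas
      coloc <- do.call(rbind, lapply(
        which(lociHits$hit), function(i) {
          blk <- blocks[[lociHits$locus[i]]]
          snps <- intersect(blk@proxies$snp, gwas$variant)
          cpg <- strsplit(lociHits$cpgs[i], ";")[[1]][1]
          me <- meqtl[meqtl$feature == cpg & meqtl$snp %in% snps, ]
          snps <- intersect(snps, me$snp)
          if (length(snps) < 1) return(NULL)
          gw <- gwas[match(snps, gwas$variant), ]
          me <- me[match(snps, me$snp), ]
          l1 <- wakefieldLogAbf(gw$beta, gw$se,
                                priorSd = params$colocPriorSd)
          l2 <- wakefieldLogAbf(me$beta, me$se,
                                priorSd = params$colocPriorSd)
          cp <- colocPosteriors(setNames(l1, snps), setNames(l2, snps))
          data.frame(locus = lociHits$locus[i], n_snps = cp$nsnps,
                     t(cp$pp),
                     gate = colocGate(cp, params$pp4Min,
                                      params$pp4Pp3RatioMin),
                     stringsAsFactors = FALSE)
        }))
    }

    riskCpgs <- unique(unlist(strsplit(
      lociHits$cpgs[lociHits$hit], ";")))
    riskCpgs <- riskCpgs[nzchar(riskCpgs)]
    eqtm <- if (length(riskCpgs))
      mapEqtm(sim$methylation, sim$expression, cpgs = riskCpgs,
              windowBp = params$eqtmWindowBp)
    else mapEqtm(sim$methylation, sim$expression,
                 cpgs = character(0))

    # triplets at loci with both cis-meQTL and cis-eQTM evidence
    tripletTab <- NULL
    if (nrow(eqtm)) {
      sigEqtm <- eqtm[eqtm$q < params$eqtmFdr, , drop = FALSE]
      rows <- list()
      for (i in which(lociHits$hit)) {
        cpgs <- strsplit(lociHits$cpgs[i], ";")[[1]]
        leads <- strsplit(lociHits$lead_snps[i], ";")[[1]]
        hits <- sigEqtm[sigEqtm$cpg %in% cpgs, , drop = FALSE]
        for (j in seq_len(nrow(hits)))
          rows[[length(rows) + 1L]] <- data.frame(
            locus = lociHits$locus[i], snp = leads[1],
            cpg = hits$cpg[j], transcript = hits$transcript[j],
            stringsAsFactors = FALSE)
      }
      if (length(rows)) tripletTab <- unique(do.call(rbind, rows))
    }

    citF <- citR <- calls <- NULL
    if (!is.null(tripletTab) && nrow(tripletTab)) {
      G <- dosages(gm)
      Mx <- traitValues(sim$methylation)
      Ex <- traitValues(sim$expression)
      triplets <- lapply(seq_len(nrow(tripletTab)), function(i)
        list(id = paste(tripletTab$snp[i], tripletTab$cpg[i],
                        tripletTab$transcript[i], sep = "|"),
             L = G[, tripletTab$snp[i]],
             M = Mx[, tripletTab$cpg[i]],
             T = Ex[, tripletTab$transcript[i]]))
      citF <- citPermutationFdr(triplets, nPerm = params$nPermFdr,
                                nPermComponent = params$nPermComponent,
                                seed = seed + 101 * ci)
      citR <- citPermutationFdr(triplets, nPerm = params$nPermFdr,
                                nPermComponent = params$nPermComponent,
                                seed = seed + 101 * ci, reverse = TRUE)
      calls <- classifyTriplets(citF, citR, params$citFdr)
      calls <- cbind(tripletTab, calls[, c("forward_fdr", "reverse_fdr",
                                           "call")])
    }

    inverseFrac <- if (nrow(eqtm))
      mean(eqtm$direction[eqtm$q < params$eqtmFdr] == "inverse")
    else NA_real_

    persist(meqtl, paste0(cell, "_meqtl"))
    persist(clumps, paste0(cell, "_clumps"))
    persist(lociHits, paste0(cell, "_risk_loci"))
    persist(coloc, paste0(cell, "_coloc"))
    persist(eqtm, paste0(cell, "_eqtm"))
    persist(calls, paste0(cell, "_cit_calls"))

    cellOut[[cell]] <- list(
      sim = sim, meqtl = meqtl, clumps = clumps, lociHits = lociHits,
      coloc = coloc, eqtm = eqtm, citForward = citF, citReverse = citR,
      citCalls = calls,
      counts = list(
        n_cis = sum(sig$relation == "cis"),
        n_trans = sum(sig$relation == "trans"),
        n_clumps = if (is.null(nrow(clumps))) 0L else nrow(clumps),
        eqtm_associations = sum(eqtm$q < params$eqtmFdr),
        eqtm_cpgs = length(unique(
          eqtm$cpg[eqtm$q < params$eqtmFdr])),
        eqtm_genes = length(unique(
          eqtm$transcript[eqtm$q < params$eqtmFdr])),
        inverse_fraction = inverseFrac))
  }

  unionLoci <- unique(unlist(lapply(cellOut, function(co)
    co$lociHits$locus)))
  hitSets <- lapply(cellOut, function(co)
    co$lociHits$locus[co$lociHits$hit])
  overlap <- if (length(cellOut) >= 2)
    summarizeLocusOverlap(hitSets[[1]], hitSets[[2]], unionLoci)
  else NULL

  mediatedGenes <- lapply(cellOut, function(co) {
    if (is.null(co$citCalls)) character(0)
    else unique(co$citCalls$transcript[co$citCalls$call == "mediated"])
  })

  summary <- list(
    per_cell = lapply(cellOut, `[[`, "counts"),
    locus_overlap = overlap,
    union_loci = unionLoci,
    mediated_genes = mediatedGenes,
    mediated_calls = lapply(cellOut, `[[`, "citCalls"))

  if (!is.null(outDir)) {
    yaml::write_yaml(
      list(seed = seed, cells = as.list(cells), parameters = params),
      file.path(outDir, "pipeline_log.yaml"))
  }
  list(cells = cellOut, summary = summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
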