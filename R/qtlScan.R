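# meQTL scanning: SNP QC filters, additive OLS scan of every SNP-feature
# pair with covariates, cis/trans classification, BH FDR across all tests,
# the Genotype x Diagnosis interaction scan, and residual-PCA covariate
# inference. The per-pair OLS is computed by the Frisch-Waugh-Lovell
# decomposition: traits and dosages are residualized on the covariate
# design once, then slope/SE/t follow from cross-products, which is exact
# and lets the scan run as matrix algebra.

#' Apply SNP quality-control filters
#'
#' Removes SNPs with call rate below `minCallRate`, minor allele frequency
#' below `minMaf`, or imputation INFO score below `minInfo`. A criterion
#' whose metadata column is absent from the SNP map is skipped with a
#' warning. All rules are strict "less than" exclusions, so a SNP sitting
#' exactly at a threshold is retained.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param minCallRate,minMaf,minInfo thresholds in `[0, 1]`.
#' @return the filtered [GenotypeMatrix-class].
#' @export
filterGenotypes <- function(gm, minCallRate = 0.98, minMaf = 0.01,
                            minInfo = 0.8) {
  stopifnot(minCallRate >= 0, minCallRate <= 1, minMaf >= 0, minMaf <= 1,
            minInfo >= 0, minInfo <= 1)
  m <- snpMap(gm)
  keep <- rep(TRUE, nrow(m))
  apply1 <- function(col, thr, keep) {
    if (is.null(m[[col]])) {
      warning("SNP map lacks '", col, "'; skipping that filter")
      keep
    } else keep & !(m[[col]] < thr)
  }
  keep <- apply1("call_rate", minCallRate, keep)
  keep <- apply1("maf", minMaf, keep)
  keep <- apply1("info", minInfo, keep)
  if (!any(keep)) stop("no SNPs survive the quality filters")
  GenotypeMatrix(dosages(gm)[, keep, drop = FALSE],
                 m[keep, , drop = FALSE])
}

#' Genotype-class testability rule
#'
#' A SNP is testable when all three genotype classes (dosages rounded to
#' 0/1/2) hold at least `minPerClass` individuals, or, when the
#' minor-allele homozygote class is empty, at least
#' `minHetWithoutMinorHom` heterozygotes are present. Missing dosages are
#' excluded from the counts.
#'
#' @param dosage numeric dosage vector for one SNP.
#' @param minPerClass minimum count per genotype class.
#' @param minHetWithoutMinorHom minimum heterozygote count when minor
#'   homozygotes are absent.
#' @return logical scalar.
#' @export
testableMask <- function(dosage, minPerClass = 3,
                         minHetWithoutMinorHom = 8) {
  d <- round(dosage[!is.na(dosage)])
  if (!length(d)) {
    warning("all dosages missing; SNP not testable")
    return(FALSE)
  }
  n0 <- sum(d == 0); n1 <- sum(d == 1); n2 <- sum(d == 2)
  af <- mean(d) / 2
  minorHom <- if (af <= 0.5) n2 else n0
  if (n0 >= minPerClass && n1 >= minPerClass && n2 >= minPerClass)
    return(TRUE)
  minorHom == 0 && n1 >= minHetWithoutMinorHom
}

# residualize the columns of M on the design qr object
.residOn <- function(qrC, M) {
  as.matrix(qr.resid(qrC, M))
}

# covariate design: intercept + all numeric columns except `sample`
.covDesign <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1))
  df <- covariates[, setdiff(names(covariates), "sample"), drop = FALSE]
  X <- cbind(`(Intercept)` = 1, as.matrix(data.matrix(df)))
  if (qr(X)$rank < ncol(X))
    stop("covariate design is rank deficient after adding an intercept")
  X
}

# mean-impute missing dosages per SNP; returns list(imputed, nUsed)
.imputeDosage <- function(G) {
  nUsed <- colSums(!is.na(G))
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }
  list(G = G, nUsed = nUsed)
}

.cisRelation <- function(smap, fmap, window) {
  sameChrom <- outer(smap$chrom, fmap$chrom, "==")
  dist <- abs(outer(smap$pos, fmap$pos, "-"))
  dist[!sameChrom] <- NA_real_
  relation <- ifelse(sameChrom & dist < window, "cis", "trans")
  list(relation = relation, distance = dist)
}

#' Scan every SNP-feature pair with an additive linear model
#'
#' For each pair, fits ordinary least squares of the trait on dosage with
#' an intercept and the supplied covariates; reports the slope (trait
#' units per alt allele), its SE, t statistic and two-sided p from the t
#' distribution with `n - k` residual degrees of freedom. Missing dosages
#' are mean-imputed per SNP (`n` records the observed count). SNPs failing
#' [testableMask()] are dropped. A pair is `cis` when SNP and feature share
#' a chromosome and are separated by less than `cisWindow` bp, `trans`
#' otherwise (cross-chromosome distance is `NA`). Benjamini-Hochberg
#' q-values are computed across all tests jointly.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param tm a [TraitMatrix-class] aligned to the same samples.
#' @param covariates optional data.frame of per-sample covariates
#'   (numeric; a `sample` id column is ignored).
#' @param cisWindow cis distance bound in bp (strict `<`).
#' @param applyTestableMask drop SNPs failing the genotype-class rule.
#' @return data.frame with columns `snp`, `feature`, `beta`, `se`, `t`,
#'   `p`, `q`, `n`, `relation`, `distance`, ordered by (snp, feature).
#' @examples
#' sim <- simulateCohort(simConfig(nSamples = 60, nSnps = 10, nCpgs = 5,
#'                                 nTranscripts = 2, seed = 11))
#' res <- scanQtl(sim$genotypes, sim$methylation, sim$covariates)
#' @export
scanQtl <- function(gm, tm, covariates = NULL, cisWindow = 1e6,
                    applyTestableMask = TRUE) {
  G <- dosages(gm)
  Y <- traitValues(tm)
  if (nrow(G) != nrow(Y))
    stop("genotype and trait matrices have different sample counts")
  if (!is.null(rownames(G)) && !is.null(rownames(Y)) &&
      !identical(rownames(G), rownames(Y)))
    stop("sample ids of genotype and trait matrices are not aligned")
  smap <- snpMap(gm)

  if (applyTestableMask) {
    ok <- vapply(seq_len(ncol(G)),
                 function(j) testableMask(G[, j]), logical(1))
    G <- G[, ok, drop = FALSE]
    smap <- smap[ok, , drop = FALSE]
  }
  if (!ncol(G)) stop("no testable SNPs")

  n <- nrow(G)
  C <- .covDesign(covariates, n)
  k <- ncol(C) + 1L            # intercept+covariates+dosage
  df <- n - k
  if (df < 2) stop("not enough samples for the covariate design")

  imp <- .imputeDosage(G)
  qrC <- qr(C)
  Gres <- .residOn(qrC, imp$G)
  Yres <- .residOn(qrC, Y)
  gss <- colSums(Gres^2)
  yss <- colSums(Yres^2)
  xy <- crossprod(Gres, Yres)              # SNP x feature
  beta <- xy / gss
  rss <- pmax(sweep(-beta * xy, 2, yss, "+"), 0)
  se <- sqrt(rss / df / gss)
  tstat <- beta / se
  p <- 2 * pt(-abs(tstat), df)

  fmap <- featureMap(tm)
  rel <- .cisRelation(smap, fmap, cisWindow)

  res <- data.frame(
    snp = rep(smap$snp, times = ncol(Y)),
    feature = rep(fmap$feature, each = ncol(G)),
    beta = as.vector(beta), se = as.vector(se), t = as.vector(tstat),
    p = as.vector(p), q = NA_real_,
    n = rep(imp$nUsed, times = ncol(Y)),
    relation = as.vector(rel$relation),
    distance = as.vector(rel$distance),
    stringsAsFactors = FALSE)
  res <- res[is.finite(res$p), , drop = FALSE]
  res$q <- bhFdr(res$p)
  res <- res[order(res$snp, res$feature), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg step-up q-values
#'
#' Computed across the full set of supplied p-values (cis and trans tests
#' jointly). Thin, named wrapper over `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values of the same length; empty input gives empty output.
#' @export
bhFdr <- function(p) {
  if (!length(p)) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Genotype x Diagnosis interaction scan
#'
#' Fits `trait ~ dosage + diagnosis + dosage:diagnosis + covariates` per
#' SNP-feature pair and reports the t-test on the interaction
#' coefficient, with BH FDR across all interaction tests. SNPs must pass
#' [testableMask()] within each diagnosis group, preventing spurious
#' interactions driven by group-specific monomorphism.
#'
#' @param gm,tm,covariates,cisWindow as in [scanQtl()]; `covariates` must
#'   contain a binary `diagnosis` column with both groups present.
#' @param minPerClass,minHetWithoutMinorHom per-group testability
#'   thresholds, see [testableMask()].
#' @return data.frame as [scanQtl()] where `beta`/`se`/`t`/`p` describe
#'   the interaction term.
#' @export
interactionScan <- function(gm, tm, covariates, cisWindow = 1e6,
                            minPerClass = 3, minHetWithoutMinorHom = 8) {
  if (is.null(covariates$diagnosis))
    stop("covariates must contain a 'diagnosis' column")
  dgn <- covariates$diagnosis
  if (length(unique(dgn)) < 2)
    stop("both diagnosis groups must be represented")
  G <- dosages(gm)
  Y <- traitValues(tm)
  if (nrow(G) != nrow(Y) || nrow(G) != length(dgn))
    stop("sample dimensions are not aligned")
  smap <- snpMap(gm)

  ok <- vapply(seq_len(ncol(G)), function(j) {
    suppressWarnings(
      testableMask(G[dgn == dgn[1], j], minPerClass,
                   minHetWithoutMinorHom) &&
      testableMask(G[dgn != dgn[1], j], minPerClass,
                   minHetWithoutMinorHom))
  }, logical(1))
  G <- G[, ok, drop = FALSE]
  smap <- smap[ok, , drop = FALSE]
  if (!ncol(G)) stop("no SNPs testable within both diagnosis groups")

  n <- nrow(G)
  base <- covariates[, setdiff(names(covariates),
                               c("sample", "diagnosis")), drop = FALSE]
  Cbase <- cbind(1, if (ncol(base)) data.matrix(base), dgn)
  k <- ncol(Cbase) + 2L         # + dosage + interaction
  df <- n - k
  imp <- .imputeDosage(G)

  out <- vector("list", ncol(G))
  for (j in seq_len(ncol(G))) {
    g <- imp$G[, j]
    X <- cbind(Cbase, g)
    z <- g * dgn
    qrX <- qr(X)
    zres <- qr.resid(qrX, z)
    Yres <- .residOn(qrX, Y)
    zss <- sum(zres^2)
    if (zss < 1e-12) next
    xy <- crossprod(zres, Yres)[1, ]
    beta <- xy / zss
    rss <- pmax(colSums(Yres^2) - beta * xy, 0)
    se <- sqrt(rss / df / zss)
    tstat <- beta / se
    out[[j]] <- data.frame(
      snp = smap$snp[j], feature = featureMap(tm)$feature,
      beta = beta, se = se, t = tstat, p = 2 * pt(-abs(tstat), df),
      q = NA_real_, n = imp$nUsed[j],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) stop("no interaction tests could be computed")

  fmap <- featureMap(tm)
  i <- match(res$snp, smap$snp); jf <- match(res$feature, fmap$feature)
  same <- smap$chrom[i] == fmap$chrom[jf]
  dist <- abs(smap$pos[i] - fmap$pos[jf])
  dist[!same] <- NA_real_
  res$relation <- ifelse(same & dist < cisWindow, "cis", "trans")
  res$distance <- dist
  res <- res[is.finite(res$p), , drop = FALSE]
  res$q <- bhFdr(res$p)
  res <- res[order(res$snp, res$feature), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Infer confounder covariates by protected residual PCA
#'
#' Estimates unknown structured confounders (batch, cell composition,
#' technical drift) as the top `k` principal components of the trait
#' matrix after residualizing each feature on the protected covariates, so
#' the inferred components conserve protected effects such as disease
#' diagnosis.
#'
#' @param tm a [TraitMatrix-class].
#' @param covariates data.frame of known covariates.
#' @param protect character vector of covariate columns whose effects must
#'   be conserved (removed before the PCA).
#' @param k number of components to append; `k <= 0` returns the
#'   covariates unchanged.
#' @return `covariates` with columns `PC1..PCk` appended.
#' @export
inferCovariates <- function(tm, covariates, protect = "diagnosis", k = 5) {
  if (k <= 0) return(covariates)
  Y <- traitValues(tm)
  if (k >= nrow(Y) - length(protect))
    stop("k must be smaller than n_samples minus protected columns")
  prot <- covariates[, intersect(protect, names(covariates)),
                     drop = FALSE]
  C <- cbind(1, if (ncol(prot)) data.matrix(prot))
  R <- .residOn(qr(C), Y)
  pc <- prcomp(R, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(min(k, ncol(pc$x))), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  cbind(covariates, as.data.frame(scores))
}
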