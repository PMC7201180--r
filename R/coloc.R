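# GWAS risk-locus intersection with the meQTL landscape and Bayesian
# colocalization via Wakefield approximate Bayes factors: the standard
# five-hypothesis enumeration (no association / trait-1 only / trait-2
# only / two distinct variants / one shared variant), evaluated with
# log-sum-exp for numerical stability.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b
logdiff <- function(a, b) {
  if (b > a) stop("logdiff needs a >= b")
  a + log1p(-exp(b - a))
}

#' Wakefield log approximate Bayes factor
#'
#' For an estimated effect `beta` with standard error `se` and a normal
#' effect-size prior of standard deviation `priorSd`: with `V = se^2`,
#' `W = priorSd^2`, `r = W / (V + W)` and `z = beta / se`,
#' `log ABF = 0.5 * log(1 - r) + 0.5 * z^2 * r`. Strictly increasing in
#' `|z|` at fixed V and W. Vectorized over `beta`/`se`.
#'
#' @param beta,se effect estimates and standard errors (`se > 0`).
#' @param priorSd prior SD of the true effect; 0.15 is the quantitative-
#'   trait convention, 0.2 the case-control (log-odds) convention.
#' @return log approximate Bayes factor(s) favouring association.
#' @export
wakefieldLogAbf <- function(beta, se, priorSd = 0.15) {
  if (any(se <= 0)) stop("se must be > 0")
  V <- se^2
  W <- priorSd^2
  r <- W / (V + W)
  z <- beta / se
  0.5 * log(1 - r) + 0.5 * z^2 * r
}

#' Colocalization posteriors from per-SNP log Bayes factors
#'
#' Enumerates the five hypotheses over causal-variant configurations in a
#' region given per-SNP log ABFs for two traits and per-SNP prior
#' probabilities `p1`/`p2` (single-trait association) and `p12` (shared
#' variant): H0 no association; H1/H2 one trait only; H3 two distinct
#' variants; H4 one shared variant. Posteriors are returned normalized to
#' sum to one; SNP order is immaterial.
#'
#' @param labf1,labf2 numeric vectors of per-SNP log ABFs for the two
#'   traits, same SNPs in the same order (names checked when present).
#' @param p1,p2,p12 prior probabilities per SNP.
#' @return list with `nsnps` and `pp`, a named numeric of
#'   `PP0..PP4` summing to 1.
#' @examples
#' colocPosteriors(c(a = 20), c(a = 20))
#' @export
colocPosteriors <- function(labf1, labf2, p1 = 1e-4, p2 = 1e-4,
                            p12 = 1e-5) {
  if (length(labf1) != length(labf2))
    stop("trait 1 and trait 2 must cover the same SNP set")
  if (!length(labf1)) stop("need at least one SNP")
  if (!is.null(names(labf1)) && !is.null(names(labf2))) {
    if (!setequal(names(labf1), names(labf2)))
      stop("trait 1 and trait 2 must cover the same SNP set")
    labf2 <- labf2[names(labf1)]
  }
  l1 <- logsumexp(labf1)                  # sum_i ABF1_i
  l2 <- logsumexp(labf2)                  # sum_j ABF2_j
  l4 <- logsumexp(labf1 + labf2)          # sum_i ABF1_i ABF2_i
  lH0 <- 0
  lH1 <- log(p1) + l1
  lH2 <- log(p2) + l2
  # sum_{i != j} ABF1_i ABF2_j = (sum_i)(sum_j) - sum_i ABF1_i ABF2_i
  lH3 <- if (length(labf1) > 1 && l1 + l2 > l4)
    log(p1) + log(p2) + logdiff(l1 + l2, l4) else -Inf
  lH4 <- log(p12) + l4
  lh <- c(lH0, lH1, lH2, lH3, lH4)
  pp <- exp(lh - logsumexp(lh))
  names(pp) <- paste0("PP", 0:4)
  list(nsnps = length(labf1), pp = pp / sum(pp))
}

#' Colocalization evidence gate
#'
#' `TRUE` iff `PP4 > pp4Min` and `PP4 / PP3 > ratioMin`; a PP3 of exactly
#' zero passes the ratio condition.
#'
#' @param result list from [colocPosteriors()], or a numeric of PP0..PP4.
#' @param pp4Min minimum shared-variant posterior.
#' @param ratioMin minimum PP4/PP3 ratio.
#' @return logical scalar.
#' @export
colocGate <- function(result, pp4Min = 0.75, ratioMin = 5) {
  pp <- if (is.list(result)) result$pp else result
  pp4 <- pp[["PP4"]]; pp3 <- pp[["PP3"]]
  ratioOk <- if (pp3 == 0) TRUE else (pp4 / pp3) > ratioMin
  pp4 > pp4Min && ratioOk
}

#' Intersect GWAS risk loci with meQTL clumps
#'
#' A risk locus is meQTL-positive when any clump's lead or member SNP lies
#' in the locus LD block (id match against the block's proxies). Reports,
#' per locus, the overlapping (CpG, lead SNP) pairs.
#'
#' @param clumps data.frame from [clumpAssociations()] (columns `snp`,
#'   `feature`, `members`, ...).
#' @param riskLoci data.frame with columns `locus` (id), `trait`,
#'   `variant`; one row per risk locus.
#' @param blocks named list of [LdBlock-class], one per `locus` id.
#' @return data.frame with one row per locus: `locus`, `trait`,
#'   `variant`, `hit` (logical), `n_pairs`, `cpgs` and `lead_snps`
#'   (semicolon-delimited).
#' @export
intersectRiskLoci <- function(clumps, riskLoci, blocks) {
  missingBlock <- setdiff(riskLoci$locus, names(blocks))
  if (length(missingBlock))
    stop("no LD block supplied for locus: ",
         paste(missingBlock, collapse = ", "))
  memberList <- strsplit(clumps$members, ";")
  memberSnps <- lapply(memberList, function(x) sub(":.*$", "", x))
  out <- lapply(seq_len(nrow(riskLoci)), function(i) {
    blk <- blocks[[riskLoci$locus[i]]]
    blockSnps <- blk@proxies$snp
    hit <- vapply(seq_len(nrow(clumps)), function(j) {
      clumps$snp[j] %in% blockSnps ||
        any(memberSnps[[j]] %in% blockSnps)
    }, logical(1))
    data.frame(
      locus = riskLoci$locus[i],
      trait = riskLoci$trait[i],
      variant = riskLoci$variant[i],
      hit = any(hit),
      n_pairs = sum(hit),
      cpgs = paste(unique(clumps$feature[hit]), collapse = ";"),
      lead_snps = paste(unique(clumps$snp[hit]), collapse = ";"),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
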