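# Pairwise LD from dosage correlation, greedy clumping of association
# results into independent signals, and LD-block/proxy construction for
# GWAS intersection.

#' Pairwise linkage disequilibrium as squared dosage correlation
#'
#' Composite LD: the squared Pearson correlation of two dosage vectors
#' after pairwise-complete filtering. Symmetric and invariant to allele
#' flips (`g -> 2 - g`).
#'
#' @param g1,g2 numeric dosage vectors of equal length.
#' @return r-squared in `[0, 1]`.
#' @export
pairwiseR2 <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("dosage vectors differ in length")
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 3) stop("need at least 3 pairwise-complete genotypes")
  if (var(g1[ok]) == 0 || var(g2[ok]) == 0)
    stop("zero-variance dosage vector")
  cor(g1[ok], g2[ok])^2
}

#' Greedy LD clumping of association results
#'
#' Repeatedly takes the smallest-p unassigned association as the lead and
#' assigns every unassigned associated SNP on the same chromosome within
#' `windowBp` with r-squared at least `r2Threshold` to that clump. Ties in
#' p are broken lexicographically by SNP id for determinism. Clumps
#' partition the input: every association lands in exactly one clump.
#'
#' @param associations data.frame as from [scanQtl()] (needs `snp`, `p`;
#'   other columns are carried through on the lead).
#' @param gm [GenotypeMatrix-class] holding every SNP in `associations`.
#' @param r2Threshold LD threshold in `[0, 1]`.
#' @param windowBp clump window in bp.
#' @return data.frame, one row per clump: lead association columns plus
#'   `n_members` and `members` (semicolon-delimited `snp:r2`).
#' @export
clumpAssociations <- function(associations, gm, r2Threshold = 0.8,
                              windowBp = 1e6) {
  stopifnot(r2Threshold >= 0, r2Threshold <= 1)
  if (!nrow(associations)) return(associations)
  missingSnp <- setdiff(associations$snp, snpMap(gm)$snp)
  if (length(missingSnp))
    stop("SNP(s) absent from the genotype matrix: ",
         paste(missingSnp, collapse = ", "))
  a <- associations[order(associations$p, associations$snp), ,
                    drop = FALSE]
  m <- snpMap(gm)
  G <- dosages(gm)
  pos <- setNames(m$pos, m$snp)
  chrom <- setNames(m$chrom, m$snp)

  assigned <- rep(FALSE, nrow(a))
  clumps <- list()
  while (!all(assigned)) {
    leadIdx <- which(!assigned)[1]
    lead <- a[leadIdx, , drop = FALSE]
    cand <- which(!assigned)
    cand <- cand[chrom[a$snp[cand]] == chrom[lead$snp] &
                 abs(pos[a$snp[cand]] - pos[lead$snp]) <= windowBp]
    r2 <- vapply(cand, function(i) {
      if (a$snp[i] == lead$snp) return(1)
      tryCatch(pairwiseR2(G[, lead$snp], G[, a$snp[i]]),
               error = function(e) 0)
    }, numeric(1))
    member <- cand[r2 >= r2Threshold]
    assigned[member] <- TRUE
    assigned[leadIdx] <- TRUE
    memberSnp <- unique(a$snp[member])
    memberR2 <- r2[match(memberSnp, a$snp[cand])]
    lead$n_members <- length(memberSnp)
    lead$members <- paste(sprintf("%s:%.4f", memberSnp, memberR2),
                          collapse = ";")
    clumps[[length(clumps) + 1L]] <- lead
  }
  out <- do.call(rbind, clumps)
  rownames(out) <- NULL
  out
}

#' Build the LD block around an index SNP
#'
#' Collects every SNP within `windowBp` of the index whose r-squared with
#' the index reaches `r2Threshold`; the block interval spans the min/max
#' proxy positions (1-based inclusive).
#'
#' @param indexSnp SNP id present in `gm`.
#' @param gm a [GenotypeMatrix-class].
#' @param r2Threshold proxy threshold in `[0, 1]`.
#' @param windowBp lookup window in bp.
#' @return an [LdBlock-class]; the index is always a member with r2 = 1.
#' @export
ldBlock <- function(indexSnp, gm, r2Threshold = 0.8, windowBp = 1e6) {
  if (r2Threshold < 0 || r2Threshold > 1)
    stop("r2Threshold must lie in [0, 1]")
  m <- snpMap(gm)
  i <- match(indexSnp, m$snp)
  if (is.na(i)) stop("index SNP not found: ", indexSnp)
  G <- dosages(gm)
  gIdx <- G[, i]
  if (var(gIdx, na.rm = TRUE) == 0)
    stop("index SNP is monomorphic: ", indexSnp)
  cand <- which(m$chrom == m$chrom[i] & abs(m$pos - m$pos[i]) <= windowBp)
  r2 <- vapply(cand, function(j) {
    if (j == i) return(1)
    tryCatch(pairwiseR2(gIdx, G[, j]), error = function(e) 0)
  }, numeric(1))
  keep <- cand[r2 >= r2Threshold]
  proxies <- data.frame(snp = m$snp[keep],
                        r2 = r2[match(keep, cand)],
                        stringsAsFactors = FALSE)
  new("LdBlock", indexSnp = indexSnp, proxies = proxies,
      chrom = m$chrom[i],
      start = min(m$pos[keep]), end = max(m$pos[keep]),
      r2Threshold = r2Threshold)
}
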