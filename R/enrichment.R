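# Regulatory-annotation enrichment of risk-associated CpGs: chromatin
# state / TFBS assignment, Fisher exact enrichment against non-risk
# cis-CpGs, a Storey-type cross-cell-type sharing estimator, detection of
# opposing allelic effects between cell types, and the allelic expression
# imbalance test.

#' Read an annotation track from a BED file
#'
#' Wraps [rtracklayer::import()] and returns the track in its native
#' 0-based half-open frame with the BED `name` field as the label.
#'
#' @param path BED file.
#' @return data.frame with columns `chrom`, `start` (0-based), `end`
#'   (exclusive), `label`.
#' @export
readBedIntervals <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  lab <- if (!is.null(gr$name)) as.character(gr$name)
         else rep("interval", length(gr))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             label = lab, stringsAsFactors = FALSE)
}

#' Default collapse of the 15 chromatin states into 5 groups
#'
#' Roadmap 15-state labels mapped to five groups: promoter/TSS-flanking,
#' enhancer, transcribed, bivalent, repressed/quiescent. Shipped as an
#' editable YAML config (`system.file("extdata", "state_collapse.yaml",
#' package = "meQTLmediate")`).
#'
#' @param path optional alternative YAML mapping file (`group: [labels]`).
#' @return named character vector, state label -> group.
#' @export
defaultStateCollapse <- function(path = system.file(
    "extdata", "state_collapse.yaml", package = "meQTLmediate")) {
  cfg <- yaml::read_yaml(path)
  unlist(lapply(names(cfg), function(g)
    setNames(rep(g, length(cfg[[g]])), cfg[[g]])))
}

#' Assign CpGs to annotation intervals
#'
#' Each CpG receives the (optionally collapsed) label of the containing
#' interval; overlaps are resolved by first-in-file precedence and
#' uncovered CpGs are labelled `"unassigned"`. A CpG at reported position
#' `p` is contained in `[start, end)` when `start <= p < end`, i.e.
#' positions are compared directly in the track's half-open frame.
#'
#' @param cpgMap data.frame with columns `feature`, `chrom`, `pos`.
#' @param intervals data.frame from [readBedIntervals()] (`chrom`,
#'   `start`, `end`, `label`).
#' @param collapse optional named vector mapping interval labels to
#'   groups, e.g. [defaultStateCollapse()]; labels absent from the map
#'   are kept as-is.
#' @return character vector of group labels, one per CpG, named by
#'   feature id.
#' @export
assignStates <- function(cpgMap, intervals, collapse = NULL) {
  bad <- which(!(intervals$start < intervals$end))
  if (length(bad))
    stop("malformed interval(s) at row(s): ",
         paste(bad, collapse = ", "))
  res <- rep("unassigned", nrow(cpgMap))
  names(res) <- cpgMap$feature
  for (ch in unique(intervals$chrom)) {
    ii <- which(intervals$chrom == ch)
    qi <- which(cpgMap$chrom == ch)
    if (!length(qi)) next
    # start <= p < end  <=>  p + 1 in [start + 1, end] (1-based closed)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(cpgMap$pos[qi] + 1L, width = 1L),
      IRanges::IRanges(intervals$start[ii] + 1L, intervals$end[ii]))
    if (!length(hits)) next
    first <- tapply(S4Vectors::subjectHits(hits),
                    S4Vectors::queryHits(hits), min)
    res[qi[as.integer(names(first))]] <-
      intervals$label[ii[as.integer(first)]]
  }
  if (!is.null(collapse)) {
    mapped <- res %in% names(collapse)
    res[mapped] <- unname(collapse[res[mapped]])
  }
  res
}

#' Fisher exact enrichment of risk CpGs across annotation labels
#'
#' For every label, builds the 2x2 table (risk-in-label, risk-not-in,
#' background-in, background-not-in), computes the two-sided Fisher exact
#' p from the hypergeometric distribution and the sample odds ratio, with
#' a Haldane 0.5 correction (flagged) when any cell is zero. The intended
#' background is the non-risk cis-CpG set.
#'
#' @param riskLabels,backgroundLabels character vectors of per-CpG group
#'   labels for the disjoint risk and background sets.
#' @return data.frame: `label`, `a`, `b`, `c`, `d`, `odds_ratio`, `p`,
#'   `haldane`.
#' @export
fisherEnrichment <- function(riskLabels, backgroundLabels) {
  if (!length(backgroundLabels)) stop("background set is empty")
  if (!length(riskLabels)) stop("risk set is empty")
  labels <- sort(unique(c(riskLabels, backgroundLabels)))
  out <- lapply(labels, function(lab) {
    a <- sum(riskLabels == lab)
    b <- length(riskLabels) - a
    c <- sum(backgroundLabels == lab)
    d <- length(backgroundLabels) - c
    p <- fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value
    haldane <- any(c(a, b, c, d) == 0)
    h <- if (haldane) 0.5 else 0
    oddsRatio <- ((a + h) * (d + h)) / ((b + h) * (c + h))
    data.frame(label = lab, a = a, b = b, c = c, d = d,
               odds_ratio = oddsRatio, p = p, haldane = haldane,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Storey-type sharing estimate (pi1) from cross-cell-type p-values
#'
#' Estimates the proportion of true alternatives among p-values of
#' cell-type-B tests evaluated at cell-type-A discovery sites:
#' `pi0(lambda) = #(p > lambda) / (m * (1 - lambda))` over a lambda grid,
#' smoothed with a cubic spline and read off at the largest lambda;
#' `pi1 = 1 - pi0`, clamped to `[0, 1]`.
#'
#' @param p numeric p-values in `[0, 1]` (>= 100 recommended).
#' @param lambda grid of tuning values in (0, 1).
#' @return pi1 estimate in `[0, 1]`.
#' @export
sharingPi1 <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  if (!length(p)) stop("no p-values supplied")
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  pi0 <- vapply(lambda, function(l) sum(p > l) / (m * (1 - l)),
                numeric(1))
  pi0Smooth <- if (length(lambda) >= 4)
    predict(smooth.spline(lambda, pi0, df = 3), x = max(lambda))$y
  else pi0[length(pi0)]
  pi0Smooth <- min(max(pi0Smooth, 0), 1)
  1 - pi0Smooth
}

#' Detect opposing allelic effects between two cell types
#'
#' Reports features significant in both result sets (q below the
#' threshold) whose lead-SNP effect estimates have opposite signs after
#' aligning both results to the same effect allele. When allele columns
#' (`effect_allele`, `other_allele`) are present, a result reported on
#' the flipped allele has its beta sign-corrected; unalignable alleles
#' skip the feature with a warning. Without allele columns the codings
#' are assumed harmonized.
#'
#' @param resA,resB data.frames with columns `feature`, `beta`, `q` and
#'   optionally `effect_allele`, `other_allele`.
#' @param fdrThreshold significance threshold on `q`.
#' @return data.frame of discordant features: `feature`, `beta_A`,
#'   `beta_B` (aligned), `q_A`, `q_B`.
#' @export
opposingEffects <- function(resA, resB, fdrThreshold = 0.05) {
  shared <- intersect(resA$feature, resB$feature)
  a <- resA[match(shared, resA$feature), , drop = FALSE]
  b <- resB[match(shared, resB$feature), , drop = FALSE]
  haveAlleles <- all(c("effect_allele", "other_allele") %in% names(a)) &&
    all(c("effect_allele", "other_allele") %in% names(b))
  betaB <- b$beta
  keep <- rep(TRUE, length(shared))
  if (haveAlleles) {
    same <- a$effect_allele == b$effect_allele &
      a$other_allele == b$other_allele
    flipped <- a$effect_allele == b$other_allele &
      a$other_allele == b$effect_allele
    betaB[flipped] <- -betaB[flipped]
    bad <- !(same | flipped)
    if (any(bad)) {
      warning("unalignable alleles; skipping feature(s): ",
              paste(shared[bad], collapse = ", "))
      keep[bad] <- FALSE
    }
  }
  sig <- keep & a$q < fdrThreshold & b$q < fdrThreshold &
    sign(a$beta) * sign(betaB) < 0
  res <- data.frame(feature = shared[sig], beta_A = a$beta[sig],
                    beta_B = betaB[sig], q_A = a$q[sig], q_B = b$q[sig],
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

# Exact null distribution of the signed-rank statistic W+ over all 2^n
# sign assignments, with average ranks for tied |d| (so ties are handled
# exactly, where the classical exact algorithm refuses). Ranks are
# doubled to make them integers; the distribution is built by the usual
# polynomial-product recursion.
.signedRankExact <- function(d, alternative = "two.sided") {
  r2 <- as.integer(round(2 * rank(abs(d))))
  W2 <- sum(r2[d > 0])
  counts <- c(1, rep(0, sum(r2)))        # counts[s + 1] = #assignments
  for (ri in r2) {
    shifted <- c(rep(0, ri), counts[seq_len(length(counts) - ri)])
    counts <- counts + shifted
  }
  total <- sum(counts)
  pGe <- sum(counts[(W2 + 1):length(counts)]) / total
  pLe <- sum(counts[seq_len(W2 + 1)]) / total
  p <- switch(alternative,
              greater = pGe,
              less = pLe,
              two.sided = min(1, 2 * min(pGe, pLe)))
  list(W = sum(rank(abs(d))[d > 0]), p = p)
}

#' Allelic expression imbalance test
#'
#' Paired one-sample test on per-individual differences between the
#' allele fraction measured in mRNA and in genomic DNA at a transcribed
#' proxy SNP, across individuals heterozygous at the regulatory SNP.
#' Uses the exact Wilcoxon signed-rank test for n <= 25 (normal
#' approximation beyond), reflecting that the measurements are
#' pyrosequencing allele proportions rather than read counts.
#'
#' @param mrnaFrac,gdnaFrac allele fractions in `[0, 1]`, one pair per
#'   heterozygous individual (n >= 3).
#' @param alternative passed to [stats::wilcox.test()].
#' @return list with `statistic` (signed-rank V), `p`, `mean_diff`,
#'   `direction` (`"mRNA-enriched"`, `"mRNA-depleted"` or `"balanced"`),
#'   `n`.
#' @export
aeiTest <- function(mrnaFrac, gdnaFrac, alternative = "two.sided") {
  if (length(mrnaFrac) != length(gdnaFrac))
    stop("fraction vectors differ in length")
  n <- length(mrnaFrac)
  if (n < 3) stop("need at least 3 heterozygous individuals")
  if (any(mrnaFrac < 0 | mrnaFrac > 1 | gdnaFrac < 0 | gdnaFrac > 1))
    stop("allele fractions must lie in [0, 1]")
  d <- mrnaFrac - gdnaFrac
  md <- mean(d)
  if (all(d == 0))
    return(list(statistic = 0, p = 1, mean_diff = 0,
                direction = "balanced", n = n))
  dz <- d[d != 0]
  if (length(dz) <= 25) {
    ex <- .signedRankExact(dz, alternative)
    wt <- list(statistic = ex$W, p.value = ex$p)
  } else {
    wt <- suppressWarnings(
      wilcox.test(d, mu = 0, alternative = alternative, exact = FALSE))
  }
  list(statistic = unname(wt$statistic), p = wt$p.value, mean_diff = md,
       direction = if (md > 0) "mRNA-enriched"
                   else if (md < 0) "mRNA-depleted" else "balanced",
       n = n)
}
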