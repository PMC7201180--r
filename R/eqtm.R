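# eQTM mapping: windowed Spearman correlation between CpG methylation and
# transcript abundance.

#' Map expression quantitative trait methylations (eQTMs)
#'
#' For each CpG in `cpgs`, tests every transcript whose anchor lies within
#' `windowBp` of the CpG on the same chromosome using Spearman rank
#' correlation (average ranks for ties; exact p for n <= 10 without ties,
#' t-approximation otherwise). Benjamini-Hochberg FDR is computed across
#' all tested pairs in the run. `direction` is `inverse` when rho < 0
#' (higher methylation, lower expression), `positive` otherwise.
#'
#' @param methylation,expression [TraitMatrix-class] objects on aligned
#'   samples.
#' @param cpgs CpG ids to anchor the windows (default: all CpGs).
#' @param windowBp half-width of the cis window in bp (`<=` bound).
#' @param covariates optional data.frame; when given, both variables are
#'   residualized on the covariates before ranking.
#' @return data.frame with columns `cpg`, `transcript`, `rho`, `p`, `q`,
#'   `distance`, `direction`.
#' @export
mapEqtm <- function(methylation, expression,
                    cpgs = featureMap(methylation)$feature,
                    windowBp = 5e5, covariates = NULL) {
  M <- traitValues(methylation)
  E <- traitValues(expression)
  if (nrow(M) != nrow(E))
    stop("methylation and expression sample counts differ")
  cmap <- featureMap(methylation)
  tmap <- featureMap(expression)
  badCpg <- setdiff(cpgs, cmap$feature)
  if (length(badCpg))
    stop("unknown CpG id(s): ", paste(badCpg, collapse = ", "))

  if (!is.null(covariates)) {
    C <- .covDesign(covariates, nrow(M))
    qrC <- qr(C)
    M <- .residOn(qrC, M)
    E <- .residOn(qrC, E)
  }

  rows <- list()
  for (cg in cpgs) {
    ci <- match(cg, cmap$feature)
    near <- which(tmap$chrom == cmap$chrom[ci] &
                  abs(tmap$pos - cmap$pos[ci]) <= windowBp)
    for (ti in near) {
      x <- M[, ci]; y <- E[, ti]
      if (sd(x) == 0 || sd(y) == 0) {
        warning("constant vector for pair ", cg, " / ",
                tmap$feature[ti], "; skipped")
        next
      }
      ct <- suppressWarnings(
        cor.test(x, y, method = "spearman",
                 exact = length(x) <= 10))
      rows[[length(rows) + 1L]] <- data.frame(
        cpg = cg, transcript = tmap$feature[ti],
        rho = unname(ct$estimate), p = ct$p.value,
        distance = abs(tmap$pos[ti] - cmap$pos[ci]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(cpg = character(), transcript = character(),
                      rho = numeric(), p = numeric(), q = numeric(),
                      distance = numeric(), direction = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  res$q <- bhFdr(res$p)
  res$direction <- ifelse(res$rho < 0, "inverse", "positive")
  res <- res[, c("cpg", "transcript", "rho", "p", "q", "distance",
                 "direction")]
  res <- res[order(res$cpg, res$transcript), , drop = FALSE]
  rownames(res) <- NULL
  res
}
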