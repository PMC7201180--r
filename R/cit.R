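# Causal inference test (CIT) for (variant L, mediator M, outcome T)
# triplets: an intersection-union test of four conditional-association
# conditions whose omnibus p is the maximum component p. Genotype enters
# every component as a categorical factor (up to 2 df), which is robust to
# non-additive allelic effects. The fourth (equivalence) component
# compares the observed conditional F of L in T ~ L + M against
# surrogates in which M is permuted within genotype classes of L,
# preserving the L-M marginal association while destroying the residual
# M-T coupling; p4 is the left-tail proportion of surrogate F values at
# or below the observed one.

# genotype dummy matrix (n x (classes - 1)) from rounded dosages
.genoDummy <- function(L) {
  cls <- round(L)
  lv <- sort(unique(cls))
  if (length(lv) < 2)
    stop("genotype vector has fewer than 2 classes")
  D <- vapply(lv[-1], function(v) as.numeric(cls == v),
              numeric(length(cls)))
  dim(D) <- c(length(cls), length(lv) - 1L)
  D
}

# F test of the columns `add` on top of design X0 (X0 must include an
# intercept)
.fAdd <- function(y, X0, add) {
  X1 <- cbind(X0, add)
  f0 <- lm.fit(X0, y)
  f1 <- lm.fit(X1, y)
  rss0 <- sum(f0$residuals^2)
  rss1 <- sum(f1$residuals^2)
  df1 <- f1$rank - f0$rank
  df2 <- length(y) - f1$rank
  if (df1 < 1 || df2 < 1) return(list(F = NA_real_, p = NA_real_))
  Fs <- ((rss0 - rss1) / df1) / (rss1 / df2)
  list(F = Fs, p = pf(Fs, df1, df2, lower.tail = FALSE))
}

.citCore <- function(L, M, T, covariates = NULL, nPerm = 1000) {
  n <- length(L)
  stopifnot(length(M) == n, length(T) == n)
  D <- .genoDummy(L)
  C <- .covDesign(covariates, n)

  p1 <- .fAdd(T, C, D)$p                       # T ~ L
  p2 <- .fAdd(M, cbind(C, T), D)$p             # M ~ L | T
  p3 <- .fAdd(T, cbind(C, D), M)$p             # T ~ M | L

  classIdx <- split(seq_len(n), round(L))
  fAll <- citP4C(T, C, D, M, unname(classIdx), as.integer(nPerm))
  p4 <- mean(fAll[-1] <= fAll[1])

  c(p1 = p1, p2 = p2, p3 = p3, p4 = p4,
    omnibus_p = max(p1, p2, p3, p4))
}

#' Causal inference test for one triplet
#'
#' Tests whether the mediator M (CpG methylation in the forward
#' direction) transmits the effect of the genetic variant L on the
#' outcome T (transcript abundance). Components: (1) T associated with L;
#' (2) M associated with L given T; (3) T associated with M given L;
#' (4) equivalence test that L is independent of T given M, evaluated
#' against within-genotype-class permutations of M. The omnibus p is the
#' maximum of the four component p-values, so the causal chain is
#' supported only when every condition holds.
#'
#' @param L dosage vector (rounded to genotype classes; >= 2 classes
#'   required).
#' @param M mediator vector.
#' @param T outcome vector.
#' @param covariates optional data.frame included in all component
#'   models.
#' @param nPerm permutation count for the equivalence component; values
#'   below 100 trigger a warning.
#' @param seed optional integer; when given, the permutation stream is
#'   seeded locally and the caller's RNG state is untouched.
#' @return one-row data.frame: `p1..p4`, `omnibus_p`, `direction`.
#' @examples
#' set.seed(1)
#' g <- rbinom(120, 2, 0.3)
#' m <- 0.6 * g + rnorm(120)
#' t <- 0.6 * m + rnorm(120)
#' citTest(g, m, t, nPerm = 200, seed = 1)
#' @export
citTest <- function(L, M, T, covariates = NULL, nPerm = 1000,
                    seed = NULL) {
  if (nPerm < 100)
    warning("fewer than 100 permutations gives a coarse p4")
  run <- function() .citCore(L, M, T, covariates, nPerm)
  p <- if (is.null(seed)) run() else withSeed(seed, run())
  out <- as.data.frame(as.list(p))
  out$direction <- "forward"
  out
}

#' Reverse-direction causal inference test
#'
#' Identical machinery with mediator and outcome swapped: transcript
#' abundance is treated as the mediator and CpG methylation as the
#' outcome, probing reverse causation (variant -> expression ->
#' methylation).
#'
#' @inheritParams citTest
#' @return one-row data.frame as [citTest()] with `direction =
#'   "reverse"`.
#' @export
citReverse <- function(L, M, T, covariates = NULL, nPerm = 1000,
                       seed = NULL) {
  out <- citTest(L, T, M, covariates, nPerm, seed)
  out$direction <- "reverse"
  out
}

#' Permutation-FDR estimator on fixed p-value tables
#'
#' For each observed omnibus p-value `p*`, the estimated FDR is the mean
#' over permutations of the count of permuted omnibus p-values at or
#' below `p*`, divided by the count of observed omnibus p-values at or
#' below `p*`; capped at 1 and made monotone non-decreasing in `p*`.
#'
#' @param observed numeric vector of observed omnibus p-values.
#' @param permMatrix numeric matrix of permuted omnibus p-values
#'   (permutations in rows, triplets in columns).
#' @return numeric vector of FDR estimates aligned with `observed`.
#' @export
permFdrFromPvalues <- function(observed, permMatrix) {
  stopifnot(is.matrix(permMatrix))
  permAll <- as.vector(permMatrix)
  nPerm <- nrow(permMatrix)
  fdr <- vapply(observed, function(ps) {
    nObs <- sum(observed <= ps)
    if (nObs == 0) return(1)
    expFalse <- sum(permAll <= ps) / nPerm
    min(1, expFalse / nObs)
  }, numeric(1))
  # enforce monotonicity in the threshold
  ord <- order(observed)
  fdr[ord] <- cummax(fdr[ord])
  fdr
}

#' Permutation-based FDR for a set of CIT triplets
#'
#' Computes the observed CIT for every triplet, then for each of `nPerm`
#' permutations permutes the sample labels of L relative to (M, T)
#' jointly per triplet and recomputes all omnibus p-values; FDR estimates
#' follow [permFdrFromPvalues()]. The component-4 permutations and the
#' FDR permutations draw from separate seeded streams (`seed` and
#' `seed + 1000003`), both recorded as attributes of the result.
#'
#' @param triplets list of lists, each with numeric vectors `L`, `M`, `T`
#'   and optionally an `id`.
#' @param covariates optional data.frame shared by all triplets.
#' @param nPerm number of FDR permutations.
#' @param nPermComponent permutations for the equivalence component.
#' @param seed integer seed.
#' @param reverse if `TRUE`, run the reverse-direction test (M and T
#'   swapped) throughout.
#' @return data.frame, one row per triplet: `id`, `p1..p4`, `omnibus_p`,
#'   `perm_fdr`, `direction`.
#' @export
citPermutationFdr <- function(triplets, covariates = NULL, nPerm = 1000,
                              nPermComponent = 1000, seed = 1,
                              reverse = FALSE) {
  stopifnot(length(triplets) >= 1)
  ids <- vapply(seq_along(triplets), function(i) {
    id <- triplets[[i]]$id
    if (is.null(id)) paste0("triplet", i) else as.character(id)
  }, character(1))
  componentSeed <- as.integer(seed)
  fdrSeed <- as.integer(seed) + 1000003L

  one <- function(tr, Lperm = NULL) {
    L <- if (is.null(Lperm)) tr$L else Lperm
    if (reverse) .citCore(L, tr$T, tr$M, covariates, nPermComponent)
    else .citCore(L, tr$M, tr$T, covariates, nPermComponent)
  }

  obs <- withSeed(componentSeed,
                  t(vapply(triplets, one, numeric(5))))

  permMat <- withSeed(fdrSeed, {
    pm <- matrix(NA_real_, nPerm, length(triplets))
    for (b in seq_len(nPerm)) {
      for (i in seq_along(triplets)) {
        tr <- triplets[[i]]
        Lp <- tr$L[sample.int(length(tr$L))]
        pm[b, i] <- one(tr, Lperm = Lp)[["omnibus_p"]]
      }
    }
    pm
  })

  res <- data.frame(id = ids, obs,
                    perm_fdr = permFdrFromPvalues(obs[, "omnibus_p"],
                                                  permMat),
                    direction = if (reverse) "reverse" else "forward",
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "componentSeed") <- componentSeed
  attr(res, "fdrSeed") <- fdrSeed
  res
}

#' Classify triplets from forward and reverse CIT results
#'
#' A direction "passes" when its permutation FDR is below `fdrThreshold`
#' and its omnibus p is nominally significant (below `pThreshold`); the
#' latter guards against the permutation-FDR estimator over-calling
#' moderate omnibus p-values when few triplets are tested, since null
#' omnibus p-values (a maximum of four components) concentrate near 1.
#' `mediated` when only the forward test passes, `reverse-mediated` when
#' only the reverse test passes, `ambiguous` when both pass, `none`
#' otherwise.
#'
#' @param forward,reverse data.frames from [citPermutationFdr()] with
#'   columns `id`, `omnibus_p` and `perm_fdr`, covering the same
#'   triplets.
#' @param fdrThreshold call threshold on the permutation FDR.
#' @param pThreshold nominal significance bound on the omnibus p.
#' @return data.frame with `id`, `forward_fdr`, `reverse_fdr`, `call`.
#' @export
classifyTriplets <- function(forward, reverse, fdrThreshold = 0.05,
                             pThreshold = 0.05) {
  if (!setequal(forward$id, reverse$id))
    stop("forward and reverse results cover different triplets")
  reverse <- reverse[match(forward$id, reverse$id), , drop = FALSE]
  f <- forward$perm_fdr < fdrThreshold & forward$omnibus_p < pThreshold
  r <- reverse$perm_fdr < fdrThreshold & reverse$omnibus_p < pThreshold
  call <- ifelse(f & r, "ambiguous",
          ifelse(f, "mediated",
          ifelse(r, "reverse-mediated", "none")))
  data.frame(id = forward$id, forward_fdr = forward$perm_fdr,
             reverse_fdr = reverse$perm_fdr, call = call,
             stringsAsFactors = FALSE)
}
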