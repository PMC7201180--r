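makeGm <- function(dosage, chrom = NULL, pos = NULL, maf = NULL,
                   info = NULL, callRate = NULL) {
  s <- ncol(dosage)
  map <- data.frame(snp = sprintf("s%02d", seq_len(s)),
                    chrom = chrom %||% rep("chr1", s),
                    pos = pos %||% seq(1e5, by = 1e5, length.out = s),
                    stringsAsFactors = FALSE)
  if (!is.null(maf)) map$maf <- maf
  if (!is.null(info)) map$info <- info
  if (!is.null(callRate)) map$call_rate <- callRate
  colnames(dosage) <- map$snp
  GenotypeMatrix(dosage, map)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("QC filters drop SNPs below each threshold and keep boundary
           cases", {
  set.seed(1)
  d <- matrix(rbinom(50 * 5, 2, 0.3), 50, 5)
  gm <- makeGm(d,
               maf = c(0.30, 0.009, 0.010, 0.20, 0.25),
               info = c(0.95, 0.95, 0.95, 0.79, 0.95),
               callRate = c(0.99, 0.99, 0.99, 0.99, 0.97))
  out <- filterGenotypes(gm)
  # s2 fails MAF (< 0.01), s4 fails INFO, s5 fails call rate;
  # s3 sits exactly at the MAF bound and is retained
  expect_identical(snpMap(out)$snp, c("s01", "s03"))
})

test_that("filters with absent metadata are skipped with a warning", {
  set.seed(2)
  gm <- makeGm(matrix(rbinom(40, 2, 0.4), 20, 2), maf = c(0.4, 0.3))
  ws <- capture_warnings(out <- filterGenotypes(gm))
  expect_match(ws, "skipping", all = TRUE)
  expect_length(ws, 2)    # call_rate and info columns are both absent
  expect_equal(ncol(dosages(out)), 2)
})

test_that("an empty filter result is a distinct error", {
  gm <- makeGm(matrix(rbinom(40, 2, 0.4), 20, 2), maf = c(0.001, 0.002))
  suppressWarnings(expect_error(filterGenotypes(gm), "no SNPs survive"))
})

test_that("genotype-class testability rule follows the boundary counts", {
  expect_true(testableMask(rep(c(0, 1, 2), c(50, 30, 3))))
  expect_true(testableMask(rep(c(0, 1, 2), c(90, 8, 0))))
  expect_false(testableMask(rep(c(0, 1, 2), c(95, 7, 0))))
  expect_false(testableMask(rep(c(0, 1, 2), c(50, 30, 2))))
  expect_warning(expect_false(testableMask(c(NA, NA))), "missing")
})

test_that("a trait equal to dosage is fit exactly", {
  set.seed(3)
  g <- rbinom(30, 2, 0.4)
  gm <- makeGm(matrix(g, 30, 1))
  tm <- TraitMatrix(matrix(g, 30, 1),
                    data.frame(feature = "f1", chrom = "chr1",
                               pos = 1.5e5))
  res <- scanQtl(gm, tm, applyTestableMask = FALSE)
  expect_lt(abs(res$beta - 1), 1e-10)
  expect_lt(res$p, 1e-20)
  expect_identical(res$relation, "cis")
})

test_that("scan estimates match the closed-form normal-equation oracle", {
  g <- c(0, 1, 2, 1, 0, 2)
  y <- c(0.1, 0.9, 2.1, 1.1, -0.1, 1.9)
  gm <- makeGm(matrix(g, 6, 1))
  tm <- TraitMatrix(matrix(y, 6, 1),
                    data.frame(feature = "f1", chrom = "chr1", pos = 100))
  res <- scanQtl(gm, tm, applyTestableMask = FALSE)
  oracle <- olsOracle(g, y)
  expect_lt(abs(res$beta - oracle$beta), 1e-10)
  expect_lt(abs(res$se - oracle$se), 1e-10)
  expect_lt(abs(res$p - oracle$p), 1e-10)
})

test_that("scan with covariates agrees with lm() on random small
           designs", {
  set.seed(4)
  for (rep in 1:20) {
    n <- sample(12:20, 1)
    k <- sample(1:3, 1)
    g <- rbinom(n, 2, 0.4)
    C <- matrix(rnorm(n * k), n, k,
                dimnames = list(NULL, paste0("c", seq_len(k))))
    y <- 0.4 * g + C %*% rnorm(k) + rnorm(n)
    gm <- makeGm(matrix(as.numeric(g), n, 1))
    tm <- TraitMatrix(matrix(as.numeric(y), n, 1),
                      data.frame(feature = "f1", chrom = "chr1",
                                 pos = 100))
    res <- scanQtl(gm, tm, covariates = as.data.frame(C),
                   applyTestableMask = FALSE)
    fit <- summary(lm(y ~ g + C))$coefficients["g", ]
    expect_lt(abs(res$beta - fit["Estimate"]), 1e-8)
    expect_lt(abs(res$se - fit["Std. Error"]), 1e-8)
    expect_lt(abs(res$p - fit["Pr(>|t|)"]), 1e-8)
  }
})

test_that("missing dosages are mean-imputed and n records the observed
           count", {
  set.seed(5)
  g <- rbinom(40, 2, 0.5)
  gmiss <- g; gmiss[1:5] <- NA
  y <- rnorm(40)
  gm <- makeGm(matrix(as.numeric(gmiss), 40, 1))
  tm <- TraitMatrix(matrix(y, 40, 1),
                    data.frame(feature = "f1", chrom = "chr1", pos = 100))
  res <- scanQtl(gm, tm, applyTestableMask = FALSE)
  expect_equal(res$n, 35)
  gimp <- gmiss; gimp[1:5] <- mean(gmiss, na.rm = TRUE)
  expect_lt(abs(res$beta - olsOracle(gimp, y)$beta), 1e-10)
})

test_that("cis/trans labels partition pairs by chromosome and distance", {
  set.seed(6)
  d <- matrix(rbinom(200 * 2, 2, 0.4), 200, 2)
  gm <- makeGm(d, chrom = c("chr1", "chr2"), pos = c(1e6, 1e6))
  fm <- data.frame(feature = c("f1", "f2", "f3"),
                   chrom = c("chr1", "chr1", "chr2"),
                   pos = c(1.5e6, 2.5e6, 1.2e6))
  tm <- TraitMatrix(matrix(rnorm(600), 200, 3), fm)
  res <- scanQtl(gm, tm, cisWindow = 1e6, applyTestableMask = FALSE)
  lab <- setNames(res$relation, paste(res$snp, res$feature))
  expect_identical(unname(lab[c("s01 f1", "s01 f2", "s01 f3")]),
                   c("cis", "trans", "trans"))
  expect_identical(unname(lab["s02 f3"]), "cis")
  # cross-chromosome distance undefined
  expect_true(is.na(res$distance[res$snp == "s01" &
                                 res$feature == "f3"]))
  # boundary: exactly 1 Mb is trans ("less than" rule)
  fm2 <- data.frame(feature = "fb", chrom = "chr1", pos = 2e6)
  tmb <- TraitMatrix(matrix(rnorm(200), 200, 1), fm2)
  resb <- scanQtl(gm, tmb, cisWindow = 1e6, applyTestableMask = FALSE)
  expect_identical(resb$relation[resb$snp == "s01"], "trans")
})

test_that("BH q-values equal the step-up enumeration", {
  expect_equal(bhFdr(0.01), 0.01)
  p <- c(0.01, 0.02, 0.03, 0.5, 1.0)
  # step-up by hand: p_(i) * m / i, cumulative minimum from the top
  m <- length(p)
  byHand <- rev(cummin(rev(sort(p) * m / seq_len(m))))[rank(p)]
  expect_equal(bhFdr(p), byHand)
  expect_equal(bhFdr(rep(0.2, 4)), rep(0.2, 4))
  expect_identical(bhFdr(numeric(0)), numeric(0))
})

test_that("null scans are calibrated at the 5% level", {
  set.seed(7)
  n <- 100
  d <- matrix(rbinom(n * 100, 2, 0.3), n, 100)
  gm <- makeGm(d)
  tm <- TraitMatrix(matrix(rnorm(n * 100), n, 100),
                    data.frame(feature = sprintf("f%03d", 1:100),
                               chrom = "chr2", pos = seq_len(100) * 1e5))
  res <- scanQtl(gm, tm, applyTestableMask = FALSE)
  expect_equal(nrow(res), 10000)
  frac <- mean(res$p < 0.05)
  expect_gte(frac, 0.04)
  expect_lte(frac, 0.06)
})

test_that("a planted interaction is detected and the interaction model
           matches lm()", {
  set.seed(8)
  n <- 400
  g <- rbinom(n, 2, 0.4)
  dgn <- rep(c(0, 1), each = n / 2)
  y <- 0.5 * g * dgn + rnorm(n, 0, 0.2)
  gm <- makeGm(matrix(as.numeric(g), n, 1))
  tm <- TraitMatrix(matrix(y, n, 1),
                    data.frame(feature = "f1", chrom = "chr1", pos = 100))
  cov <- data.frame(diagnosis = dgn)
  res <- interactionScan(gm, tm, cov)
  expect_lt(res$p, 0.01)
  fit <- summary(lm(y ~ g * dgn))$coefficients["g:dgn", ]
  expect_lt(abs(res$beta - fit["Estimate"]), 1e-8)
  expect_lt(abs(res$p - fit["Pr(>|t|)"]), 1e-8)
})

test_that("interaction p-values are uniform under equal slopes", {
  set.seed(9)
  n <- 200
  nrep <- 400
  g <- rbinom(n, 2, 0.4)
  dgn <- rep(c(0, 1), each = n / 2)
  gm <- makeGm(matrix(as.numeric(g), n, 1))
  cov <- data.frame(diagnosis = dgn)
  Y <- 0.5 * g + matrix(rnorm(n * nrep), n, nrep)
  tm <- TraitMatrix(Y, data.frame(feature = sprintf("f%03d", 1:nrep),
                                  chrom = "chr1",
                                  pos = seq_len(nrep) * 1e4))
  res <- interactionScan(gm, tm, cov)
  expect_gt(ks.test(res$p, "punif")$p.value, 0.01)
})

test_that("a single-group cohort is rejected by the interaction scan", {
  gm <- makeGm(matrix(rbinom(40, 2, 0.4), 20, 2))
  tm <- TraitMatrix(matrix(rnorm(20), 20, 1),
                    data.frame(feature = "f1", chrom = "chr1", pos = 100))
  expect_error(interactionScan(gm, tm, data.frame(diagnosis = rep(1, 20))),
               "both diagnosis groups")
})

test_that("residual PCA finds a planted batch and conserves protected
           effects", {
  set.seed(10)
  n <- 80
  batch <- rep(c(0, 1), each = n / 2)
  dgn <- rbinom(n, 1, 0.5)
  Y <- matrix(rnorm(n * 60, 0, 0.3), n, 60) +
    outer(batch, rnorm(60, 2, 0.2)) +       # batch mean shift
    outer(dgn, rnorm(60, 1, 0.2))           # protected diagnosis effect
  tm <- TraitMatrix(Y, data.frame(feature = sprintf("f%02d", 1:60),
                                  chrom = "chr1",
                                  pos = seq_len(60) * 1e4))
  cov <- data.frame(diagnosis = dgn)
  out <- inferCovariates(tm, cov, protect = "diagnosis", k = 2)
  expect_identical(inferCovariates(tm, cov, k = 0), cov)
  expect_gt(abs(cor(out$PC1, batch)), 0.9)
  expect_lt(abs(cor(out$PC1, dgn)), 0.2)
  expect_lt(abs(cor(out$PC2, dgn)), 0.2)
})
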