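test_that("genotypes follow Hardy-Weinberg proportions at the set MAF", {
  gm <- simulateGenotypes(simConfig(nSamples = 10000, nSnps = 6,
                                    mafRange = c(0.3, 0.3), ldRho = 0,
                                    seed = 2))
  d <- dosages(gm)
  exp <- c(0.49, 0.42, 0.09)
  sdHwe <- sqrt(exp * (1 - exp) / 10000)
  for (j in seq_len(ncol(d))) {
    obs <- c(mean(d[, j] == 0), mean(d[, j] == 1), mean(d[, j] == 2))
    expect_true(all(abs(obs - exp) < 3 * sdHwe))
  }
})

test_that("empirical MAF tracks the configured MAF", {
  gm <- simulateGenotypes(simConfig(nSamples = 2000, nSnps = 30,
                                    mafRange = c(0.2, 0.2), ldRho = 0,
                                    seed = 9))
  af <- colMeans(dosages(gm)) / 2
  expect_true(all(abs(af - 0.2) < 3 * sqrt(0.2 * 0.8 / (2 * 2000))))
})

test_that("the haplotype-copying scheme yields the requested LD", {
  gm <- simulateGenotypes(simConfig(nSamples = 10000, nSnps = 2,
                                    nChrom = 1, ldBlockSize = 2,
                                    ldRho = 0.95, mafRange = c(0.3, 0.3),
                                    seed = 3))
  d <- dosages(gm)
  expect_gt(pairwiseR2(d[, 1], d[, 2]), 0.8)
})

test_that("a fixed seed reproduces the cohort bit for bit", {
  cfg <- simConfig(nSamples = 40, nSnps = 30, nCpgs = 12,
                   nTranscripts = 6, seed = 5)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(dosages(a$genotypes), dosages(b$genotypes))
  expect_identical(traitValues(a$methylation), traitValues(b$methylation))
  expect_identical(traitValues(a$expression), traitValues(b$expression))
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$truth, b$truth)
})

test_that("config validation rejects bad counts and MAF ranges", {
  expect_error(simConfig(nSamples = 0), "counts")
  expect_error(simConfig(mafRange = c(0, 0.5)), "mafRange")
  expect_error(simConfig(mafRange = c(0.1, 0.6)), "mafRange")
  expect_error(simConfig(ldRho = 1), "ldRho")
})

test_that("a noiseless causal chain makes expression an exact affine
           function of dosage", {
  pt <- plantedTriplet("snp0001", "cg0001", "tx0001", "causal",
                       aLM = 0.7, bMT = 0.5)
  sim <- simulateCohort(simConfig(nSamples = 50, nSnps = 4, nCpgs = 2,
                                  nTranscripts = 2, nChrom = 1,
                                  plantedTriplets = pt,
                                  noiseSdMethylation = 0,
                                  noiseSdExpression = 0, seed = 11))
  g <- dosages(sim$genotypes)[, "snp0001"]
  t <- traitValues(sim$expression)[, "tx0001"]
  fit <- lm(t ~ g)
  expect_lt(max(abs(residuals(fit))), 1e-10)
})

test_that("a planted null triplet shows no dosage-trait correlation", {
  pt <- plantedTriplet("snp0001", "cg0001", "tx0001", "null")
  sim <- simulateCohort(simConfig(nSamples = 10000, nSnps = 4, nCpgs = 2,
                                  nTranscripts = 2, nChrom = 1,
                                  plantedTriplets = pt, seed = 13))
  g <- dosages(sim$genotypes)[, "snp0001"]
  expect_lt(abs(cor(g, traitValues(sim$methylation)[, "cg0001"])), 0.05)
  expect_lt(abs(cor(g, traitValues(sim$expression)[, "tx0001"])), 0.05)
})

test_that("beta- and M-value scales round trip algebraically", {
  sim <- simulateCohort(simConfig(nSamples = 30, nSnps = 4, nCpgs = 6,
                                  nTranscripts = 2, seed = 17))
  M <- traitValues(sim$methylation)
  B <- traitValues(sim$methylationBeta)
  expect_true(all(B > 0 & B < 1))
  expect_lt(max(abs(betaToM(B) - M)), 1e-12)
  expect_lt(max(abs(mToBeta(M) - B)), 1e-12)
})

test_that("planted effect sizes are recovered by OLS within 3 SE", {
  pt <- rbind(
    plantedTriplet("snp0001", "cg0001", "tx0001", "causal",
                   aLM = 0.6, bMT = 0.5),
    plantedTriplet("snp0006", "cg0002", "tx0002", "independent",
                   aLM = 0.4, cLT = 0.7))
  sim <- simulateCohort(simConfig(nSamples = 600, nSnps = 10, nCpgs = 4,
                                  nTranscripts = 4, nChrom = 1,
                                  plantedTriplets = pt, seed = 19))
  g <- dosages(sim$genotypes)
  m <- traitValues(sim$methylation)
  e <- traitValues(sim$expression)
  f1 <- summary(lm(m[, "cg0001"] ~ g[, "snp0001"]))$coefficients
  expect_lt(abs(f1[2, 1] - 0.6), 3 * f1[2, 2])
  f2 <- summary(lm(e[, "tx0002"] ~ g[, "snp0006"]))$coefficients
  expect_lt(abs(f2[2, 1] - 0.7), 3 * f2[2, 2])
})

test_that("dangling planted ids are rejected", {
  pt <- plantedTriplet("snp9999", "cg0001", "tx0001", "causal",
                       aLM = 1, bMT = 1)
  expect_error(
    simulateCohort(simConfig(nSamples = 20, nSnps = 4, nCpgs = 2,
                             nTranscripts = 2, plantedTriplets = pt)),
    "snp9999")
})

test_that("planted-triplet invariants are enforced at construction", {
  expect_error(plantedTriplet("s", "c", "t", "null", aLM = 0.5), "null")
  expect_error(plantedTriplet("s", "c", "t", "causal", aLM = 0.5),
               "causal")
  expect_silent(plantedTriplet("s", "c", "t", "independent",
                               aLM = 0.5, cLT = 0.5))
})

test_that("interaction effects add a diagnosis-specific genotype slope", {
  ie <- data.frame(snp = "snp0001", cpg = "cg0001", delta = 1.5)
  sim <- simulateCohort(simConfig(nSamples = 800, nSnps = 4, nCpgs = 2,
                                  nTranscripts = 2, nChrom = 1,
                                  interactionEffects = ie,
                                  noiseSdMethylation = 0.3, seed = 23))
  g <- dosages(sim$genotypes)[, "snp0001"]
  m <- traitValues(sim$methylation)[, "cg0001"]
  d <- sim$covariates$diagnosis
  sCase <- coef(lm(m[d == 1] ~ g[d == 1]))[2]
  sCtrl <- coef(lm(m[d == 0] ~ g[d == 0]))[2]
  expect_gt(sCase - sCtrl, 1.0)
})

test_that("cohort TSV/VCF writers round trip through the readers", {
  dir <- withr::local_tempdir()
  sim <- simulateCohort(simConfig(nSamples = 15, nSnps = 8, nCpgs = 4,
                                  nTranscripts = 3, seed = 29))
  files <- writeCohort(sim, dir)
  gm2 <- readGenotypesTsv(files["genotypes"], files["snp_map"])
  expect_equal(dosages(gm2), dosages(sim$genotypes),
               ignore_attr = FALSE)
  tm2 <- readTraitMatrix(files["methylation"], files["cpg_map"])
  expect_equal(traitValues(tm2), traitValues(sim$methylation),
               tolerance = 1e-12)
  gmv <- readGenotypesVcf(files["vcf"])
  expect_equal(unname(dosages(gmv)[, snpMap(sim$genotypes)$snp]),
               unname(dosages(sim$genotypes)), tolerance = 1e-4)
  expect_equal(snpMap(gmv)$pos, snpMap(sim$genotypes)$pos)
})
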