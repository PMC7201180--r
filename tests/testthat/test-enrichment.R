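test_that("interval containment follows the half-open boundary and
           first-in-file precedence", {
  iv <- data.frame(chrom = "chr1", start = c(99, 150), end = c(200, 400),
                   label = c("7_Enh", "4_Tx"), stringsAsFactors = FALSE)
  cpgs <- data.frame(feature = c("a", "b", "c", "d", "e"),
                     chrom = "chr1", pos = c(100, 99, 98, 199, 300))
  got <- assignStates(cpgs, iv)
  expect_identical(unname(got[c("a", "b", "c")]),
                   c("7_Enh", "7_Enh", "unassigned"))
  expect_identical(unname(got[["d"]]), "7_Enh")   # first interval wins
  expect_identical(unname(got[["e"]]), "4_Tx")
  collapsed <- assignStates(cpgs, iv, collapse = defaultStateCollapse())
  expect_identical(unname(collapsed[["a"]]), "enhancer")
  expect_identical(unname(collapsed[["e"]]), "transcribed")
})

test_that("assignment is total and matches an exhaustive containment
           check", {
  set.seed(61)
  iv <- data.frame(chrom = sample(c("chr1", "chr2"), 10, TRUE),
                   start = sample(0:900, 10),
                   label = sample(c("7_Enh", "1_TssA", "15_Quies"), 10,
                                  TRUE), stringsAsFactors = FALSE)
  iv$end <- iv$start + sample(20:120, 10)
  cpgs <- data.frame(feature = sprintf("cg%02d", 1:20),
                     chrom = sample(c("chr1", "chr2"), 20, TRUE),
                     pos = sample(0:1000, 20))
  got <- assignStates(cpgs, iv)
  expect_length(got, 20)
  for (i in seq_len(20)) {
    hits <- which(iv$chrom == cpgs$chrom[i] & iv$start <= cpgs$pos[i] &
                  cpgs$pos[i] < iv$end)
    want <- if (length(hits)) iv$label[min(hits)] else "unassigned"
    expect_identical(unname(got[[i]]), want)
  }
})

test_that("malformed intervals are reported with their row number", {
  iv <- data.frame(chrom = "chr1", start = c(10, 50), end = c(20, 50),
                   label = c("x", "y"))
  cpgs <- data.frame(feature = "a", chrom = "chr1", pos = 15)
  expect_error(assignStates(cpgs, iv), "2")
})

test_that("BED round trip preserves the half-open frame", {
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "states.bed")
  writeLines(c("chr1\t99\t200\t7_Enh", "chr2\t0\t50\t1_TssA"), bed)
  iv <- readBedIntervals(bed)
  expect_equal(iv$start, c(99, 0))
  expect_equal(iv$end, c(200, 50))
  expect_identical(iv$label, c("7_Enh", "1_TssA"))
})

test_that("Fisher enrichment matches hypergeometric enumeration and
           handles identical proportions and zero cells", {
  # identical proportions: OR 1, p 1
  risk <- rep(c("enh", "other"), c(10, 90))
  bg <- rep(c("enh", "other"), c(100, 900))
  res <- fisherEnrichment(risk, bg)
  enh <- res[res$label == "enh", ]
  expect_equal(enh$odds_ratio, 1)
  expect_equal(enh$p, 1, tolerance = 1e-12)

  # (20, 80, 10, 190) against direct two-sided hypergeometric enumeration
  risk2 <- rep(c("enh", "other"), c(20, 80))
  bg2 <- rep(c("enh", "other"), c(10, 190))
  res2 <- fisherEnrichment(risk2, bg2)
  a <- 20; m <- 30; nTot <- 300; nRisk <- 100
  dens <- dhyper(0:m, m, nTot - m, nRisk)
  pEnum <- sum(dens[dens <= dhyper(a, m, nTot - m, nRisk) *
                      (1 + 1e-7)])
  expect_equal(res2$p[res2$label == "enh"], pEnum, tolerance = 1e-12)

  # zero cell: Haldane-corrected OR, flagged
  risk3 <- rep("other", 50)
  bg3 <- rep(c("enh", "other"), c(10, 90))
  res3 <- fisherEnrichment(risk3, bg3)
  enh3 <- res3[res3$label == "enh", ]
  expect_true(enh3$haldane)
  expect_equal(enh3$odds_ratio,
               (0.5 * 90.5) / (50.5 * 10.5), tolerance = 1e-12)
  expect_error(fisherEnrichment(risk3, character(0)), "background")
})

test_that("Fisher p is symmetric under simultaneous row and column
           swap", {
  risk <- rep(c("x", "y"), c(7, 13))
  bg <- rep(c("x", "y"), c(40, 25))
  p1 <- fisherEnrichment(risk, bg)
  p2 <- fisherEnrichment(bg, risk)     # swapped rows
  expect_equal(p1$p[p1$label == "x"], p2$p[p2$label == "x"],
               tolerance = 1e-12)
})

test_that("planted 2x enhancer enrichment is detected in at least 90% of
           replicates", {
  set.seed(62)
  hits <- logical(100)
  for (r in 1:100) {
    # background: 20% enhancer; risk: 40% enhancer
    bg <- sample(c("enhancer", "other"), 600, TRUE, prob = c(0.2, 0.8))
    risk <- sample(c("enhancer", "other"), 120, TRUE,
                   prob = c(0.4, 0.6))
    res <- fisherEnrichment(risk, bg)
    enh <- res[res$label == "enhancer", ]
    hits[r] <- enh$odds_ratio > 1 && enh$p < 0.05
  }
  expect_gte(mean(hits), 0.9)
})

test_that("pi1 recovers the alternative fraction of p-value mixtures", {
  set.seed(63)
  expect_lt(sharingPi1(runif(10000)), 0.05)
  expect_equal(sharingPi1(rep(1e-8, 500)), 1)
  p <- c(runif(7000), pnorm(-abs(rnorm(3000, 6, 1))))
  expect_lt(abs(sharingPi1(p) - 0.3), 0.05)
  expect_error(sharingPi1(numeric(0)), "no p-values")
})

test_that("opposing effects respect significance, sign discordance and
           allele harmonization", {
  set.seed(64)
  panel <- makeOpposingPanel(nConcordant = 100, discordant = 3)
  out <- opposingEffects(panel$a, panel$b)
  expect_setequal(out$feature, panel$planted)

  # flipped allele coding turns an apparent discordance into agreement
  b2 <- panel$b
  i <- match(panel$planted, b2$feature)
  b2$effect_allele[i] <- "A"; b2$other_allele[i] <- "G"
  out2 <- opposingEffects(panel$a, b2)
  expect_equal(nrow(out2), 0)

  # non-significant discordant feature is not reported
  b3 <- panel$b
  b3$q[match(panel$planted[1], b3$feature)] <- 0.5
  expect_setequal(opposingEffects(panel$a, b3)$feature,
                  panel$planted[-1])

  # unalignable alleles skip with a warning
  b4 <- panel$b
  b4$effect_allele[1] <- "T"
  expect_warning(out4 <- opposingEffects(panel$a, b4), "unalignable")
  expect_false(panel$a$feature[1] %in% out4$feature)
})

test_that("the allelic imbalance test matches the exact signed-rank
           tail", {
  z <- aeiTest(rep(0.5, 8), rep(0.5, 8))
  expect_equal(z$p, 1)
  expect_equal(z$mean_diff, 0)
  expect_identical(z$direction, "balanced")

  # all differences +0.2: one-sided exact p = 1 / 2^8
  res <- aeiTest(rep(0.7, 8), rep(0.5, 8), alternative = "greater")
  expect_equal(res$p, 1 / 2^8, tolerance = 1e-12)
  expect_identical(res$direction, "mRNA-enriched")

  expect_error(aeiTest(c(0.6, 0.5), c(0.5, 0.5)), "at least 3")
  expect_error(aeiTest(c(1.2, 0.5, 0.4), c(0.5, 0.5, 0.4)), "\\[0, 1\\]")
})
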