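# Shared fixtures built in code: small cohorts, triplet generators and
# brute-force oracles used across test files.

# simulate one triplet under a named regulatory model
makeTriplet <- function(model, n = 200, maf = 0.3, a = 0.8, b = 0.8,
                        c = 0.8, noise = 1) {
  g <- rbinom(n, 2, maf)
  while (length(unique(round(g))) < 2) g <- rbinom(n, 2, maf)
  switch(model,
    causal = {
      m <- a * g + rnorm(n, 0, noise)
      t <- b * m + rnorm(n, 0, noise)
      list(L = g, M = m, T = t)
    },
    reactive = {
      t <- c * g + rnorm(n, 0, noise)
      m <- b * t + rnorm(n, 0, noise)
      list(L = g, M = m, T = t)
    },
    independent = {
      m <- a * g + rnorm(n, 0, noise)
      t <- c * g + rnorm(n, 0, noise)
      list(L = g, M = m, T = t)
    },
    null = list(L = g, M = rnorm(n, 0, noise), T = rnorm(n, 0, noise)))
}

# closed-form simple OLS (slope, se, t, p) via normal equations
olsOracle <- function(g, y) {
  n <- length(g)
  X <- cbind(1, g)
  XtX <- t(X) %*% X
  bhat <- solve(XtX, t(X) %*% y)
  r <- y - X %*% bhat
  s2 <- sum(r^2) / (n - 2)
  se <- sqrt(s2 * solve(XtX)[2, 2])
  tst <- bhat[2] / se
  list(beta = bhat[2], se = se, t = tst,
       p = 2 * pt(-abs(tst), n - 2))
}

# exhaustive reference implementation of the greedy clumping rule
clumpOracle <- function(assoc, pos, chrom, r2mat, r2Threshold, windowBp) {
  a <- assoc[order(assoc$p, assoc$snp), ]
  assigned <- rep(FALSE, nrow(a))
  leads <- list()
  while (!all(assigned)) {
    li <- which(!assigned)[1]
    lead <- a$snp[li]
    members <- character()
    for (j in which(!assigned)) {
      s <- a$snp[j]
      if (chrom[s] == chrom[lead] &&
          abs(pos[s] - pos[lead]) <= windowBp &&
          (s == lead || r2mat[lead, s] >= r2Threshold))
        members <- c(members, s)
    }
    assigned[a$snp %in% members] <- TRUE
    assigned[li] <- TRUE
    leads[[length(leads) + 1]] <- list(lead = lead,
                                       members = unique(members))
  }
  leads
}

# brute-force five-hypothesis colocalization enumeration over explicit
# SNP configurations (independent oracle for colocPosteriors)
colocOracle <- function(labf1, labf2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  k <- length(labf1)
  abf1 <- exp(labf1); abf2 <- exp(labf2)
  h0 <- 1
  h1 <- p1 * sum(abf1)
  h2 <- p2 * sum(abf2)
  h3 <- 0
  for (i in seq_len(k)) for (j in seq_len(k))
    if (i != j) h3 <- h3 + p1 * p2 * abf1[i] * abf2[j]
  h4 <- p12 * sum(abf1 * abf2)
  pp <- c(h0, h1, h2, h3, h4)
  pp / sum(pp)
}

# small two-cell-type meQTL result pair with planted discordant features
makeOpposingPanel <- function(nConcordant = 100, discordant = 3) {
  feat <- sprintf("cg%03d", seq_len(nConcordant + discordant))
  beta <- runif(length(feat), 0.2, 1)
  a <- data.frame(feature = feat, beta = beta,
                  q = rep(0.001, length(feat)),
                  effect_allele = "G", other_allele = "A",
                  stringsAsFactors = FALSE)
  b <- a
  b$beta[seq_len(discordant)] <- -b$beta[seq_len(discordant)]
  list(a = a, b = b, planted = feat[seq_len(discordant)])
}
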