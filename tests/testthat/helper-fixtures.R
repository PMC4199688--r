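# Shared fixtures built in code.

# The bundled 15-SNP x 9-variant cDNA haplotype matrix.
hap_fixture <- function() pho1a_haplotypes()

# A small deterministic dosage matrix over parseable marker ids.
dosage_fixture <- function(n = 60, seed = 42) {
  withr::with_seed(seed, {
    m <- cbind(
      "LocA-T_100_C" = rbinom(n, 4, 0.3),
      "LocA-G_450_A" = rbinom(n, 4, 0.2),
      "LocA-C_1200_T" = rbinom(n, 4, 0.4),
      "LocB-A_300_G" = rbinom(n, 4, 0.45)
    )
    rownames(m) <- sprintf("ind%02d", seq_len(n))
    dosage_matrix(m)
  })
}

# Brute-force one-way sums-of-squares oracle, independent of the package.
anova_oracle <- function(y, g) {
  g <- factor(g)
  gm <- mean(y)
  sst <- sum((y - gm)^2)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  k <- nlevels(g); n <- length(y)
  f <- (ssb / (k - 1)) / ((sst - ssb) / (n - k))
  list(F = f, p = pf(f, k - 1, n - k, lower.tail = FALSE),
       eta2 = ssb / sst)
}

# Textbook BH step-up oracle.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}
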