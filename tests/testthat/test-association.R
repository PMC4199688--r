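test_that("one-way dosage-class ANOVA matches a sums-of-squares oracle", {
  y <- c(1, 2, 3, 2, 3, 4, 4, 5, 6)
  g <- rep(0:2, each = 3)
  res <- oneway_dosage_anova(y, g)
  orc <- anova_oracle(y, g)
  expect_equal(res$F, orc$F)
  expect_equal(res$p_value, orc$p)
  expect_equal(res$eta2, orc$eta2)

  # random small instances, 1e-10 relative agreement with the oracle and
  # with R's linear-model decomposition
  withr::with_seed(101, {
    for (rep in 1:20) {
      n <- sample(10:40, 1)
      g <- sample(0:3, n, replace = TRUE)
      while (min(table(g)) < 2L) g <- sample(0:3, n, replace = TRUE)
      y <- rnorm(n) + 0.5 * g
      res <- oneway_dosage_anova(y, g)
      orc <- anova_oracle(y, g)
      expect_equal(res$eta2, orc$eta2, tolerance = 1e-10)
      expect_equal(res$p_value, orc$p, tolerance = 1e-10)
      fit <- summary(lm(y ~ factor(g)))
      expect_equal(res$eta2, fit$r.squared, tolerance = 1e-10)
    }
  })
})

test_that("ANOVA handles degenerate inputs as specified", {
  # perfect separation
  ps <- oneway_dosage_anova(c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(ps$eta2, 1); expect_equal(ps$p_value, 0)
  # all values equal -> eta2 = 0, p = 1
  z <- oneway_dosage_anova(rep(5, 8), rep(0:1, 4))
  expect_equal(z$eta2, 0); expect_equal(z$p_value, 1)
  # single class -> not testable, distinct from ns
  s <- oneway_dosage_anova(rnorm(10), rep(0, 10))
  expect_false(s$testable); expect_true(is.na(s$p_value))
})

test_that("eta2 is invariant to affine trait transforms; p to relabeling", {
  withr::with_seed(7, {
    g <- sample(0:2, 30, replace = TRUE)
    y <- rnorm(30) + g
  })
  a <- oneway_dosage_anova(y, g)
  b <- oneway_dosage_anova(3 * y - 10, g)
  expect_equal(a$eta2, b$eta2)
  relab <- c("BBBB", "AABB", "AAAA")[g + 1]
  expect_equal(oneway_dosage_anova(y, relab)$p_value, a$p_value)
})

test_that("singleton dosage classes merge into the adjacent class", {
  y <- c(rnorm(10), rnorm(10, 1), 50)
  g <- c(rep(0, 10), rep(1, 10), 4)
  res <- oneway_dosage_anova(y, g)
  expect_equal(res$k, 2L)
  expect_equal(res$merged, "4")
})

test_that("direction of effect follows the weighted slope of class means", {
  d <- rep(0:2, each = 10)
  expect_equal(direction_of_effect(d + rnorm(30, sd = 0.01), d), "up")
  expect_equal(direction_of_effect(-d + rnorm(30, sd = 0.01), d), "down")
  # means (10, 14, 6) with tight groups: sign alternation -> inconsistent
  y <- c(rnorm(10, 10, 0.1), rnorm(10, 14, 0.1), rnorm(10, 6, 0.1))
  expect_equal(direction_of_effect(y, d), "inconsistent")
  # small wiggles below tau stay directional
  y2 <- c(rnorm(200, 10, 3), rnorm(200, 10.2, 3), rnorm(200, 9.9, 3))
  expect_true(direction_of_effect(y2, rep(0:2, each = 200)) %in%
                c("up", "down"))
  expect_error(direction_of_effect(1:5, rep(1, 5)), "2 dosage groups")
})

test_that("significance tiers follow the reporting map", {
  expect_equal(significance_tier(c(0.5, 0.049, 0.0099, 0.0005, NA)),
               c("ns", "*", "**", "***", NA))
  expect_equal(significance_tier(0.05), "ns")
  expect_equal(significance_tier(0.01), "*")
  expect_equal(significance_tier(0.001), "**")
})

test_that("log10 validation transform is exact and guards its domain", {
  expect_equal(validation_transform(1), 0)
  expect_equal(validation_transform(100), 2)
  expect_equal(var(validation_transform(c(10, 100, 1000))), var(1:3))
  expect_error(validation_transform(c(1, 0)), "strictly positive")
  expect_error(validation_transform(-1), "strictly positive")
})

test_that("associate_all joins, filters, tiers, and flags reportable markers", {
  withr::with_seed(300, {
    n <- 208
    d_causal <- simulate_dosages(n, 0.2)
    d_null <- simulate_dosages(n, 0.3)
    d_rare <- c(rep(1L, 5), rep(0L, n - 5))   # < 8 carriers
    m <- cbind("LocA-T_100_C" = d_causal, "LocA-G_450_A" = d_null,
               "LocB-C_900_T" = d_rare)
    rownames(m) <- sprintf("i%03d", 1:n)
    dm <- dosage_matrix(m)
    tt <- trait_table(data.frame(
      TSC = simulate_trait(d_causal, 0.2, residual_sd = 2, mu = 16),
      TY = rnorm(n, 400, 50),
      row.names = rownames(m)))
  })
  res <- associate_all(dm, tt, mode = "discovery")
  expect_s3_class(res, "association_result")
  # the rare marker is filtered out in discovery mode
  expect_false("LocB-C_900_T" %in% res$marker)
  causal <- res[res$marker == "LocA-T_100_C" & res$trait == "TSC", ]
  expect_lt(causal$p_value, 0.01)
  expect_true(causal$reportable)
  expect_equal(causal$tier, significance_tier(causal$p_value))
  expect_true(all(res$percent_variance >= 0 & res$percent_variance <= 100))
  # direction is none iff tier is ns
  expect_identical(res$direction == "none", res$tier == "ns")
  # validation mode keeps the rare marker (3-carrier rule) ... with 5 carriers
  resv <- associate_all(dm, tt, mode = "validation")
  expect_true("LocB-C_900_T" %in% resv$marker)
  # id mismatch errors
  tt_bad <- trait_table(data.frame(TSC = rnorm(5),
                                   row.names = paste0("x", 1:5)))
  expect_error(associate_all(dm, tt_bad, "discovery"), "ids")
})

test_that("validation mode log10-transforms declared sugar traits", {
  withr::with_seed(301, {
    n <- 40
    d <- simulate_dosages(n, 0.3)
    sugar <- 10^rnorm(n, 0.5, 0.3)
    tt <- trait_table(
      data.frame(T12 = sugar, row.names = sprintf("i%02d", 1:n)),
      metadata = data.frame(trait = "T12", scale = "continuous",
                            transform = "log10"))
    m <- cbind("L-A_1_G" = d); rownames(m) <- rownames(tt)
    dm <- dosage_matrix(m)
  })
  res <- associate_all(dm, tt, mode = "validation")
  direct <- oneway_dosage_anova(log10(sugar), d)
  expect_equal(res$p_value[res$trait == "T12"], direct$p_value)
})

test_that("a strong causal marker is reportable with probability ~ 1", {
  hits <- vapply(1:30, function(i) {
    d <- simulate_dosages(208, 0.2, seed = 4000 + i)
    y <- simulate_trait(d, target_r2 = 0.20, residual_sd = 2,
                        seed = 5000 + i)
    oneway_dosage_anova(y, d)$p_value < 0.01
  }, logical(1))
  expect_true(all(hits))
})

test_that("the wide reporting layout carries %VE, tier, and arrows", {
  withr::with_seed(302, {
    n <- 120
    d <- simulate_dosages(n, 0.25)
    m <- cbind("L-A_5_G" = d); rownames(m) <- sprintf("i%03d", 1:n)
    tt <- trait_table(data.frame(TSC = simulate_trait(d, 0.25),
                                 row.names = rownames(m)))
    w <- association_wide(associate_all(dosage_matrix(m), tt, "discovery"))
  })
  expect_equal(w$marker, "L-A_5_G")
  expect_match(w$TSC, "^[0-9.]+\\*+")
})
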