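test_that("consensus rule needs >= 3 clones from >= 2 batches", {
  mk_clones <- function(alt_batches) {
    n <- 10
    df <- data.frame(
      clone = sprintf("c%02d", 1:n), cultivar = "x", tissue = "tuber",
      batch = rep(c("amp1", "amp2"), length.out = n),
      pos_10 = rep("A", n), pos_20 = rep("C", n),
      stringsAsFactors = FALSE)
    for (k in seq_along(alt_batches)) {
      df$pos_10[k] <- "G"
      df$batch[k] <- alt_batches[k]
    }
    df
  }
  ref <- c("10" = "A", "20" = "C")
  # 3 clones from 2 batches -> retained
  r1 <- consensus_snps(mk_clones(c("amp1", "amp1", "amp2")), ref)
  expect_equal(r1$position, 10L); expect_equal(r1$alt, "G")
  # 3 clones, all one batch -> rejected
  r2 <- consensus_snps(mk_clones(c("amp1", "amp1", "amp1")), ref)
  expect_equal(nrow(r2), 0L)
  # 2 clones from 2 batches -> rejected
  r3 <- consensus_snps(mk_clones(c("amp1", "amp2")), ref)
  expect_equal(nrow(r3), 0L)
  # missing batch ids are a data error
  bad <- mk_clones(c("amp1", "amp2", "amp1")); bad$batch[1] <- NA
  expect_error(consensus_snps(bad, ref), "batch")
})

test_that("consensus recovers simulated variants exactly at zero error", {
  hm <- hap_fixture()
  ct <- simulate_clone_table(hm, n_clones = 161, n_batches = 3,
                             error_rate = 0, seed = 81)
  ref <- setNames(unclass(hm)[, "v1"], attr(hm, "positions"))
  snps <- consensus_snps(ct, ref)
  # true variant set: every (position, base != v1 base) present in v2..v9
  truth <- do.call(rbind, lapply(seq_len(nrow(hm)), function(i) {
    alts <- setdiff(unique(unclass(hm)[i, ]), unclass(hm)[i, "v1"])
    if (length(alts)) data.frame(position = attr(hm, "positions")[i],
                                 alt = alts, stringsAsFactors = FALSE)
  }))
  expect_identical(snps[, c("position", "alt")],
                   truth[order(truth$position, truth$alt), ,
                         drop = FALSE])
})

test_that("singleton sequencing errors do not survive the consensus rule", {
  hm <- hap_fixture()
  false_pos <- vapply(1:40, function(i) {
    ct <- simulate_clone_table(hm, n_clones = 50, n_batches = 3,
                               error_rate = 1e-3, seed = 900 + i)
    ref <- setNames(unclass(hm)[, "v1"], attr(hm, "positions"))
    snps <- consensus_snps(ct, ref)
    truth_keys <- unlist(lapply(seq_len(nrow(hm)), function(r) {
      alts <- setdiff(unique(unclass(hm)[r, ]), unclass(hm)[r, "v1"])
      paste(attr(hm, "positions")[r], alts)
    }))
    sum(!paste(snps$position, snps$alt) %in% truth_keys)
  }, 0)
  expect_equal(sum(false_pos), 0)
})

test_that("the bundled cDNA matrix has nine pairwise-distinct variants", {
  hm <- hap_fixture()
  dv <- distinct_variants(hm)
  expect_equal(dv$n, 9L)
  # appending a duplicate column leaves the count unchanged
  dup <- haplotype_matrix(cbind(unclass(hm), v10 = unclass(hm)[, "v3"]),
                          positions = attr(hm, "positions"))
  expect_equal(distinct_variants(dup)$n, 9L)
  one <- haplotype_matrix(unclass(hm)[, 1, drop = FALSE],
                          positions = attr(hm, "positions"))
  expect_equal(distinct_variants(one)$n, 1L)
  # invariant under column permutation
  perm <- haplotype_matrix(unclass(hm)[, sample(9)],
                           positions = attr(hm, "positions"))
  expect_equal(distinct_variants(perm)$n, 9L)
})

test_that("haplotype pattern matching identifies diagnostic variants", {
  hm <- hap_fixture()
  # the starch-content-associated allele is variant 5
  expect_equal(match_haplotype(hm, c("22" = "T", "322" = "A", "824" = "G",
                                     "2776" = "A")), "v5")
  expect_equal(match_haplotype(hm, c("22" = "C", "322" = "G")),
               c("v1", "v7", "v8", "v9"))
  expect_equal(match_haplotype(hm, character(0)), colnames(hm))
  expect_error(match_haplotype(hm, c("99" = "A")), "absent")
})

test_that("haplotype distances are symmetric and metric on the matrix", {
  hm <- hap_fixture()
  expect_equal(haplotype_distance(hm, "v1", "v1"), 0L)
  expect_equal(haplotype_distance(hm, "v1", "v5"), 10L)
  ids <- colnames(hm)
  for (a in ids) for (b in ids) {
    expect_equal(haplotype_distance(hm, a, b), haplotype_distance(hm, b, a))
  }
  # triangle inequality over all triples
  for (a in ids) for (b in ids) for (c in ids)
    expect_lte(haplotype_distance(hm, a, c),
               haplotype_distance(hm, a, b) + haplotype_distance(hm, b, c))
})

test_that("concordance counts identical calls over non-missing pairs", {
  expect_equal(concordance(rep(1, 10), rep(1, 10))$concordance, 1)
  a <- c(rep(1, 9), 0); b <- rep(1, 10)
  expect_equal(concordance(a, b)$concordance, 0.9)
  # missing excluded, not mismatched
  a[1] <- NA
  r <- concordance(a, b)
  expect_equal(r$n_compared, 9L)
  expect_equal(r$concordance, 8 / 9)
  # 11% independent flips on 208 calls -> mean concordance ~ 0.89
  conc <- vapply(1:200, function(i) {
    withr::with_seed(1000 + i, {
      x <- rbinom(208, 1, 0.3)
      y <- ifelse(runif(208) < 0.11, 1L - x, x)
    })
    concordance(x, y)$concordance
  }, 0)
  expect_lt(abs(mean(conc) - 0.89), 3 * sd(conc) / sqrt(200))
})

test_that("ORF coordinate arithmetic maps positions to residues", {
  r <- residue_of(c(1, 22, 322, 2776))
  expect_equal(r$residue, c(1L, 8L, 108L, 926L))
  expect_equal(r$codon_offset, c(1L, 1L, 1L, 1L))
  # exact inverse: positions 3r-2..3r all map to residue r
  for (res in c(1L, 8L, 275L, 926L)) {
    pos <- (3L * res - 2L):(3L * res)
    expect_true(all(residue_of(pos)$residue == res))
    expect_equal(residue_of(pos)$codon_offset, 1:3)
  }
  expect_error(residue_of(0), ">= 1")
})

test_that("codon-position partition matches the amino-acid annotations", {
  hm <- hap_fixture()
  tp <- third_position_snps(hm)
  expect_length(tp$third, 7L)
  expect_length(tp$non_third, 8L)
  # the annotated (amino-acid-changing) sites are exactly the non-third set
  aa <- attr(hm, "aa_change")
  expect_setequal(attr(hm, "positions")[!is.na(aa)], tp$non_third)
  expect_equal(third_position_snps(3L)$third, 3L)
  expect_equal(residue_of(4L)$codon_offset, 1L)
})

test_that("annotation checking flags the inconsistent residue label", {
  chk <- annotation_check(hap_fixture())
  bad <- chk[!chk$consistent, ]
  expect_equal(bad$position, 2795L)
  expect_equal(bad$annotated_residue, 923L)
  expect_equal(bad$computed_residue, 932L)
  expect_true(all(chk$consistent[chk$position != 2795]))
})

test_that("haplotype matrices derive from pre-aligned cDNA sequences", {
  seqs <- c(ref = "ATGGCATTA", a1 = "ATGACATTA", a2 = "ATGACGTTA")
  hm <- haplotypes_from_cdna(seqs)
  expect_equal(attr(hm, "positions"), c(4L, 6L))
  expect_equal(unclass(hm)[, "a1"], c("4" = "A", "6" = "A"))
  expect_equal(match_haplotype(hm, c("4" = "A", "6" = "G")), "a2")
  expect_error(haplotypes_from_cdna(c(a = "ATG", b = "ATGC")), "equal length")
})
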