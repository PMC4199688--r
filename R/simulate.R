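#' Simulate tetrasomic allele dosages
#'
#' Draws the minor-allele dosage (0-4) of one biallelic SNP for `n`
#' tetraploid individuals under random chromosomal segregation, i.e. the
#' number of minor-allele copies among 4 chromosomes is Binomial(4, p).
#' Double reduction is not modeled.
#'
#' @param n number of individuals.
#' @param p minor-allele copy frequency in \[0, 1\].
#' @param seed optional integer seed; the caller's RNG state is untouched.
#' @return integer vector of length `n` with values in 0..4.
#' @examples
#' table(simulate_dosages(1000, 0.085, seed = 1))
#' @export
simulate_dosages <- function(n, p, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != floor(n))
    stop("`n` must be a positive integer", call. = FALSE)
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("`p` must be a frequency in [0, 1]", call. = FALSE)
  if (!is.null(seed)) seed_locally(seed)
  as.integer(rbinom(n, size = 4L, prob = p))
}

#' Simulate dosages at two loci in linkage disequilibrium
#'
#' Each individual receives four independent two-locus haplotypes drawn from
#' the haplotype frequencies (p1 p2 + D, p1 q2 - D, q1 p2 - D, q1 q2 + D);
#' per-locus dosages are the sums over the four haplotypes. For four
#' independent haplotype draws the expected dosage correlation is
#' D / sqrt(p1 q1 p2 q2).
#'
#' @param n number of individuals.
#' @param p1,p2 minor-allele frequencies at the two loci.
#' @param D haplotype-level disequilibrium coefficient; must satisfy
#'   `max(-p1*p2, -q1*q2) <= D <= min(p1*q2, q1*p2)`.
#' @param seed optional integer seed.
#' @return list with integer dosage vectors `dosage_i` and `dosage_j`.
#' @export
simulate_linked_pair <- function(n, p1, p2, D, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n))
    stop("`n` must be a positive integer", call. = FALSE)
  for (f in c(p1, p2))
    if (!is.numeric(f) || is.na(f) || f < 0 || f > 1)
      stop("allele frequencies must lie in [0, 1]", call. = FALSE)
  q1 <- 1 - p1; q2 <- 1 - p2
  lo <- max(-p1 * p2, -q1 * q2)
  hi <- min(p1 * q2, q1 * p2)
  tol <- 1e-12
  if (!is.numeric(D) || is.na(D) || D < lo - tol || D > hi + tol)
    stop(sprintf("inadmissible D = %g for (p1 = %g, p2 = %g): bounds [%g, %g]",
                 D, p1, p2, lo, hi), call. = FALSE)
  hf <- c(p1 * p2 + D, p1 * q2 - D, q1 * p2 - D, q1 * q2 + D)
  hf <- pmax(hf, 0); hf <- hf / sum(hf)
  if (!is.null(seed)) seed_locally(seed)
  # haplotypes coded 1..4; minor allele present at locus 1 for codes 1,2 and
  # at locus 2 for codes 1,3
  hap <- matrix(sample.int(4L, n * 4L, replace = TRUE, prob = hf), nrow = n)
  list(
    dosage_i = as.integer(rowSums(hap == 1L | hap == 2L)),
    dosage_j = as.integer(rowSums(hap == 1L | hap == 3L))
  )
}

#' Simulate a quantitative trait with a dosage-additive genetic effect
#'
#' Generates `y = mu + beta * d + e`, `e ~ N(0, residual_sd^2)`, with `beta`
#' calibrated against the sample variance of the supplied dosages so that the
#' fraction of trait variance attributable to the dosage term equals
#' `target_r2`. With `scale = "ordinal_1_9"` the continuous values are binned
#' into nine equal-probability categories labelled 1-9, the convention used
#' for chip-color scores (1 very dark ... 9 very light).
#'
#' @param dosages integer dosage vector (the causal marker), or `NULL` for a
#'   trait with no genetic component.
#' @param target_r2 desired fraction of variance explained, in \[0, 1).
#' @param residual_sd residual standard deviation (> 0).
#' @param mu intercept.
#' @param scale `"continuous"` or `"ordinal_1_9"`.
#' @param seed optional integer seed.
#' @return numeric vector (continuous) or integer vector in 1..9 (ordinal).
#' @export
simulate_trait <- function(dosages, target_r2 = 0, residual_sd = 1, mu = 0,
                           scale = c("continuous", "ordinal_1_9"),
                           seed = NULL) {
  scale <- match.arg(scale)
  if (!is.numeric(target_r2) || target_r2 < 0 || target_r2 >= 1)
    stop("`target_r2` must lie in [0, 1)", call. = FALSE)
  if (residual_sd <= 0) stop("`residual_sd` must be positive", call. = FALSE)
  if (is.null(dosages)) {
    if (target_r2 > 0) stop("`target_r2` > 0 requires dosages", call. = FALSE)
    stop("`dosages` must be supplied (length defines n)", call. = FALSE)
  }
  d <- as.numeric(dosages)
  vd <- var(d)
  if (target_r2 > 0 && (is.na(vd) || vd == 0))
    stop("`target_r2` > 0 requires non-constant dosages", call. = FALSE)
  beta <- if (target_r2 > 0)
    residual_sd * sqrt(target_r2 / ((1 - target_r2) * vd)) else 0
  if (!is.null(seed)) seed_locally(seed)
  y <- mu + beta * d + rnorm(length(d), 0, residual_sd)
  if (scale == "ordinal_1_9") {
    br <- quantile(y, probs = seq(0, 1, length.out = 10), names = FALSE)
    br[1] <- -Inf; br[10] <- Inf
    y <- as.integer(cut(y, breaks = br, labels = FALSE, include.lowest = TRUE))
  }
  y
}

#' Simulate a two-allele sequencing peak signal
#'
#' Produces the pair of base-calling peak heights whose noise-free ratio is
#' dosage : (4 - dosage), i.e. the overlapping-peak pattern an autotetraploid
#' heterozygote shows in a Sanger trace (1:3, 2:2, 3:1). Noise is
#' multiplicative log-normal with the given coefficient of variation.
#'
#' @param dosage integer in 0..4 (copies of the second, "alt" allele).
#' @param noise_cv nonnegative coefficient of variation of each height.
#' @param seed optional integer seed.
#' @return numeric vector `c(ref = , alt = )` of nonnegative heights.
#' @export
simulate_peaks <- function(dosage, noise_cv = 0, seed = NULL) {
  if (!is.numeric(dosage) || length(dosage) != 1L || is.na(dosage) ||
      !dosage %in% 0:4)
    stop("`dosage` must be an integer in 0..4", call. = FALSE)
  if (noise_cv < 0) stop("`noise_cv` must be nonnegative", call. = FALSE)
  h <- c(ref = (4 - dosage) / 4, alt = dosage / 4)
  if (noise_cv > 0) {
    if (!is.null(seed)) seed_locally(seed)
    sdlog <- sqrt(log(1 + noise_cv^2))
    h <- h * exp(rnorm(2L, -sdlog^2 / 2, sdlog))
  }
  h
}

#' Simulate a clone base-call table from true cDNA variants
#'
#' Emulates cloning and Sanger sequencing of full-length cDNA alleles:
#' clones sample the true variant columns uniformly, each clone belongs to an
#' amplification batch (independent PCR), and each base call is flipped to a
#' random other base with probability `error_rate` (PCR/sequencing error).
#'
#' @param true_variants a [haplotype_matrix()] of true cDNA variants
#'   (positions x variants).
#' @param n_clones number of clones to draw.
#' @param n_batches number of amplification batches (>= 2 so the consensus
#'   rule is exercisable); clones are assigned to batches cyclically.
#' @param error_rate per-base error probability in \[0, 1).
#' @param seed optional integer seed.
#' @return a `clone_table`: data.frame with columns `clone`, `cultivar`,
#'   `tissue`, `batch`, `true_variant`, then one column per scored position
#'   (named `pos_<position>`).
#' @export
simulate_clone_table <- function(true_variants, n_clones, n_batches,
                                 error_rate = 0, seed = NULL) {
  stopifnot(inherits(true_variants, "haplotype_matrix"))
  if (n_batches < 1) stop("`n_batches` must be >= 1", call. = FALSE)
  if (error_rate < 0 || error_rate >= 1)
    stop("`error_rate` must lie in [0, 1)", call. = FALSE)
  if (!is.null(seed)) seed_locally(seed)
  bases <- c("A", "C", "G", "T")
  nv <- ncol(true_variants)
  pick <- sample.int(nv, n_clones, replace = TRUE)
  calls <- t(unclass(true_variants)[, pick, drop = FALSE])
  if (error_rate > 0) {
    flip <- matrix(stats::runif(length(calls)) < error_rate, nrow = nrow(calls))
    if (any(flip)) {
      idx <- which(flip)
      calls[idx] <- vapply(calls[idx],
                           function(b) sample(setdiff(bases, b), 1L), "")
    }
  }
  out <- data.frame(
    clone = sprintf("clone%03d", seq_len(n_clones)),
    cultivar = "synthetic",
    tissue = "tuber",
    batch = sprintf("amp%d", ((seq_len(n_clones) - 1L) %% n_batches) + 1L),
    true_variant = colnames(true_variants)[pick],
    stringsAsFactors = FALSE
  )
  colnames(calls) <- sprintf("pos_%d", attr(true_variants, "positions"))
  out <- cbind(out, as.data.frame(calls, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  class(out) <- c("clone_table", "data.frame")
  out
}

#' Simulation configuration for a synthetic association population
#'
#' Bundles and validates every parameter of the synthetic population. The
#' defaults mirror the discovery-population design of a tetraploid
#' candidate-gene study: 208 individuals, five tuber traits (CQA, CQS, TSC,
#' TY, TSY), with the validation panel (`n = 40`, log10-transformed reducing
#' sugar time series T0-T12) available via `preset = "validation"`.
#'
#' @param n_individuals population size.
#' @param markers data.frame with columns `id`, `maf`, `scoring_mode`
#'   ("dosage" or "presence_absence").
#' @param ld_pairs optional data.frame with columns `marker_i`, `marker_j`,
#'   `D` (haplotype disequilibrium; admissibility is checked).
#' @param trait_specs data.frame with columns `trait`, `causal_marker`
#'   (id or NA), `target_r2`, `residual_sd`, `scale`
#'   ("continuous"/"ordinal_1_9"), `transform` ("none"/"log10"), `mu`.
#' @param peak_noise_cv coefficient of variation of simulated peak heights.
#' @param clone_spec list with `n_clones`, `n_batches`, `error_rate`.
#' @param seed integer master seed for [simulate_population()].
#' @param preset `"discovery"` (n = 208, tuber traits) or `"validation"`
#'   (n = 40, sugar time points); explicit arguments override the preset.
#' @return object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_individuals = NULL, markers = NULL,
                              ld_pairs = NULL, trait_specs = NULL,
                              peak_noise_cv = 0.05,
                              clone_spec = list(n_clones = 161, n_batches = 3,
                                                error_rate = 0.001),
                              seed = 1L,
                              preset = c("discovery", "validation")) {
  preset <- match.arg(preset)
  if (is.null(n_individuals))
    n_individuals <- if (preset == "discovery") 208L else 40L
  if (is.null(markers))
    markers <- data.frame(
      id = c("AGPaseS-T_1259_C", "PHO1b-T_4404_C", "PWD-T_10547_C",
             "INV-8/2-T_2076_C", "BMY1-G_2657_A"),
      maf = c(0.085, 0.118, 0.490, 0.376, 0.100),
      scoring_mode = "dosage",
      stringsAsFactors = FALSE
    )
  if (is.null(trait_specs)) {
    trait_specs <- if (preset == "discovery")
      data.frame(
        trait = c("CQA", "CQS", "TSC", "TY", "TSY"),
        causal_marker = c("AGPaseS-T_1259_C", "AGPaseS-T_1259_C",
                          "AGPaseS-T_1259_C", NA, "AGPaseS-T_1259_C"),
        target_r2 = c(0.074, 0.101, 0.199, 0, 0.103),
        residual_sd = c(1, 1, 2, 50, 15),
        scale = c("ordinal_1_9", "ordinal_1_9", "continuous", "continuous",
                  "continuous"),
        transform = "none",
        mu = c(5, 5, 16, 400, 70),
        stringsAsFactors = FALSE
      )
    else
      data.frame(
        trait = c("T0", "T1", "T2", "T4", "T12"),
        causal_marker = "AGPaseS-T_1259_C",
        target_r2 = c(0.063, 0.041, 0.034, 0.072, 0.108),
        residual_sd = 0.3,
        scale = "continuous",
        transform = "log10",
        mu = 0.5,
        stringsAsFactors = FALSE
      )
  }
  stopifnot(is.data.frame(markers),
            all(c("id", "maf", "scoring_mode") %in% names(markers)),
            is.data.frame(trait_specs),
            all(c("trait", "causal_marker", "target_r2", "residual_sd",
                  "scale") %in% names(trait_specs)))
  if (anyDuplicated(markers$id)) stop("duplicate marker ids", call. = FALSE)
  if (any(markers$maf < 0 | markers$maf > 1))
    stop("marker `maf` must lie in [0, 1]", call. = FALSE)
  if (any(trait_specs$target_r2 < 0 | trait_specs$target_r2 >= 1))
    stop("`target_r2` must lie in [0, 1)", call. = FALSE)
  if (any(trait_specs$residual_sd <= 0))
    stop("`residual_sd` must be positive", call. = FALSE)
  ok <- is.na(trait_specs$causal_marker) |
    trait_specs$causal_marker %in% markers$id
  if (!all(ok)) stop("unknown causal marker id", call. = FALSE)
  if (!is.null(ld_pairs)) {
    stopifnot(all(c("marker_i", "marker_j", "D") %in% names(ld_pairs)),
              all(ld_pairs$marker_i %in% markers$id),
              all(ld_pairs$marker_j %in% markers$id))
    for (k in seq_len(nrow(ld_pairs))) {
      p1 <- markers$maf[markers$id == ld_pairs$marker_i[k]]
      p2 <- markers$maf[markers$id == ld_pairs$marker_j[k]]
      lo <- max(-p1 * p2, -(1 - p1) * (1 - p2))
      hi <- min(p1 * (1 - p2), (1 - p1) * p2)
      if (ld_pairs$D[k] < lo - 1e-12 || ld_pairs$D[k] > hi + 1e-12)
        stop(sprintf("inadmissible D for pair %s / %s",
                     ld_pairs$marker_i[k], ld_pairs$marker_j[k]),
             call. = FALSE)
    }
  }
  if (!is.null(trait_specs$transform) &&
      !all(trait_specs$transform %in% c("none", "log10")))
    stop("`transform` must be \"none\" or \"log10\"", call. = FALSE)
  stopifnot(peak_noise_cv >= 0, clone_spec$n_batches >= 1,
            clone_spec$error_rate >= 0, clone_spec$error_rate < 1)
  structure(list(n_individuals = as.integer(n_individuals), markers = markers,
                 ld_pairs = ld_pairs, trait_specs = trait_specs,
                 peak_noise_cv = peak_noise_cv, clone_spec = clone_spec,
                 seed = as.integer(seed), preset = preset),
            class = "simulation_config")
}

#' Simulate a complete synthetic association dataset
#'
#' Draws, from one master seed, a dosage matrix (with LD between configured
#' pairs), trait table, per-individual-x-marker peak signals, and a clone
#' table, together with a `truth` record (causal markers, true beta, true
#' R-squared, true variant assignments) sufficient for parameter-recovery
#' tests.
#'
#' @param config a [simulation_config()].
#' @return list of class `simulated_dataset` with elements `dosage_matrix`,
#'   `trait_table`, `peak_signals` (long data.frame), `clone_table`, `truth`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  seed_locally(config$seed)
  n <- config$n_individuals
  ids <- sprintf("ind%03d", seq_len(n))
  mk <- config$markers
  dm <- matrix(NA_integer_, n, nrow(mk), dimnames = list(ids, mk$id))

  done <- character(0)
  if (!is.null(config$ld_pairs)) {
    for (k in seq_len(nrow(config$ld_pairs))) {
      mi <- config$ld_pairs$marker_i[k]; mj <- config$ld_pairs$marker_j[k]
      pr <- simulate_linked_pair(n, mk$maf[mk$id == mi], mk$maf[mk$id == mj],
                                 config$ld_pairs$D[k])
      dm[, mi] <- pr$dosage_i; dm[, mj] <- pr$dosage_j
      done <- c(done, mi, mj)
    }
  }
  for (m in setdiff(mk$id, done))
    dm[, m] <- simulate_dosages(n, mk$maf[mk$id == m])
  modes <- setNames(mk$scoring_mode, mk$id)
  for (m in mk$id[mk$scoring_mode == "presence_absence"])
    dm[, m] <- as.integer(dm[, m] > 0L)
  dmat <- dosage_matrix(dm, scoring_mode = modes)

  ts <- config$trait_specs
  truth_beta <- setNames(numeric(nrow(ts)), ts$trait)
  tt <- data.frame(row.names = ids)
  for (k in seq_len(nrow(ts))) {
    cm <- ts$causal_marker[k]
    d <- if (is.na(cm)) rep(0, n) else dm[, cm]
    r2 <- if (is.na(cm)) 0 else ts$target_r2[k]
    sdres <- ts$residual_sd[k]
    vd <- var(as.numeric(d))
    truth_beta[k] <- if (r2 > 0 && vd > 0)
      sdres * sqrt(r2 / ((1 - r2) * vd)) else 0
    mu <- if (!is.null(ts$mu)) ts$mu[k] else 0
    y <- simulate_trait(if (is.na(cm)) rep(0L, n) else dm[, cm],
                        target_r2 = r2, residual_sd = sdres, mu = mu,
                        scale = ts$scale[k])
    tr <- if (!is.null(ts$transform)) ts$transform[k] else "none"
    if (tr == "log10") y <- 10^y   # store on the raw scale; analysis logs it
    tt[[ts$trait[k]]] <- y
  }
  meta <- data.frame(trait = ts$trait, scale = ts$scale,
                     transform = if (!is.null(ts$transform)) ts$transform
                                 else "none",
                     stringsAsFactors = FALSE)
  ttab <- trait_table(tt, metadata = meta)

  dos_markers <- mk$id[mk$scoring_mode == "dosage"]
  peaks <- do.call(rbind, lapply(dos_markers, function(m) {
    hh <- t(vapply(dm[, m], function(d)
      simulate_peaks(d, config$peak_noise_cv), numeric(2L)))
    data.frame(individual = ids, marker = m,
               height_ref = hh[, 1], height_alt = hh[, 2],
               stringsAsFactors = FALSE)
  }))
  rownames(peaks) <- NULL

  hm <- pho1a_haplotypes()
  cs <- config$clone_spec
  ct <- simulate_clone_table(hm, n_clones = cs$n_clones,
                             n_batches = cs$n_batches,
                             error_rate = cs$error_rate)

  structure(list(
    dosage_matrix = dmat, trait_table = ttab, peak_signals = peaks,
    clone_table = ct,
    truth = list(causal_marker = setNames(ts$causal_marker, ts$trait),
                 beta = truth_beta,
                 r2 = setNames(ifelse(is.na(ts$causal_marker), 0,
                                      ts$target_r2), ts$trait),
                 variant_assignment = setNames(ct$true_variant, ct$clone),
                 maf = setNames(mk$maf, mk$id))
  ), class = "simulated_dataset")
}
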