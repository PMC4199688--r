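#' One-way analysis of variance across genotype classes
#'
#' Fixed-effects one-way ANOVA of a trait across the observed genotype
#' classes of a marker, reporting the F statistic, its p-value on
#' (k - 1, n - k) degrees of freedom, and eta-squared
#' (SS_between / SS_total), the fraction of trait variance explained by
#' genotype class. Genotype is treated as categorical, not as a linear
#' dosage covariate, so class-specific (e.g. recessive) effects and
#' non-monotone patterns are captured.
#'
#' Classes with a single observation are merged into the nearest adjacent
#' dosage class before testing (`merge_singletons = TRUE`); the merging is
#' recorded in the result.
#'
#' @param y numeric trait values.
#' @param classes genotype classes (dosage integers or class labels);
#'   coerced to factor. Pairs with missing y or class are dropped.
#' @param merge_singletons merge single-observation classes into the
#'   adjacent class (by numeric dosage order) before testing.
#' @param rank_based if `TRUE` run a Kruskal-Wallis test instead (p from the
#'   chi-square approximation; eta2 still reported from the SS decomposition
#'   of the raw values).
#' @return list with `F`, `p_value`, `eta2`, `df1`, `df2`, `n_used`, `k`,
#'   `testable`, `merged` (labels of merged classes), `class_means`,
#'   `class_n`.
#' @export
oneway_dosage_anova <- function(y, classes, merge_singletons = TRUE,
                                rank_based = FALSE) {
  ok <- !is.na(y) & !is.na(classes)
  y <- as.numeric(y[ok])
  g <- classes[ok]
  n <- length(y)
  not_testable <- function(reason) list(
    F = NA_real_, p_value = NA_real_, eta2 = NA_real_, df1 = NA_integer_,
    df2 = NA_integer_, n_used = n, k = length(unique(g)), testable = FALSE,
    reason = reason, merged = character(0), class_means = NULL,
    class_n = NULL)
  if (n < 3L) return(not_testable("fewer than 3 observations"))
  merged <- character(0)
  if (merge_singletons) {
    repeat {
      tab <- table(g)
      if (length(tab) < 2L || all(tab >= 2L)) break
      lone <- names(tab)[tab == 1L][1L]
      lv <- suppressWarnings(as.numeric(names(tab)))
      others <- setdiff(names(tab), lone)
      target <- if (!anyNA(lv)) {
        ov <- lv[match(others, names(tab))]
        others[which.min(abs(ov - lv[names(tab) == lone]))]
      } else others[1L]
      g[g == lone] <- target
      merged <- c(merged, lone)
    }
  }
  g <- factor(g)
  k <- nlevels(g)
  if (k < 2L) return(not_testable("single genotype class"))
  gm <- mean(y)
  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  ss_total <- sum((y - gm)^2)
  ss_between <- sum(ns * (means - gm)^2)
  if (ss_total == 0)
    return(c(list(F = NA_real_, p_value = 1, eta2 = 0, df1 = k - 1L,
                  df2 = n - k, n_used = n, k = k, testable = TRUE,
                  reason = "zero total variance", merged = merged),
             list(class_means = means, class_n = ns)))
  ss_within <- ss_total - ss_between
  df1 <- k - 1L; df2 <- n - k
  if (rank_based) {
    kw <- stats::kruskal.test(y, g)
    Fst <- unname(kw$statistic); p <- kw$p.value
  } else if (ss_within == 0) {
    Fst <- Inf; p <- 0
  } else {
    Fst <- (ss_between / df1) / (ss_within / df2)
    p <- pf(Fst, df1, df2, lower.tail = FALSE)
  }
  list(F = Fst, p_value = p, eta2 = ss_between / ss_total, df1 = df1,
       df2 = df2, n_used = n, k = k, testable = TRUE, reason = NULL,
       merged = merged, class_means = means, class_n = ns)
}

#' Direction of the minor-allele effect on a trait
#'
#' Orders the class means by MFA dosage and returns the sign of the
#' count-weighted least-squares slope of class mean on dosage ("up"/"down").
#' When successive class-mean differences strictly alternate in sign and
#' each exceeds a tolerance `tau` (default 0.25 x pooled within-class SD),
#' the effect direction is declared "inconsistent" between genotypic groups
#' (the up-down arrow of association tables).
#'
#' @param y trait values.
#' @param dosage MFA dosage per individual (0-4).
#' @param tau_factor tolerance as a multiple of the pooled within-class SD.
#' @return one of `"up"`, `"down"`, `"inconsistent"`.
#' @export
direction_of_effect <- function(y, dosage, tau_factor = 0.25) {
  ok <- !is.na(y) & !is.na(dosage)
  y <- as.numeric(y[ok]); d <- as.numeric(dosage[ok])
  lev <- sort(unique(d))
  if (length(lev) < 2L)
    stop("need >= 2 dosage groups", call. = FALSE)
  means <- tapply(y, d, mean)[as.character(lev)]
  ns <- tapply(y, d, length)[as.character(lev)]
  n <- sum(ns); k <- length(lev)
  ss_within <- sum((y - means[as.character(d)])^2)
  pooled_sd <- if (n > k) sqrt(ss_within / (n - k)) else 0
  tau <- tau_factor * pooled_sd
  diffs <- diff(means)
  if (length(diffs) >= 2L) {
    big <- abs(diffs) > tau
    alt <- all(big) && all(sign(diffs[-1L]) == -sign(diffs[-length(diffs)])) &&
      all(sign(diffs) != 0)
    if (alt) return("inconsistent")
  }
  wbar <- sum(ns * lev) / n
  slope <- sum(ns * (lev - wbar) * means) / sum(ns * (lev - wbar)^2)
  if (slope >= 0) "up" else "down"
}

#' Significance tier of a p-value
#'
#' The reporting convention of candidate-gene association tables:
#' `ns` for p > 0.05, `*` for 0.05 > p >= 0.01, `**` for 0.01 > p >= 0.001,
#' `***` for p < 0.001.
#'
#' @param p numeric vector of p-values.
#' @return character vector of tiers.
#' @export
significance_tier <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", "ns"))))
}

#' Base-10 log transform for reducing-sugar traits
#'
#' Validation panels measure tuber reducing-sugar content (mg/100 mg dry
#' weight), which is log10-transformed to approach normality before ANOVA.
#' Nonpositive values are a domain error; no offset is applied silently.
#'
#' @param x strictly positive numeric vector (`NA` allowed).
#' @return log10(x).
#' @export
validation_transform <- function(x) {
  if (any(!is.na(x) & x <= 0))
    stop("log10 transform requires strictly positive values", call. = FALSE)
  log10(x)
}

#' Marker-trait association scan
#'
#' Runs the one-way dosage-class ANOVA for every retained marker x trait
#' combination. `mode` sets the MFA carrier filter (discovery: >= 8 carrier
#' genotypes; validation: >= 3) and, in validation mode, applies the log10
#' transform to traits whose metadata declares `transform = "log10"`.
#' A marker is flagged reportable iff p < `alpha_report` for at least one
#' trait. For dosage markers whose MFA is the reference allele, direction is
#' evaluated against the MFA dosage (4 - alt dosage).
#'
#' @param dosages a [dosage_matrix()].
#' @param traits a [trait_table()] over the same individuals.
#' @param mode `"discovery"` or `"validation"`.
#' @param alpha_report reporting threshold on the per-test p-value.
#' @param rank_based use Kruskal-Wallis instead of parametric one-way ANOVA.
#' @param min_carriers override of the mode's MFA carrier filter.
#' @return data.frame of class `association_result`: one row per marker x
#'   trait with `marker`, `trait`, `n_used`, `p_value`, `percent_variance`,
#'   `mfa_allele`, `mfa_frequency_percent`, `direction`, `tier`,
#'   `reportable`, `testable`.
#' @export
associate_all <- function(dosages, traits, mode = c("discovery", "validation"),
                          alpha_report = 0.01, rank_based = FALSE,
                          min_carriers = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(dosages, "dosage_matrix"),
            inherits(traits, "trait_table"))
  ids <- rownames(dosages)
  if (!setequal(ids, rownames(traits)))
    stop("individual ids of genotypes and traits do not match",
         call. = FALSE)
  tr <- as.data.frame(traits)[ids, , drop = FALSE]
  meta <- attr(traits, "metadata")
  if (mode == "validation")
    for (cn in meta$trait[meta$transform == "log10"])
      tr[[cn]] <- validation_transform(tr[[cn]])
  if (is.null(min_carriers))
    min_carriers <- if (mode == "discovery") 8L else 3L
  keep <- apply_mfa_filter(dosages, min_carriers)
  sm <- attr(dosages, "scoring_mode")
  rows <- list()
  for (m in keep) {
    v <- unclass(dosages)[, m]
    if (sm[m] == "presence_absence") {
      pf_ <- presence_frequency(v)
      mfa_allele <- "present"; mfa_pct <- 100 * pf_$carrier_fraction
      mfa_dosage <- v
    } else {
      maf <- minor_allele_frequency(v)
      mfa_allele <- maf$mfa_allele; mfa_pct <- 100 * maf$frequency
      mfa_dosage <- if (maf$mfa_allele == "ref") 4L - v else v
    }
    for (trait in names(tr)) {
      y <- tr[[trait]]
      res <- oneway_dosage_anova(y, v, rank_based = rank_based)
      dir <- if (!res$testable || is.na(res$p_value) ||
                 res$p_value >= 0.05) "none"
             else direction_of_effect(y, mfa_dosage)
      rows[[length(rows) + 1L]] <- data.frame(
        marker = m, trait = trait, n_used = res$n_used,
        p_value = res$p_value,
        percent_variance = 100 * res$eta2,
        mfa_allele = mfa_allele, mfa_frequency_percent = mfa_pct,
        direction = dir, tier = significance_tier(res$p_value),
        testable = res$testable, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  else {
    rp <- tapply(!is.na(out$p_value) & out$p_value < alpha_report,
                 out$marker, any)
    out$reportable <- unname(rp[out$marker])
    rownames(out) <- NULL
  }
  attr(out, "mode") <- mode
  attr(out, "alpha_report") <- alpha_report
  class(out) <- c("association_result", "data.frame")
  out
}

#' Reshape an association scan into the wide reporting layout
#'
#' One row per marker, MFA percentage, and per trait a formatted cell
#' "percent variance + tier + direction glyph" mirroring the layout of
#' published candidate-gene association tables.
#'
#' @param x an `association_result` from [associate_all()].
#' @return data.frame with one row per marker.
#' @export
association_wide <- function(x) {
  stopifnot(inherits(x, "association_result"))
  glyph <- c(up = "↑", down = "↓", inconsistent = "↑↓",
             none = "")
  cell <- ifelse(!x$testable | is.na(x$p_value), "nt",
                 ifelse(x$tier == "ns", "ns",
                        sprintf("%.1f%s %s", x$percent_variance, x$tier,
                                glyph[x$direction])))
  mks <- unique(x$marker)
  out <- data.frame(marker = mks,
                    mfa_percent = round(x$mfa_frequency_percent[
                      match(mks, x$marker)], 1L),
                    stringsAsFactors = FALSE)
  for (tr in unique(x$trait))
    out[[tr]] <- trimws(cell[x$trait == tr][match(mks, x$marker[x$trait == tr])])
  out
}
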