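#' Chi-square linkage-disequilibrium test between two dosage markers
#'
#' Phase-free LD test for unphased tetraploid data: a chi-square test of
#' independence on the observed genotype-class contingency table (rows =
#' dosage classes of marker i, columns = classes of marker j), df =
#' (r - 1)(c - 1), no continuity correction. Because tetraploid class
#' tables are sparse at n of a few hundred, classes whose expected counts
#' fall below `pool_threshold` (default 1) are pooled with the adjacent
#' dosage class before testing; a warning notes remaining cells with
#' expected counts < 5. The composite dosage correlation r is reported as
#' an effect size.
#'
#' @param dosages_i,dosages_j integer dosage vectors over the same
#'   individuals (`NA` allowed; pairwise-complete used).
#' @param min_n minimum pairwise-complete sample size (default 10).
#' @param pool_threshold minimum expected count per class margin.
#' @return list with `chi2`, `df`, `p_value`, `n_used`, `r` (dosage
#'   correlation), `testable`, `reason`.
#' @export
ld_chi2 <- function(dosages_i, dosages_j, min_n = 10L, pool_threshold = 1) {
  if (length(dosages_i) != length(dosages_j))
    stop("dosage vectors must have equal length", call. = FALSE)
  ok <- !is.na(dosages_i) & !is.na(dosages_j)
  di <- as.integer(dosages_i[ok]); dj <- as.integer(dosages_j[ok])
  n <- length(di)
  nt <- function(reason) list(chi2 = NA_real_, df = NA_integer_,
                              p_value = NA_real_, n_used = n, r = NA_real_,
                              testable = FALSE, reason = reason)
  if (n < min_n) return(nt("too few pairwise-complete individuals"))
  if (length(unique(di)) < 2L || length(unique(dj)) < 2L)
    return(nt("monomorphic marker"))
  tab <- table(factor(di, levels = sort(unique(di))),
               factor(dj, levels = sort(unique(dj))))
  tab <- pool_sparse_classes(tab, pool_threshold)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    return(nt("all classes pooled"))
  exp_ <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp_ < 5))
    warning("expected counts < 5 remain after pooling; chi-square ",
            "approximation may be rough", call. = FALSE)
  suppressWarnings(ct <- chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, n_used = n,
       r = stats::cor(di, dj), testable = TRUE, reason = NULL)
}

# Merge rows/columns whose expected counts all fall below `threshold` into
# the adjacent dosage class (nearer neighbor by dosage value, ties toward
# the lower dosage). Row/column names are dosage values.
pool_sparse_classes <- function(tab, threshold = 1) {
  merge_margin <- function(tab, margin) {
    repeat {
      if (dim(tab)[margin] <= 2L) return(tab)
      exp_ <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      low <- apply(exp_ < threshold, margin, any)
      if (!any(low)) return(tab)
      i <- which(low)[1L]
      vals <- as.numeric(dimnames(tab)[[margin]])
      nb <- c(i - 1L, i + 1L)
      nb <- nb[nb >= 1L & nb <= length(vals)]
      j <- nb[which.min(abs(vals[nb] - vals[i]))]
      keep <- setdiff(seq_along(vals), i)
      if (margin == 1L) {
        tab[j, ] <- tab[j, ] + tab[i, ]
        tab <- tab[keep, , drop = FALSE]
      } else {
        tab[, j] <- tab[, j] + tab[, i]
        tab <- tab[, keep, drop = FALSE]
      }
    }
  }
  tab <- merge_margin(tab, 1L)
  merge_margin(tab, 2L)
}

#' Multiple-testing correction to q-values
#'
#' `"bh"`: Benjamini-Hochberg step-up false-discovery-rate q-values
#' (monotone, q >= p). `"storey"`: Storey q-values with the null proportion
#' pi0 estimated on a lambda grid (0.05..0.95) with cubic-spline smoothing
#' evaluated at the largest lambda; with pi0 < 1 a q-value may drop below
#' its p-value. Both are order-preserving in p.
#'
#' @param p p-values in \[0, 1\].
#' @param method `"bh"` or `"storey"`.
#' @return numeric vector of q-values in input order (empty in, empty out).
#' @export
correct_pvalues <- function(p, method = c("bh", "storey")) {
  method <- match.arg(method)
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (method == "bh") return(p.adjust(p, method = "BH"))
  storey_qvalues(p)
}

# Storey q-values: pi0 from the fixed-lambda grid with the spline smoother;
# q(i) = min over j >= i of pi0 * m * p(j) / j on the sorted p-values.
storey_qvalues <- function(p, lambda = seq(0.05, 0.95, 0.05)) {
  ok <- !is.na(p)
  pv <- p[ok]
  m <- length(pv)
  if (m == 0L) return(p)
  pi0_lambda <- vapply(lambda, function(l) mean(pv > l) / (1 - l), 0)
  pi0 <- if (m >= 100 && length(unique(pv)) > 4L) {
    fit <- try(smooth.spline(lambda, pi0_lambda, df = 3), silent = TRUE)
    if (inherits(fit, "try-error")) min(pi0_lambda)
    else predict(fit, x = max(lambda))$y
  } else {
    # small families: the smoother is unstable; fall back to the
    # conservative pi0 = 1 (BH-equivalent)
    1
  }
  pi0 <- min(max(pi0, 0), 1)
  if (pi0 <= 0) pi0 <- min(pi0_lambda[pi0_lambda > 0], 1)
  o <- order(pv)
  q_sorted <- pi0 * m * pv[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m); q[o] <- q_sorted
  out <- rep(NA_real_, length(p)); out[ok] <- q
  out
}

#' Pairwise LD scan over a dosage matrix
#'
#' Runs [ld_chi2()] for every pair of dosage-scored markers (or a supplied
#' pair list), attaches q-values, and — for pairs whose marker ids parse to
#' the same locus and coordinate system — the same-locus flag and base-pair
#' distance used by [ld_blocks()].
#'
#' @param dosages a [dosage_matrix()].
#' @param pairs optional 2-column matrix/data.frame of marker ids; default
#'   all pairs of dosage-scored markers.
#' @param method q-value method for [correct_pvalues()].
#' @param ... passed to [ld_chi2()].
#' @return data.frame of class `ld_result`: `marker_i`, `marker_j`, `chi2`,
#'   `df`, `p_value`, `q_value`, `r`, `n_used`, `same_locus`, `distance_bp`,
#'   `testable`; attribute `method` records the correction used.
#' @export
ld_scan <- function(dosages, pairs = NULL, method = c("bh", "storey"), ...) {
  method <- match.arg(method)
  stopifnot(inherits(dosages, "dosage_matrix"))
  sm <- attr(dosages, "scoring_mode")
  mks <- colnames(dosages)[sm == "dosage"]
  if (is.null(pairs)) {
    if (length(mks) < 2L) stop("need >= 2 dosage-scored markers",
                               call. = FALSE)
    pairs <- t(combn(mks, 2L))
  } else {
    pairs <- as.matrix(pairs)
    if (!all(pairs %in% colnames(dosages)))
      stop("unknown marker id in `pairs`", call. = FALSE)
  }
  info <- tryCatch(parse_marker_id(unique(c(pairs))), error = function(e) NULL)
  res <- lapply(seq_len(nrow(pairs)), function(k) {
    a <- pairs[k, 1L]; b <- pairs[k, 2L]
    lt <- ld_chi2(unclass(dosages)[, a], unclass(dosages)[, b], ...)
    same <- NA; dist <- NA_real_
    if (!is.null(info)) {
      ia <- info[info$id == a, ]; ib <- info[info$id == b, ]
      same <- ia$locus == ib$locus
      if (isTRUE(same)) dist <- abs(ia$position - ib$position)
    }
    data.frame(marker_i = a, marker_j = b, chi2 = lt$chi2, df = lt$df,
               p_value = lt$p_value, r = lt$r, n_used = lt$n_used,
               same_locus = same, distance_bp = dist,
               testable = lt$testable, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- NA_real_
  idx <- out$testable
  out$q_value[idx] <- correct_pvalues(out$p_value[idx], method)
  out <- out[, c("marker_i", "marker_j", "chi2", "df", "p_value", "q_value",
                 "r", "n_used", "same_locus", "distance_bp", "testable")]
  attr(out, "method") <- method
  class(out) <- c("ld_result", "data.frame")
  out
}

#' Group same-locus markers into LD blocks
#'
#' Single-linkage grouping of same-locus markers connected by pairs with
#' q <= `q_threshold` and physical distance <= `max_span_bp` (strong LD
#' blocks in candidate-gene amplicons span up to roughly 700 bp). Each
#' block nominates one representative marker (lowest position, ties by id)
#' for reporting.
#'
#' @param results an `ld_result` from [ld_scan()] (or a data.frame with the
#'   same columns).
#' @param q_threshold q-value cutoff for an edge (default 0.05).
#' @param max_span_bp maximum pair distance for an edge (default 700).
#' @return data.frame with `block`, `marker`, `representative`.
#' @export
ld_blocks <- function(results, q_threshold = 0.05, max_span_bp = 700) {
  need <- c("marker_i", "marker_j", "q_value", "same_locus", "distance_bp")
  stopifnot(all(need %in% names(results)))
  mks <- unique(c(results$marker_i, results$marker_j))
  parent <- setNames(mks, mks)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  edge <- !is.na(results$q_value) & results$q_value <= q_threshold &
    isTRUE_vec(results$same_locus) &
    !is.na(results$distance_bp) & results$distance_bp <= max_span_bp
  for (k in which(edge)) {
    ra <- find(results$marker_i[k]); rb <- find(results$marker_j[k])
    if (ra != rb) parent[[rb]] <- ra
  }
  root <- vapply(mks, find, "")
  pos <- tryCatch(setNames(parse_marker_id(mks)$position, mks),
                  error = function(e) setNames(rep(NA_integer_,
                                                   length(mks)), mks))
  out <- do.call(rbind, lapply(unique(root), function(r) {
    members <- mks[root == r]
    o <- order(pos[members], members)
    members <- members[o]
    data.frame(marker = members, representative = members[1L],
               stringsAsFactors = FALSE)
  }))
  out$block <- match(out$representative, unique(out$representative))
  rownames(out) <- NULL
  out[, c("block", "marker", "representative")]
}

isTRUE_vec <- function(x) !is.na(x) & x == TRUE
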