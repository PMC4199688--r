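#' Parse a SNP marker id
#'
#' Marker ids follow the `Locus-REF_position_ALT` convention, e.g.
#' `"GWD-A_3452_G"` (locus GWD, reference base A at position 3452, alternate
#' G). The ALT field may be empty (`"PHO1b-C_4404_"`) or hold a multi-base
#' indel allele (`"PHO1b-A_4207_GT"`).
#'
#' @param id character vector of marker ids.
#' @return data.frame with columns `id`, `locus`, `ref`, `position`, `alt`.
#' @examples
#' parse_marker_id("AGPaseS-T_1259_C")
#' @export
parse_marker_id <- function(id) {
  m <- regmatches(id, regexec("^(.*)-([ACGT]*)_([0-9]+)_([ACGT]*)$", id))
  bad <- vapply(m, length, 0L) != 5L
  if (any(bad))
    stop("unparsable marker id(s): ", paste(id[bad], collapse = ", "),
         call. = FALSE)
  data.frame(id = id,
             locus = vapply(m, `[`, "", 2L),
             ref = vapply(m, `[`, "", 3L),
             position = as.integer(vapply(m, `[`, "", 4L)),
             alt = vapply(m, `[`, "", 5L),
             stringsAsFactors = FALSE)
}

#' Enumerate tetraploid genotype classes
#'
#' All distinct allele-count compositions of 4 chromosomes over `n_alleles`
#' alleles: 5 classes for a biallelic SNP (AAAA, AAAB, AABB, ABBB, BBBB),
#' 15 for a triallelic one (AAAA, AAAB, ..., AABC, ...).
#'
#' @param n_alleles 2 or 3.
#' @return data.frame with one row per class: `label` plus one count column
#'   per allele letter, sorted by canonical label.
#' @export
genotype_classes <- function(n_alleles = 2L) {
  stopifnot(n_alleles %in% 2:3)
  letters4 <- LETTERS[seq_len(n_alleles)]
  grid <- expand.grid(rep(list(0:4), n_alleles))
  grid <- grid[rowSums(grid) == 4L, , drop = FALSE]
  names(grid) <- letters4
  lab <- apply(grid, 1L, function(cnt)
    paste(rep(letters4, cnt), collapse = ""))
  out <- cbind(data.frame(label = lab, stringsAsFactors = FALSE), grid)
  out <- out[order(out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert a genotype class label to allele dosages (and back)
#'
#' @param label class string over allele letters, length 4 (e.g. "AABB").
#' @param n_alleles number of alleles the marker segregates for.
#' @return `class_to_dosage`: named integer vector of per-allele counts
#'   summing to 4. `dosage_to_class`: the canonical class label.
#' @export
class_to_dosage <- function(label, n_alleles = 2L) {
  letters4 <- LETTERS[seq_len(n_alleles)]
  ch <- strsplit(label, "")[[1]]
  if (length(ch) != 4L || !all(ch %in% letters4))
    stop("`label` must be 4 letters over ", paste(letters4, collapse = "/"),
         call. = FALSE)
  vapply(letters4, function(a) sum(ch == a), 0L)
}

#' @param dosage integer vector of per-allele counts summing to 4.
#' @rdname class_to_dosage
#' @export
dosage_to_class <- function(dosage) {
  dosage <- as.integer(dosage)
  if (sum(dosage) != 4L || any(dosage < 0L))
    stop("`dosage` must be nonnegative counts summing to 4", call. = FALSE)
  paste(rep(LETTERS[seq_along(dosage)], dosage), collapse = "")
}

#' Call tetraploid allele dosage from a two-allele peak signal
#'
#' The minor/alt-allele peak fraction f = h_alt / (h_ref + h_alt) is mapped
#' to the nearest of the five expected fractions {0, 1/4, 1/2, 3/4, 1}
#' (AAAA..BBBB; heterozygote height ratios 1:3, 2:2, 3:1). The decision
#' boundaries are therefore the midpoints 0.125/0.375/0.625/0.875. A
#' confidence value (half-width-scaled distance to the nearest centroid) is
#' returned to support an optional no-call band.
#'
#' @param heights numeric vector of two nonnegative peak heights
#'   (reference allele first).
#' @param alleles two allele letters for the class label.
#' @return list with `label`, `dosage` (alt-allele copies 0-4),
#'   `dosage_vector`, `confidence` in \[0, 1\] (1 = exactly on a centroid).
#' @examples
#' call_dosage(c(0.26, 0.74))  # ABBB, dosage 3
#' @export
call_dosage <- function(heights, alleles = c("A", "B")) {
  if (length(heights) == 3L)
    return(call_dosage_triallelic(heights, alleles = LETTERS[1:3]))
  if (length(heights) != 2L || any(is.na(heights)) || any(heights < 0))
    stop("`heights` must be two nonnegative numbers", call. = FALSE)
  if (sum(heights) == 0)
    stop("invalid signal: all peak heights are zero", call. = FALSE)
  f <- heights[2L] / sum(heights)
  centroids <- (0:4) / 4
  d <- abs(f - centroids)
  dose <- which.min(d) - 1L
  list(label = dosage_to_class(c(4L - dose, dose)),
       dosage = dose,
       dosage_vector = setNames(c(4L - dose, dose), alleles[1:2]),
       confidence = 1 - min(d) / 0.125)
}

#' Call a triallelic tetraploid genotype from three peak heights
#'
#' Finds the integer dosage vector (d1, d2, d3) with d1+d2+d3 = 4 whose
#' expected height fractions (d1, d2, d3)/4 are nearest (Euclidean) to the
#' observed fractions, by exhaustive search over the 15 compositions of 4
#' into 3 parts; ties break toward the lexicographically smallest label.
#'
#' @param heights three nonnegative peak heights, not all zero.
#' @param alleles three allele letters.
#' @return list as in [call_dosage()]; `dosage` is the alt1+alt2 copy total.
#' @export
call_dosage_triallelic <- function(heights, alleles = c("A", "B", "C")) {
  if (length(heights) != 3L || any(is.na(heights)) || any(heights < 0))
    stop("`heights` must be three nonnegative numbers", call. = FALSE)
  if (sum(heights) == 0)
    stop("invalid signal: all peak heights are zero", call. = FALSE)
  f <- heights / sum(heights)
  classes <- genotype_classes(3L)
  grid <- as.matrix(classes[, LETTERS[1:3]])
  dist2 <- rowSums(sweep(grid / 4, 2L, f)^2)
  # classes are sorted by label, so which.min's first match is the
  # lexicographic tie-break
  best <- which.min(dist2)
  dv <- setNames(grid[best, ], alleles[1:3])
  list(label = classes$label[best],
       dosage = sum(dv[-1L]),
       dosage_vector = dv,
       confidence = 1 - sqrt(dist2[best]) / 0.125)
}

#' Minor-frequency-allele and its copy frequency
#'
#' For a dosage-scored marker the alt-allele copy frequency is
#' sum(dosage) / (4 * n_non_missing); the minor frequency allele (MFA) is
#' whichever of the two alleles has frequency <= 0.5 (ties resolve to the
#' alternate allele), and the returned frequency is the MFA's.
#'
#' @param dosages integer vector of alt-allele dosages 0-4 (`NA` allowed).
#' @param alleles optional `c(ref, alt)` allele names.
#' @return list with `mfa_allele` ("ref"/"alt" or the supplied name),
#'   `frequency`, `n_used`.
#' @examples
#' minor_allele_frequency(c(rep(1, 8), rep(0, 200)))  # 8/832
#' @export
minor_allele_frequency <- function(dosages, alleles = c("ref", "alt")) {
  d <- dosages[!is.na(dosages)]
  if (length(d) == 0L)
    stop("all dosages missing: frequency undefined", call. = FALSE)
  if (any(!d %in% 0:4))
    stop("dosages must be integers in 0..4", call. = FALSE)
  f_alt <- sum(d) / (4 * length(d))
  if (f_alt <= 0.5)
    list(mfa_allele = alleles[2L], frequency = f_alt, n_used = length(d))
  else
    list(mfa_allele = alleles[1L], frequency = 1 - f_alt, n_used = length(d))
}

#' Reporting frequency of a presence/absence marker
#'
#' Allele-specific assays score a marker as present (1) or absent (0)
#' without dosage information, so a copy frequency is not derivable. Two
#' summaries are returned: the carrier fraction (carriers / n) and the copy
#' frequency under the assumption that every carrier is simplex
#' (carriers / (4 n)); neither is asserted to be commensurable with the
#' dosage-based copy frequency.
#'
#' @param calls 0/1 vector (`NA` allowed).
#' @return list with `carrier_fraction`, `simplex_copy_frequency`, `n_used`.
#' @export
presence_frequency <- function(calls) {
  x <- calls[!is.na(calls)]
  if (length(x) == 0L) stop("all calls missing", call. = FALSE)
  if (any(!x %in% 0:1)) stop("calls must be 0/1", call. = FALSE)
  list(carrier_fraction = mean(x),
       simplex_copy_frequency = mean(x) / 4,
       n_used = length(x))
}

#' Filter markers by minor-allele carrier count
#'
#' A marker is retained iff at least `min_carrier_genotypes` genotypes carry
#' one or more copies of its minor frequency allele. The defaults used in
#' practice are 8 carriers in a discovery population of ~208 (MFA < 1%
#' excluded) and 3 in a validation panel of ~40 (MFA < 2% excluded).
#' Presence/absence markers count carriers as calls equal to 1.
#'
#' @param x a [dosage_matrix()].
#' @param min_carrier_genotypes minimum carrier count (>= 0).
#' @return character vector of retained marker ids.
#' @export
apply_mfa_filter <- function(x, min_carrier_genotypes = 8L) {
  stopifnot(inherits(x, "dosage_matrix"), min_carrier_genotypes >= 0)
  sm <- attr(x, "scoring_mode")
  keep <- vapply(colnames(x), function(m) {
    v <- unclass(x)[, m]
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(FALSE)
    carriers <- if (sm[m] == "presence_absence") {
      sum(v == 1L)
    } else {
      f_alt <- sum(v) / (4 * length(v))
      if (f_alt == 0 && all(v == 0L)) 0L            # monomorphic
      else if (f_alt <= 0.5) sum(v >= 1L)           # MFA = alt
      else sum(v <= 3L)                             # MFA = ref
    }
    carriers >= min_carrier_genotypes
  }, logical(1L))
  # monomorphic-for-alt columns (all dosage 4) have MFA = ref with 0 carriers
  names(keep)[keep]
}

#' Fraction of missing calls per marker
#'
#' Markers exceeding `threshold` missingness are worth flagging before
#' association analysis.
#'
#' @param x a [dosage_matrix()].
#' @param threshold flag fraction (default 0.2).
#' @return data.frame with `marker`, `missing_fraction`, `flagged`.
#' @export
missingness_report <- function(x, threshold = 0.2) {
  stopifnot(inherits(x, "dosage_matrix"))
  mf <- colMeans(is.na(unclass(x)))
  data.frame(marker = colnames(x), missing_fraction = unname(mf),
             flagged = unname(mf > threshold), stringsAsFactors = FALSE)
}

#' Call a dosage matrix from a long table of peak signals
#'
#' @param peaks data.frame with columns `individual`, `marker`,
#'   `height_ref`, `height_alt` (and optionally `height_alt2` for
#'   triallelic markers).
#' @return a [dosage_matrix()] of alt-allele dosages.
#' @export
call_dosage_matrix <- function(peaks) {
  stopifnot(all(c("individual", "marker", "height_ref", "height_alt") %in%
                  names(peaks)))
  tri <- "height_alt2" %in% names(peaks)
  ids <- unique(peaks$individual); mks <- unique(peaks$marker)
  out <- matrix(NA_integer_, length(ids), length(mks),
                dimnames = list(ids, mks))
  for (k in seq_len(nrow(peaks))) {
    h <- c(peaks$height_ref[k], peaks$height_alt[k],
           if (tri) peaks$height_alt2[k])
    h <- h[!is.na(h)]
    out[peaks$individual[k], peaks$marker[k]] <- call_dosage(h)$dosage
  }
  dosage_matrix(out, scoring_mode = "dosage")
}
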