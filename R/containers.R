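#' Dosage matrix constructor
#'
#' The central genotype container: an integer matrix of individuals x
#' markers. Dosage-scored markers hold minor/alt-allele copy counts 0-4
#' (a biallelic tetraploid has five genotype classes); presence/absence
#' markers hold 0/1. `NA` marks missing calls.
#'
#' @param x integer matrix with individual rownames and marker colnames.
#' @param scoring_mode named character vector (one of "dosage",
#'   "presence_absence" per marker); unnamed scalar recycles to all markers.
#' @return object of class `dosage_matrix` (an integer matrix with a
#'   `scoring_mode` attribute).
#' @export
dosage_matrix <- function(x, scoring_mode = "dosage") {
  x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("`x` needs individual rownames and marker colnames", call. = FALSE)
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x)))
    stop("duplicate individual or marker ids", call. = FALSE)
  storage.mode(x) <- "integer"
  if (length(scoring_mode) == 1L && is.null(names(scoring_mode)))
    scoring_mode <- setNames(rep(scoring_mode, ncol(x)), colnames(x))
  if (!all(colnames(x) %in% names(scoring_mode)))
    stop("`scoring_mode` must cover every marker", call. = FALSE)
  scoring_mode <- scoring_mode[colnames(x)]
  if (!all(scoring_mode %in% c("dosage", "presence_absence")))
    stop("unknown scoring mode", call. = FALSE)
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    rng <- if (scoring_mode[j] == "dosage") 0:4 else 0:1
    if (any(!is.na(v) & !v %in% rng))
      stop(sprintf("marker %s: value out of range for %s scoring",
                   colnames(x)[j], scoring_mode[j]), call. = FALSE)
  }
  structure(x, scoring_mode = scoring_mode, class = "dosage_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("dosage_matrix: %d individuals x %d markers (%d dosage, %d presence/absence)\n",
              nrow(x), ncol(x), sum(attr(x, "scoring_mode") == "dosage"),
              sum(attr(x, "scoring_mode") == "presence_absence")))
  miss <- mean(is.na(x))
  cat(sprintf("missing: %.1f%%\n", 100 * miss))
  print(head(unclass(x), 5L))
  invisible(x)
}

#' @export
`[.dosage_matrix` <- function(x, i, j, ..., drop = FALSE) {
  sm <- attr(x, "scoring_mode")
  out <- unclass(x)[i, j, ..., drop = drop]
  if (is.matrix(out))
    structure(out, scoring_mode = sm[colnames(out)], class = "dosage_matrix")
  else out
}

#' Trait table constructor
#'
#' Individuals x named phenotypes, with per-trait metadata: measurement
#' scale (`continuous` or `ordinal_1_9`, the 1-9 chip-color convention) and
#' analysis transform (`none` or `log10`, the latter used for reducing-sugar
#' content in validation panels).
#'
#' @param x data.frame of trait columns with individual rownames.
#' @param metadata data.frame with columns `trait`, `scale`, `transform`
#'   (defaults: all continuous, no transform).
#' @return object of class `trait_table`.
#' @export
trait_table <- function(x, metadata = NULL) {
  x <- as.data.frame(x)
  if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
    stop("`x` needs unique individual rownames", call. = FALSE)
  if (is.null(metadata))
    metadata <- data.frame(trait = names(x), scale = "continuous",
                           transform = "none", stringsAsFactors = FALSE)
  stopifnot(all(names(x) %in% metadata$trait),
            all(metadata$scale %in% c("continuous", "ordinal_1_9")),
            all(metadata$transform %in% c("none", "log10")))
  metadata <- metadata[match(names(x), metadata$trait), , drop = FALSE]
  for (k in seq_along(x)) {
    v <- x[[k]]
    if (metadata$scale[k] == "ordinal_1_9" &&
        any(!is.na(v) & (v != floor(v) | v < 1 | v > 9)))
      stop(sprintf("trait %s: ordinal_1_9 values must be integers in 1..9",
                   names(x)[k]), call. = FALSE)
  }
  structure(x, metadata = metadata, class = c("trait_table", "data.frame"))
}

#' Haplotype matrix constructor
#'
#' SNP positions (rows, 1-based ORF coordinates with position 1 the A of the
#' ATG start codon) x cDNA variants (columns), holding single-nucleotide base
#' calls, with optional amino-acid-change annotation per position (e.g.
#' "His8Tyr"; "-" or NA for silent sites).
#'
#' @param x character matrix of bases; colnames are variant ids.
#' @param positions strictly increasing integer vector of ORF positions.
#' @param aa_change optional character vector of annotations per position.
#' @return object of class `haplotype_matrix`.
#' @export
haplotype_matrix <- function(x, positions, aa_change = NULL) {
  x <- as.matrix(x)
  positions <- as.integer(positions)
  if (length(positions) != nrow(x))
    stop("`positions` must match the number of rows", call. = FALSE)
  if (any(positions < 1L) || is.unsorted(positions, strictly = TRUE))
    stop("`positions` must be strictly increasing and >= 1", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- as.character(seq_len(ncol(x)))
  if (!all(x %in% c("A", "C", "G", "T")))
    stop("bases must be single nucleotides A/C/G/T", call. = FALSE)
  if (!is.null(aa_change)) {
    if (length(aa_change) != length(positions))
      stop("`aa_change` must match `positions`", call. = FALSE)
    aa_change[aa_change %in% c("-", "")] <- NA_character_
  }
  rownames(x) <- as.character(positions)
  structure(x, positions = positions, aa_change = aa_change,
            class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("haplotype_matrix: %d SNP positions x %d cDNA variants\n",
              nrow(x), ncol(x)))
  print(unclass(x))
  invisible(x)
}

#' Bundled PHO1a cDNA SNP haplotype matrix
#'
#' The 15-SNP x 9-variant base-call matrix of full-length plastidic starch
#' phosphorylase (PHO1a) cDNA alleles cloned from four tetraploid potato
#' cultivars, with amino-acid-change annotations. Variant 1 is the reference
#' allele (GenBank D00520/X52385); variant 5 is the allele associated with
#' increased tuber starch content.
#'
#' @return a [haplotype_matrix()].
#' @export
pho1a_haplotypes <- function() {
  path <- system.file("extdata", "pho1a_cdna_snps.tsv", package = "tetrassoc",
                      mustWork = TRUE)
  read_haplotype_tsv(path)
}
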