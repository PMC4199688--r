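#' Clone-consensus SNP calling
#'
#' Sanger-sequenced clones of PCR products carry polymerase and sequencing
#' errors, so a variant observed in a single clone is not trustworthy. A
#' variant (position, base != reference) is accepted as factual iff it is
#' carried by at least `min_clones` clones originating from at least
#' `min_batches` distinct amplification batches (independent PCRs).
#'
#' @param clones a `clone_table` (see [simulate_clone_table()] /
#'   [read_clone_csv()]): one row per clone with a `batch` column and
#'   `pos_<position>` base-call columns.
#' @param reference named character vector of reference bases, names =
#'   positions (defaults to the majority base per position).
#' @param min_clones minimum carrying clones (default 3).
#' @param min_batches minimum distinct batches among carriers (default 2).
#' @return data.frame with `position`, `alt`, `n_clones`, `n_batches`,
#'   `accepted`; accepted variants only unless `all_candidates = TRUE`.
#' @param all_candidates return rejected candidates too.
#' @export
consensus_snps <- function(clones, reference = NULL, min_clones = 3L,
                           min_batches = 2L, all_candidates = FALSE) {
  stopifnot(is.data.frame(clones))
  if (!"batch" %in% names(clones) || anyNA(clones$batch))
    stop("every clone needs an amplification batch id", call. = FALSE)
  poscols <- grep("^pos_", names(clones), value = TRUE)
  if (length(poscols) == 0L) stop("no position columns found", call. = FALSE)
  positions <- as.integer(sub("^pos_", "", poscols))
  if (nrow(clones) < min_clones)
    stop("need at least ", min_clones, " clones", call. = FALSE)
  if (length(unique(clones$batch)) < min_batches)
    stop("need clones from at least ", min_batches, " batches", call. = FALSE)
  if (is.null(reference)) {
    reference <- vapply(poscols, function(cn)
      names(sort(table(clones[[cn]]), decreasing = TRUE))[1L], "")
    names(reference) <- positions
  } else {
    if (!all(as.character(positions) %in% names(reference)))
      stop("`reference` must cover every scored position", call. = FALSE)
  }
  rows <- list()
  for (i in seq_along(poscols)) {
    calls <- clones[[poscols[i]]]
    ref <- reference[[as.character(positions[i])]]
    for (b in setdiff(unique(calls), c(ref, NA))) {
      carrier <- !is.na(calls) & calls == b
      rows[[length(rows) + 1L]] <- data.frame(
        position = positions[i], alt = b,
        n_clones = sum(carrier),
        n_batches = length(unique(clones$batch[carrier])),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(position = integer(0), alt = character(0),
                         n_clones = integer(0), n_batches = integer(0))
  out$accepted <- out$n_clones >= min_clones & out$n_batches >= min_batches
  out <- out[order(out$position, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  if (all_candidates) out else out[out$accepted, , drop = FALSE]
}

#' Count pairwise-distinct haplotype columns
#'
#' @param x a [haplotype_matrix()].
#' @return list with `n` (number of distinct full-length haplotypes) and
#'   `representatives` (first-seen variant id of each distinct column).
#' @export
distinct_variants <- function(x) {
  stopifnot(inherits(x, "haplotype_matrix"), ncol(x) >= 1L)
  key <- apply(unclass(x), 2L, paste, collapse = "")
  reps <- colnames(x)[!duplicated(key)]
  list(n = length(reps), representatives = reps)
}

#' Find haplotype columns matching a base pattern
#'
#' @param x a [haplotype_matrix()].
#' @param pattern named character vector, names = ORF positions, values =
#'   required bases; an empty pattern matches every variant.
#' @return character vector of matching variant ids.
#' @examples
#' hm <- pho1a_haplotypes()
#' match_haplotype(hm, c("22" = "T", "322" = "A", "824" = "G", "2776" = "A"))
#' @export
match_haplotype <- function(x, pattern) {
  stopifnot(inherits(x, "haplotype_matrix"))
  if (length(pattern) == 0L) return(colnames(x))
  pos <- names(pattern)
  if (!all(pos %in% rownames(x)))
    stop("pattern position(s) absent from the matrix: ",
         paste(setdiff(pos, rownames(x)), collapse = ", "), call. = FALSE)
  sub <- unclass(x)[pos, , drop = FALSE]
  colnames(x)[colSums(sub == pattern) == length(pattern)]
}

#' Hamming distance between two haplotype columns
#'
#' @param x a [haplotype_matrix()].
#' @param id_a,id_b variant ids.
#' @return integer count of differing scored positions.
#' @export
haplotype_distance <- function(x, id_a, id_b) {
  stopifnot(inherits(x, "haplotype_matrix"))
  if (!all(c(id_a, id_b) %in% colnames(x)))
    stop("unknown variant id", call. = FALSE)
  sum(unclass(x)[, id_a] != unclass(x)[, id_b])
}

#' Concordance between two marker-call vectors
#'
#' Fraction of individuals with identical calls among non-missing pairs —
#' the statistic used to establish that an SSCP band and an SNP allele
#' diagnose the same underlying haplotype (e.g. 89% identical distributions
#' in a population of 208).
#'
#' @param calls_a,calls_b vectors over the same individuals (named vectors
#'   are joined on names).
#' @return list with `concordance` in \[0, 1\] and `n_compared`.
#' @export
concordance <- function(calls_a, calls_b) {
  if (!is.null(names(calls_a)) && !is.null(names(calls_b))) {
    shared <- intersect(names(calls_a), names(calls_b))
    if (length(shared) == 0L) stop("no shared individual ids", call. = FALSE)
    calls_a <- calls_a[shared]; calls_b <- calls_b[shared]
  } else if (length(calls_a) != length(calls_b)) {
    stop("call vectors must share individuals", call. = FALSE)
  }
  ok <- !is.na(calls_a) & !is.na(calls_b)
  if (!any(ok)) stop("no non-missing pairs", call. = FALSE)
  list(concordance = mean(calls_a[ok] == calls_b[ok]), n_compared = sum(ok))
}

#' Map a cDNA ORF position to its codon residue and offset
#'
#' Positions are 1-based on the open reading frame with position 1 the A of
#' the ATG start codon, so residue = floor((position - 1) / 3) + 1 and the
#' within-codon offset is 1..3.
#'
#' @param cdna_position integer vector of ORF positions (>= 1).
#' @return data.frame with `position`, `residue`, `codon_offset`.
#' @examples
#' residue_of(c(22, 322, 2776))  # residues 8, 108, 926
#' @export
residue_of <- function(cdna_position) {
  pos <- as.integer(cdna_position)
  if (any(is.na(pos) | pos < 1L))
    stop("ORF positions must be integers >= 1", call. = FALSE)
  data.frame(position = pos,
             residue = (pos - 1L) %/% 3L + 1L,
             codon_offset = (pos - 1L) %% 3L + 1L)
}

#' Partition SNP positions by codon position
#'
#' Third-codon-position substitutions are mostly synonymous; splitting the
#' scored ORF positions into third vs non-third sets gives an arithmetic
#' cross-check on the amino-acid-change annotations.
#'
#' @param x a [haplotype_matrix()] or an integer vector of ORF positions.
#' @return list with integer vectors `third` and `non_third`.
#' @export
third_position_snps <- function(x) {
  pos <- if (inherits(x, "haplotype_matrix")) attr(x, "positions")
         else as.integer(x)
  off <- residue_of(pos)$codon_offset
  list(third = pos[off == 3L], non_third = pos[off != 3L])
}

#' Check amino-acid-change annotations against coordinate arithmetic
#'
#' Recomputes the residue index of every annotated position from the ORF
#' coordinate and flags annotations whose stated residue number disagrees;
#' disagreements are reported, never silently corrected.
#'
#' @param x a [haplotype_matrix()] with `aa_change` annotations.
#' @return data.frame with `position`, `aa_change`, `annotated_residue`,
#'   `computed_residue`, `consistent`.
#' @export
annotation_check <- function(x) {
  stopifnot(inherits(x, "haplotype_matrix"))
  aa <- attr(x, "aa_change")
  if (is.null(aa)) stop("matrix carries no annotations", call. = FALSE)
  pos <- attr(x, "positions")
  keep <- !is.na(aa)
  ann_res <- as.integer(sub("^[A-Za-z]+([0-9]+)[A-Za-z]+$", "\\1", aa[keep]))
  comp <- residue_of(pos[keep])$residue
  data.frame(position = pos[keep], aa_change = aa[keep],
             annotated_residue = ann_res, computed_residue = comp,
             consistent = ann_res == comp, stringsAsFactors = FALSE)
}

#' Derive a haplotype matrix from aligned full-length cDNA sequences
#'
#' Given pre-aligned, equal-length cDNA sequences (the first record is the
#' reference), returns the haplotype matrix over all positions at which any
#' sequence differs from the reference.
#'
#' @param seqs named character vector of equal-length sequences, or a path
#'   to a FASTA file (read with `seqinr`-free base parsing).
#' @return a [haplotype_matrix()].
#' @export
haplotypes_from_cdna <- function(seqs) {
  if (length(seqs) == 1L && file.exists(seqs)) seqs <- read_fasta(seqs)
  if (length(seqs) < 2L) stop("need >= 2 sequences", call. = FALSE)
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences must be pre-aligned to equal length", call. = FALSE)
  mat <- do.call(cbind, strsplit(toupper(seqs), ""))
  colnames(mat) <- names(seqs)
  varying <- which(rowSums(mat != mat[, 1L]) > 0L)
  haplotype_matrix(mat[varying, , drop = FALSE], positions = varying)
}

# minimal FASTA reader (uppercased, concatenated multi-line records)
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file: ", path, call. = FALSE)
  id <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], id[!hdr]), paste, "", collapse = "")
  names(seqs) <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  toupper(seqs)
}
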