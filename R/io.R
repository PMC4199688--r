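#' Read a genotype TSV into a dosage matrix
#'
#' Expected layout: header row of marker ids, first column individual ids,
#' cells one of: dosage digits 0-4, 0/1 presence-absence, genotype class
#' strings (e.g. `AABB`, accepted as a human-friendly dialect of the dosage
#' coding: the count of non-A letters), or `NA`. Scoring mode is inferred
#' per marker: columns containing class strings or digits 2-4 are dosage;
#' columns with only 0/1 are presence_absence. Mixed class-string/numeric
#' columns are rejected, as are out-of-range digits.
#'
#' @param path file path.
#' @return a [dosage_matrix()].
#' @export
read_genotype_tsv <- function(path) {
  df <- read.delim(path, colClasses = "character", check.names = FALSE,
                   na.strings = NULL)
  if (ncol(df) < 2L) stop("genotype TSV needs id + marker columns",
                          call. = FALSE)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate individual id: ", ids[duplicated(ids)][1L],
         call. = FALSE)
  mks <- names(df)[-1L]
  if (anyDuplicated(mks))
    stop("duplicate marker id: ", mks[duplicated(mks)][1L], call. = FALSE)
  out <- matrix(NA_integer_, length(ids), length(mks),
                dimnames = list(ids, mks))
  mode <- setNames(character(length(mks)), mks)
  for (m in mks) {
    cells <- trimws(df[[m]])
    miss <- cells %in% c("NA", "", ".")
    v <- cells[!miss]
    is_class <- grepl("^[A-D]{4}$", v)
    is_num <- grepl("^[0-9]+$", v)
    if (any(!is_class & !is_num))
      stop(sprintf("marker %s: unparsable cell \"%s\"", m,
                   v[!is_class & !is_num][1L]), call. = FALSE)
    if (any(is_class) && any(is_num))
      stop(sprintf("marker %s: mixed class-string and numeric coding", m),
           call. = FALSE)
    if (any(is_class)) {
      val <- vapply(v, function(s) 4L - sum(strsplit(s, "")[[1]] == "A"), 0L)
      mode[m] <- "dosage"
    } else {
      val <- as.integer(v)
      if (any(val > 4L))
        stop(sprintf("marker %s: dosage value out of range (%d)", m,
                     max(val)), call. = FALSE)
      mode[m] <- if (all(val <= 1L)) "presence_absence" else "dosage"
    }
    col <- rep(NA_integer_, length(cells))
    col[!miss] <- val
    out[, m] <- col
  }
  dosage_matrix(out, scoring_mode = mode)
}

#' @param x a [dosage_matrix()].
#' @param path output path.
#' @rdname read_genotype_tsv
#' @export
write_genotype_tsv <- function(x, path) {
  stopifnot(inherits(x, "dosage_matrix"))
  df <- data.frame(individual = rownames(x), unclass(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read / write a trait table TSV
#'
#' First column individual ids, remaining columns traits. Per-trait
#' metadata (scale, transform) can be supplied in a sidecar header comment
#' or via the `metadata` argument.
#'
#' @param path file path.
#' @param metadata optional metadata data.frame (see [trait_table()]).
#' @return a [trait_table()].
#' @export
read_trait_tsv <- function(path, metadata = NULL) {
  df <- read.delim(path, check.names = FALSE)
  rownames(df) <- df[[1L]]
  trait_table(df[, -1L, drop = FALSE], metadata = metadata)
}

#' @param x a [trait_table()].
#' @rdname read_trait_tsv
#' @export
write_trait_tsv <- function(x, path) {
  stopifnot(inherits(x, "trait_table"))
  df <- data.frame(individual = rownames(x), as.data.frame(x),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read / write a long-format peak-signal CSV
#'
#' Columns: `individual`, `marker`, `height_ref`, `height_alt`, optionally
#' `height_alt2` for triallelic markers.
#'
#' @param path file path.
#' @return data.frame of peak signals.
#' @export
read_peak_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  need <- c("individual", "marker", "height_ref", "height_alt")
  if (!all(need %in% names(df)))
    stop("peak CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}

#' @param x peak-signal data.frame.
#' @rdname read_peak_csv
#' @export
write_peak_csv <- function(x, path) {
  write.table(x, path, sep = ",", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read / write a clone base-call CSV
#'
#' Columns: `clone`, `cultivar`, `tissue`, `batch`, then `pos_<position>`
#' base-call columns.
#'
#' @param path file path.
#' @return a `clone_table` data.frame.
#' @export
read_clone_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (!"batch" %in% names(df) || !any(grepl("^pos_", names(df))))
    stop("clone CSV needs a `batch` column and pos_<position> columns",
         call. = FALSE)
  class(df) <- c("clone_table", "data.frame")
  df
}

#' @param x a `clone_table`.
#' @rdname read_clone_csv
#' @export
write_clone_csv <- function(x, path) {
  write.table(x, path, sep = ",", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read / write a haplotype-matrix TSV
#'
#' Layout mirrors published cDNA-allele tables: one row per SNP position,
#' columns `position`, `aa_change` (`-` for silent), then one column per
#' cDNA variant.
#'
#' @param path file path.
#' @return a [haplotype_matrix()].
#' @export
read_haplotype_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (!"position" %in% names(df))
    stop("haplotype TSV needs a `position` column", call. = FALSE)
  aa <- if ("aa_change" %in% names(df)) df$aa_change else NULL
  vcols <- setdiff(names(df), c("position", "aa_change"))
  haplotype_matrix(as.matrix(df[, vcols, drop = FALSE]),
                   positions = as.integer(df$position), aa_change = aa)
}

#' @param x a [haplotype_matrix()].
#' @rdname read_haplotype_tsv
#' @export
write_haplotype_tsv <- function(x, path) {
  stopifnot(inherits(x, "haplotype_matrix"))
  aa <- attr(x, "aa_change")
  df <- data.frame(position = attr(x, "positions"),
                   aa_change = if (is.null(aa)) "-" else
                     ifelse(is.na(aa), "-", aa),
                   unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Import tetraploid genotypes from a VCF file
#'
#' Maps polyploid GT fields (e.g. `0/0/0/1`) to alt-allele dosage counts.
#' Biallelic records become one dosage marker; multiallelic records are
#' imported as triallelic markers whose value is the total non-reference
#' dosage (per-allele counts are retained in the `allele_counts`
#' attribute). Missing GTs (`./././.`) and records of ploidy other than 4
#' (warned per record) become missing values.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @return a [dosage_matrix()] with markers named
#'   `<locus>-<REF>_<POS>_<ALT>` (CHROM as locus).
#' @export
read_vcf_polyploid <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  ids <- colnames(gt)
  mks <- sprintf("%s-%s_%s_%s", fix[, "CHROM"], fix[, "REF"], fix[, "POS"],
                 sub(",.*$", "", fix[, "ALT"]))
  out <- matrix(NA_integer_, length(ids), length(mks),
                dimnames = list(ids, mks))
  for (i in seq_len(nrow(gt))) {
    for (j in seq_len(ncol(gt))) {
      g <- gt[i, j]
      if (is.na(g)) next
      al <- strsplit(g, "[/|]")[[1]]
      if (length(al) != 4L) {
        warning(sprintf("record %s sample %s: ploidy %d != 4; set missing",
                        mks[i], ids[j], length(al)), call. = FALSE)
        next
      }
      if (any(al == ".")) next
      out[j, i] <- sum(as.integer(al) > 0L)
    }
  }
  dosage_matrix(out, scoring_mode = "dosage")
}

#' Write association results (long and wide)
#'
#' `write_association_tsv` writes the machine-readable long format; the
#' wide companion (`*_wide.tsv`) mirrors the layout of published
#' association tables (marker, MFA %, per-trait percent variance + tier +
#' direction glyph).
#'
#' @param x an `association_result` from [associate_all()].
#' @param path output path for the long table.
#' @param wide also write the wide companion next to `path`.
#' @return invisibly, the path(s) written.
#' @export
write_association_tsv <- function(x, path, wide = TRUE) {
  stopifnot(inherits(x, "association_result"))
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  paths <- path
  if (wide) {
    wp <- sub("(\\.tsv)?$", "_wide.tsv", path)
    write.table(association_wide(x), wp, sep = "\t", quote = FALSE,
                row.names = FALSE, na = "NA")
    paths <- c(paths, wp)
  }
  invisible(paths)
}

#' Write an LD pair table and pairwise q-value matrix
#'
#' @param x an `ld_result` from [ld_scan()].
#' @param path output path for the long pair table; the q-value matrix goes
#'   to `*_qmatrix.tsv`.
#' @return invisibly, the paths written.
#' @export
write_ld_tsv <- function(x, path) {
  stopifnot(inherits(x, "ld_result"))
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  mks <- unique(c(x$marker_i, x$marker_j))
  qm <- matrix(NA_real_, length(mks), length(mks),
               dimnames = list(mks, mks))
  diag(qm) <- 0
  for (k in seq_len(nrow(x))) {
    qm[x$marker_i[k], x$marker_j[k]] <- x$q_value[k]
    qm[x$marker_j[k], x$marker_i[k]] <- x$q_value[k]
  }
  qp <- sub("(\\.tsv)?$", "_qmatrix.tsv", path)
  write.table(data.frame(marker = mks, qm, check.names = FALSE), qp,
              sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(c(path, qp))
}

#' Write / read the truth sidecar of a simulated dataset
#'
#' Key-value text format: `trait<TAB>causal_marker<TAB>beta<TAB>r2` rows
#' under a `[traits]` section and `marker<TAB>maf` rows under `[markers]`.
#'
#' @param truth the `truth` element of a `simulated_dataset`.
#' @param path file path.
#' @export
write_truth_sidecar <- function(truth, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("[traits]", con)
  for (tr in names(truth$causal_marker))
    writeLines(sprintf("%s\t%s\t%.10g\t%.10g", tr,
                       ifelse(is.na(truth$causal_marker[tr]), "NA",
                              truth$causal_marker[tr]),
                       truth$beta[tr], truth$r2[tr]), con)
  writeLines("[markers]", con)
  for (m in names(truth$maf))
    writeLines(sprintf("%s\t%.10g", m, truth$maf[m]), con)
  invisible(path)
}

#' Write every component of a simulated dataset to a directory
#'
#' Emits the standard file set: `genotypes.tsv`, `traits.tsv`, `peaks.csv`,
#' `clones.csv`, and `truth.tsv`.
#'
#' @param dataset a `simulated_dataset` from [simulate_population()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_simulated_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "simulated_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genotype_tsv(dataset$dosage_matrix, file.path(dir, "genotypes.tsv"))
  write_trait_tsv(dataset$trait_table, file.path(dir, "traits.tsv"))
  write_peak_csv(dataset$peak_signals, file.path(dir, "peaks.csv"))
  write_clone_csv(dataset$clone_table, file.path(dir, "clones.csv"))
  write_truth_sidecar(dataset$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
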