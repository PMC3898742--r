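# Readers/writers for the external formats the pipeline touches, and the
# canonical in-memory record containers.
#
# Coordinate conventions: all in-memory genomic coordinates are 0-based
# half-open. The human-readable call TSV is 1-based; emitted BED is 0-based
# half-open.

#' Construct a set of sequence records
#'
#' The atomic read/contig container used throughout the pipeline: parallel
#' vectors of identifiers and DNA sequences, plus an optional list of phred
#' quality vectors.
#'
#' @param id character vector of record identifiers.
#' @param seq character vector of DNA sequences (alphabet A/C/G/T/N).
#' @param qual optional list of integer phred scores, one vector per record,
#'   each the same length as its sequence.
#' @return an object of class `seq_set`.
#' @export
seq_set <- function(id, seq, qual = NULL) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq)) stop("id and seq must have equal length")
  .validate_dna(seq, "read sequence")
  if (!is.null(qual)) {
    if (length(qual) != length(seq)) stop("qual must have one entry per record")
    qlen <- vapply(qual, length, integer(1))
    bad <- which(qlen != nchar(seq))
    if (length(bad)) {
      stop(sprintf("quality/sequence length mismatch for record '%s' (%d quality values, %d bases)",
                   id[bad[1L]], qlen[bad[1L]], nchar(seq)[bad[1L]]))
    }
    if (any(unlist(qual, use.names = FALSE) < 0)) stop("phred scores must be >= 0")
  }
  structure(list(id = id, seq = seq, qual = qual), class = "seq_set")
}

#' @export
length.seq_set <- function(x) length(x$id)

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("<seq_set> %d records%s\n", length(x),
              if (is.null(x$qual)) "" else " (with qualities)"))
  invisible(x)
}

#' Subset a seq_set
#' @param x a `seq_set`.
#' @param i index vector.
#' @param ... ignored.
#' @export
`[.seq_set` <- function(x, i, ...) {
  seq_set(x$id[i], x$seq[i], if (is.null(x$qual)) NULL else x$qual[i])
}

#' Read sequence records from FASTA or FASTQ
#'
#' @param path file path (optionally gzip-compressed).
#' @param format `"fasta"`, `"fastq"`, or `"auto"` (by extension).
#' @return a [seq_set]; FASTQ records carry phred qualities (Sanger +33).
#' @export
read_seq_files <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.f(ast)?q(\\.gz)?$", path, ignore.case = TRUE)) "fastq" else "fasta"
  }
  if (format == "fastq") {
    parsed <- tryCatch({
      # the loader warns about dropped metadata columns; irrelevant here
      x <- withCallingHandlers(
        Biostrings::readQualityScaledDNAStringSet(path),
        warning = function(w) {
          if (grepl("metadata columns", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        })
      list(id = names(x), seq = as.character(x),
           qual = as.list(methods::as(Biostrings::quality(x), "IntegerList")))
    }, error = function(e) {
      stop(sprintf("malformed FASTQ in %s: %s", path,
                   gsub("[^ -~]", "", conditionMessage(e))))
    })
    seq_set(parsed$id, parsed$seq, parsed$qual)
  } else {
    x <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop(sprintf("malformed FASTA in %s: %s",
                                                   path, conditionMessage(e))))
    seq_set(names(x), as.character(x))
  }
}

#' Write sequence records to FASTA or FASTQ
#' @param x a [seq_set].
#' @param path output path.
#' @param format `"fasta"` or `"fastq"` (`"fastq"` requires qualities).
#' @return `path`, invisibly.
#' @export
write_seq_files <- function(x, path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  dna <- Biostrings::DNAStringSet(x$seq)
  names(dna) <- x$id
  if (format == "fastq") {
    if (is.null(x$qual)) stop("FASTQ output requires qualities")
    q <- Biostrings::PhredQuality(methods::as(x$qual, "IntegerList"))
    qs <- Biostrings::QualityScaledDNAStringSet(dna, q)
    Biostrings::writeQualityScaledXStringSet(qs, path)
  } else {
    Biostrings::writeXStringSet(dna, path)
  }
  invisible(path)
}

#' Load a retrotransposon consensus library
#'
#' FASTA with structured headers `>family|end_tag|full_length`, where
#' `end_tag` is `five_prime` or `three_prime` and `full_length` is the length
#' of the family's full consensus in nucleotides. Each entry is a terminal
#' segment of the family consensus. `cons_offset` gives the 0-based consensus
#' coordinate of the entry's first base (0 for 5' entries,
#' `full_length - nchar(seq)` for 3' entries).
#'
#' @param path FASTA path.
#' @return an object of class `consensus_library`: a data.frame with columns
#'   `family`, `end_tag`, `seq`, `entry_len`, `full_length`, `cons_offset`.
#'   Families represented by only one end are usable for single-end detection
#'   only (a warning is issued).
#' @export
load_consensus_library <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 3L)) {
    stop(sprintf("consensus header '%s' does not follow family|end_tag|full_length",
                 names(x)[which(nfield != 3L)[1L]]))
  }
  family <- vapply(parts, `[`, "", 1L)
  end_tag <- vapply(parts, `[`, "", 2L)
  full_length <- suppressWarnings(as.integer(vapply(parts, `[`, "", 3L)))
  if (!all(end_tag %in% c("five_prime", "three_prime"))) {
    stop(sprintf("unknown end_tag '%s' (expected five_prime/three_prime)",
                 setdiff(end_tag, c("five_prime", "three_prime"))[1L]))
  }
  if (any(is.na(full_length))) stop("full_length field is not an integer")
  seqs <- as.character(x)
  if (any(nchar(seqs) == 0L)) stop("consensus entries must be non-empty")
  .validate_dna(seqs, "consensus entry", allow_n = FALSE)
  lib <- data.frame(family = family, end_tag = end_tag, seq = seqs,
                    entry_len = nchar(seqs), full_length = full_length,
                    stringsAsFactors = FALSE, row.names = NULL)
  lib$cons_offset <- ifelse(lib$end_tag == "three_prime",
                            lib$full_length - lib$entry_len, 0L)
  single <- names(which(tapply(lib$end_tag, lib$family,
                               function(e) length(unique(e))) < 2L))
  if (length(single)) {
    warning(sprintf("family with a single end entry (single-end detection only): %s",
                    paste(single, collapse = ", ")))
  }
  class(lib) <- c("consensus_library", "data.frame")
  lib
}

#' Load a known-insertion database (BED or TSV)
#'
#' Accepts BED (>= 4 columns, no header, 0-based half-open) or a
#' tab-separated file with a header naming at least
#' `chrom`, `start`, `end`, `family` (same coordinate convention).
#' Entries are deduplicated on (chrom, start, end, family) and sorted.
#'
#' @param path file path.
#' @param source_label label recorded for all entries of this file.
#' @return an object of class `known_db` (data.frame with columns `chrom`,
#'   `start`, `end`, `family`, `source`).
#' @export
load_known_db <- function(path, source_label = basename(path)) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("chrom", first, ignore.case = TRUE)
  tab <- utils::read.table(path, sep = "\t", header = has_header,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 4L) stop("known-insertion file needs >= 4 columns (chrom, start, end, family)")
  if (has_header) {
    names(tab) <- tolower(names(tab))
    tab <- tab[, c("chrom", "start", "end", "family")]
  } else {
    tab <- tab[, 1:4]
    names(tab) <- c("chrom", "start", "end", "family")
  }
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  bad <- which(!(tab$start < tab$end) | tab$start < 0L)
  if (length(bad)) {
    stop(sprintf("invalid interval at row %d: start %d, end %d (need 0 <= start < end)",
                 bad[1L] + as.integer(has_header), tab$start[bad[1L]], tab$end[bad[1L]]))
  }
  tab$source <- source_label
  tab <- unique(tab[, c("chrom", "start", "end", "family", "source")])
  tab <- tab[order(tab$chrom, tab$start, tab$end, tab$family), , drop = FALSE]
  row.names(tab) <- NULL
  class(tab) <- c("known_db", "data.frame")
  tab
}

# Fixed column order of the call TSV (External Interfaces contract).
CALL_TSV_COLS <- c("sample", "chrom", "bp5", "bp3", "family", "orientation",
                   "ends_detected", "n_amplicons_5", "n_amplicons_3", "label")

.validate_calls <- function(calls) {
  if (!is.data.frame(calls)) stop("calls must be a data.frame")
  missing <- setdiff(CALL_TSV_COLS, names(calls))
  if (length(missing)) stop(sprintf("calls lack columns: %s", paste(missing, collapse = ", ")))
  if (!all(calls$ends_detected %in% c("five_only", "three_only", "both"))) {
    stop("ends_detected must be five_only/three_only/both")
  }
  invisible(calls)
}

#' Write insertion calls as a TSV report and a BED track
#'
#' The TSV reports breakpoints 1-based; the BED interval spans the detected
#' junction coordinate(s), 0-based half-open. Re-reading the TSV with
#' [read_calls()] reconstructs the calls field-by-field.
#'
#' @param calls an insertion-call data.frame (see [read_calls()] for columns);
#'   internal `bp5`/`bp3` are 0-based junction coordinates (NA when the end
#'   was not detected).
#' @param out_prefix output path prefix; writes `<prefix>.calls.tsv` and
#'   `<prefix>.calls.bed`.
#' @return named character vector of the two file paths, invisibly.
#' @export
write_calls <- function(calls, out_prefix) {
  .validate_calls(calls)
  tsv <- calls[, CALL_TSV_COLS, drop = FALSE]
  tsv$bp5 <- ifelse(is.na(tsv$bp5), NA_integer_, tsv$bp5 + 1L)
  tsv$bp3 <- ifelse(is.na(tsv$bp3), NA_integer_, tsv$bp3 + 1L)
  tsv_path <- paste0(out_prefix, ".calls.tsv")
  bed_path <- paste0(out_prefix, ".calls.bed")
  utils::write.table(tsv, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(calls)) {
    lo <- pmin(calls$bp5, calls$bp3, na.rm = TRUE)
    hi <- pmax(calls$bp5, calls$bp3, na.rm = TRUE)
    bed <- data.frame(chrom = calls$chrom, start = lo, end = hi + 1L,
                      name = paste0(calls$family, "_", calls$sample))
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    file.create(bed_path)
  }
  invisible(c(tsv = tsv_path, bed = bed_path))
}

#' Read an insertion-call TSV written by [write_calls()]
#' @param path TSV path.
#' @return insertion-call data.frame with 0-based `bp5`/`bp3`.
#' @export
read_calls <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = c(sample = "character", chrom = "character",
                                          family = "character", label = "character"))
  tab$bp5 <- ifelse(is.na(tab$bp5), NA_integer_, as.integer(tab$bp5) - 1L)
  tab$bp3 <- ifelse(is.na(tab$bp3), NA_integer_, as.integer(tab$bp3) - 1L)
  .validate_calls(tab)
  tab[, CALL_TSV_COLS, drop = FALSE]
}
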