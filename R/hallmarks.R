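# Target-primed reverse transcription (TPRT) hallmark characterization for
# both-end insertion calls: target-site duplication or junction deletion,
# poly-A tail, endonuclease motif, 5' inversion (twin priming), insertion
# length/truncation, and mechanism classification.

#' Target-site duplication or junction deletion from call geometry
#'
#' With single-nucleotide breakpoints the TSD is the overlap of the two
#' junction coordinates on the reference; a gap between them is a junction
#' deletion. Computed exactly from coordinates, no fuzzy sequence matching:
#' for a + orientation insertion the signed overlap is `bp5 - bp3 + 1`, for
#' a - orientation it is `bp3 - bp5 + 1`.
#'
#' @param bp5,bp3 0-based junction coordinates (reference base flanking the
#'   TE at the 5'-end and 3'-end junctions).
#' @param orientation insertion orientation relative to the reference
#'   (`"+"`/`"-"`).
#' @param genome optional named chromosome vector; with `chrom`, returns the
#'   duplicated sequence.
#' @param chrom chromosome of the call (needed for `tsd_seq`).
#' @param max_tsd separations beyond this are flagged unresolved rather than
#'   forced into either class (default 50).
#' @return list with `tsd_len`, `deletion_len`, `tsd_seq` (NA unless a
#'   genome is supplied), and `resolved`.
#' @export
detect_tsd <- function(bp5, bp3, orientation = "+", genome = NULL,
                       chrom = NULL, max_tsd = 50L) {
  sep <- if (orientation == "+") bp5 - bp3 + 1L else bp3 - bp5 + 1L
  if (abs(sep) > max_tsd) {
    return(list(tsd_len = NA_integer_, deletion_len = NA_integer_,
                tsd_seq = NA_character_, resolved = FALSE))
  }
  tsd_len <- max(sep, 0L)
  deletion_len <- max(-sep, 0L)
  tsd_seq <- NA_character_
  if (tsd_len > 0L && !is.null(genome) && !is.null(chrom)) {
    g <- .as_genome(genome)
    a <- min(bp5, bp3)
    tsd_seq <- substr(g[[chrom]], a + 1L, a + tsd_len)
  }
  list(tsd_len = tsd_len, deletion_len = deletion_len, tsd_seq = tsd_seq,
       resolved = TRUE)
}

#' Poly-A tail length at a 3'-end junction
#'
#' Length of the adenosine run at the TE-to-genome boundary, scanned from
#' the junction into the TE side, permitting at most one non-A per 10 nt
#' window; the run terminates at consensus-matching sequence. Operates on a
#' normalized contig (non-TE section first), where a 3'-end junction shows
#' the tail as a T run immediately before the minus-orientation TE span.
#'
#' @param contig normalized contig DNA string.
#' @param te_match TE match row (normalized spans) for the contig.
#' @return tail length in nt (0 = no tail found).
#' @export
measure_polya <- function(contig, te_match) {
  chars <- .chars(if (is.list(contig) && !is.null(contig$seq)) contig$seq else contig)
  run <- if (te_match$orientation == "-") {
    .tolerant_run(chars, te_match$te_start, -1L, "T")
  } else {
    # element-sense layout (TE section then genome): scan the A run forward
    # from the TE end boundary
    .tolerant_run(chars, te_match$te_end + 1L, 1L, "A")
  }
  as.integer(run[["count"]])
}

#' L1 endonuclease motif at an insertion site
#'
#' Returns the 6 nt spanning the first-strand nick, written 5' to 3' on the
#' nicked strand with `/` at the scissile position, orientation-normalized
#' so the canonical site reads `TT/AAAA`. The nicked strand is the reference
#' bottom strand for + orientation insertions and the top strand for -
#' orientation insertions; in both cases the motif is a deterministic
#' function of the 3'-junction coordinate and the orientation, so evidence
#' from either sequenced strand yields the identical string.
#'
#' @param genome named chromosome vector.
#' @param chrom chromosome.
#' @param bp3 0-based 3'-end junction coordinate (reference base adjacent to
#'   the poly-A tail).
#' @param genome_strand insertion orientation (`"+"`/`"-"`).
#' @return 7-character motif string (6 bases and `/`), or NA when the site
#'   is closer than 5 nt to a reference edge.
#' @export
extract_en_motif <- function(genome, chrom, bp3, genome_strand = "+") {
  g <- .as_genome(genome)
  s <- g[[chrom]]
  n <- nchar(s)
  if (genome_strand == "+") {
    a <- bp3 - 4L; b <- bp3 + 1L
    if (a < 0L || b >= n) return(NA_character_)
    m <- revcomp(substr(s, a + 1L, b + 1L))
  } else {
    a <- bp3 - 1L; b <- bp3 + 4L
    if (a < 0L || b >= n) return(NA_character_)
    m <- substr(s, a + 1L, b + 1L)
  }
  paste0(substr(m, 1L, 2L), "/", substr(m, 3L, 6L))
}

#' Detect a twin-priming 5' inversion
#'
#' A twin-primed insertion shows its 5'-junction TE section as two adjacent
#' blocks aligning to the family consensus in opposite orientations, the
#' genome-proximal block inverted. Returns the length of the inverted block
#' on consensus coordinates (0 = no inversion).
#'
#' @param contig normalized 5'-junction contig DNA string.
#' @param te_match TE match row for the contig (normalized spans).
#' @param library `consensus_library` (the matched family's entries are
#'   aligned against).
#' @param min_block minimum credible block length in nt (default 20).
#' @return inverted block length (integer, 0 when the section aligns in a
#'   single orientation).
#' @export
detect_inversion <- function(contig, te_match, library, min_block = 20L) {
  seq <- if (is.list(contig) && !is.null(contig$seq)) contig$seq else contig
  entries <- library[library$family == te_match$family &
                       library$end_tag == "five_prime", , drop = FALSE]
  if (!nrow(entries)) {
    entries <- library[library$family == te_match$family, , drop = FALSE]
  }
  best <- 0L
  for (e in seq_len(nrow(entries))) {
    tb <- .twin_blocks(seq, entries$seq[e], entries$cons_offset[e], min_block)
    if (tb$found && tb$inv_len > best) best <- tb$inv_len
  }
  as.integer(best)
}

# Two-block twin-priming search: an inverted block (matching the reverse
# complement of the entry) immediately left-adjacent, on the contig and on
# consensus coordinates, to a sense block. Returns the inverted block length
# and its consensus start.
.twin_blocks <- function(seq, entry_seq, cons_offset = 0L, min_block = 20L,
                         adj_tol = 6L) {
  n <- nchar(seq)
  if (n < 2L * min_block) return(list(found = FALSE, inv_len = 0L))
  mat <- .subst_matrix(2, -3)
  elen <- nchar(entry_seq)
  al_inv <- Biostrings::pairwiseAlignment(seq, revcomp(entry_seq),
                                          type = "local",
                                          substitutionMatrix = mat,
                                          gapOpening = 5, gapExtension = 2)
  ps <- IRanges::start(Biostrings::pattern(al_inv))
  pe <- IRanges::end(Biostrings::pattern(al_inv))
  blen <- pe - ps + 1L
  idy <- Biostrings::nmatch(al_inv) / Biostrings::nchar(al_inv)
  if (blen < min_block || idy < 0.9) return(list(found = FALSE, inv_len = 0L))
  ss <- IRanges::start(Biostrings::subject(al_inv))
  se <- IRanges::end(Biostrings::subject(al_inv))
  inv_cons_start <- elen - se + cons_offset      # 0-based on consensus
  inv_cons_end <- elen - ss + 1L + cons_offset
  rest <- substr(seq, pe + 1L, n)
  if (nchar(rest) < 12L) {
    return(list(found = FALSE, inv_len = as.integer(blen),
                inv_cons_start = inv_cons_start, inv_start = ps - 1L,
                split = pe))
  }
  al_dir <- Biostrings::pairwiseAlignment(rest, entry_seq, type = "local",
                                          substitutionMatrix = mat,
                                          gapOpening = 5, gapExtension = 2)
  dlen <- Biostrings::nchar(al_dir)
  didy <- Biostrings::nmatch(al_dir) / dlen
  dps <- IRanges::start(Biostrings::pattern(al_dir))
  dss <- IRanges::start(Biostrings::subject(al_dir))
  dir_cons_start <- dss - 1L + cons_offset
  ok <- dlen >= 12L && didy >= 0.9 &&
    dps - 1L <= adj_tol &&                        # contig-adjacent
    abs(dir_cons_start - inv_cons_end) <= adj_tol # consensus-adjacent
  list(found = ok, inv_len = as.integer(blen),
       inv_cons_start = inv_cons_start, inv_start = ps - 1L, split = pe)
}

#' Insertion length and full-length status
#'
#' The junction-visible insertion length is the family consensus length
#' minus the consensus start coordinate of the 5'-junction match (a
#' twin-priming inverted block starts at the same consensus coordinate and
#' does not extend the length). Full length means >= 99.9 percent of the
#' consensus.
#'
#' @param cons_start5 consensus coordinate (0-based) where the 5'-junction
#'   TE section begins; NA for single-end calls.
#' @param full_length_nt family consensus length in nt.
#' @return list with `insertion_len` (NA when only a lower bound exists) and
#'   `full_length` (logical, NA when unknown).
#' @export
estimate_insertion_len <- function(cons_start5, full_length_nt) {
  if (is.na(cons_start5)) {
    return(list(insertion_len = NA_integer_, full_length = NA))
  }
  len <- as.integer(full_length_nt - cons_start5)
  list(insertion_len = len, full_length = len >= 0.999 * full_length_nt)
}

#' Characterize TPRT hallmarks for emitted calls
#'
#' @param calls insertion-call data.frame carrying `polya_len` and
#'   `cons_start5` (as produced by [call_insertions()]).
#' @param genome named chromosome vector.
#' @param library `consensus_library`.
#' @param max_tsd TSD/deletion resolution bound (default 50).
#' @return data.frame of hallmark reports (one row per both-end call):
#'   tsd_len, tsd_seq, deletion_len, polya_len, en_motif, inversion_len,
#'   insertion_len, full_length, mechanism.
#' @export
characterize_calls <- function(calls, genome, library, max_tsd = 50L) {
  both <- which(calls$ends_detected == "both")
  rows <- vector("list", length(both))
  fam_len <- tapply(library$full_length, library$family, max)
  for (j in seq_along(both)) {
    i <- both[j]
    tsd <- detect_tsd(calls$bp5[i], calls$bp3[i], calls$orientation[i],
                      genome, calls$chrom[i], max_tsd)
    motif <- extract_en_motif(genome, calls$chrom[i], calls$bp3[i],
                              calls$orientation[i])
    inv <- if (!is.null(calls$inversion_len)) calls$inversion_len[i] else 0L
    il <- estimate_insertion_len(calls$cons_start5[i],
                                 fam_len[[calls$family[i]]])
    mech <- if (!is.na(inv) && inv > 0L) "twin_priming"
    else if (isTRUE(tsd$deletion_len > 0L)) "deletion_no_tsd"
    else "tprt_tsd"
    rows[[j]] <- data.frame(
      sample = calls$sample[i], chrom = calls$chrom[i],
      bp5 = calls$bp5[i], bp3 = calls$bp3[i], family = calls$family[i],
      orientation = calls$orientation[i],
      tsd_len = tsd$tsd_len, tsd_seq = tsd$tsd_seq,
      deletion_len = tsd$deletion_len, resolved = tsd$resolved,
      polya_len = calls$polya_len[i], en_motif = motif,
      inversion_len = if (is.null(inv)) 0L else inv,
      insertion_len = il$insertion_len, full_length = il$full_length,
      mechanism = mech, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(sample = character(0), chrom = character(0),
                      bp5 = integer(0), bp3 = integer(0), family = character(0),
                      orientation = character(0), tsd_len = integer(0),
                      tsd_seq = character(0), deletion_len = integer(0),
                      resolved = logical(0), polya_len = integer(0),
                      en_motif = character(0), inversion_len = integer(0),
                      insertion_len = integer(0), full_length = logical(0),
                      mechanism = character(0), stringsAsFactors = FALSE)
  }
  row.names(res) <- NULL
  res
}

#' Cohort-level hallmark summaries
#'
#' Histograms of TSD and poly-A length per family, a 4 x 6 position
#' frequency matrix over the endonuclease motif with per-column information
#' content, and mechanism class counts.
#'
#' @param reports hallmark reports ([characterize_calls()]).
#' @return list with `tsd_hist`, `polya_hist`, `pfm`, `information_bits`,
#'   `mechanism_counts`.
#' @export
summarize_hallmarks <- function(reports) {
  if (nrow(reports) == 0L) stop("at least one hallmark report is required")
  tsd_hist <- table(family = reports$family, tsd_len = reports$tsd_len)
  polya_hist <- table(family = reports$family, polya_len = reports$polya_len)
  motifs <- reports$en_motif[!is.na(reports$en_motif)]
  bases <- do.call(rbind, strsplit(gsub("/", "", motifs, fixed = TRUE), ""))
  pfm <- matrix(0, 4, 6, dimnames = list(DNA_BASES4, paste0("pos", 1:6)))
  for (p in 1:6) {
    tb <- table(factor(bases[, p], levels = DNA_BASES4))
    pfm[, p] <- as.numeric(tb)
  }
  freq <- sweep(pfm, 2, pmax(colSums(pfm), 1), "/")
  ic <- apply(freq, 2, function(f) {
    f <- f[f > 0]
    2 + sum(f * log2(f))
  })
  list(tsd_hist = tsd_hist, polya_hist = polya_hist, pfm = pfm,
       information_bits = ic,
       mechanism_counts = table(factor(reports$mechanism,
                                       levels = c("tprt_tsd", "twin_priming",
                                                  "deletion_no_tsd"))))
}
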