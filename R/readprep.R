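# Read preparation: quality trimming, overlap assembly of read pairs into
# contigs, and linker/ligation-artifact screening.

#' Trim low-quality bases from read ends
#'
#' Removes bases from the 5' and 3' ends while the terminal base quality is
#' below `qmin`; interior bases are untouched. A fully low-quality read
#' becomes an empty record (dropped downstream).
#'
#' @param reads a [seq_set] with qualities.
#' @param qmin minimum terminal base quality retained (default 10).
#' @return a trimmed [seq_set].
#' @export
trim_low_quality <- function(reads, qmin = 10L) {
  if (is.null(reads$qual)) stop("trim_low_quality requires qualities")
  n <- length(reads)
  seq <- character(n)
  qual <- vector("list", n)
  for (i in seq_len(n)) {
    q <- reads$qual[[i]]
    keep <- which(q >= qmin)
    if (length(keep) == 0L) {
      seq[i] <- ""
      qual[[i]] <- integer(0)
    } else {
      a <- keep[1L]; b <- keep[length(keep)]
      seq[i] <- substr(reads$seq[i], a, b)
      qual[[i]] <- q[a:b]
    }
  }
  seq_set(reads$id, seq, qual)
}

#' Assemble one read pair into a merged contig
#'
#' Read 2 is reverse-complemented, then the overlap between the 3' end of
#' read 1 and the 5' end of the reoriented read 2 that maximizes matched
#' bases is chosen, subject to a minimum overlap length and a maximum
#' mismatch rate. In the overlap the higher-quality base wins and its quality
#' is retained. Ties in matched bases go to the longest overlap.
#'
#' @param r1,r2 single-record [seq_set]s (or lists with `seq`/`qual`),
#'   already quality-trimmed.
#' @param min_overlap minimum acceptable overlap (nt, default 10).
#' @param max_mismatch_rate maximum mismatch fraction in the overlap
#'   (default 0.1).
#' @return a list with `id`, `seq`, `qual`, `overlap_len`, `source_pair`, or
#'   `NULL` when no qualifying overlap exists.
#' @export
merge_pair <- function(r1, r2, min_overlap = 10L, max_mismatch_rate = 0.1) {
  s1 <- if (is.list(r1) && !is.null(r1$seq)) r1$seq[1L] else as.character(r1)
  s2 <- if (is.list(r2) && !is.null(r2$seq)) r2$seq[1L] else as.character(r2)
  get_qual <- function(r, n) {
    q <- if (is.list(r)) r$qual else NULL
    if (is.list(q)) q <- q[[1L]]
    if (is.null(q) || length(q) != n) rep(30L, n) else as.integer(q)
  }
  q1 <- get_qual(r1, nchar(s1))
  q2 <- get_qual(r2, nchar(s2))
  id1 <- if (is.list(r1) && !is.null(r1$id)) r1$id[1L] else "read/1"
  id2 <- if (is.list(r2) && !is.null(r2$id)) r2$id[1L] else "read/2"
  n1 <- nchar(s1); n2 <- nchar(s2)
  if (n1 < min_overlap || n2 < min_overlap) return(NULL)

  s2rc <- revcomp(s2)
  q2rc <- rev(q2)
  i1 <- .ints(s1); i2 <- .ints(s2rc)

  best_matches <- -1L; best_len <- 0L
  for (len in seq.int(min(n1, n2), min_overlap)) {
    if (len <= best_matches) break  # cannot beat current best
    ov1 <- i1[(n1 - len + 1L):n1]
    ov2 <- i2[1:len]
    matches <- sum(ov1 == ov2)
    if ((len - matches) / len <= max_mismatch_rate && matches > best_matches) {
      best_matches <- matches
      best_len <- len
    }
  }
  if (best_len == 0L) return(NULL)

  len <- best_len
  ovl_idx1 <- (n1 - len + 1L):n1
  ovl_idx2 <- 1:len
  take1 <- q1[ovl_idx1] >= q2rc[ovl_idx2]
  ovl_chars <- ifelse(take1, .chars(s1)[ovl_idx1], .chars(s2rc)[ovl_idx2])
  ovl_qual <- ifelse(take1, q1[ovl_idx1], q2rc[ovl_idx2])
  seq <- paste0(substr(s1, 1L, n1 - len),
                paste(ovl_chars, collapse = ""),
                substr(s2rc, len + 1L, n2))
  qual <- c(q1[seq_len(n1 - len)], ovl_qual, q2rc[seq.int(len + 1L, length.out = n2 - len)])
  list(id = sub("/[12]$", "", id1), seq = seq, qual = as.integer(qual),
       overlap_len = len, source_pair = c(id1, id2))
}

#' Assemble all read pairs of a library
#'
#' Applies quality trimming and pairwise overlap assembly to parallel
#' read-1/read-2 sets. Unmerged pairs are dropped from calling: single-
#' nucleotide junction resolution requires the full insert.
#'
#' @param r1,r2 [seq_set]s of equal length (mates in the same order).
#' @param qmin terminal quality threshold for trimming.
#' @inheritParams merge_pair
#' @return list with `contigs` (a [seq_set]), `overlap_len` (integer vector
#'   parallel to `contigs`), and `counts` (merged / unmerged totals).
#' @export
merge_pairs <- function(r1, r2, qmin = 10L, min_overlap = 10L,
                        max_mismatch_rate = 0.1) {
  if (length(r1) != length(r2)) stop("r1 and r2 must pair up")
  r1 <- trim_low_quality(r1, qmin)
  r2 <- trim_low_quality(r2, qmin)
  n <- length(r1)
  ids <- character(n); seqs <- character(n)
  quals <- vector("list", n); ovl <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    m <- merge_pair(list(id = r1$id[i], seq = r1$seq[i], qual = r1$qual[i]),
                    list(id = r2$id[i], seq = r2$seq[i], qual = r2$qual[i]),
                    min_overlap = min_overlap,
                    max_mismatch_rate = max_mismatch_rate)
    if (!is.null(m)) {
      k <- k + 1L
      ids[k] <- m$id; seqs[k] <- m$seq; quals[[k]] <- m$qual; ovl[k] <- m$overlap_len
    }
  }
  contigs <- seq_set(ids[seq_len(k)], seqs[seq_len(k)], quals[seq_len(k)])
  list(contigs = contigs, overlap_len = ovl[seq_len(k)],
       counts = c(input = n, merged = k, unmerged = n - k))
}

#' Default sequencing linker/adapter sequences
#'
#' The ligation-mediated PCR primers and the universal paired-end adapter
#' stems screened against assembled contigs to remove ligation artifacts.
#' @return named character vector of linker sequences.
#' @export
illumina_linkers <- function() {
  c(lmpcr_1 = "AATGATACGGCGACCACCGAGA",
    lmpcr_2 = "CAAGCAGAAGACGGCATACGAG",
    adapter_r1 = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
    adapter_r2 = "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGT")
}

#' Screen contigs against linker sequences
#'
#' A contig is dropped when a local alignment against any linker (either
#' strand) reaches `min_score` under a BLASTN-like scheme (match +1,
#' mismatch -3, gap open -5, gap extend -2), so a score of 22 corresponds to
#' a ~22 nt near-exact linker match.
#'
#' @param contigs a [seq_set] (or single character string).
#' @param linkers character vector of linker sequences.
#' @param min_score dropping threshold (default 22).
#' @return logical vector: `TRUE` = keep, `FALSE` = drop.
#' @export
screen_linker <- function(contigs, linkers = illumina_linkers(), min_score = 22) {
  if (length(linkers) == 0L) stop("linkers must be non-empty")
  seqs <- if (inherits(contigs, "seq_set")) contigs$seq else as.character(contigs)
  keep <- rep(TRUE, length(seqs))
  if (!length(seqs)) return(keep)
  nonempty <- which(nchar(seqs) > 0L)
  if (!length(nonempty)) return(keep)
  pat <- Biostrings::DNAStringSet(seqs[nonempty])
  mat <- .subst_matrix(1, -3)
  for (lnk in unique(c(linkers, revcomp(linkers)))) {
    alive <- which(keep[nonempty])
    if (!length(alive)) break
    sc <- Biostrings::pairwiseAlignment(pat[alive], lnk, type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = 5, gapExtension = 2,
                                        scoreOnly = TRUE)
    keep[nonempty[alive][sc >= min_score]] <- FALSE
  }
  keep
}
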