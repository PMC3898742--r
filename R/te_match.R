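# Retrotransposon terminus identification on assembled contigs: which
# consensus-library entry matches one contig end, in which orientation, and
# contig layout normalization (non-TE section first, TE section last).

TE_MATCH_FIELDS <- c("contig_id", "family", "end_tag", "orientation",
                     "identity", "aligned_len", "score",
                     "te_start", "te_end", "nonte_start", "nonte_end",
                     "cons_start", "cons_end", "terminus", "ambiguous")

# k-mer index over library entries (both strands) used to shortlist the
# entries a contig could match before running the full local alignment.
.lib_kmer_index <- function(library, k = 12L) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  add <- function(seq, key) {
    n <- nchar(seq)
    if (n < k) return(invisible())
    starts <- seq_len(n - k + 1L)
    kmers <- unique(substring(seq, starts, starts + k - 1L))
    for (km in kmers) {
      cur <- if (exists(km, envir = env, inherits = FALSE)) get(km, envir = env) else character(0)
      assign(km, unique(c(cur, key)), envir = env)
    }
  }
  for (i in seq_len(nrow(library))) {
    add(library$seq[i], paste0(i, "+"))
    add(revcomp(library$seq[i]), paste0(i, "-"))
  }
  attr(env, "k") <- k
  env
}

.candidate_keys <- function(seq, index, stride = 4L) {
  k <- attr(index, "k")
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- unique(c(seq.int(1L, n - k + 1L, by = stride), n - k + 1L))
  kmers <- unique(substring(seq, starts, starts + k - 1L))
  hits <- character(0)
  for (km in kmers) {
    if (exists(km, envir = index, inherits = FALSE)) {
      hits <- c(hits, get(km, envir = index))
    }
  }
  unique(hits)
}

# Qualify + score alignments of a batch of contigs against one library entry
# on one strand. Returns a data.frame of qualifying matches.
.align_entry <- function(seqs, ids, entry_row, library, strand,
                         min_identity, min_len, terminus_tol,
                         require_nonte = TRUE) {
  subject <- library$seq[entry_row]
  if (strand == "-") subject <- revcomp(subject)
  entry_len <- library$entry_len[entry_row]
  mat <- .subst_matrix(2, -3)
  al <- Biostrings::pairwiseAlignment(Biostrings::DNAStringSet(seqs), subject,
                                      type = "local", substitutionMatrix = mat,
                                      gapOpening = 5, gapExtension = 2)
  cols <- Biostrings::nchar(al)
  idy <- Biostrings::nmatch(al) / cols
  ps <- IRanges::start(Biostrings::pattern(al))
  pe <- IRanges::end(Biostrings::pattern(al))
  ss <- IRanges::start(Biostrings::subject(al))
  se <- IRanges::end(Biostrings::subject(al))
  n <- nchar(seqs)
  left_ab <- (ps - 1L) <= terminus_tol
  right_ab <- (n - pe) <= terminus_tol
  # when both ends abut (TE spans whole contig) classify by larger flank later
  terminus <- ifelse(right_ab, "right", ifelse(left_ab, "left", NA_character_))
  nonte_len <- ifelse(terminus == "right", ps - 1L, n - pe)
  ok <- !is.na(terminus) & cols >= min_len & idy >= min_identity
  if (require_nonte) ok <- ok & nonte_len >= min_len
  if (!any(ok)) return(NULL)
  w <- which(ok)
  # subject range back to entry coordinates (0-based half-open)
  es <- ifelse(rep(strand == "+", length(w)), ss[w] - 1L, entry_len - se[w])
  ee <- ifelse(rep(strand == "+", length(w)), se[w], entry_len - ss[w] + 1L)
  data.frame(contig_idx = w, contig_id = ids[w],
             family = library$family[entry_row],
             end_tag = library$end_tag[entry_row],
             orientation = strand,
             identity = idy[w], aligned_len = cols[w],
             score = Biostrings::score(al)[w],
             te_start = ps[w] - 1L, te_end = pe[w],
             nonte_start = ifelse(terminus[w] == "right", 0L, pe[w]),
             nonte_end = ifelse(terminus[w] == "right", ps[w] - 1L, n[w]),
             cons_start = es + library$cons_offset[entry_row],
             cons_end = ee + library$cons_offset[entry_row],
             terminus = terminus[w], ambiguous = FALSE,
             stringsAsFactors = FALSE)
}

# Pick the best qualifying match per contig: highest score, then highest
# identity, then lexicographically first family (flagged ambiguous).
.best_per_contig <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  hits <- hits[order(hits$contig_idx, -hits$score, -hits$identity, hits$family), , drop = FALSE]
  first <- !duplicated(hits$contig_idx)
  best <- hits[first, , drop = FALSE]
  # flag score+identity ties across distinct families
  key <- paste(hits$contig_idx, hits$score, round(hits$identity, 10))
  bkey <- paste(best$contig_idx, best$score, round(best$identity, 10))
  tied <- tapply(hits$family, key, function(f) length(unique(f)) > 1L)
  best$ambiguous <- unname(tied[bkey])
  row.names(best) <- NULL
  best
}

#' Match a retrotransposon terminus on one contig
#'
#' Finds the best-scoring local alignment between the contig and any library
#' entry (both strands). A match qualifies when identity >= `min_identity`
#' over >= `min_len` alignment columns (gaps count as columns), the TE
#' alignment abuts one contig terminus (within `terminus_tol` nt), and a
#' non-TE section of >= `min_len` nt remains on the other side. Contigs
#' matching entries at both termini (fully TE-internal fragments) are set
#' aside and return `NULL`.
#'
#' @param contig a single-record [seq_set], or a character string.
#' @param library a `consensus_library` from [load_consensus_library()].
#' @param min_identity identity floor (matches / alignment columns),
#'   default 0.95.
#' @param min_len minimum alignment length and minimum non-TE section length
#'   (nt), default 33.
#' @param terminus_tol tolerance (nt) for "abuts a contig terminus",
#'   default 2.
#' @return a one-row data.frame describing the match (contig spans 0-based
#'   half-open; `cons_start`/`cons_end` on the family's full consensus), or
#'   `NULL` if no entry qualifies.
#' @export
match_te_end <- function(contig, library, min_identity = 0.95, min_len = 33L,
                         terminus_tol = 2L) {
  seq <- if (is.list(contig) && !is.null(contig$seq)) contig$seq[1L] else as.character(contig)
  id <- if (is.list(contig) && !is.null(contig$id)) contig$id[1L] else "contig"
  if (nchar(seq) < 2L * min_len) return(NULL)
  hits <- NULL
  for (i in seq_len(nrow(library))) {
    for (strand in c("+", "-")) {
      h <- .align_entry(seq, id, i, library, strand, min_identity, min_len,
                        terminus_tol)
      if (!is.null(h)) hits <- rbind(hits, h)
    }
  }
  best <- .best_per_contig(hits)
  if (is.null(best)) return(NULL)
  if (.matches_other_terminus(seq, best, library, min_identity, min_len,
                              terminus_tol)) {
    return(NULL)
  }
  best$contig_idx <- NULL
  best
}

# TRUE when the non-TE remainder itself carries a qualifying TE match
# abutting the opposite (outer) contig terminus. An optional k-mer index
# shortlists the entry/strand pairs worth aligning.
.matches_other_terminus <- function(seq, match, library, min_identity,
                                    min_len, terminus_tol, index = NULL) {
  sec <- substr(seq, match$nonte_start + 1L, match$nonte_end)
  if (nchar(sec) < min_len) return(FALSE)
  outer <- if (match$terminus == "right") "left" else "right"
  pairs <- if (is.null(index)) {
    as.vector(outer(seq_len(nrow(library)), c("+", "-"), paste0))
  } else {
    .candidate_keys(sec, index)
  }
  for (key in pairs) {
    i <- as.integer(sub("[+-]$", "", key))
    strand <- substr(key, nchar(key), nchar(key))
    h <- .align_entry(sec, "sec", i, library, strand, min_identity, min_len,
                      terminus_tol, require_nonte = FALSE)
    if (!is.null(h) && any(h$terminus == outer)) return(TRUE)
  }
  FALSE
}

#' Normalize contig layout so the non-TE section precedes the TE section
#'
#' Reverse-complements the contig when the TE match abuts its 5' terminus,
#' updating all spans and the orientation flag consistently. Applying the
#' operation to an already-normalized contig is the identity.
#'
#' @param contig list or single-record [seq_set] with `seq` (and optionally
#'   `qual`).
#' @param match a TE match row from [match_te_end()].
#' @return list with elements `contig` (same shape, possibly
#'   reverse-complemented) and `match` (spans updated).
#' @export
orient_contig <- function(contig, match) {
  seq <- if (inherits(contig, "seq_set")) contig$seq[1L] else contig$seq
  qual <- if (inherits(contig, "seq_set")) contig$qual[[1L]] else contig$qual
  id <- if (!is.null(contig$id)) contig$id[1L] else "contig"
  if (match$terminus == "right") {
    return(list(contig = list(id = id, seq = seq, qual = qual), match = match))
  }
  n <- nchar(seq)
  flip <- function(s, e) c(n - e, n - s)
  te <- flip(match$te_start, match$te_end)
  nonte <- flip(match$nonte_start, match$nonte_end)
  match$te_start <- te[1L]; match$te_end <- te[2L]
  match$nonte_start <- nonte[1L]; match$nonte_end <- nonte[2L]
  match$orientation <- if (match$orientation == "+") "-" else "+"
  match$terminus <- "right"
  list(contig = list(id = id, seq = revcomp(seq),
                     qual = if (is.null(qual)) NULL else rev(qual)),
       match = match)
}

#' Annotate retrotransposon termini across a batch of contigs
#'
#' Shortlists candidate library entries per contig by exact k-mer sharing,
#' aligns each shortlist group in a single vectorized call, applies the
#' qualification rules of [match_te_end()], sets aside fully TE-internal
#' contigs, and normalizes retained contigs with [orient_contig()].
#'
#' @param contigs a [seq_set].
#' @param library a `consensus_library`.
#' @inheritParams match_te_end
#' @return list with `matches` (data.frame, one row per retained contig,
#'   spans referring to the *normalized* contig), `contigs` (normalized
#'   [seq_set], parallel to `matches`), and `status` (per input contig:
#'   retained / no_match / both_termini / short).
#' @export
annotate_te_contigs <- function(contigs, library, min_identity = 0.95,
                                min_len = 33L, terminus_tol = 2L) {
  n <- length(contigs)
  status <- rep("no_match", n)
  status[nchar(contigs$seq) < 2L * min_len] <- "short"
  eligible <- which(status != "short")
  index <- .lib_kmer_index(library)
  cand <- lapply(contigs$seq, function(s) character(0))
  cand[eligible] <- lapply(contigs$seq[eligible], .candidate_keys, index = index)
  # group contigs by candidate (entry, strand) key and align in batches
  keys <- unique(unlist(cand, use.names = FALSE))
  hits <- vector("list", length(keys))
  for (j in seq_along(keys)) {
    key <- keys[j]
    entry_row <- as.integer(sub("[+-]$", "", key))
    strand <- substr(key, nchar(key), nchar(key))
    members <- which(vapply(cand, function(k) key %in% k, logical(1)))
    h <- .align_entry(contigs$seq[members], contigs$id[members], entry_row,
                      library, strand, min_identity, min_len, terminus_tol)
    if (!is.null(h)) {
      h$contig_idx <- members[h$contig_idx]
      hits[[j]] <- h
    }
  }
  best <- .best_per_contig(do.call(rbind, hits))
  if (is.null(best)) {
    return(list(matches = NULL, contigs = seq_set(character(0), character(0)),
                status = status))
  }
  drop_both <- logical(nrow(best))
  for (r in seq_len(nrow(best))) {
    drop_both[r] <- .matches_other_terminus(contigs$seq[best$contig_idx[r]],
                                            best[r, ], library, min_identity,
                                            min_len, terminus_tol,
                                            index = index)
  }
  status[best$contig_idx[drop_both]] <- "both_termini"
  best <- best[!drop_both, , drop = FALSE]
  status[best$contig_idx] <- "retained"

  out_id <- character(nrow(best)); out_seq <- character(nrow(best))
  out_qual <- vector("list", nrow(best))
  has_qual <- !is.null(contigs$qual)
  for (r in seq_len(nrow(best))) {
    i <- best$contig_idx[r]
    o <- orient_contig(list(id = contigs$id[i], seq = contigs$seq[i],
                            qual = if (has_qual) contigs$qual[[i]] else NULL),
                       best[r, ])
    best[r, names(o$match)] <- o$match
    out_id[r] <- o$contig$id; out_seq[r] <- o$contig$seq
    out_qual[[r]] <- o$contig$qual
  }
  best$contig_idx <- NULL
  row.names(best) <- NULL
  list(matches = best,
       contigs = seq_set(out_id, out_seq, if (has_qual) out_qual else NULL),
       status = status)
}
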