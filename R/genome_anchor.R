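# Reference-genome anchoring of the non-TE section of each normalized
# contig: exact k-mer seeding plus vectorized ungapped extension, uniqueness
# testing, molecular-chimera and reference-event screens, and derivation of
# single-nucleotide junction breakpoints.
#
# The genome is a named character vector (or DNAStringSet) of chromosome
# sequences; all coordinates are 0-based half-open on the top strand.

.as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) genome <- as.character(genome)
  if (is.null(names(genome)) || any(names(genome) == "")) {
    stop("genome must be a named vector of chromosome sequences")
  }
  genome
}

ANCHOR_SEED_K <- 15L

# Seed offsets (1-based) used for one sequence: junction-proximal end,
# middle, far end. Several seeds tolerate a sequencing error inside one.
.seed_offsets <- function(n, k = ANCHOR_SEED_K) {
  if (n < k) return(integer(0))
  unique(c(n - k + 1L, max(1L, (n - k) %/% 2L + 1L), 1L))
}

# Batch candidate discovery + ungapped scoring for `sections` against the
# genome. junction = "right" requires the anchoring alignment to include the
# right (junction-proximal) terminus of the section; "none" drops that
# requirement (used by the reference-event screen).
# Returns a list (one element per section) of candidate data.frames with
# columns chrom, strand, g_start, g_end, aligned_len, matches, score.
.anchor_candidates <- function(sections, genome, junction = "right",
                               match = 2L, mismatch = -3L) {
  genome <- .as_genome(genome)
  k <- ANCHOR_SEED_K
  ns <- length(sections)
  out <- rep(list(NULL), ns)
  lens <- nchar(sections)
  rc_sections <- if (ns) as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(sections))) else character(0)
  # collect seeds (both strands) without quadratic appends
  offs_list <- lapply(lens, .seed_offsets, k = k)
  n_offs <- lengths(offs_list)
  seed_sec <- rep.int(seq_len(ns), n_offs)
  seed_off <- unlist(offs_list, use.names = FALSE)
  if (!length(seed_off)) return(out)
  fwd <- substring(sections[seed_sec], seed_off, seed_off + k - 1L)
  rev <- substring(rc_sections[seed_sec], seed_off, seed_off + k - 1L)
  seed_seq <- c(fwd, rev)
  seed_sec <- c(seed_sec, seed_sec)
  seed_off <- c(seed_off, seed_off)
  seed_strand <- rep(c("+", "-"), each = length(fwd))
  keep <- !grepl("N", seed_seq, fixed = TRUE)
  seed_seq <- seed_seq[keep]; seed_sec <- seed_sec[keep]
  seed_off <- seed_off[keep]; seed_strand <- seed_strand[keep]
  if (!length(seed_seq)) return(out)

  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seed_seq))
  c_sec <- integer(0); c_strand <- character(0)
  c_start <- integer(0); c_chrom <- character(0)
  for (chrom in names(genome)) {
    m <- Biostrings::matchPDict(pd, Biostrings::DNAString(genome[[chrom]]))
    starts <- IRanges::start(m)  # IntegerList, one element per seed
    hit_n <- lengths(starts)
    if (!sum(hit_n)) next
    idx <- rep.int(seq_along(seed_seq), hit_n)
    hs <- unlist(starts, use.names = FALSE)
    # implied 1-based genomic start of the full (rc-)section placement
    place <- hs - (seed_off[idx] - 1L)
    dup <- duplicated(paste0(seed_sec[idx], seed_strand[idx], "@", place))
    c_sec <- c(c_sec, seed_sec[idx][!dup])
    c_strand <- c(c_strand, seed_strand[idx][!dup])
    c_start <- c(c_start, place[!dup])
    c_chrom <- c(c_chrom, rep(chrom, sum(!dup)))
  }
  if (!length(c_sec)) return(out)
  ord <- order(c_sec)
  c_sec <- c_sec[ord]; c_strand <- c_strand[ord]
  c_start <- c_start[ord]; c_chrom <- c_chrom[ord]
  grp_end <- cumsum(rle(c_sec)$lengths)
  grp_start <- c(1L, grp_end[-length(grp_end)] + 1L)
  grp_sec <- c_sec[grp_start]

  for (g in seq_along(grp_sec)) {
    i <- grp_sec[g]
    rows <- grp_start[g]:grp_end[g]
    n <- lens[i]
    nr <- length(rows)
    r_chrom <- character(nr); r_strand <- character(nr)
    r_gs <- integer(nr); r_ge <- integer(nr); r_alen <- integer(nr)
    r_mt <- integer(nr); r_trim <- integer(nr)
    kept <- 0L
    for (r in rows) {
      chrom <- c_chrom[r]; strand <- c_strand[r]; s1 <- c_start[r]
      clen <- nchar(genome[[chrom]])
      a <- max(1L, s1); b <- min(clen, s1 + n - 1L)
      if (b < a) next
      # the placed sequence is the section (+) or its reverse complement (-);
      # junction-proximal terminus of the section is its RIGHT end; under a
      # "-" placement that end maps to the LEFT end of the genomic window
      if (junction == "right") {
        if (strand == "+" && b < s1 + n - 1L) next
        if (strand == "-" && a > s1) next
      }
      placed <- if (strand == "+") sections[i] else rc_sections[i]
      eq <- utf8ToInt(substr(placed, a - s1 + 1L, b - s1 + 1L)) ==
        utf8ToInt(substr(genome[[chrom]], a, b))
      trim <- 0L
      if (junction == "right" && length(eq) && !all(eq)) {
        # trim the junction-proximal mismatch run: those bases are not
        # reference sequence (they belong to the junction-ward side)
        if (strand == "+") {
          while (trim < length(eq) && !eq[length(eq) - trim]) trim <- trim + 1L
          if (trim > 0L) { b <- b - trim; eq <- eq[seq_len(length(eq) - trim)] }
        } else {
          while (trim < length(eq) && !eq[trim + 1L]) trim <- trim + 1L
          if (trim > 0L) { a <- a + trim; eq <- eq[-seq_len(trim)] }
        }
        if (!length(eq)) next
      }
      kept <- kept + 1L
      r_chrom[kept] <- chrom; r_strand[kept] <- strand
      r_gs[kept] <- a - 1L; r_ge[kept] <- b
      r_alen[kept] <- length(eq); r_mt[kept] <- sum(eq)
      r_trim[kept] <- trim
    }
    if (!kept) next
    sel <- seq_len(kept)
    res <- data.frame(chrom = r_chrom[sel], strand = r_strand[sel],
                      g_start = r_gs[sel], g_end = r_ge[sel],
                      aligned_len = r_alen[sel], matches = r_mt[sel],
                      score = match * r_mt[sel] + mismatch * (r_alen[sel] - r_mt[sel]),
                      junction_trim = r_trim[sel],
                      stringsAsFactors = FALSE)
    out[[i]] <- res[order(-res$score), , drop = FALSE]
  }
  out
}

#' Anchor a non-TE section to the reference genome
#'
#' Exact 15-mer seeds taken from the junction-proximal (right) end, middle,
#' and far end of the section locate candidate loci on both strands; each
#' candidate is scored by ungapped extension (match +2, mismatch -3). The
#' anchoring is `unique` iff the best candidate exceeds the second best by at
#' least `uniqueness_margin` score points and the alignment includes the
#' junction-proximal terminus of the section.
#'
#' @param section DNA string (the non-TE section of a normalized contig; its
#'   right end is junction-proximal).
#' @param genome named character vector (or DNAStringSet) of chromosomes.
#' @param min_len minimum section/alignment length (default 33).
#' @param uniqueness_margin score margin over the second-best locus
#'   (default 5).
#' @return list with `status` (`unique`, `ambiguous`, or `unaligned`) and,
#'   when unique, `chrom`, `start`, `end` (0-based half-open, aligned part),
#'   `strand` (+ = section matches top strand), `score`.
#' @export
anchor_nonte <- function(section, genome, min_len = 33L, uniqueness_margin = 5) {
  if (nchar(section) < min_len) {
    stop(sprintf("section shorter than min_len (%d < %d)", nchar(section), min_len))
  }
  cands <- .anchor_candidates(section, genome)[[1L]]
  if (is.null(cands)) cands <- data.frame()
  if (nrow(cands)) {
    cands <- cands[cands$aligned_len >= min_len &
                     cands$matches / cands$aligned_len >= 0.9, , drop = FALSE]
  }
  if (!nrow(cands)) return(list(status = "unaligned"))
  if (nrow(cands) >= 2L && cands$score[1L] - cands$score[2L] < uniqueness_margin) {
    return(list(status = "ambiguous", n_candidates = nrow(cands)))
  }
  list(status = "unique", chrom = cands$chrom[1L], start = cands$g_start[1L],
       end = cands$g_end[1L], strand = cands$strand[1L], score = cands$score[1L])
}

#' Route contigs that align end-to-end to the reference
#'
#' Contigs matching the reference over >= `min_cover` of their length at
#' >= `min_identity` identity detect reference-genome (fixed) insertions and
#' are routed out of novel-insertion calling.
#'
#' @param contig DNA string.
#' @param genome named character vector of chromosomes.
#' @param min_identity identity floor over the aligned part (default 0.95).
#' @param min_cover minimum aligned fraction of the contig (default 0.95).
#' @return `"reference_stream"` or `"novel_stream"`.
#' @export
reference_event_screen <- function(contig, genome, min_identity = 0.95,
                                   min_cover = 0.95) {
  cands <- .anchor_candidates(contig, genome, junction = "none")[[1L]]
  if (is.null(cands)) return("novel_stream")
  n <- nchar(contig)
  full <- cands$aligned_len >= min_cover * n &
    cands$matches / cands$aligned_len >= min_identity
  if (any(full)) "reference_stream" else "novel_stream"
}

#' Molecular-chimera screen (10 nt reference-extension rule)
#'
#' Drops a contig when the reference continues contiguously from the
#' anchored non-TE section through the first `probe_len` bases of the
#' TE-side sequence (at most `max_mismatch` mismatches): the "TE" sequence
#' continues the local reference, indicating a reference-resident element or
#' a ligation chimera rather than a novel junction.
#'
#' @param contig normalized contig DNA string (non-TE section first).
#' @param te_side_start 0-based position of the first TE-side base (the base
#'   after the anchored genomic section, including any poly-A tail).
#' @param anchor unique anchoring of the non-TE section (from
#'   [anchor_nonte()]).
#' @param genome named character vector of chromosomes.
#' @param probe_len bases of TE-side sequence tested (default 10).
#' @param max_mismatch mismatches tolerated in the extension (default 1).
#' @return `"drop"` or `"pass"`.
#' @export
chimera_screen <- function(contig, te_side_start, anchor, genome,
                           probe_len = 10L, max_mismatch = 1L) {
  genome <- .as_genome(genome)
  probe <- substr(contig, te_side_start + 1L, te_side_start + probe_len)
  if (nchar(probe) < probe_len) return("pass")
  chrom <- genome[[anchor$chrom]]
  if (anchor$strand == "+") {
    a <- anchor$end + 1L
    cont <- substr(chrom, a, a + probe_len - 1L)
  } else {
    b <- anchor$start
    cont <- if (b - probe_len >= 0L) revcomp(substr(chrom, b - probe_len + 1L, b)) else ""
  }
  if (nchar(cont) < probe_len) return("pass")
  if (probe_len - .n_agree(probe, cont) <= max_mismatch) "drop" else "pass"
}

#' Junction breakpoint and strand from a section anchoring
#'
#' The breakpoint is the reference coordinate of the base immediately
#' flanking the TE sequence; the genome strand is + when the TE sense strand
#' equals the reference top strand. The amplicon start is the fragmentation
#' (outer) coordinate of the non-TE alignment, the natural PCR-duplicate key
#' for capture libraries.
#'
#' @param anchor unique anchoring of the non-TE section ([anchor_nonte()]).
#' @param side `"five_prime"` or `"three_prime"`: which TE end the junction
#'   shows.
#' @return list with `chrom`, `breakpoint` (0-based), `genome_strand`,
#'   `amplicon_start`.
#' @export
breakpoint_of <- function(anchor, side) {
  stopifnot(anchor$status == "unique")
  if (anchor$strand == "+") {
    bp <- anchor$end - 1L
    amp <- anchor$start
  } else {
    bp <- anchor$start
    amp <- anchor$end - 1L
  }
  gs <- if (side == "five_prime") anchor$strand else if (anchor$strand == "+") "-" else "+"
  list(chrom = anchor$chrom, breakpoint = bp, genome_strand = gs,
       amplicon_start = amp)
}

# Tolerant homopolymer run: scan `chars` from position `from` in direction
# `dir`, permitting at most one non-matching base per 10 nt window; the run
# ends on a matching base. Returns c(count = matching bases in the run,
# extent = positions spanned by the run, interior tolerated bases included).
.tolerant_run <- function(chars, from, dir, base, window = 10L) {
  n <- length(chars)
  i <- from
  last_bad <- -Inf; pos <- 0L
  count <- 0L; best_count <- 0L; best_extent <- 0L
  while (i >= 1L && i <= n) {
    pos <- pos + 1L
    if (chars[i] == base) {
      count <- count + 1L
      best_count <- count
      best_extent <- pos
    } else {
      if (pos - last_bad <= window) break
      last_bad <- pos
    }
    i <- i + dir
  }
  c(count = best_count, extent = best_extent)
}

#' Build junction evidence for a batch of annotated contigs
#'
#' Applies, per normalized contig: reference-event routing, poly-A tail
#' delimitation on 3'-end junctions, non-TE section anchoring, the chimera
#' screen, and breakpoint derivation. The junction side is taken from the
#' TE orientation on the normalized contig (+ = 5'-end junction, - = 3'-end
#' junction); a "-" match against a 5'-end library entry without a poly-A
#' tail is recognized as a twin-priming 5' junction.
#'
#' @param annotated output of [annotate_te_contigs()].
#' @param genome named character vector of chromosomes.
#' @param sample_id sample identifier stored in the evidence.
#' @param min_len minimum anchorable section length (default 33).
#' @param uniqueness_margin see [anchor_nonte()] (default 5).
#' @param chimera_probe_len see [chimera_screen()] (default 10).
#' @param library the `consensus_library`; when supplied, failed anchorings
#'   of 5'-end junction contigs are re-examined for the two-block
#'   twin-priming structure.
#' @return list with `evidence` (data.frame, one row per retained contig)
#'   and `rejects` (data.frame contig_id/reason with reasons
#'   unaligned, ambiguous, chimera, reference_event, short_anchor).
#' @export
build_junction_evidence <- function(annotated, genome, sample_id = "sample",
                                    min_len = 33L, uniqueness_margin = 5,
                                    chimera_probe_len = 10L, library = NULL) {
  m <- annotated$matches
  ctg <- annotated$contigs
  empty_ev <- data.frame(contig_id = character(0), sample_id = character(0),
                         family = character(0), side = character(0),
                         chrom = character(0), breakpoint = integer(0),
                         genome_strand = character(0), amplicon_start = integer(0),
                         anchor_len = integer(0), unique = logical(0),
                         polya_len = integer(0), cons_start = integer(0),
                         cons_end = integer(0), end_tag = character(0),
                         twin_primed = logical(0), inversion_len = integer(0),
                         stringsAsFactors = FALSE)
  rejects <- data.frame(contig_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  if (is.null(m) || nrow(m) == 0L) return(list(evidence = empty_ev, rejects = rejects))

  n <- nrow(m)
  side <- character(n); tail_count <- integer(n); twin <- logical(n)
  tail_extent <- integer(n); inv_len <- integer(n)
  sec_end <- integer(n)
  for (i in seq_len(n)) {
    if (m$orientation[i] == "+") {
      side[i] <- "five_prime"
    } else {
      chars <- .chars(ctg$seq[i])
      tl <- .tolerant_run(chars, m$te_start[i], -1L, "T")
      if (tl[["count"]] < 5L && m$end_tag[i] == "five_prime") {
        # twin-priming 5' junction showing only the inverted block: the
        # observed block length is a lower bound on the inversion
        side[i] <- "five_prime"; twin[i] <- TRUE
        inv_len[i] <- m$te_end[i] - m$te_start[i]
      } else {
        side[i] <- "three_prime"
        tail_count[i] <- tl[["count"]]
        tail_extent[i] <- tl[["extent"]]
      }
    }
    sec_end[i] <- m$te_start[i] - tail_extent[i]
  }
  sections <- substr(ctg$seq, 1L, sec_end)

  short <- nchar(sections) < min_len
  status <- rep("", n)
  status[short] <- "short_anchor"
  todo <- which(!short)

  # reference-event screen on the full contig, then section anchoring
  full_cands <- .anchor_candidates(ctg$seq[todo], genome, junction = "none")
  is_ref <- logical(length(todo))
  for (j in seq_along(todo)) {
    cc <- full_cands[[j]]
    if (is.null(cc)) next
    len <- nchar(ctg$seq[todo[j]])
    is_ref[j] <- any(cc$aligned_len >= 0.95 * len &
                       cc$matches / cc$aligned_len >= 0.95)
  }
  status[todo[is_ref]] <- "reference_event"
  todo <- todo[!is_ref]

  anchors <- vector("list", n)
  pick_anchor <- function(cc, i) {
    # anchors must be credible reference matches (>= 90 percent identity
    # over the trimmed window)
    if (!is.null(cc)) {
      cc <- cc[cc$aligned_len >= min_len &
                 cc$matches / cc$aligned_len >= 0.9, , drop = FALSE]
    }
    if (is.null(cc) || nrow(cc) == 0L) return("unaligned")
    if (nrow(cc) >= 2L && cc$score[1L] - cc$score[2L] < uniqueness_margin) {
      return("ambiguous")
    }
    anchors[[i]] <<- list(status = "unique", chrom = cc$chrom[1L],
                          start = cc$g_start[1L], end = cc$g_end[1L],
                          strand = cc$strand[1L], score = cc$score[1L])
    # bases trimmed at the junction-proximal anchor end were not genomic:
    # move the effective section boundary back over them
    sec_end[i] <<- sec_end[i] - cc$junction_trim[1L]
    ""
  }
  sec_cands <- .anchor_candidates(sections[todo], genome)
  for (j in seq_along(todo)) {
    status[todo[j]] <- pick_anchor(sec_cands[[j]], todo[j])
  }

  # twin-priming fallback: a 5'-end junction contig showing the inverted
  # block AND the sense continuation has its section contaminated with the
  # (non-genomic) inverted block, so plain anchoring fails. Resolve the
  # two-block structure against the 5' consensus entry, shorten the section
  # to the true genomic part, and re-anchor.
  lib <- library
  for (i in which(status %in% c("unaligned", "ambiguous") &
                    side == "five_prime" & m$orientation == "+")) {
    if (is.null(lib)) break
    ent <- lib[lib$family == m$family[i] & lib$end_tag == "five_prime", , drop = FALSE]
    if (!nrow(ent)) next
    tb <- .twin_blocks(substr(ctg$seq[i], 1L, m$te_end[i]), ent$seq[1L],
                       ent$cons_offset[1L])
    if (!tb$found) next
    new_end <- tb$inv_start
    if (new_end < min_len) next
    cc <- .anchor_candidates(substr(ctg$seq[i], 1L, new_end), genome)[[1L]]
    sec_end[i] <- new_end
    st <- pick_anchor(cc, i)
    if (st == "") {
      twin[i] <- TRUE
      inv_len[i] <- tb$inv_len
      m$cons_start[i] <- tb$inv_cons_start
      status[i] <- ""
    } else {
      status[i] <- st
    }
  }
  for (i in which(status == "" )) {
    # probe starts at the first base after the anchored section (poly-A tail
    # included on the TE side)
    verdict <- chimera_screen(ctg$seq[i], sec_end[i], anchors[[i]], genome,
                              probe_len = chimera_probe_len)
    if (verdict == "drop") status[i] <- "chimera"
  }

  # junction-ward anchor extension: the genome claims every boundary base it
  # can explain (maximal genomic extension), which fixes the inherent
  # ambiguity of poly-A tails abutting A-rich target sites and of element
  # bases that coincide with the reference continuation. Bounded by the
  # trimmed tail on 3'-end junctions and by 25 nt into the TE span on
  # 5'-end junctions.
  genome_chr <- .as_genome(genome)
  for (i in which(status == "")) {
    a <- anchors[[i]]
    bound <- if (side[i] == "three_prime") tail_extent[i] else 25L
    if (bound <= 0L) next
    chrom <- genome_chr[[a$chrom]]
    clen <- nchar(chrom)
    e <- 0L
    while (e < bound) {
      cc <- substr(ctg$seq[i], sec_end[i] + e + 1L, sec_end[i] + e + 1L)
      if (cc == "") break
      if (a$strand == "+") {
        gpos <- a$end + e + 1L            # 1-based next reference base
        if (gpos > clen) break
        gc <- substr(chrom, gpos, gpos)
        if (cc != gc) break
      } else {
        gpos <- a$start - e               # 1-based previous reference base
        if (gpos < 1L) break
        gc <- substr(chrom, gpos, gpos)
        if (cc != .complement1(gc)) break
      }
      e <- e + 1L
    }
    if (e > 0L) {
      if (a$strand == "+") a$end <- a$end + e else a$start <- a$start - e
      anchors[[i]] <- a
      sec_end[i] <- sec_end[i] + e
      if (side[i] == "three_prime") {
        tail_count[i] <- max(0L, tail_count[i] - e)
        tail_extent[i] <- max(0L, tail_extent[i] - e)
      }
    }
  }


  keep <- which(status == "")
  ev <- NULL
  if (length(keep)) {
    rows <- vector("list", length(keep))
    for (j in seq_along(keep)) {
      i <- keep[j]
      bp <- breakpoint_of(anchors[[i]], side[i])
      if (twin[i]) bp$genome_strand <- anchors[[i]]$strand
      rows[[j]] <- data.frame(contig_id = ctg$id[i], sample_id = sample_id,
                              family = m$family[i], side = side[i],
                              chrom = bp$chrom, breakpoint = bp$breakpoint,
                              genome_strand = bp$genome_strand,
                              amplicon_start = bp$amplicon_start,
                              anchor_len = anchors[[i]]$end - anchors[[i]]$start,
                              unique = TRUE, polya_len = tail_count[i],
                              cons_start = m$cons_start[i], cons_end = m$cons_end[i],
                              end_tag = m$end_tag[i], twin_primed = twin[i],
                              inversion_len = inv_len[i],
                              stringsAsFactors = FALSE)
    }
    ev <- do.call(rbind, rows)
  }
  rej <- which(status != "")
  if (length(rej)) {
    rejects <- data.frame(contig_id = ctg$id[rej], reason = status[rej],
                          stringsAsFactors = FALSE)
  }
  list(evidence = if (is.null(ev)) empty_ev else ev, rejects = rejects)
}
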