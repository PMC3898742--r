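# Collapse junction evidence into insertion calls: PCR-duplicate-aware
# amplicon counting, per-side breakpoint clustering, joining of opposing
# 5'/3' clusters, and the two-amplicon reporting rule.

#' Count unique amplicons among fragmentation start coordinates
#'
#' Supporting reads evidence independent DNA fragments only when their
#' genomic fragmentation starts differ sufficiently; this returns the size
#' of the largest subset of `starts` that is pairwise separated by at least
#' `min_sep` nt (greedy on the sorted list, which is optimal in 1-D).
#'
#' @param starts integer vector of genomic fragmentation coordinates.
#' @param min_sep minimum pairwise separation (default 5).
#' @return integer count of unique amplicons.
#' @export
count_unique_amplicons <- function(starts, min_sep = 5L) {
  if (length(starts) == 0L) stop("starts must be non-empty")
  s <- sort(starts)
  count <- 1L
  last <- s[1L]
  for (x in s[-1L]) {
    if (x - last >= min_sep) {
      count <- count + 1L
      last <- x
    }
  }
  count
}

#' Cluster junction evidence per side
#'
#' Single-linkage grouping of evidence sharing (sample, family, side,
#' strand, chrom) with breakpoints within `wobble` nt of a chain neighbour.
#' The cluster consensus breakpoint is the modal member breakpoint (ties to
#' the smallest coordinate), which restores single-nucleotide exactness
#' under read error.
#'
#' @param evidence junction-evidence data.frame
#'   (see [build_junction_evidence()]); only unique-anchored rows are used.
#' @param wobble intra-cluster breakpoint tolerance (nt, default 10).
#' @param min_sep amplicon separation passed to [count_unique_amplicons()].
#' @return data.frame of clusters: sample_id, family, side, genome_strand,
#'   chrom, consensus_breakpoint, n_reads, unique_amplicons, median poly-A,
#'   representative consensus span, plus a list-column `members` of row
#'   indices into `evidence`.
#' @export
build_clusters <- function(evidence, wobble = 10L, min_sep = 5L) {
  ev <- evidence[evidence$unique, , drop = FALSE]
  if (nrow(ev) == 0L) {
    return(data.frame(sample_id = character(0), family = character(0),
                      side = character(0), genome_strand = character(0),
                      chrom = character(0), consensus_breakpoint = integer(0),
                      n_reads = integer(0), unique_amplicons = integer(0),
                      polya_len = integer(0), cons_start = integer(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste(ev$sample_id, ev$family, ev$side, ev$genome_strand, ev$chrom,
               sep = "\r")
  rows <- split(seq_len(nrow(ev)), key)
  out <- list()
  for (grp in rows) {
    o <- grp[order(ev$breakpoint[grp])]
    bp <- ev$breakpoint[o]
    brk <- which(diff(bp) > wobble)
    starts <- c(1L, brk + 1L)
    ends <- c(brk, length(bp))
    for (ci in seq_along(starts)) {
      mem <- o[starts[ci]:ends[ci]]
      bps <- ev$breakpoint[mem]
      tb <- table(bps)
      modal <- as.integer(names(tb)[tb == max(tb)])
      consensus <- min(modal)
      out[[length(out) + 1L]] <- data.frame(
        sample_id = ev$sample_id[mem[1L]], family = ev$family[mem[1L]],
        side = ev$side[mem[1L]], genome_strand = ev$genome_strand[mem[1L]],
        chrom = ev$chrom[mem[1L]], consensus_breakpoint = consensus,
        n_reads = length(mem),
        unique_amplicons = count_unique_amplicons(ev$amplicon_start[mem], min_sep),
        polya_len = as.integer(stats::median(ev$polya_len[mem])),
        cons_start = as.integer(stats::median(ev$cons_start[mem])),
        stringsAsFactors = FALSE)
      out[[length(out)]]$members <- I(list(mem))
    }
  }
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  res
}

#' Join opposing 5'/3' clusters into insertion calls
#'
#' A 5'-end cluster and a 3'-end cluster with the same sample, family,
#' chromosome and implied TE orientation merge into one both-ends call when
#' their consensus breakpoints are within `max_sep` nt. Each cluster joins
#' at most one partner (nearest; ties to the smaller-coordinate partner);
#' unpaired clusters become single-end calls.
#'
#' @param clusters data.frame from [build_clusters()].
#' @param max_sep maximum 5'/3' breakpoint separation (nt, default 100).
#' @return insertion-call data.frame with columns sample, chrom, bp5, bp3,
#'   family, orientation, ends_detected, n_amplicons_5, n_amplicons_3,
#'   label (NA), plus polya_len and cons_start5 carried for hallmark
#'   characterization.
#' @export
join_opposing <- function(clusters, max_sep = 100L) {
  if (nrow(clusters) == 0L) {
    return(data.frame(sample = character(0), chrom = character(0),
                      bp5 = integer(0), bp3 = integer(0), family = character(0),
                      orientation = character(0), ends_detected = character(0),
                      n_amplicons_5 = integer(0), n_amplicons_3 = integer(0),
                      label = character(0), polya_len = integer(0),
                      cons_start5 = integer(0), stringsAsFactors = FALSE))
  }
  key <- paste(clusters$sample_id, clusters$family, clusters$chrom,
               clusters$genome_strand, sep = "\r")
  calls <- list()
  for (grp in split(seq_len(nrow(clusters)), key)) {
    five <- grp[clusters$side[grp] == "five_prime"]
    three <- grp[clusters$side[grp] == "three_prime"]
    pairs <- NULL
    if (length(five) && length(three)) {
      pairs <- expand.grid(f = five, t = three)
      pairs$dist <- abs(clusters$consensus_breakpoint[pairs$f] -
                          clusters$consensus_breakpoint[pairs$t])
      pairs <- pairs[pairs$dist <= max_sep, , drop = FALSE]
      pairs <- pairs[order(pairs$dist,
                           pmin(clusters$consensus_breakpoint[pairs$f],
                                clusters$consensus_breakpoint[pairs$t])), ,
                     drop = FALSE]
    }
    used_f <- integer(0); used_t <- integer(0)
    if (!is.null(pairs)) {
      for (r in seq_len(nrow(pairs))) {
        f <- pairs$f[r]; t <- pairs$t[r]
        if (f %in% used_f || t %in% used_t) next
        used_f <- c(used_f, f); used_t <- c(used_t, t)
        calls[[length(calls) + 1L]] <- data.frame(
          sample = clusters$sample_id[f], chrom = clusters$chrom[f],
          bp5 = clusters$consensus_breakpoint[f],
          bp3 = clusters$consensus_breakpoint[t],
          family = clusters$family[f],
          orientation = clusters$genome_strand[f],
          ends_detected = "both",
          n_amplicons_5 = clusters$unique_amplicons[f],
          n_amplicons_3 = clusters$unique_amplicons[t],
          label = NA_character_,
          polya_len = clusters$polya_len[t],
          cons_start5 = clusters$cons_start[f],
          stringsAsFactors = FALSE)
      }
    }
    for (f in setdiff(five, used_f)) {
      calls[[length(calls) + 1L]] <- data.frame(
        sample = clusters$sample_id[f], chrom = clusters$chrom[f],
        bp5 = clusters$consensus_breakpoint[f], bp3 = NA_integer_,
        family = clusters$family[f], orientation = clusters$genome_strand[f],
        ends_detected = "five_only",
        n_amplicons_5 = clusters$unique_amplicons[f], n_amplicons_3 = 0L,
        label = NA_character_, polya_len = NA_integer_,
        cons_start5 = clusters$cons_start[f], stringsAsFactors = FALSE)
    }
    for (t in setdiff(three, used_t)) {
      calls[[length(calls) + 1L]] <- data.frame(
        sample = clusters$sample_id[t], chrom = clusters$chrom[t],
        bp5 = NA_integer_, bp3 = clusters$consensus_breakpoint[t],
        family = clusters$family[t], orientation = clusters$genome_strand[t],
        ends_detected = "three_only",
        n_amplicons_5 = 0L, n_amplicons_3 = clusters$unique_amplicons[t],
        label = NA_character_, polya_len = clusters$polya_len[t],
        cons_start5 = NA_integer_, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, calls)
  row.names(res) <- NULL
  res
}

#' Apply the two-amplicon reporting threshold
#'
#' Only calls supported by at least `min_amplicons` unique amplicons on at
#' least one side are reported; the rule is applied per side, not pooled
#' across sides (5' and 3' clusters are separate detection events).
#'
#' @param calls insertion-call data.frame ([join_opposing()]).
#' @param min_amplicons reporting threshold (default 2).
#' @return the reported subset of `calls`.
#' @export
emit_calls <- function(calls, min_amplicons = 2L) {
  keep <- pmax(calls$n_amplicons_5, calls$n_amplicons_3) >= min_amplicons
  res <- calls[keep, , drop = FALSE]
  row.names(res) <- NULL
  res
}

#' Cluster evidence and emit insertion calls
#'
#' Convenience wrapper: [build_clusters()], [join_opposing()],
#' [emit_calls()].
#' @param evidence junction-evidence data.frame.
#' @param wobble,min_sep,max_sep,min_amplicons stage parameters.
#' @return reported insertion-call data.frame.
#' @export
call_insertions <- function(evidence, wobble = 10L, min_sep = 5L,
                            max_sep = 100L, min_amplicons = 2L) {
  cl <- build_clusters(evidence, wobble = wobble, min_sep = min_sep)
  emit_calls(join_opposing(cl, max_sep = max_sep), min_amplicons = min_amplicons)
}
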