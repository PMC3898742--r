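# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and Biostrings) wherever they stand as the
# reference for one.

# Full Smith-Waterman local alignment score by dynamic programming with
# affine gaps (a gap of length L costs gap_open + L * gap_ext), the same
# cost model as the pipeline's aligner configuration.
sw_local_score_oracle <- function(a, b, match = 2, mismatch = -3,
                                  gap_open = 5, gap_ext = 2) {
  av <- utf8ToInt(a); bv <- utf8ToInt(b)
  n <- length(av); m <- length(bv)
  open_cost <- gap_open + gap_ext
  M <- matrix(0, n + 1, m + 1)       # match/mismatch state
  X <- matrix(-Inf, n + 1, m + 1)    # gap in b (consume a)
  Y <- matrix(-Inf, n + 1, m + 1)    # gap in a (consume b)
  best <- 0
  for (i in 2:(n + 1)) {
    sub <- ifelse(av[i - 1] == bv, match, mismatch)
    for (j in 2:(m + 1)) {
      X[i, j] <- max(M[i - 1, j] - open_cost, X[i - 1, j] - gap_ext)
      Y[i, j] <- max(M[i, j - 1] - open_cost, Y[i, j - 1] - gap_ext)
      M[i, j] <- max(0, sub[j - 1] + max(M[i - 1, j - 1], X[i - 1, j - 1],
                                         Y[i - 1, j - 1]))
      best <- max(best, M[i, j], X[i, j], Y[i, j])
    }
  }
  best
}

# Exhaustive maximum subset of points pairwise separated by >= min_sep.
max_separated_subset_oracle <- function(starts, min_sep) {
  n <- length(starts)
  best <- 0L
  for (mask in 0:(2^n - 1)) {
    sel <- starts[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    if (length(sel) <= best) next
    if (length(sel) <= 1L || all(diff(sort(sel)) >= min_sep)) {
      best <- length(sel)
    }
  }
  best
}

# Naive O(n^2) double-loop paired-motif scan.
naive_paired_motif_oracle <- function(seq, cfg) {
  n <- nchar(seq)
  rc <- function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }
  p1 <- cfg$unit_pattern
  p2 <- if (cfg$arrangement == "palindromic") rc(cfg$unit_pattern) else p1
  mm <- function(x, p) sum(strsplit(x, "")[[1]] != strsplit(p, "")[[1]])
  hits <- list()
  for (s1 in 1:(n - 15)) {
    u1 <- substr(seq, s1, s1 + 7)
    if (nchar(u1) < 8 || mm(u1, p1) > cfg$max_unit_mismatch) next
    for (s2 in 1:(n - 7)) {
      gap <- s2 - s1 - 8
      if (gap < cfg$gap_range[1] || gap > cfg$gap_range[2]) next
      u2 <- substr(seq, s2, s2 + 7)
      if (nchar(u2) < 8 || mm(u2, p2) > cfg$max_unit_mismatch) next
      hits[[length(hits) + 1]] <- c(s1 - 1, s1 + 7, s2 - 1, s2 + 7, gap)
    }
  }
  if (!length(hits)) {
    return(data.frame(u1_start = integer(0), u1_end = integer(0),
                      u2_start = integer(0), u2_end = integer(0),
                      gap = integer(0)))
  }
  df <- as.data.frame(do.call(rbind, hits))
  names(df) <- c("u1_start", "u1_end", "u2_start", "u2_end", "gap")
  df[order(df$u1_start, df$u2_start), ]
}

# Exhaustive split-point search for a two-block (inverted + sense)
# decomposition of a TE section against a consensus: for each split, both
# parts must occur exactly in the consensus in the expected orientations.
exhaustive_inversion_oracle <- function(sec, consensus, min_block = 20) {
  rc <- function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }
  n <- nchar(sec)
  for (split in seq(n - min_block, min_block)) {
    left <- substr(sec, 1, split)
    right <- substr(sec, split + 1, n)
    if (grepl(rc(left), consensus, fixed = TRUE) &&
        grepl(right, consensus, fixed = TRUE)) {
      return(split)
    }
  }
  0L
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
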