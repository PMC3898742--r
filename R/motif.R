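# Paired near-match 8-mer motif scanning (the palindromic enhancer motif
# bisected by the tumor-specific L1 insertion) and the permutation estimate
# of the probability that a random insertion bisects such a motif.

#' Configuration for paired-motif scanning
#'
#' Two 8 nt units: unit 1 matches `unit_pattern` and unit 2 matches either
#' the pattern (direct arrangement) or its reverse complement (palindromic
#' arrangement), each with at most `max_unit_mismatch` mismatches, separated
#' by a gap inside `gap_range`.
#'
#' @param unit_pattern 8 nt DNA pattern.
#' @param max_unit_mismatch mismatches tolerated per unit (default 1).
#' @param gap_range integer gap interval, inclusive (default c(0, 11)).
#' @param arrangement `"palindromic"` (default) or `"direct"`.
#' @return list of class `paired_motif_config`.
#' @export
paired_motif_config <- function(unit_pattern = "AAGGTCAC",
                                max_unit_mismatch = 1L,
                                gap_range = c(0L, 11L),
                                arrangement = c("palindromic", "direct")) {
  arrangement <- match.arg(arrangement)
  unit_pattern <- toupper(unit_pattern)
  if (nchar(unit_pattern) != 8L) stop("unit_pattern must be 8 nt")
  .validate_dna(unit_pattern, "unit_pattern", allow_n = FALSE)
  if (gap_range[1L] < 0L || gap_range[2L] < gap_range[1L]) {
    stop("gap_range must satisfy 0 <= lower <= upper")
  }
  structure(list(unit_pattern = unit_pattern,
                 max_unit_mismatch = as.integer(max_unit_mismatch),
                 gap_range = as.integer(gap_range),
                 arrangement = arrangement),
            class = "paired_motif_config")
}

# Hamming mismatch counts of every length-8 window of `ints` (utf8 vector)
# against the utf8 pattern `pat`.
.window_mismatches <- function(ints, pat) {
  n <- length(ints)
  w <- length(pat)
  if (n < w) return(integer(0))
  mm <- integer(n - w + 1L)
  for (j in seq_len(w)) {
    mm <- mm + (ints[j:(n - w + j)] != pat[j])
  }
  mm
}

#' Find paired near-match motif occurrences
#'
#' Exhaustive scan: every pair of unit placements satisfying the mismatch
#' and gap constraints is reported; overlapping occurrences are allowed.
#'
#' @param seq DNA string of length >= 16.
#' @param cfg a [paired_motif_config()].
#' @return data.frame of occurrences: `u1_start`, `u1_end`, `u2_start`,
#'   `u2_end` (0-based half-open), `gap`, `mm1`, `mm2`.
#' @export
find_paired_motifs <- function(seq, cfg = paired_motif_config()) {
  if (nchar(seq) < 16L) stop("sequence shorter than two units")
  ints <- .ints(seq)
  pat1 <- .ints(cfg$unit_pattern)
  pat2 <- if (cfg$arrangement == "palindromic") .ints(revcomp(cfg$unit_pattern)) else pat1
  mm1 <- .window_mismatches(ints, pat1)
  mm2 <- .window_mismatches(ints, pat2)
  ok1 <- which(mm1 <= cfg$max_unit_mismatch)
  ok2 <- which(mm2 <= cfg$max_unit_mismatch)
  out <- list()
  for (s1 in ok1) {
    lo <- s1 + 8L + cfg$gap_range[1L]
    hi <- s1 + 8L + cfg$gap_range[2L]
    s2s <- ok2[ok2 >= lo & ok2 <= hi]
    for (s2 in s2s) {
      out[[length(out) + 1L]] <- c(s1 - 1L, s1 + 7L, s2 - 1L, s2 + 7L,
                                   s2 - s1 - 8L, mm1[s1], mm2[s2])
    }
  }
  res <- as.data.frame(do.call(rbind, out))
  if (!nrow(res)) {
    res <- data.frame(matrix(integer(0), 0, 7))
  }
  names(res) <- c("u1_start", "u1_end", "u2_start", "u2_end", "gap", "mm1", "mm2")
  res
}

#' Does an insertion position bisect a motif occurrence?
#'
#' True iff unit 1 lies strictly 5' of the insertion point and unit 2
#' strictly 3' of it: the insertion separates the two units. Insertions
#' inside a unit do not count.
#'
#' @param pos 0-based insertion point (between bases `pos - 1` and `pos`).
#' @param occ one occurrence row from [find_paired_motifs()].
#' @return logical.
#' @export
insertion_bisects <- function(pos, occ) {
  occ$u1_end <= pos && pos <= occ$u2_start
}

#' Closed-form bound for the bisection probability
#'
#' Under an iid uniform background, a unit near-matches the pattern with
#' probability `q = sum_(k<=m) C(8,k) 3^k / 4^8` (`25/65536` for m = 1).
#' For a fixed insertion point, an occurrence with gap `g` is bisected for
#' `g + 1` placements of the pair, so the expected number of bisecting
#' occurrences -- an upper bound on the bisection probability -- is
#' `q^2 * sum_(g in gap_range) (g + 1)`.
#'
#' @param cfg a [paired_motif_config()].
#' @return list with `q` (per-unit near-match probability) and `bound`.
#' @export
analytic_position_probability <- function(cfg = paired_motif_config()) {
  m <- cfg$max_unit_mismatch
  q <- sum(choose(8, 0:m) * 3^(0:m)) / 4^8
  gaps <- cfg$gap_range[1L]:cfg$gap_range[2L]
  list(q = q, bound = q^2 * sum(gaps + 1))
}

#' Permutation estimate of the motif bisection probability
#'
#' Fraction of (random iid-uniform sequence, random insertion position)
#' trials in which the position bisects a qualifying paired-motif
#' occurrence. Seeded and reproducible. Only the window of the sequence
#' that could contain a bisected occurrence (the 19 nt on either side of
#' the insertion point) influences the outcome, and the scan exploits that.
#'
#' @param cfg a [paired_motif_config()].
#' @param seq_len length of each random sequence (default 1000).
#' @param n_trials number of trials (default 1e5, minimum 1e4).
#' @param seed RNG seed (required).
#' @return list with `estimate`, `se` (binomial Monte-Carlo SE), `hits`,
#'   `n_trials`, `seed`.
#' @export
permutation_probability <- function(cfg = paired_motif_config(),
                                    seq_len = 1000L, n_trials = 1e5L,
                                    seed) {
  if (n_trials < 1e4) stop("n_trials must be >= 1e4")
  reach <- 8L + cfg$gap_range[2L]  # how far a bisected unit can start from pos
  with_seed(seed, {
    hits <- 0L
    chunk <- 2000L
    done <- 0L
    pat1 <- .ints(cfg$unit_pattern)
    pat2 <- if (cfg$arrangement == "palindromic") .ints(revcomp(cfg$unit_pattern)) else pat1
    base_ints <- utf8ToInt("ACGT")
    while (done < n_trials) {
      nb <- min(chunk, n_trials - done)
      pos <- sample.int(seq_len - 1L, nb, replace = TRUE)  # 1..len-1 interior
      # window of the sequence that can carry a bisected occurrence
      lo <- pmax(1L, pos - reach + 1L)
      hi <- pmin(seq_len, pos + reach)
      wlen <- hi - lo + 1L
      for (t in seq_len(nb)) {
        w <- base_ints[sample.int(4L, wlen[t], replace = TRUE)]
        cut <- pos[t] - lo[t] + 1L  # insertion after this many window bases
        mm1 <- .window_mismatches(w, pat1)
        mm2 <- .window_mismatches(w, pat2)
        ok1 <- which(mm1 <= cfg$max_unit_mismatch)
        ok1 <- ok1[ok1 + 7L <= cut]          # unit1 strictly 5' of cut
        hit <- FALSE
        for (s1 in ok1) {
          lo2 <- s1 + 8L + cfg$gap_range[1L]
          hi2 <- s1 + 8L + cfg$gap_range[2L]
          s2s <- which(mm2 <= cfg$max_unit_mismatch)
          s2s <- s2s[s2s >= max(lo2, cut + 1L) & s2s <= hi2]
          if (length(s2s)) { hit <- TRUE; break }
        }
        hits <- hits + hit
      }
      done <- done + nb
    }
    est <- hits / n_trials
    list(estimate = est, se = sqrt(max(est, 1 / n_trials) * (1 - est) / n_trials),
         hits = hits, n_trials = as.integer(n_trials), seed = as.integer(seed))
  })
}
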