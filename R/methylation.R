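# Bisulphite clone scoring of the L1 promoter CpG island: mock conversion of
# the reference, per-clone per-site methylation calls, percent methylation,
# and the 2x2 chi-square group comparison.

#' Mock bisulphite conversion of a reference sequence
#'
#' Every cytosine outside CpG context is converted to T; CpG-context
#' cytosines are marked ambiguous (IUPAC `Y`, matching C or T) because their
#' conversion depends on methylation state.
#'
#' @param reference DNA string.
#' @param cpg_positions 0-based positions of the CpG cytosines scored.
#' @return converted reference string with `Y` at CpG cytosines.
#' @export
mock_convert <- function(reference, cpg_positions) {
  chars <- .chars(reference)
  for (p in cpg_positions) {
    if (p + 2L > length(chars) || chars[p + 1L] != "C" || chars[p + 2L] != "G") {
      stop(sprintf("position %d is not a CpG cytosine in the reference", p))
    }
  }
  is_c <- chars == "C"
  chars[is_c] <- "T"
  chars[cpg_positions + 1L] <- "Y"
  paste(chars, collapse = "")
}

# Global alignment of a clone against the converted reference; returns the
# clone character aligned to each reference position ("-" for deletions)
# plus the identity of the alignment.
.align_clone <- function(clone, converted_ref) {
  bases <- c(DNA_BASES4, "N", "Y")
  mat <- matrix(-3, 6, 6, dimnames = list(bases, bases))
  diag(mat)[1:4] <- 1
  mat["C", "Y"] <- mat["Y", "C"] <- 1
  mat["T", "Y"] <- mat["Y", "T"] <- 1
  al <- Biostrings::pairwiseAlignment(clone, converted_ref, type = "global",
                                      substitutionMatrix = mat,
                                      gapOpening = 5, gapExtension = 2)
  p <- .chars(as.character(Biostrings::alignedPattern(al)))
  s <- .chars(as.character(Biostrings::alignedSubject(al)))
  ref_cols <- s != "-"
  per_ref <- p[ref_cols]                   # clone char at each ref position
  matches <- sum(p == s & p != "-") +
    sum(s == "Y" & p %in% c("C", "T"))
  list(per_ref = per_ref, identity = matches / length(p))
}

#' Score one bisulphite clone at the CpG sites
#'
#' The clone is globally aligned to the mock-converted reference; at each
#' CpG site the aligned dinucleotide is read as `CG` = methylated (`M`),
#' `TG` = unmethylated (`U`), anything else including a deletion = mutated
#' (`X`). Clones below the identity floor are rejected.
#'
#' @param clone DNA string of one capillary-sequenced clone.
#' @param converted_ref mock-converted reference ([mock_convert()]).
#' @param cpg_positions 0-based CpG cytosine positions on the reference.
#' @param min_identity acceptance floor for the clone/reference alignment
#'   (default 0.9).
#' @return character vector of site states (`M`/`U`/`X`), one per CpG site,
#'   with attribute `identity`; or `NULL` when the clone is rejected.
#' @export
score_clone <- function(clone, converted_ref, cpg_positions,
                        min_identity = 0.9) {
  al <- .align_clone(clone, converted_ref)
  if (al$identity < min_identity) return(NULL)
  states <- character(length(cpg_positions))
  for (k in seq_along(cpg_positions)) {
    p <- cpg_positions[k]
    c1 <- al$per_ref[p + 1L]
    c2 <- if (p + 2L <= length(al$per_ref)) al$per_ref[p + 2L] else "-"
    states[k] <- if (c1 == "C" && c2 == "G") "M"
    else if (c1 == "T" && c2 == "G") "U"
    else "X"
  }
  structure(states, identity = al$identity)
}

#' Score a set of clones into a methylation call matrix
#'
#' @param clones a [seq_set] of clone sequences (FASTA headers
#'   `sample|group` become `sample_id`/`group`).
#' @param reference unconverted reference DNA string.
#' @param cpg_positions 0-based CpG cytosine positions.
#' @param min_identity clone acceptance floor (default 0.9).
#' @return list with `matrix` (clones x sites, states M/U/X), `meta`
#'   (data.frame sample_id, group, identity), and `rejected` (ids).
#' @export
score_clones <- function(clones, reference, cpg_positions, min_identity = 0.9) {
  conv <- mock_convert(reference, cpg_positions)
  n <- length(clones)
  rows <- list(); meta <- list(); rejected <- character(0)
  for (i in seq_len(n)) {
    st <- score_clone(clones$seq[i], conv, cpg_positions, min_identity)
    if (is.null(st)) {
      rejected <- c(rejected, clones$id[i])
      next
    }
    parts <- strsplit(clones$id[i], "|", fixed = TRUE)[[1L]]
    rows[[length(rows) + 1L]] <- st
    meta[[length(meta) + 1L]] <- data.frame(
      clone_id = clones$id[i],
      sample_id = parts[1L],
      group = if (length(parts) >= 2L) parts[2L] else NA_character_,
      identity = attr(st, "identity"), stringsAsFactors = FALSE)
  }
  mat <- do.call(rbind, rows)
  if (is.null(mat)) mat <- matrix(character(0), 0, length(cpg_positions))
  colnames(mat) <- paste0("cpg", seq_along(cpg_positions))
  list(matrix = mat, meta = do.call(rbind, meta), rejected = rejected)
}

#' Percent methylation of a call matrix
#'
#' methylated / (methylated + unmethylated) x 100; mutated cells are
#' excluded from the denominator. A column with no countable cells is
#' reported as missing.
#'
#' @param matrix clone x site state matrix (`M`/`U`/`X`).
#' @param scope `"overall"` (single percentage) or `"per_site"`.
#' @return numeric percentage(s).
#' @export
percent_methylation <- function(matrix, scope = c("overall", "per_site")) {
  scope <- match.arg(scope)
  if (length(matrix) == 0L) stop("matrix must be non-empty")
  pct <- function(x) {
    m <- sum(x == "M"); u <- sum(x == "U")
    if (m + u == 0L) NA_real_ else 100 * m / (m + u)
  }
  if (scope == "overall") pct(matrix) else apply(matrix, 2, pct)
}

#' Chi-square comparison of pooled methylation between two groups
#'
#' 2x2 test on pooled (methylated, unmethylated) counts using the
#' closed-form statistic `(ad - bc)^2 N / (r1 r2 c1 c2)`, without continuity
#' correction by default.
#'
#' @param matrix_a,matrix_b state matrices of the two groups.
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return list with `statistic`, `p_value`, `df`, and the 2x2 `counts`.
#' @export
chi2_compare <- function(matrix_a, matrix_b, correct = FALSE) {
  counts <- vapply(list(matrix_a, matrix_b),
                   function(m) c(sum(m == "M"), sum(m == "U")), numeric(2))
  dimnames(counts) <- list(state = c("M", "U"), group = c("A", "B"))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("chi-square undefined: a marginal total is zero")
  }
  a <- counts[1, 1]; b <- counts[1, 2]; c <- counts[2, 1]; d <- counts[2, 2]
  N <- a + b + c + d
  dev <- abs(a * d - b * c)
  if (correct) dev <- max(0, dev - N / 2)
  stat <- dev^2 * N / ((a + b) * (c + d) * (a + c) * (b + d))
  list(statistic = stat, p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
       df = 1L, counts = counts)
}

#' Select clones for graphical display
#'
#' The `n` clones with the highest sequence identity to the converted
#' reference; ties are broken by clone id for determinism.
#'
#' @param meta clone metadata (data.frame with `clone_id` and `identity`,
#'   as returned by [score_clones()]).
#' @param n number of clones to keep (default 7).
#' @return `meta` subset, ordered by decreasing identity.
#' @export
select_display_clones <- function(meta, n = 7L) {
  if (nrow(meta) < n) {
    warning(sprintf("only %d clones available (requested %d)", nrow(meta), n))
    n <- nrow(meta)
  }
  o <- order(-meta$identity, meta$clone_id)
  res <- meta[o[seq_len(n)], , drop = FALSE]
  row.names(res) <- NULL
  res
}

#' Synthetic L1 promoter fixture
#'
#' A deterministic synthetic stand-in for the internal L1 promoter CpG
#' island: ~360 nt containing exactly 20 CpG dinucleotides at irregular
#' spacings. It is a constructed sequence (not the L1.3 accession), adequate
#' for exercising conversion, scoring and group statistics.
#'
#' @return list with `sequence` and 0-based `cpg_positions` (length 20).
#' @export
l1_promoter_synthetic <- function() {
  seq <- with_seed(19880601, {
    n <- 360L
    chars <- sample(DNA_BASES4, n, replace = TRUE, prob = c(.3, .2, .2, .3))
    # clear accidental CpGs, then plant 20 at fixed positions
    for (i in seq_len(n - 1L)) {
      if (chars[i] == "C" && chars[i + 1L] == "G") chars[i + 1L] <- "A"
    }
    sites <- sort(sample(seq(5L, n - 5L, by = 2L), 20L))
    while (any(diff(sites) < 4L)) {
      sites <- sort(sample(seq(5L, n - 5L, by = 2L), 20L))
    }
    for (s in sites) {
      chars[s] <- "C"; chars[s + 1L] <- "G"
      if (s + 2L <= n && chars[s + 2L] == "G" && chars[s + 1L] == "C") chars[s + 2L] <- "A"
    }
    # planting may create new upstream CpGs; clear any C directly before a
    # planted C? keep scan simple: remove CpGs not at planted sites
    repeat {
      cpg <- which(chars[-n] == "C" & chars[-1L] == "G")
      extra <- setdiff(cpg, sites)
      if (!length(extra)) break
      chars[extra + 1L] <- "A"
    }
    paste(chars, collapse = "")
  })
  cpg <- gregexpr("CG", seq, fixed = TRUE)[[1L]]
  list(sequence = seq, cpg_positions = as.integer(cpg) - 1L)
}
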