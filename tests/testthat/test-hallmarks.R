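lib <- test_library()
full_cons <- attr(lib, "full_consensus")

test_that("TSD and deletion lengths are exact coordinate arithmetic", {
  # 13 nt duplication: bp5 = p + 13 - 1, bp3 = p
  d13 <- detect_tsd(bp5 = 1012L, bp3 = 1000L, orientation = "+")
  expect_equal(d13$tsd_len, 13L)
  expect_equal(d13$deletion_len, 0L)
  d17 <- detect_tsd(bp5 = 1016L, bp3 = 1000L, orientation = "+")
  expect_equal(d17$tsd_len, 17L)
  # blunt insertion
  blunt <- detect_tsd(bp5 = 999L, bp3 = 1000L, orientation = "+")
  expect_equal(blunt$tsd_len, 0L)
  expect_equal(blunt$deletion_len, 0L)
  # an 8 nt gap is a junction deletion
  gap <- detect_tsd(bp5 = 999L, bp3 = 1008L, orientation = "+")
  expect_equal(gap$deletion_len, 8L)
  # beyond max_tsd: unresolved, forced into neither class
  far <- detect_tsd(bp5 = 1100L, bp3 = 1000L, orientation = "+", max_tsd = 50L)
  expect_false(far$resolved)
  expect_true(is.na(far$tsd_len))
  # exhaustive identity over the +-max_tsd square, both orientations
  for (orient in c("+", "-")) {
    for (delta in -30:30) {
      bp5 <- if (orient == "+") 1000L + delta else 1000L
      bp3 <- if (orient == "+") 1000L else 1000L + delta
      d <- detect_tsd(bp5, bp3, orient)
      expect_equal(d$tsd_len, max(delta + 1L, 0L))
      expect_equal(d$deletion_len, max(-(delta + 1L), 0L))
    }
  }
  # duplicated sequence is read off the reference
  g <- c(chr1 = paste0(strrep("C", 1000), "ACGTAGGTAAAGT", strrep("C", 100)))
  ds <- detect_tsd(1012L, 1000L, "+", g, "chr1")
  expect_equal(ds$tsd_seq, "ACGTAGGTAAAGT")
})

test_that("poly-A tails tolerate one non-A per 10 nt window", {
  # normalized layout: genome section, T-run tail, minus-orientation TE
  tm <- list(orientation = "-", te_start = 62L, te_end = 120L)
  contig <- paste0(random_dna(50, seed = 2), strrep("T", 12), random_dna(58))
  expect_equal(measure_polya(contig, tm), 12L)
  # 30 T with one interior G still count 30
  tm2 <- list(orientation = "-", te_start = 81L, te_end = 140L)
  tail2 <- paste0(strrep("T", 12), "G", strrep("T", 18))
  contig2 <- paste0(random_dna(50, seed = 3), tail2, random_dna(59))
  expect_equal(measure_polya(contig2, tm2), 30L)
  # a second non-T within a 10 nt window terminates the run: the 5 T before
  # it are not counted
  tm3 <- list(orientation = "-", te_start = 70L, te_end = 120L)
  tail3 <- paste0(strrep("T", 5), "G", strrep("T", 3), "G", strrep("T", 10))
  contig3 <- paste0(random_dna(50, seed = 4), tail3, random_dna(50))
  expect_equal(measure_polya(contig3, tm3), 13L)
  # no A run at all
  tm4 <- list(orientation = "-", te_start = 50L, te_end = 100L)
  contig4 <- paste0(strrep("C", 50), strrep("G", 50))
  expect_equal(measure_polya(contig4, tm4), 0L)
})

test_that("the endonuclease motif reads TT/AAAA at canonical sites", {
  # + orientation: site with top strand TTTTAA around the first-strand nick
  left <- random_dna(60, seed = 21)
  right <- random_dna(60, seed = 22)
  g <- c(chr1 = paste0(left, "TTTTAA", right))
  bp3_plus <- 64L     # p such that top[p-4 .. p+1] == TTTTAA
  expect_equal(extract_en_motif(g, "chr1", bp3_plus, "+"), "TT/AAAA")
  # - orientation: site with top strand TTAAAA
  g2 <- c(chr1 = paste0(left, "TTAAAA", right))
  bp3_minus <- 61L    # bp3 such that top[bp3-1 .. bp3+4] == TTAAAA
  expect_equal(extract_en_motif(g2, "chr1", bp3_minus, "-"), "TT/AAAA")
  # degenerate site: GC/AAAA
  g3 <- c(chr1 = paste0(left, "GCAAAA", right))
  expect_equal(extract_en_motif(g3, "chr1", 61L, "-"), "GC/AAAA")
  g4 <- c(chr1 = paste0(left, "TTTTGC", right))
  expect_equal(extract_en_motif(g4, "chr1", 64L, "+"), "GC/AAAA")
  # too close to a reference edge: unresolved
  expect_true(is.na(extract_en_motif(c(chr1 = "ACGTACGT"), "chr1", 2L, "+")))
})

test_that("motif strings agree with junction evidence from both strands", {
  co <- small_cohort()
  hm <- co$run$hallmarks
  tr <- co$ds$truth
  # every characterized canonical-site call reads TT/AAAA
  for (i in seq_len(nrow(hm))) {
    ti <- which(tr$bp5 == hm$bp5[i] & tr$bp3 == hm$bp3[i])
    if (!length(ti)) next
    motif <- extract_en_motif(co$ds$genome$genome, hm$chrom[i], hm$bp3[i],
                              hm$orientation[i])
    expect_equal(hm$en_motif[i], motif)
  }
})

test_that("twin-priming inversions are measured from the two-block structure", {
  l1_5 <- lib[lib$family == "L1" & lib$end_tag == "five_prime", ]
  tm <- function(contig, fam = "L1") {
    m <- match_te_end(contig, lib)
    expect_false(is.null(m))
    m
  }
  mk_twin <- function(v, trunc = 0L, sense_len = 60L, flank = 60L) {
    cons <- full_cons[["L1"]]
    fl <- strsplit(random_dna(flank, seed = v), "")[[1]]
    # guard the junction: the flank's last bases are set so that the
    # inverted-block alignment cannot drift across the boundary by chance
    guard <- rev(strsplit(substr(cons, trunc + v + 1, trunc + v + 3), "")[[1]])
    fl[(flank - 2):flank] <- guard
    paste0(paste(fl, collapse = ""),
           revcomp(substr(cons, trunc + 1, trunc + v)),
           substr(cons, trunc + v + 1, trunc + v + sense_len))
  }
  c112 <- mk_twin(112L)
  expect_equal(detect_inversion(c112, tm(c112), lib), 112L)
  expect_equal(exhaustive_inversion_oracle(substr(c112, 61, nchar(c112)),
                                           full_cons[["L1"]]), 112L)
  c40 <- mk_twin(40L)
  got40 <- detect_inversion(c40, tm(c40), lib)
  oracle40 <- exhaustive_inversion_oracle(substr(c40, 61, nchar(c40)),
                                          full_cons[["L1"]])
  expect_equal(got40, oracle40)
  expect_equal(got40, 40L)
  # non-inverted 5' junction: no inversion
  plain <- paste0(random_dna(60, seed = 5), substr(full_cons[["L1"]], 1, 100))
  expect_equal(detect_inversion(plain, tm(plain), lib), 0L)
})

test_that("insertion length and full-length status follow the 5' match", {
  L <- 6019L
  expect_equal(estimate_insertion_len(0L, L),
               list(insertion_len = 6019L, full_length = TRUE))
  expect_equal(estimate_insertion_len(L - 410L, L)$insertion_len, 410L)
  expect_false(estimate_insertion_len(L - 410L, L)$full_length)
  expect_equal(estimate_insertion_len(L - 5300L, L)$insertion_len, 5300L)
  expect_false(estimate_insertion_len(L - 5300L, L)$full_length)
  # threshold: >= 99.9 percent of the consensus
  expect_true(estimate_insertion_len(floor(0.001 * L), L)$full_length)
  expect_false(estimate_insertion_len(ceiling(0.0011 * L), L)$full_length)
  # single-end calls have no length estimate
  expect_true(is.na(estimate_insertion_len(NA, L)$insertion_len))
})

test_that("cohort summaries histogram hallmarks and build the motif PFM", {
  reports <- data.frame(
    sample = "s", chrom = "chr1", bp5 = 1:6, bp3 = 1:6,
    family = c("L1", "L1", "Alu", "Alu", "Alu", "SVA"), orientation = "+",
    tsd_len = c(13L, 13L, 7L, 0L, 15L, 9L), tsd_seq = NA,
    deletion_len = c(0L, 0L, 0L, 8L, 0L, 0L), resolved = TRUE,
    polya_len = c(20L, 35L, 28L, 30L, 21L, 40L),
    en_motif = rep("TT/AAAA", 6),
    inversion_len = c(112L, 0L, 0L, 0L, 0L, 0L),
    insertion_len = c(6019L, 410L, 300L, 300L, 280L, 1565L),
    full_length = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE),
    mechanism = c("twin_priming", "tprt_tsd", "tprt_tsd", "deletion_no_tsd",
                  "tprt_tsd", "tprt_tsd"),
    stringsAsFactors = FALSE)
  s <- summarize_hallmarks(reports)
  expect_equal(sum(s$tsd_hist), 6)
  expect_equal(dim(s$pfm), c(4L, 6L))
  expect_equal(colSums(s$pfm), stats::setNames(rep(6, 6), paste0("pos", 1:6)))
  # all-canonical motifs: a point mass with 2 bits per position
  expect_equal(unname(s$information_bits), rep(2, 6))
  # mechanism counts partition the report set
  expect_equal(sum(s$mechanism_counts), nrow(reports))
  expect_equal(unname(s$mechanism_counts["twin_priming"]), 1L)
  expect_error(summarize_hallmarks(reports[0, ]), "at least one")
})
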