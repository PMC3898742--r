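make_toy_genome <- function(n = 10000, seed = 13) {
  c(chr1 = random_dna(n, seed = seed))
}

test_that("sections anchor uniquely with the junction-proximal terminus", {
  g <- make_toy_genome()
  sec <- substr(g[["chr1"]], 2001, 2100)
  a <- anchor_nonte(sec, g)
  expect_equal(a$status, "unique")
  expect_equal(a$start, 2000L)
  expect_equal(a$end, 2100L)
  expect_equal(a$strand, "+")

  # the reverse complement anchors on the minus strand, same locus
  a2 <- anchor_nonte(revcomp(sec), g)
  expect_equal(a2$status, "unique")
  expect_equal(a2$start, 2000L)
  expect_equal(a2$strand, "-")

  # a section duplicated at two loci is ambiguous
  dup <- paste0(substr(g[["chr1"]], 1, 5000), substr(g[["chr1"]], 2001, 2100),
                substr(g[["chr1"]], 5001, 10000))
  expect_equal(anchor_nonte(sec, c(chr1 = dup))$status, "ambiguous")

  # a section absent from the genome is unaligned
  expect_equal(anchor_nonte(random_dna(60, seed = 99), g)$status, "unaligned")

  # below the minimum anchorable length is a precondition violation
  expect_error(anchor_nonte(substr(sec, 1, 20), g), "min_len")
})

test_that("the 10 nt extension rule flags reference-continuing junctions", {
  g <- make_toy_genome()
  anchor <- list(status = "unique", chrom = "chr1", start = 3000L,
                 end = 3100L, strand = "+")
  sec <- substr(g[["chr1"]], 3001, 3100)
  # TE side continues the reference: a chimera/reference-resident read
  cont <- substr(g[["chr1"]], 3101, 3140)
  expect_equal(chimera_screen(paste0(sec, cont), 100L, anchor, g), "drop")
  # one mismatch in the probe is still a drop
  cont1 <- cont
  substr(cont1, 5, 5) <- if (substr(cont1, 5, 5) == "A") "C" else "A"
  expect_equal(chimera_screen(paste0(sec, cont1), 100L, anchor, g), "drop")
  # a true junction diverges at the breakpoint
  expect_equal(chimera_screen(paste0(sec, random_dna(40, seed = 3)), 100L,
                              anchor, g), "pass")
  # same rule on a minus-strand anchor
  anchor_m <- list(status = "unique", chrom = "chr1", start = 3000L,
                   end = 3100L, strand = "-")
  sec_m <- revcomp(sec)
  cont_m <- revcomp(substr(g[["chr1"]], 2961, 3000))
  expect_equal(chimera_screen(paste0(sec_m, cont_m), 100L, anchor_m, g), "drop")
})

test_that("end-to-end reference matches are routed out of novel calling", {
  g <- make_toy_genome()
  whole <- substr(g[["chr1"]], 4001, 4200)
  expect_equal(reference_event_screen(whole, g), "reference_stream")
  # 3 scattered mismatches over 200 nt (1.5 percent) still full-length
  chars <- strsplit(whole, "")[[1]]
  for (p in c(50, 100, 150)) chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
  expect_equal(reference_event_screen(paste(chars, collapse = ""), g),
               "reference_stream")
  # a split junction contig is novel
  junction <- paste0(substr(g[["chr1"]], 4001, 4100), random_dna(100, seed = 4))
  expect_equal(reference_event_screen(junction, g), "novel_stream")
})

test_that("breakpoints follow the flanking-base convention on both strands", {
  a_plus <- list(status = "unique", chrom = "chr1", start = 900L, end = 1000L,
                 strand = "+")
  bp <- breakpoint_of(a_plus, "five_prime")
  expect_equal(bp$breakpoint, 999L)
  expect_equal(bp$genome_strand, "+")
  expect_equal(bp$amplicon_start, 900L)

  a_minus <- list(status = "unique", chrom = "chr1", start = 900L, end = 1000L,
                  strand = "-")
  bp3 <- breakpoint_of(a_minus, "three_prime")
  expect_equal(bp3$breakpoint, 900L)
  expect_equal(bp3$genome_strand, "+")  # 3'-end seen on a minus anchor => + TE
  expect_equal(bp3$amplicon_start, 999L)
  expect_equal(breakpoint_of(a_minus, "five_prime")$genome_strand, "-")
})

test_that("fragments sequenced in either orientation give identical evidence", {
  co <- small_cohort()
  ev <- co$run$evidence
  truth <- co$ds$truth
  # per insertion, junction-side evidence agrees on (breakpoint, strand)
  for (i in seq_len(nrow(truth))) {
    for (sd in c("five_prime", "three_prime")) {
      bp_t <- if (sd == "five_prime") truth$bp5[i] else truth$bp3[i]
      sel <- ev$family == truth$family[i] & ev$side == sd &
        abs(ev$breakpoint - bp_t) <= 10
      if (sum(sel) < 2) next
      bps <- ev$breakpoint[sel]
      # the modal breakpoint is the truth coordinate exactly
      tb <- table(bps)
      expect_equal(as.integer(names(tb)[which.max(tb)]), bp_t)
      expect_length(unique(ev$genome_strand[sel]), 1L)
    }
  }
})
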