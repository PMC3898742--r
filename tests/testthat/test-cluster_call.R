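test_that("unique amplicon counting enforces the 5 nt separation rule", {
  expect_equal(count_unique_amplicons(c(100L, 107L)), 2L)
  expect_equal(count_unique_amplicons(c(100L, 103L)), 1L)
  expect_equal(count_unique_amplicons(c(100L, 104L, 109L)), 2L)
  expect_equal(count_unique_amplicons(c(100L, 105L)), 2L)  # boundary: >= 5
  expect_error(count_unique_amplicons(integer(0)), "non-empty")
})

test_that("greedy amplicon counting equals the exhaustive subset oracle", {
  set.seed(14)
  for (rep in 1:200) {
    n <- sample(1:12, 1)
    starts <- sample(0:60, n, replace = TRUE)
    expect_equal(count_unique_amplicons(starts),
                 max_separated_subset_oracle(starts, 5L))
  }
})

mk_ev <- function(bp, amp, side = "five_prime", family = "L1", strand = "+",
                  sample = "s1") {
  data.frame(contig_id = paste0("c", seq_along(bp)), sample_id = sample,
             family = family, side = side, chrom = "chr1", breakpoint = bp,
             genome_strand = strand, amplicon_start = amp,
             anchor_len = 50L, unique = TRUE, polya_len = 0L,
             cons_start = 0L, cons_end = 100L, end_tag = "five_prime",
             twin_primed = FALSE, inversion_len = 0L, stringsAsFactors = FALSE)
}

test_that("clusters form by single linkage with modal consensus breakpoints", {
  ev <- mk_ev(rep(1000L, 5), c(900L, 906L, 912L, 920L, 930L))
  cl <- build_clusters(ev)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$unique_amplicons, 5L)
  expect_equal(cl$consensus_breakpoint, 1000L)

  # two reads 50 nt apart split into two clusters at wobble 10
  cl2 <- build_clusters(mk_ev(c(1000L, 1050L), c(900L, 950L)))
  expect_equal(nrow(cl2), 2L)

  # modal breakpoint, ties to the smallest coordinate
  cl3 <- build_clusters(mk_ev(c(1000L, 1000L, 1000L, 1001L), c(1, 10, 20, 30)))
  expect_equal(cl3$consensus_breakpoint, 1000L)
  cl4 <- build_clusters(mk_ev(c(1000L, 1000L, 1001L, 1001L), c(1, 10, 20, 30)))
  expect_equal(cl4$consensus_breakpoint, 1000L)
})

test_that("opposing clusters join within 100 nt with compatible orientation", {
  ev <- rbind(mk_ev(rep(1000L, 3), c(900L, 910L, 920L), side = "five_prime"),
              mk_ev(rep(1080L, 3), c(1100L, 1110L, 1120L), side = "three_prime"))
  calls <- join_opposing(build_clusters(ev))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$ends_detected, "both")
  expect_equal(calls$bp5, 1000L)
  expect_equal(calls$bp3, 1080L)

  # 150 nt apart: two single-end calls
  ev2 <- rbind(mk_ev(rep(1000L, 3), c(900L, 910L, 920L), side = "five_prime"),
               mk_ev(rep(1150L, 3), c(1200L, 1210L, 1220L), side = "three_prime"))
  calls2 <- join_opposing(build_clusters(ev2))
  expect_equal(sort(calls2$ends_detected), c("five_only", "three_only"))

  # incompatible implied orientation: no join
  ev3 <- rbind(mk_ev(rep(1000L, 3), c(900L, 910L, 920L), side = "five_prime",
                     strand = "+"),
               mk_ev(rep(1010L, 3), c(1100L, 1110L, 1120L), side = "three_prime",
                     strand = "-"))
  calls3 <- join_opposing(build_clusters(ev3))
  expect_equal(nrow(calls3), 2L)
  expect_true(all(calls3$ends_detected != "both"))
})

test_that("the two-amplicon reporting rule applies per side", {
  calls <- data.frame(
    sample = "s1", chrom = "chr1", bp5 = c(1L, 2L, 3L), bp3 = c(10L, 12L, 13L),
    family = "L1", orientation = "+", ends_detected = "both",
    n_amplicons_5 = c(2L, 1L, 0L), n_amplicons_3 = c(0L, 1L, 0L),
    label = NA_character_, polya_len = 0L, cons_start5 = 0L,
    stringsAsFactors = FALSE)
  kept <- emit_calls(calls)
  expect_equal(nrow(kept), 1L)           # {2,0} reported; {1,1} and {0,0} not
  expect_equal(kept$n_amplicons_5, 2L)
})

test_that("a simulated TSD-bearing insertion yields one both-end call", {
  co <- small_cohort()
  tr <- co$ds$truth
  calls <- co$run$calls
  # both-end detection needs the 5' junction within the probe-targeted
  # terminus region (capture cannot see deep-internal truncation points)
  tsd_ins <- tr[tr$tsd_len > 0 & tr$mechanism == "tprt_tsd" &
                  tr$trunc + 40L <= 400L, ]
  found_both <- vapply(seq_len(nrow(tsd_ins)), function(i) {
    any(calls$family == tsd_ins$family[i] & calls$ends_detected == "both" &
          !is.na(calls$bp5) & calls$bp5 == tsd_ins$bp5[i] &
          calls$bp3 == tsd_ins$bp3[i])
  }, logical(1))
  expect_true(all(found_both))
  # both-end separation never exceeds the 100 nt join bound
  both <- calls[calls$ends_detected == "both", ]
  expect_true(all(abs(both$bp5 - both$bp3) <= 100L))
})
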