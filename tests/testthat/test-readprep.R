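test_that("terminal quality trimming removes only low-quality ends", {
  reads <- seq_set(c("a", "b", "c"),
                   c("ACGTG", "ACGTG", "ACGTG"),
                   list(c(2L, 9L, 30L, 30L, 9L),
                        c(30L, 30L, 30L, 30L, 10L),
                        c(2L, 2L, 2L, 2L, 2L)))
  tr <- trim_low_quality(reads, qmin = 10L)
  expect_equal(tr$seq, c("GT", "ACGTG", ""))
  expect_equal(tr$qual[[1]], c(30L, 30L))
  expect_equal(tr$qual[[2]], reads$qual[[2]])
  expect_length(tr$qual[[3]], 0L)
})

test_that("pair assembly finds the overlap and keeps the better base", {
  set.seed(42)
  frag <- random_dna(220)
  r1 <- substr(frag, 1, 150)
  r2 <- revcomp(substr(frag, 71, 220))
  m <- merge_pair(list(seq = r1, qual = rep(30L, 150)),
                  list(seq = r2, qual = rep(30L, 150)))
  expect_equal(m$overlap_len, 80L)
  expect_equal(nchar(m$seq), 220L)
  expect_equal(m$seq, frag)

  # disjoint reads do not merge
  expect_null(merge_pair(list(seq = random_dna(150), qual = rep(30L, 150)),
                         list(seq = random_dna(150), qual = rep(30L, 150))))

  # one mismatch in an 80 nt overlap: rate 1/80 <= 0.1, higher-quality wins
  r1m <- r1
  substr(r1m, 100, 100) <- if (substr(frag, 100, 100) == "A") "C" else "A"
  q1 <- rep(30L, 150); q1[100] <- 10L
  m2 <- merge_pair(list(seq = r1m, qual = q1),
                   list(seq = r2, qual = rep(30L, 150)))
  expect_equal(m2$overlap_len, 80L)
  expect_equal(substr(m2$seq, 100, 100), substr(frag, 100, 100))
  expect_equal(m2$qual[100], 30L)
  # and the winner flips when read 1 has the better quality
  q1[100] <- 38L
  m3 <- merge_pair(list(seq = r1m, qual = q1),
                   list(seq = r2, qual = rep(30L, 150)))
  expect_equal(substr(m3$seq, 100, 100), substr(r1m, 100, 100))
})

test_that("pair assembly is symmetric under mate swap with reorientation", {
  set.seed(7)
  for (insert in c(190, 220, 260)) {
    frag <- random_dna(insert)
    r1 <- substr(frag, 1, 150)
    r2 <- revcomp(substr(frag, insert - 149, insert))
    m_fwd <- merge_pair(list(seq = r1, qual = rep(30L, 150)),
                        list(seq = r2, qual = rep(30L, 150)))
    m_swp <- merge_pair(list(seq = r2, qual = rep(30L, 150)),
                        list(seq = r1, qual = rep(30L, 150)))
    expect_equal(m_fwd$overlap_len, m_swp$overlap_len)
    expect_equal(m_swp$seq, revcomp(m_fwd$seq))
  }
})

test_that("error-free pairs all merge with overlap 2*read_len - insert", {
  cfg <- sim_config(genome_len = 5e4, n_decoys = 0L, n_donors = 2L,
                    n_germline = 0L, n_private = 2L, n_tumor_specific = 0L,
                    depth_per_junction = 10L, background_pairs = 40L,
                    error_rate = 0, chimera_rate = 0, seed = 31L)
  ds <- sim_dataset(cfg)
  rd <- ds$reads[[1]]
  mg <- merge_pairs(rd$r1, rd$r2)
  expect_equal(unname(mg$counts["merged"]), length(rd$r1))
  # merged length identity: contig length = insert, overlap = 300 - insert
  expect_true(all(nchar(mg$contigs$seq) + mg$overlap_len == 300L))
  expect_true(all(mg$overlap_len >= 10L))
})

test_that("linker screen drops near-exact linker matches at score 22", {
  linkers <- illumina_linkers()
  set.seed(11)
  clean <- vapply(1:20, function(i) random_dna(220), character(1))
  expect_true(all(screen_linker(clean, linkers)))

  # a 24 nt exact linker substring scores 24 >= 22: dropped
  with_linker <- paste0(substr(clean[1], 1, 100),
                        substr(linkers[["adapter_r1"]], 1, 24),
                        substr(clean[1], 125, 220))
  expect_false(screen_linker(with_linker, linkers))
  # a contig equal to a linker: dropped
  expect_false(screen_linker(linkers[["lmpcr_1"]], linkers))
  # a 20 nt fragment scores 20 < 22: kept
  with_short <- paste0(substr(clean[2], 1, 100),
                       substr(linkers[["adapter_r2"]], 1, 20),
                       substr(clean[2], 121, 220))
  expect_true(screen_linker(with_short, linkers))
})

test_that("linker decision agrees with the exhaustive local-alignment oracle", {
  set.seed(23)
  linker <- random_dna(30)
  cases <- c(
    vapply(1:6, function(i) random_dna(120), character(1)),
    vapply(c(18, 21, 22, 25), function(k) {
      paste0(random_dna(40), substr(linker, 1, k), random_dna(40))
    }, character(1)))
  got <- screen_linker(cases, linker)
  want <- vapply(cases, function(x) {
    sw_local_score_oracle(x, linker, match = 1, mismatch = -3,
                          gap_open = 5, gap_ext = 2) < 22
  }, logical(1))
  expect_equal(unname(got), unname(want))
})
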