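test_that("the simulator is fully deterministic for a given configuration", {
  cfg <- sim_config(genome_len = 5e4, n_decoys = 1L, n_donors = 2L,
                    n_germline = 2L, n_private = 2L, n_tumor_specific = 1L,
                    depth_per_junction = 8L, background_pairs = 30L,
                    seed = 99L)
  a <- sim_dataset(cfg)
  b <- sim_dataset(cfg)
  expect_identical(a$genome$genome, b$genome$genome)
  expect_identical(a$truth, b$truth)
  for (s in names(a$reads)) {
    expect_identical(a$reads[[s]]$r1$seq, b$reads[[s]]$r1$seq)
    expect_identical(a$reads[[s]]$r2$seq, b$reads[[s]]$r2$seq)
  }
  # a different seed changes the genome
  c <- sim_genome(sim_config(genome_len = 5e4, n_decoys = 0L, seed = 100L))
  expect_false(identical(substr(a$genome$genome[["chr1"]], 1, 1000),
                         substr(c$genome[["chr1"]], 1, 1000)))
})

test_that("genome composition and decoys follow the configuration", {
  cfg <- sim_config(genome_len = 2e5, gc = 0.5, n_decoys = 5L, seed = 3L)
  g <- sim_genome(cfg)
  expect_equal(nrow(g$decoys), 5L)
  chars <- table(strsplit(substr(g$genome[["chr1"]], 1, 1e5), "")[[1]])
  freq <- chars / sum(chars)
  # base frequencies within 3 SE of 0.25 each at gc = 0.5
  se3 <- 3 * sqrt(0.25 * 0.75 / 1e5)
  expect_true(all(abs(freq - 0.25) < se3 + 0.01))
  # decoy intervals carry consensus-derived sequence: exact terminal 10-mers
  full <- attr(sim_consensus_library(), "full_consensus")
  for (i in seq_len(nrow(g$decoys))) {
    fam <- g$decoys$family[i]
    dec_seq <- substr(g$genome[["chr1"]], g$decoys$start[i] + 1, g$decoys$end[i])
    expect_equal(substr(dec_seq, 1, 10), substr(full[[fam]], 1, 10))
    expect_equal(nchar(dec_seq), nchar(full[[fam]]))
  }
})

test_that("implanted alleles reproduce their truth records from sequence", {
  co <- small_cohort()
  ds <- co$ds
  full <- attr(ds$library, "full_consensus")
  ref <- ds$genome$genome[["chr1"]]
  for (s in names(ds$samples)[1:2]) {
    samp <- ds$samples[[s]]
    jt <- samp$junctions
    for (r in seq_len(nrow(jt))) {
      tr <- ds$truth[ds$truth$insertion_id == jt$insertion_id[r], ]
      elem <- substr(samp$seq, jt$left_boundary[r] + 1, jt$right_boundary[r])
      body_len <- tr$te_len + ifelse(tr$inversion_len > 0, 0, 0)
      # tail is present with the drawn length at the element's 3' end
      tail <- if (tr$strand == "+") {
        sub(".*?(A*)$", "\\1", elem)
      } else {
        sub("^(T*).*", "\\1", elem)
      }
      expect_gte(nchar(tail), tr$polya_drawn)
      # flanks re-derive the drawn TSD: bases at [position, position+tsd)
      # appear on both sides of the element
      if (tr$tsd_drawn > 0 && tr$deletion_drawn == 0) {
        tsd_ref <- substr(ref, tr$position + 1, tr$position + tr$tsd_drawn)
        left_flank <- substr(samp$seq, jt$left_boundary[r] - tr$tsd_drawn + 1,
                             jt$left_boundary[r])
        right_flank <- substr(samp$seq, jt$right_boundary[r] + 1,
                              jt$right_boundary[r] + tr$tsd_drawn)
        expect_equal(left_flank, tsd_ref)
        expect_equal(right_flank, tsd_ref)
      }
      # element content matches the consensus-derived allele
      want <- rcseq:::.element_seq(full[[tr$family]], tr$trunc,
                                   tr$inversion_len, tr$polya_drawn)
      if (tr$strand == "-") want <- revcomp(want)
      expect_equal(elem, want)
    }
  }
})

test_that("error-free reads are exact substrings; junction depth is Poisson", {
  cfg <- sim_config(genome_len = 5e4, n_decoys = 0L, n_donors = 2L,
                    n_germline = 0L, n_private = 2L, n_tumor_specific = 0L,
                    depth_per_junction = 40L, background_pairs = 20L,
                    error_rate = 0, chimera_rate = 0, seed = 41L)
  ds <- sim_dataset(cfg)
  s <- names(ds$reads)[1]
  samp <- ds$samples[[s]]
  for (i in seq_len(min(40, length(ds$reads[[s]]$r1)))) {
    r1 <- ds$reads[[s]]$r1$seq[i]
    hit <- grepl(r1, samp$seq, fixed = TRUE) ||
      grepl(revcomp(r1), samp$seq, fixed = TRUE)
    expect_true(hit)
  }
  # junction fragment counts within 3 SE of the Poisson mean
  fr <- ds$reads[[s]]$fragments
  per_j <- table(paste(fr$insertion_id, fr$junction))
  lambda <- 40
  expect_lt(abs(mean(per_j) - lambda), 3 * sqrt(lambda / length(per_j)))
})

test_that("injected chimeras carry labels and no TSD structure", {
  cfg <- sim_config(genome_len = 1e5, n_decoys = 2L, n_donors = 2L,
                    n_germline = 2L, n_private = 0L, n_tumor_specific = 0L,
                    depth_per_junction = 10L, background_pairs = 200L,
                    chimera_rate = 0, seed = 43L)
  ds <- sim_dataset(cfg)
  s <- names(ds$reads)[1]
  before <- length(ds$reads[[s]]$r1)
  inj <- inject_chimeras(ds$reads[[s]], ds$genome, ds$library, rate = 0.05,
                         seed = 91L, cfg = cfg)
  expect_equal(length(inj$r1), before + round(0.05 * before))
  expect_gte(nrow(inj$chimeras), 1L)
  expect_true(all(inj$chimeras$chrom == "chr1"))
  # rate 0 adds nothing
  inj0 <- inject_chimeras(ds$reads[[s]], ds$genome, ds$library, rate = 0,
                          seed = 91L, cfg = cfg)
  expect_equal(length(inj0$r1), before)
  # chimera fragments splice flank directly onto consensus: by construction
  # the consensus side begins at its first base (no duplicated target site)
  full <- attr(ds$library, "full_consensus")
  chim_id <- grep("^cx_", inj$r1$id)
  expect_gte(length(chim_id), 1L)
})

test_that("conversion-efficiency extremes behave as specified", {
  prom <- l1_promoter_synthetic()
  all_m <- sim_bisulphite_clones(c(g = 1), n_clones = 5L, seed = 8L)
  conv <- mock_convert(prom$sequence, prom$cpg_positions)
  for (i in 1:5) {
    st <- score_clone(all_m$clones$seq[i], conv, prom$cpg_positions)
    expect_equal(sum(st == "M"), 20L)
  }
  # full conversion leaves no non-CpG C
  none <- sim_bisulphite_clones(c(g = 0), n_clones = 3L, seed = 9L)
  expect_false(any(grepl("C", none$clones$seq, fixed = TRUE)))
})
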