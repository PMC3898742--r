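prom <- l1_promoter_synthetic()

test_that("mock conversion turns non-CpG C to T and marks CpG C ambiguous", {
  conv <- mock_convert("ACGTCA", 1L)
  expect_equal(conv, "AYGTTA")
  ref_nc <- "ATTGGA"
  expect_equal(mock_convert(ref_nc, integer(0)), ref_nc)
  # a CpG dinucleotide tract: only CpG cytosines stay ambiguous
  tract <- "CGCGCG"
  expect_equal(mock_convert(tract, c(0L, 2L, 4L)), "YGYGYG")
  expect_error(mock_convert("ACGT", 2L), "not a CpG")

  # the packaged promoter fixture has exactly 20 CpG sites
  expect_length(prom$cpg_positions, 20L)
  conv_p <- mock_convert(prom$sequence, prom$cpg_positions)
  expect_false(grepl("C", conv_p, fixed = TRUE))
  expect_equal(nchar(conv_p), nchar(prom$sequence))
})

test_that("clone scoring reads CG as methylated, TG as unmethylated, else mutated", {
  conv <- mock_convert(prom$sequence, prom$cpg_positions)
  chars <- strsplit(prom$sequence, "")[[1]]
  # fully methylated clone: all C retained at CpG, others converted
  full_m <- chars
  full_m[full_m == "C" & !(seq_along(full_m) %in% (prom$cpg_positions + 1))] <- "T"
  st_m <- score_clone(paste(full_m, collapse = ""), conv, prom$cpg_positions)
  expect_equal(unname(table(st_m)[["M"]]), 20L)
  # fully unmethylated clone
  full_u <- chars
  full_u[full_u == "C"] <- "T"
  st_u <- score_clone(paste(full_u, collapse = ""), conv, prom$cpg_positions)
  expect_equal(unname(table(st_u)[["U"]]), 20L)
  # CA at one site is a mutated call
  mut <- full_m
  mut[prom$cpg_positions[5] + 2] <- "A"
  st_x <- score_clone(paste(mut, collapse = ""), conv, prom$cpg_positions)
  expect_equal(st_x[5], "X")
  expect_equal(sum(st_x == "M"), 19L)
  # a clone far from the reference is rejected
  expect_null(score_clone(random_dna(nchar(prom$sequence), seed = 50), conv,
                          prom$cpg_positions))
})

test_that("percent methylation excludes mutated cells from the denominator", {
  m <- matrix("M", 10, 20)
  expect_equal(percent_methylation(m), 100)
  mixed <- matrix(c(rep("M", 11), rep("U", 9), rep("X", 4)), ncol = 1)
  expect_equal(percent_methylation(mixed), 100 * 11 / 20)
  col_mut <- matrix("X", 5, 2)
  col_mut[, 1] <- c("M", "M", "U", "U", "U")
  per_site <- percent_methylation(col_mut, "per_site")
  expect_equal(unname(per_site[1]), 40)
  expect_true(is.na(per_site[2]))
})

test_that("the 2x2 chi-square equals the closed form and stats::chisq.test", {
  a <- matrix(c(rep("M", 55), rep("U", 45)), ncol = 1)
  b <- matrix(c(rep("M", 69), rep("U", 31)), ncol = 1)
  got <- chi2_compare(a, b)
  tab <- matrix(c(55, 45, 69, 31), 2)
  want <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  expect_equal(got$statistic, unname(want$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, want$p.value, tolerance = 1e-12)

  # identical proportions: statistic 0, p = 1
  same <- chi2_compare(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # 100 random tables agree with the generic implementation to 1e-9
  set.seed(77)
  for (i in 1:100) {
    n <- matrix(sample(5:200, 4, replace = TRUE), 2)
    ma <- matrix(c(rep("M", n[1, 1]), rep("U", n[2, 1])), ncol = 1)
    mb <- matrix(c(rep("M", n[1, 2]), rep("U", n[2, 2])), ncol = 1)
    got_i <- chi2_compare(ma, mb)
    want_i <- suppressWarnings(stats::chisq.test(n, correct = FALSE))
    expect_equal(got_i$statistic, unname(want_i$statistic), tolerance = 1e-9)
  }

  # empty group is an error
  expect_error(chi2_compare(a, matrix(character(0), 0, 1)), "marginal")
})

test_that("display-clone selection takes the top identities deterministically", {
  meta <- data.frame(clone_id = paste0("c", 1:9),
                     identity = c(.99, .98, .98, .97, .96, .95, .95, .95, .91))
  top <- select_display_clones(meta, 7)
  expect_equal(nrow(top), 7L)
  expect_equal(top$clone_id[1], "c1")
  # tie at rank 7 resolved by clone id
  expect_true(all(c("c6", "c7") %in% top$clone_id))
  expect_false("c9" %in% top$clone_id)
  expect_warning(few <- select_display_clones(meta[1:5, ], 7), "5 clones")
  expect_equal(nrow(few), 5L)
})

test_that("simulated clone sets recover group methylation and differences", {
  sim <- sim_bisulphite_clones(c(tumor = 0.548, nontumor = 0.692),
                               n_clones = 60L, seed = 555L)
  sc <- score_clones(sim$clones, prom$sequence, prom$cpg_positions)
  expect_equal(nrow(sc$matrix), 120L)
  grp <- sc$meta$group
  pt <- percent_methylation(sc$matrix[grp == "tumor", , drop = FALSE])
  pn <- percent_methylation(sc$matrix[grp == "nontumor", , drop = FALSE])
  # percent methylation converges to 100 p within ~2 SE
  se <- function(p, n) 100 * sqrt(p * (1 - p) / n)
  expect_lt(abs(pt - 54.8), 3 * se(0.548, 60 * 20))
  expect_lt(abs(pn - 69.2), 3 * se(0.692, 60 * 20))
  # the group difference is recovered as significant
  cmp <- chi2_compare(sc$matrix[grp == "tumor", , drop = FALSE],
                      sc$matrix[grp == "nontumor", , drop = FALSE])
  expect_lt(cmp$p_value, 0.05)
  # scoring is reproducible clone by clone
  again <- score_clones(sim$clones, prom$sequence, prom$cpg_positions)
  expect_identical(sc$matrix, again$matrix)
})
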