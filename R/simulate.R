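# Ground-truth capture-sequencing simulator: random genomes with
# reference-resident decoy elements, implanted insertions with full TPRT
# structure (TSD, poly-A, truncation, twin-priming inversion, endonuclease
# site bias), matched tumor/nontumor read sets with capture enrichment at
# junctions, ligation-chimera artifacts, and bisulphite clone sets.

.derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

#' Simulation configuration
#'
#' Defaults describe the study conditions the package is exercised under: a
#' 1 Mb genome, three donors with matched tumor/nontumor samples, 40
#' implanted insertions (15 shared germline, 15 private germline, 10
#' tumor-specific), 2 x 150 nt reads from ~220 nt inserts, 50x junction
#' depth, and 0.2 percent substitution error.
#'
#' @param genome_len reference length in nt.
#' @param gc GC fraction of the random reference.
#' @param n_decoys reference-resident (fixed) TE copies planted as chimera
#'   and reference-event fodder.
#' @param decoy_divergence interior divergence of decoy copies from the
#'   consensus (terminal 10 nt kept exact, as for recently fixed elements).
#' @param n_donors,n_germline,n_private,n_tumor_specific cohort structure.
#' @param family_mix germline family proportions (L1/Alu/SVA); defaults to
#'   the proportions observed in germline RC-seq cohorts. Tumor-specific
#'   insertions are L1, as observed somatically.
#' @param tsd_shape,tsd_scale,tsd_cap TSD length ~ discretized
#'   Gamma(shape, scale), capped.
#' @param polya_min,polya_mean poly-A length ~ `polya_min` + Geometric with
#'   the given mean.
#' @param p_truncate_l1 probability an L1 is 5' truncated (offset uniform
#'   over the consensus, >= 500 nt retained); Alu/SVA insert full length.
#' @param p_inversion probability of a twin-priming 5' inversion (L1 only),
#'   block length uniform in 30..150 nt.
#' @param p_deletion_no_tsd probability of the deletion-without-TSD
#'   mechanism (deletion 1..30 nt, no TSD).
#' @param en_site_weight probability an insertion is placed at a canonical
#'   TT/AAAA endonuclease site rather than uniformly.
#' @param read_len,insert_mean,insert_sd read geometry.
#' @param depth_per_junction expected fragments per junction per sample.
#' @param background_pairs non-junction fragments per sample (residual
#'   non-captured background).
#' @param error_rate iid substitution error per base.
#' @param chimera_rate ligation-chimera pairs added, as a fraction of the
#'   sample's real pairs.
#' @param seed root RNG seed (mandatory).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(genome_len = 1e6, gc = 0.41, n_decoys = 5L,
                       decoy_divergence = 0.12,
                       n_donors = 3L, n_germline = 15L, n_private = 15L,
                       n_tumor_specific = 10L,
                       family_mix = c(L1 = 0.14, Alu = 0.82, SVA = 0.04),
                       tsd_shape = 2, tsd_scale = 4, tsd_cap = 30L,
                       polya_min = 10L, polya_mean = 30L,
                       p_truncate_l1 = 0.65, p_inversion = 0.08,
                       p_deletion_no_tsd = 0.08, en_site_weight = 0.8,
                       read_len = 150L, insert_mean = 220L, insert_sd = 15L,
                       depth_per_junction = 50L, background_pairs = 1000L,
                       error_rate = 0.002, chimera_rate = 0.02, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  .stopifnot_scalar_fraction(gc, "gc")
  for (nm in c("p_truncate_l1", "p_inversion", "p_deletion_no_tsd",
               "en_site_weight", "error_rate", "chimera_rate")) {
    .stopifnot_scalar_fraction(get(nm), nm)
  }
  if (abs(sum(family_mix) - 1) > 1e-8) stop("family_mix must sum to 1")
  structure(as.list(environment()), class = "sim_config")
}

#' Synthetic retrotransposon consensus library
#'
#' Deterministic synthetic consensus sequences for three mutually dissimilar
#' families (an L1 of 6019 nt, an Alu of 312 nt, an SVA of 1565 nt) with 5'
#' and 3' terminal entries sized to cover any junction-visible segment of a
#' ~220 nt insert. These are constructed stand-ins, not database accessions.
#'
#' @return a `consensus_library` data.frame (see
#'   [load_consensus_library()]); the full consensus sequences are in
#'   `attr(, "full_consensus")`.
#' @export
sim_consensus_library <- function() {
  full <- with_seed(20130301, {
    lens <- c(L1 = 6019L, Alu = 312L, SVA = 1565L)
    vapply(names(lens), function(f) {
      paste(sample(DNA_BASES4, lens[[f]], replace = TRUE), collapse = "")
    }, character(1))
  })
  entry_len <- c(L1 = 400L, Alu = 300L, SVA = 400L)
  rows <- list()
  for (f in names(full)) {
    L <- nchar(full[[f]]); el <- min(entry_len[[f]], L)
    rows[[length(rows) + 1L]] <- data.frame(
      family = f, end_tag = "five_prime", seq = substr(full[[f]], 1L, el),
      entry_len = el, full_length = L, cons_offset = 0L,
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      family = f, end_tag = "three_prime", seq = substr(full[[f]], L - el + 1L, L),
      entry_len = el, full_length = L, cons_offset = L - el,
      stringsAsFactors = FALSE)
  }
  lib <- do.call(rbind, rows)
  class(lib) <- c("consensus_library", "data.frame")
  attr(lib, "full_consensus") <- full
  lib
}

.random_dna <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES4, n, replace = TRUE, prob = p), collapse = "")
}

.mutate_interior <- function(seq, divergence, protect = 10L) {
  n <- nchar(seq)
  if (n <= 2L * protect) return(seq)
  chars <- .chars(seq)
  idx <- (protect + 1L):(n - protect)
  k <- round(divergence * length(idx))
  if (k == 0L) return(seq)
  pos <- sample(idx, k)
  for (p in pos) {
    chars[p] <- sample(setdiff(DNA_BASES4, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Simulate a reference genome with decoy TE copies
#'
#' Seeded random genome (single chromosome `chr1`) containing
#' `cfg$n_decoys` full-length reference-resident TE copies whose interiors
#' diverge from the consensus but whose terminal 10 nt are exact.
#'
#' @param cfg a [sim_config()].
#' @param library a consensus library with `full_consensus` attribute
#'   (default [sim_consensus_library()]).
#' @param seed RNG seed (defaults to one derived from `cfg$seed`).
#' @return list with `genome` (named character vector) and `decoys`
#'   (data.frame chrom/start/end/family, 0-based half-open).
#' @export
sim_genome <- function(cfg, library = sim_consensus_library(),
                       seed = .derive_seed(cfg$seed, 1L)) {
  full <- attr(library, "full_consensus")
  with_seed(seed, {
    base <- .random_dna(cfg$genome_len, cfg$gc)
    nd <- cfg$n_decoys
    if (nd == 0L) {
      return(list(genome = c(chr1 = base), decoys = data.frame(
        chrom = character(0), start = integer(0), end = integer(0),
        family = character(0), stringsAsFactors = FALSE)))
    }
    fams <- sample(names(full), nd, replace = TRUE,
                   prob = cfg$family_mix[names(full)])
    # insertion points, well separated and away from the edges
    repeat {
      pts <- sort(sample.int(cfg$genome_len - 20000L, nd) + 10000L)
      if (nd == 1L || min(diff(pts)) > 20000L) break
    }
    pieces <- character(0)
    cursor <- 1L
    decoys <- list()
    off <- 0L
    for (i in seq_len(nd)) {
      copy <- .mutate_interior(full[[fams[i]]], cfg$decoy_divergence)
      pieces <- c(pieces, substr(base, cursor, pts[i]), copy)
      start <- pts[i] + off
      decoys[[i]] <- data.frame(chrom = "chr1", start = start,
                                end = start + nchar(copy), family = fams[i],
                                stringsAsFactors = FALSE)
      off <- off + nchar(copy)
      cursor <- pts[i] + 1L
    }
    pieces <- c(pieces, substr(base, cursor, cfg$genome_len))
    list(genome = c(chr1 = paste(pieces, collapse = "")),
         decoys = do.call(rbind, decoys))
  })
}

# Draw the structural parameters of one insertion.
.draw_allele <- function(cfg, family, full_len) {
  polya <- cfg$polya_min + stats::rgeom(1L, 1 / (cfg$polya_mean - cfg$polya_min + 1))
  del <- 0L; tsd <- 0L; inv <- 0L; trunc <- 0L
  if (stats::runif(1) < cfg$p_deletion_no_tsd) {
    del <- sample.int(30L, 1L)
  } else {
    tsd <- min(cfg$tsd_cap, round(stats::rgamma(1L, cfg$tsd_shape, scale = cfg$tsd_scale)))
    if (family == "L1" && stats::runif(1) < cfg$p_inversion) {
      inv <- sample(30:150, 1L)
    }
  }
  if (family == "L1" && stats::runif(1) < cfg$p_truncate_l1) {
    trunc <- sample.int(max(full_len - 500L - inv, 1L), 1L) - 1L
  }
  list(tsd_len = as.integer(tsd), deletion_len = as.integer(del),
       polya_len = as.integer(polya), trunc = as.integer(trunc),
       inversion_len = as.integer(inv))
}

# Canonical junction coordinates under the caller's maximal-genomic-
# extension convention: the genome claims every junction-adjacent base it
# can explain, so a poly-A tail abutting an A-run of the reference and
# element bases coinciding with the reference continuation shift the
# junction-visible breakpoints deterministically. `body` is the inserted
# element sequence (sense, without the tail), `k` the drawn tail length.
.canonical_junctions <- function(ref, p, tsd, del, strand, body, k,
                                 te_ext_cap = 25L) {
  rc <- function(x) chartr("ACGTN", "TGCAN", x)
  # the element's own 3'-terminal adenosines are junction-indistinguishable
  # from the tail: the effective tail includes them
  body_a <- 0L
  while (body_a < nchar(body) &&
         substr(body, nchar(body) - body_a, nchar(body) - body_a) == "A") {
    body_a <- body_a + 1L
  }
  k <- k + body_a
  run_left <- function(x, base) {     # run of `base` in ref at x, x-1, ...
    r <- 0L
    while (x - r >= 0L && substr(ref, x - r + 1L, x - r + 1L) == base) r <- r + 1L
    r
  }
  run_right <- function(x, base) {    # run of `base` in ref at x, x+1, ...
    r <- 0L
    n <- nchar(ref)
    while (x + r < n && substr(ref, x + r + 1L, x + r + 1L) == base) r <- r + 1L
    r
  }
  body_match_fwd <- function(x) {     # run body[j] == ref[x + j]
    s <- 0L
    while (s < te_ext_cap && s < nchar(body) &&
           substr(body, s + 1L, s + 1L) == substr(ref, x + s + 1L, x + s + 1L)) {
      s <- s + 1L
    }
    s
  }
  body_match_rev <- function(x) {     # run body[j] == complement(ref[x - j])
    s <- 0L
    while (s < te_ext_cap && s < nchar(body) &&
           substr(body, s + 1L, s + 1L) == rc(substr(ref, x - s + 1L, x - s + 1L))) {
      s <- s + 1L
    }
    s
  }
  if (strand == "+") {
    if (del > 0L) {
      e3 <- min(run_left(p + del - 1L, "A"), k)
      bp3 <- p + del - e3
      bp5 <- p - 1L + body_match_fwd(p)
    } else {
      e3 <- min(run_left(p - 1L, "A"), k)
      bp3 <- p - e3
      bp5 <- p + tsd - 1L + body_match_fwd(p + tsd)
    }
  } else {
    if (del > 0L) {
      e3 <- min(run_right(p, "T"), k)
      bp3 <- p - 1L + e3
      bp5 <- p + del - body_match_rev(p + del - 1L)
    } else {
      e3 <- min(run_right(p + tsd, "T"), k)
      bp3 <- p + tsd - 1L + e3
      bp5 <- p - body_match_rev(p - 1L)
    }
  }
  list(bp5 = bp5, bp3 = bp3, polya = k - e3)
}

# Element sequence (sense orientation): possibly 5'-truncated consensus,
# with an optional twin-priming inverted 5' block, then the poly-A tail.
.element_seq <- function(full_cons, trunc, inversion_len, polya_len) {
  L <- nchar(full_cons)
  a <- trunc
  body <- if (inversion_len > 0L) {
    paste0(revcomp(substr(full_cons, a + 1L, a + inversion_len)),
           substr(full_cons, a + inversion_len + 1L, L))
  } else {
    substr(full_cons, a + 1L, L)
  }
  paste0(body, strrep("A", polya_len))
}

#' Implant insertions and build per-sample genomes
#'
#' Selects insertion sites (biased toward canonical endonuclease sites),
#' draws TPRT structure per insertion, assigns cohort presence (shared
#' germline in >= 2 donors, private germline in one donor, tumor-specific in
#' one tumor only), and splices alleles into per-sample genomes.
#'
#' @param genome_obj output of [sim_genome()].
#' @param cfg a [sim_config()].
#' @param library consensus library with `full_consensus`.
#' @param seed RNG seed.
#' @return list with `truth` (one row per insertion: reference position =
#'   5'-most duplicated base, structure, truth breakpoints, `present_in`
#'   semicolon-joined sample ids, mechanism), `cohort` (a [sample_set()]),
#'   and `samples` (per sample: spliced genome string and junction table in
#'   sample coordinates).
#' @export
sim_implant <- function(genome_obj, cfg, library = sim_consensus_library(),
                        seed = .derive_seed(cfg$seed, 2L)) {
  full <- attr(library, "full_consensus")
  ref <- genome_obj$genome[["chr1"]]
  n_ref <- nchar(ref)
  cohort <- sample_set(paste0("d", seq_len(cfg$n_donors)),
                       paste0("d", seq_len(cfg$n_donors), "T"),
                       paste0("d", seq_len(cfg$n_donors), "NT"))
  with_seed(seed, {
    n_ins <- cfg$n_germline + cfg$n_private + cfg$n_tumor_specific
    classes <- c(rep("germline_shared", cfg$n_germline),
                 rep("private_germline", cfg$n_private),
                 rep("tumor_specific", cfg$n_tumor_specific))
    fams <- ifelse(classes == "tumor_specific", "L1",
                   sample(names(cfg$family_mix), n_ins, replace = TRUE,
                          prob = cfg$family_mix))
    strands <- sample(c("+", "-"), n_ins, replace = TRUE)

    # canonical first-strand nick sites on each orientation
    plus_sites <- as.integer(gregexpr("TTTTAA", ref, fixed = TRUE)[[1L]])
    minus_sites <- as.integer(gregexpr("TTAAAA", ref, fixed = TRUE)[[1L]])

    forbidden <- rbind(genome_obj$decoys[, c("start", "end")],
                       data.frame(start = c(0L, n_ref - 2000L),
                                  end = c(2000L, n_ref)))
    taken <- integer(0)
    ok_site <- function(p) {
      if (p < 2000L || p > n_ref - 2000L) return(FALSE)
      if (length(taken) && min(abs(taken - p)) < 500L) return(FALSE)
      !any(p >= forbidden$start - 300L & p <= forbidden$end + 300L)
    }

    rows <- list()
    for (i in seq_len(n_ins)) {
      al <- .draw_allele(cfg, fams[i], nchar(full[[fams[i]]]))
      use_en <- al$deletion_len == 0L && stats::runif(1) < cfg$en_site_weight
      p <- NA_integer_
      if (use_en) {
        # "+": motif site TTTTAA at 1-based o gives p = o + 3 (0-based);
        # "-": motif site TTAAAA at 1-based o gives bp3 = o, p = o - tsd + 1
        pool <- if (strands[i] == "+") plus_sites + 3L
        else minus_sites - al$tsd_len + 1L
        pool <- pool[pool > 0]
        pool <- sample(pool)
        for (cand in pool) {
          if (ok_site(cand)) { p <- cand; break }
        }
      }
      if (is.na(p)) {
        repeat {
          cand <- sample.int(n_ref - 4000L, 1L) + 2000L
          if (ok_site(cand)) { p <- cand; break }
        }
      }
      taken <- c(taken, p)
      # presence
      if (classes[i] == "germline_shared") {
        if (cfg$n_donors < 2L) stop("shared germline insertions need >= 2 donors")
        dn <- sort(sample(cohort$donor_id, sample(2:min(3L, cfg$n_donors), 1L)))
        pres <- c(cohort$tumor[match(dn, cohort$donor_id)],
                  cohort$nontumor[match(dn, cohort$donor_id)])
      } else if (classes[i] == "private_germline") {
        d <- sample(cohort$donor_id, 1L)
        pres <- c(cohort$tumor[match(d, cohort$donor_id)],
                  cohort$nontumor[match(d, cohort$donor_id)])
      } else {
        d <- sample(cohort$donor_id, 1L)
        pres <- cohort$tumor[match(d, cohort$donor_id)]
      }
      t <- al$tsd_len; d <- al$deletion_len
      elem_full <- .element_seq(full[[fams[i]]], al$trunc, al$inversion_len,
                                al$polya_len)
      body <- substr(elem_full, 1L, nchar(elem_full) - al$polya_len)
      cj <- .canonical_junctions(ref, p, t, d, strands[i], body, al$polya_len)
      tsd_vis <- max(if (strands[i] == "+") cj$bp5 - cj$bp3 + 1L
                     else cj$bp3 - cj$bp5 + 1L, 0L)
      del_vis <- max(if (strands[i] == "+") cj$bp3 - cj$bp5 - 1L
                     else cj$bp5 - cj$bp3 - 1L, 0L)
      rows[[i]] <- data.frame(
        insertion_id = sprintf("ins%02d", i), chrom = "chr1", position = p,
        family = fams[i], strand = strands[i], class = classes[i],
        tsd_drawn = t, deletion_drawn = d, polya_drawn = al$polya_len,
        tsd_len = tsd_vis, deletion_len = del_vis, polya_len = cj$polya,
        trunc = al$trunc, inversion_len = al$inversion_len,
        te_len = nchar(full[[fams[i]]]) - al$trunc,
        mechanism = if (d > 0L) "deletion_no_tsd"
        else if (al$inversion_len > 0L) "twin_priming" else "tprt_tsd",
        bp5 = cj$bp5, bp3 = cj$bp3,
        present_in = paste(pres, collapse = ";"),
        stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, rows)

    all_samples <- c(cohort$tumor, cohort$nontumor)
    samples <- vector("list", length(all_samples))
    names(samples) <- all_samples
    for (s in all_samples) {
      here <- truth[vapply(strsplit(truth$present_in, ";", fixed = TRUE),
                           function(v) s %in% v, logical(1)), , drop = FALSE]
      here <- here[order(here$position), , drop = FALSE]
      pieces <- character(0)
      cursor <- 1L   # 1-based ref cursor
      jl <- list()
      slen <- 0L
      for (r in seq_len(nrow(here))) {
        p <- here$position[r]; t <- here$tsd_drawn[r]; d <- here$deletion_drawn[r]
        elem <- .element_seq(full[[here$family[r]]], here$trunc[r],
                             here$inversion_len[r], here$polya_drawn[r])
        if (here$strand[r] == "-") elem <- revcomp(elem)
        left_end1 <- if (d > 0L) p else p + t      # 1-based inclusive end of left piece
        pieces <- c(pieces, substr(ref, cursor, left_end1), elem)
        slen <- slen + (left_end1 - cursor + 1L)
        Lb <- slen                                  # boundary before element
        slen <- slen + nchar(elem)
        Rb <- slen
        cursor <- if (d > 0L) p + d + 1L else p + 1L
        jl[[r]] <- data.frame(insertion_id = here$insertion_id[r],
                              left_boundary = Lb, right_boundary = Rb,
                              strand = here$strand[r],
                              polya_len = here$polya_drawn[r],
                              stringsAsFactors = FALSE)
      }
      pieces <- c(pieces, substr(ref, cursor, n_ref))
      samples[[s]] <- list(seq = paste(pieces, collapse = ""),
                           junctions = if (length(jl)) do.call(rbind, jl)
                           else data.frame(insertion_id = character(0),
                                           left_boundary = integer(0),
                                           right_boundary = integer(0),
                                           strand = character(0),
                                           polya_len = integer(0)))
    }
    list(truth = truth, cohort = cohort, samples = samples)
  })
}

.apply_errors <- function(seq, error_rate) {
  if (error_rate <= 0) return(seq)
  n <- nchar(seq)
  k <- stats::rbinom(1L, n, error_rate)
  if (k == 0L) return(seq)
  chars <- .chars(seq)
  pos <- sample.int(n, k)
  for (p in pos) chars[p] <- sample(setdiff(DNA_BASES4, chars[p]), 1L)
  paste(chars, collapse = "")
}

# One fragment -> paired reads with errors; random sequencing orientation.
.fragment_to_pair <- function(frag, read_len, error_rate) {
  if (stats::runif(1) < 0.5) frag <- revcomp(frag)
  n <- nchar(frag)
  r1 <- .apply_errors(substr(frag, 1L, min(read_len, n)), error_rate)
  r2 <- .apply_errors(revcomp(substr(frag, max(1L, n - read_len + 1L), n)),
                      error_rate)
  list(r1 = r1, r2 = r2)
}

#' Simulate capture reads for one sample
#'
#' Fragments are drawn around each insertion junction (Poisson
#' `depth_per_junction` per junction, insert length ~
#' Normal(`insert_mean`, `insert_sd`) truncated to the mergeable range),
#' plus uniform background fragments and, optionally, ligation-chimera
#' fragments at decoy-element boundaries. Reads carry iid substitution
#' errors and constant phred qualities consistent with the error rate.
#'
#' @param sample_obj one element of `sim_implant()$samples`.
#' @param cfg a [sim_config()].
#' @param sample_id sample identifier (used in read ids).
#' @param genome_obj output of [sim_genome()] (needed for chimeras).
#' @param library consensus library with `full_consensus`.
#' @param seed RNG seed.
#' @return list with `r1`, `r2` ([seq_set]s), `fragments` (truth sidecar:
#'   per junction fragment, its insertion, side, outer coordinate, and
#'   usability for junction evidence), and `chimeras` (locus labels).
#' @export
sim_reads <- function(sample_obj, cfg, sample_id, genome_obj,
                      library = sim_consensus_library(),
                      seed = .derive_seed(cfg$seed, 3L)) {
  full <- attr(library, "full_consensus")
  sseq <- sample_obj$seq
  n <- nchar(sseq)
  rl <- cfg$read_len
  q_per_base <- if (cfg$error_rate > 0) {
    as.integer(min(40L, round(-10 * log10(cfg$error_rate))))
  } else 40L
  with_seed(seed, {
    ids <- character(0); s1 <- character(0); s2 <- character(0)
    frag_truth <- list()
    k <- 0L
    draw_len <- function() {
      max(160L, min(2L * rl - 10L, round(stats::rnorm(1L, cfg$insert_mean, cfg$insert_sd))))
    }
    jt <- sample_obj$junctions
    for (r in seq_len(nrow(jt))) {
      for (side_pt in c("left", "right")) {
        b <- if (side_pt == "left") jt$left_boundary[r] else jt$right_boundary[r]
        nfrag <- stats::rpois(1L, cfg$depth_per_junction)
        for (f in seq_len(nfrag)) {
          len <- draw_len()
          s <- b - sample.int(len - 20L, 1L) - 9L + 1L  # >=10 nt each side
          s <- max(1L, min(s, n - len + 1L))
          frag <- substr(sseq, s, s + len - 1L)
          pr <- .fragment_to_pair(frag, rl, cfg$error_rate)
          k <- k + 1L
          ids <- c(ids, sprintf("%s_j_%s_%s_%d", sample_id, jt$insertion_id[r],
                                side_pt, f))
          s1 <- c(s1, pr$r1); s2 <- c(s2, pr$r2)
          flank_len <- if (side_pt == "left") b - (s - 1L) else (s + len - 1L) - b
          elem_len <- len - flank_len
          # the poly-A tail abuts the right boundary for + insertions and
          # the left boundary for - insertions
          tail_here <- (side_pt == "right") == (jt$strand[r] == "+")
          usable <- flank_len >= 34L &&
            elem_len >= 34L + if (tail_here) jt$polya_len[r] else 0L
          frag_truth[[k]] <- data.frame(
            insertion_id = jt$insertion_id[r],
            junction = side_pt,
            outer = if (side_pt == "left") s else s + len - 1L,
            usable = usable, stringsAsFactors = FALSE)
        }
      }
    }
    n_junction <- length(ids)
    for (f in seq_len(cfg$background_pairs)) {
      len <- draw_len()
      s <- sample.int(n - len, 1L)
      pr <- .fragment_to_pair(substr(sseq, s, s + len - 1L), rl, cfg$error_rate)
      ids <- c(ids, sprintf("%s_b_%d", sample_id, f))
      s1 <- c(s1, pr$r1); s2 <- c(s2, pr$r2)
    }
    chim <- list()
    n_chim <- round(cfg$chimera_rate * length(ids))
    if (n_chim > 0L && nrow(genome_obj$decoys)) {
      ref <- genome_obj$genome[["chr1"]]
      for (f in seq_len(n_chim)) {
        dec <- genome_obj$decoys[sample.int(nrow(genome_obj$decoys), 1L), ]
        len <- draw_len()
        m <- sample(60:100, 1L)           # genomic flank length
        d0 <- dec$start                    # 0-based decoy start
        flank <- substr(ref, d0 - m + 1L, d0)
        te <- substr(full[[dec$family]], 1L, len - m)
        pr <- .fragment_to_pair(paste0(flank, te), rl, cfg$error_rate)
        ids <- c(ids, sprintf("%s_c_%d", sample_id, f))
        s1 <- c(s1, pr$r1); s2 <- c(s2, pr$r2)
        chim[[f]] <- data.frame(chrom = dec$chrom, locus = d0 - 1L,
                                family = dec$family, stringsAsFactors = FALSE)
      }
    }
    qual1 <- lapply(nchar(s1), function(L) rep(q_per_base, L))
    qual2 <- lapply(nchar(s2), function(L) rep(q_per_base, L))
    list(r1 = seq_set(paste0(ids, "/1"), s1, qual1),
         r2 = seq_set(paste0(ids, "/2"), s2, qual2),
         fragments = if (length(frag_truth)) do.call(rbind, frag_truth)
         else data.frame(insertion_id = character(0), junction = character(0),
                         outer = integer(0), usable = logical(0)),
         chimeras = if (length(chim)) unique(do.call(rbind, chim))
         else data.frame(chrom = character(0), locus = integer(0),
                         family = character(0)),
         n_junction_pairs = n_junction)
  })
}

#' Inject ligation-chimera pairs into an existing read set
#'
#' Adds `rate * length(r1)` contig-equivalent pairs splicing a random
#' genomic flank onto a consensus 5' fragment at a decoy-element boundary,
#' with a truth-label sidecar.
#'
#' @param reads list with `r1`, `r2` [seq_set]s.
#' @param genome_obj output of [sim_genome()].
#' @param library consensus library with `full_consensus`.
#' @param rate fraction of pairs to add.
#' @param seed RNG seed.
#' @param cfg a [sim_config()] (read geometry and error rate).
#' @return `reads` with pairs appended and a `chimeras` label data.frame.
#' @export
inject_chimeras <- function(reads, genome_obj, library, rate, seed, cfg) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  full <- attr(library, "full_consensus")
  n_add <- round(rate * length(reads$r1))
  if (n_add == 0L || nrow(genome_obj$decoys) == 0L) {
    reads$chimeras <- data.frame(chrom = character(0), locus = integer(0),
                                 family = character(0))
    return(reads)
  }
  ref <- genome_obj$genome[["chr1"]]
  rl <- cfg$read_len
  with_seed(seed, {
    ids <- character(0); s1 <- character(0); s2 <- character(0)
    chim <- list()
    for (f in seq_len(n_add)) {
      dec <- genome_obj$decoys[sample.int(nrow(genome_obj$decoys), 1L), ]
      len <- max(160L, min(2L * rl - 10L,
                           round(stats::rnorm(1L, cfg$insert_mean, cfg$insert_sd))))
      m <- sample(60:100, 1L)
      flank <- substr(ref, dec$start - m + 1L, dec$start)
      te <- substr(full[[dec$family]], 1L, len - m)
      pr <- .fragment_to_pair(paste0(flank, te), rl, cfg$error_rate)
      ids <- c(ids, sprintf("cx_%d", f))
      s1 <- c(s1, pr$r1); s2 <- c(s2, pr$r2)
      chim[[f]] <- data.frame(chrom = dec$chrom, locus = dec$start - 1L,
                              family = dec$family, stringsAsFactors = FALSE)
    }
    q <- if (cfg$error_rate > 0) {
      as.integer(min(40L, round(-10 * log10(cfg$error_rate))))
    } else 40L
    add1 <- seq_set(paste0(ids, "/1"), s1, lapply(nchar(s1), function(L) rep(q, L)))
    add2 <- seq_set(paste0(ids, "/2"), s2, lapply(nchar(s2), function(L) rep(q, L)))
    reads$r1 <- seq_set(c(reads$r1$id, add1$id), c(reads$r1$seq, add1$seq),
                        c(reads$r1$qual, add1$qual))
    reads$r2 <- seq_set(c(reads$r2$id, add2$id), c(reads$r2$seq, add2$seq),
                        c(reads$r2$qual, add2$qual))
    reads$chimeras <- unique(do.call(rbind, chim))
    reads
  })
}

#' Simulate a complete cohort dataset
#'
#' Genome, implanted insertions, and per-sample paired reads, with all truth
#' sidecars. Fully deterministic for a given configuration (including seed).
#'
#' @param cfg a [sim_config()].
#' @return list with `cfg`, `library`, `genome` (genome object), `truth`,
#'   `cohort`, `samples` (spliced genomes + junction tables), and `reads`
#'   (per sample: r1/r2 sets, fragment sidecar, chimera labels).
#' @export
sim_dataset <- function(cfg) {
  library <- sim_consensus_library()
  gobj <- sim_genome(cfg, library)
  imp <- sim_implant(gobj, cfg, library)
  reads <- list()
  all_samples <- c(imp$cohort$tumor, imp$cohort$nontumor)
  for (i in seq_along(all_samples)) {
    s <- all_samples[i]
    reads[[s]] <- sim_reads(imp$samples[[s]], cfg, s, gobj, library,
                            seed = .derive_seed(cfg$seed, 100L + i))
  }
  list(cfg = cfg, library = library, genome = gobj, truth = imp$truth,
       cohort = imp$cohort, samples = imp$samples, reads = reads)
}

#' Simulate bisulphite clone sequences from the L1 promoter fixture
#'
#' Per group, clones carry per-CpG-site Bernoulli(`p_meth`) methylation;
#' unmethylated and non-CpG cytosines convert C to T with probability
#' `conversion_efficiency`.
#'
#' @param p_meth named numeric vector of per-group methylation
#'   probabilities (names become groups).
#' @param n_clones clones per group.
#' @param conversion_efficiency bisulphite conversion efficiency
#'   (default 1).
#' @param seed RNG seed.
#' @param promoter list with `sequence` and `cpg_positions`
#'   (default [l1_promoter_synthetic()]).
#' @return list with `clones` (a [seq_set] with `sample|group` headers) and
#'   `truth` (logical matrix of methylation states, clones x sites).
#' @export
sim_bisulphite_clones <- function(p_meth, n_clones, conversion_efficiency = 1,
                                  seed, promoter = l1_promoter_synthetic()) {
  stopifnot(all(p_meth >= 0 & p_meth <= 1))
  .stopifnot_scalar_fraction(conversion_efficiency, "conversion_efficiency")
  ref_chars <- .chars(promoter$sequence)
  cpg <- promoter$cpg_positions
  with_seed(seed, {
    ids <- character(0); seqs <- character(0)
    truth <- list()
    for (g in names(p_meth)) {
      for (cl in seq_len(n_clones)) {
        chars <- ref_chars
        meth <- stats::runif(length(cpg)) < p_meth[[g]]
        convert <- which(chars == "C")
        keep_c <- cpg[meth] + 1L
        for (p in convert) {
          if (p %in% keep_c) next
          if (stats::runif(1) < conversion_efficiency) chars[p] <- "T"
        }
        ids <- c(ids, sprintf("%s_clone%03d|%s", g, cl, g))
        seqs <- c(seqs, paste(chars, collapse = ""))
        truth[[length(truth) + 1L]] <- meth
      }
    }
    list(clones = seq_set(ids, seqs),
         truth = do.call(rbind, truth))
  })
}
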