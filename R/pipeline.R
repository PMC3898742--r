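# End-to-end orchestration: per-sample calling from raw pairs to reported
# insertion calls, cohort classification, hallmark characterization, and
# evaluation against simulator truth.

#' Pipeline parameters
#'
#' All stage thresholds with their published defaults: terminal quality 10,
#' consensus identity 0.95 over >= 33 nt, linker score 22, chimera probe
#' 10 nt, amplicon separation 5 nt, two amplicons to report, opposing-
#' cluster join <= 100 nt.
#'
#' @param qmin,min_overlap,max_mismatch_rate read preparation.
#' @param linker_min_score linker screen threshold.
#' @param te_min_identity,te_min_len consensus matching.
#' @param uniqueness_margin,chimera_probe_len genome anchoring.
#' @param wobble,amplicon_min_sep,join_max_sep,min_amplicons clustering.
#' @param db_window,max_tsd classification and hallmark windows.
#' @return list of class `rcseq_params`.
#' @export
rcseq_params <- function(qmin = 10L, min_overlap = 10L, max_mismatch_rate = 0.1,
                         linker_min_score = 22, te_min_identity = 0.95,
                         te_min_len = 33L, uniqueness_margin = 5,
                         chimera_probe_len = 10L, wobble = 10L,
                         amplicon_min_sep = 5L, join_max_sep = 100L,
                         min_amplicons = 2L, db_window = 50L, max_tsd = 50L) {
  structure(as.list(environment()), class = "rcseq_params")
}

#' Call insertions in one sample from raw read pairs
#'
#' Runs trimming, pair assembly, linker screening, TE-terminus annotation,
#' genome anchoring with chimera/reference screens, clustering, and the
#' reporting rule.
#'
#' @param r1,r2 [seq_set]s of raw pairs.
#' @param genome named chromosome vector.
#' @param library a `consensus_library`.
#' @param sample_id sample identifier.
#' @param params an [rcseq_params()].
#' @param linkers linker sequences for the artifact screen.
#' @return list with `calls`, `evidence`, `rejects`, `clusters`, `contigs`
#'   (normalized annotated contigs), `matches`, and per-stage `counts`.
#' @export
call_sample <- function(r1, r2, genome, library, sample_id = "sample",
                        params = rcseq_params(), linkers = illumina_linkers()) {
  mg <- merge_pairs(r1, r2, qmin = params$qmin, min_overlap = params$min_overlap,
                    max_mismatch_rate = params$max_mismatch_rate)
  keep <- screen_linker(mg$contigs, linkers, min_score = params$linker_min_score)
  contigs <- mg$contigs[keep]
  ann <- annotate_te_contigs(contigs, library,
                             min_identity = params$te_min_identity,
                             min_len = params$te_min_len)
  je <- build_junction_evidence(ann, genome, sample_id = sample_id,
                                min_len = params$te_min_len,
                                uniqueness_margin = params$uniqueness_margin,
                                chimera_probe_len = params$chimera_probe_len,
                                library = library)
  clusters <- build_clusters(je$evidence, wobble = params$wobble,
                             min_sep = params$amplicon_min_sep)
  calls <- emit_calls(join_opposing(clusters, max_sep = params$join_max_sep),
                      min_amplicons = params$min_amplicons)
  counts <- c(pairs = unname(mg$counts["input"]),
              merged = unname(mg$counts["merged"]),
              linker_dropped = sum(!keep),
              te_retained = sum(ann$status == "retained"),
              te_no_match = sum(ann$status == "no_match"),
              te_both_termini = sum(ann$status == "both_termini"),
              te_short = sum(ann$status == "short"),
              evidence = nrow(je$evidence),
              rejected_anchor = nrow(je$rejects),
              clusters = nrow(clusters),
              calls = nrow(calls))
  list(calls = calls, evidence = je$evidence, rejects = je$rejects,
       clusters = clusters, contigs = ann$contigs, matches = ann$matches,
       counts = counts)
}

# Call-level twin-priming inversion length: the largest inverted-block
# length observed among the call's 5'-side evidence (two-block contigs give
# the exact length; block-only contigs a lower bound), required in at least
# half of the 5'-side reads.
.call_inversions <- function(calls, evidence, wobble = 10L) {
  inv <- integer(nrow(calls))
  if (!nrow(calls)) return(inv)
  for (i in seq_len(nrow(calls))) {
    if (calls$ends_detected[i] != "both" || is.na(calls$bp5[i])) next
    sel <- which(evidence$sample_id == calls$sample[i] &
                   evidence$family == calls$family[i] &
                   evidence$chrom == calls$chrom[i] &
                   evidence$side == "five_prime" &
                   abs(evidence$breakpoint - calls$bp5[i]) <= wobble)
    if (!length(sel)) next
    twin <- sel[evidence$twin_primed[sel]]
    if (length(twin) < length(sel) / 2) next
    if (length(twin)) inv[i] <- max(evidence$inversion_len[twin])
  }
  inv
}

#' Run the full cohort pipeline on a simulated dataset
#'
#' Calls every sample, merges calls into cohort loci, classifies them
#' against the matched tumor/nontumor design, and characterizes TPRT
#' hallmarks of both-end calls.
#'
#' @param dataset output of [sim_dataset()] (or a list with the same
#'   shape: `reads`, `genome`, `library`, `cohort`).
#' @param params an [rcseq_params()].
#' @param db optional `known_db` for the known-polymorphism annotation.
#' @return list with per-sample `runs`, pooled `calls` and `evidence`,
#'   classified `loci`, `presence`, `donor_table`, and `hallmarks`.
#' @export
run_pipeline <- function(dataset, params = rcseq_params(), db = NULL) {
  genome <- dataset$genome$genome
  runs <- list()
  for (s in names(dataset$reads)) {
    runs[[s]] <- call_sample(dataset$reads[[s]]$r1, dataset$reads[[s]]$r2,
                             genome, dataset$library, sample_id = s,
                             params = params)
  }
  calls <- do.call(rbind, lapply(runs, `[[`, "calls"))
  evidence <- do.call(rbind, lapply(runs, `[[`, "evidence"))
  row.names(calls) <- NULL; row.names(evidence) <- NULL
  for (s in names(runs)) {
    runs[[s]]$calls$inversion_len <- .call_inversions(
      runs[[s]]$calls, runs[[s]]$evidence, wobble = params$wobble)
  }
  calls <- do.call(rbind, lapply(runs, `[[`, "calls"))
  row.names(calls) <- NULL
  loci <- merge_call_loci(calls)
  samples <- c(dataset$cohort$tumor, dataset$cohort$nontumor)
  presence <- presence_matrix(loci, evidence, samples,
                              window = params$db_window)
  loci <- classify_calls(loci, presence, db, dataset$cohort,
                         db_window = params$db_window)
  donor_table <- tabulate_donor_counts(loci, presence, dataset$cohort)
  hallmarks <- characterize_calls(calls, genome, dataset$library,
                                  max_tsd = params$max_tsd)
  list(runs = runs, calls = calls, evidence = evidence, loci = loci,
       presence = presence, donor_table = donor_table, hallmarks = hallmarks)
}

#' Evaluate a pipeline run against simulator truth
#'
#' @param run output of [run_pipeline()].
#' @param dataset the [sim_dataset()] it was run on.
#' @param match_window call-to-truth matching window (nt, default 25).
#' @return list of metrics: eligible insertions (>= 2 usable unique
#'   fragments per side in some sample), recall on them, both-end
#'   breakpoint exactness for TPRT calls, TSD exactness, poly-A agreement
#'   within 2 nt, inversion sensitivity (blocks >= 30 nt), emitted calls at
#'   chimera loci, chimera-screen drop rate, and the classification
#'   confusion table.
#' @export
evaluate_run <- function(run, dataset, match_window = 25L) {
  truth <- dataset$truth
  calls <- run$calls
  n_ins <- nrow(truth)

  # eligibility: >= 2 unique usable fragments per junction in some sample
  eligible <- logical(n_ins)
  for (i in seq_len(n_ins)) {
    for (s in strsplit(truth$present_in[i], ";", fixed = TRUE)[[1L]]) {
      fr <- dataset$reads[[s]]$fragments
      fr <- fr[fr$insertion_id == truth$insertion_id[i] & fr$usable, , drop = FALSE]
      if (!nrow(fr)) next
      nl <- fr$outer[fr$junction == "left"]
      nr <- fr$outer[fr$junction == "right"]
      if (length(nl) && length(nr) &&
          count_unique_amplicons(nl) >= 2L && count_unique_amplicons(nr) >= 2L) {
        eligible[i] <- TRUE
        break
      }
    }
  }

  # truth matching per call
  call_truth <- rep(NA_integer_, nrow(calls))
  for (j in seq_len(nrow(calls))) {
    pos <- c(calls$bp5[j], calls$bp3[j])
    pos <- pos[!is.na(pos)]
    hit <- which(truth$family == calls$family[j] & truth$chrom == calls$chrom[j] &
                   (abs(truth$bp5 - pos[1L]) <= match_window |
                      abs(truth$bp3 - pos[length(pos)]) <= match_window))
    if (length(hit)) call_truth[j] <- hit[1L]
  }
  detected <- sort(unique(call_truth[!is.na(call_truth)]))
  recall_eligible <- if (any(eligible)) {
    mean(which(eligible) %in% detected)
  } else NA_real_

  both <- which(calls$ends_detected == "both" & !is.na(call_truth))
  tprt <- both[truth$mechanism[call_truth[both]] == "tprt_tsd"]
  bp_exact <- if (length(tprt)) {
    mean(calls$bp5[tprt] == truth$bp5[call_truth[tprt]] &
           calls$bp3[tprt] == truth$bp3[call_truth[tprt]])
  } else NA_real_

  tsd_exact <- if (length(both)) {
    got <- vapply(both, function(j) {
      d <- detect_tsd(calls$bp5[j], calls$bp3[j], calls$orientation[j])
      ti <- call_truth[j]
      isTRUE(d$tsd_len == truth$tsd_len[ti] &&
               d$deletion_len == truth$deletion_len[ti])
    }, logical(1))
    mean(got)
  } else NA_real_

  polya_ok <- if (length(both)) {
    mean(abs(calls$polya_len[both] - truth$polya_len[call_truth[both]]) <= 2,
         na.rm = TRUE)
  } else NA_real_

  # only inversions whose blocks fall inside the probe-targeted 5' terminus
  # region are visible to capture sequencing
  lib5 <- dataset$library[dataset$library$end_tag == "five_prime", , drop = FALSE]
  e5 <- stats::setNames(lib5$entry_len, lib5$family)
  inv_truth <- which(truth$inversion_len >= 30L &
                       truth$trunc + truth$inversion_len + 12L <=
                         e5[truth$family])
  inv_detected <- vapply(inv_truth, function(ti) {
    j <- which(call_truth == ti & calls$ends_detected == "both")
    length(j) > 0 && any(calls$inversion_len[j] > 0L)
  }, logical(1))
  inversion_sensitivity <- if (length(inv_truth)) mean(inv_detected) else NA_real_

  # chimeras
  chim_loci <- unique(do.call(rbind, lapply(dataset$reads, `[[`, "chimeras")))
  chim_calls <- 0L
  if (!is.null(chim_loci) && nrow(chim_loci) && nrow(calls)) {
    for (j in seq_len(nrow(calls))) {
      pos <- c(calls$bp5[j], calls$bp3[j])
      pos <- pos[!is.na(pos)]
      if (any(chim_loci$chrom == calls$chrom[j] &
                abs(chim_loci$locus - pos[1L]) <= match_window)) {
        chim_calls <- chim_calls + 1L
      }
    }
  }
  chim_ids <- unlist(lapply(names(run$runs), function(s) {
    ids <- dataset$reads[[s]]$r1$id
    sub("/1$", "", ids[grepl("_c_", ids)])
  }))
  reasons <- do.call(rbind, lapply(run$runs, `[[`, "rejects"))
  chim_seen <- reasons$contig_id %in% chim_ids
  n_chim_dropped <- sum(chim_seen & reasons$reason %in% c("chimera", "reference_event", "ambiguous"))
  n_chim_chimera <- sum(chim_seen & reasons$reason == "chimera")
  chim_evidence <- sum(run$evidence$contig_id %in% chim_ids)
  chimera_drop_rate <- if (n_chim_chimera + chim_evidence > 0) {
    n_chim_chimera / (n_chim_chimera + chim_evidence)
  } else NA_real_
  true_junction_chimera_drops <- sum(reasons$reason == "chimera" &
                                       grepl("_j_", reasons$contig_id))

  # classification confusion on matched loci
  loci <- run$loci
  loci_truth <- rep(NA_integer_, nrow(loci))
  for (j in seq_len(nrow(loci))) {
    pos <- c(loci$bp5[j], loci$bp3[j]); pos <- pos[!is.na(pos)]
    hit <- which(truth$family == loci$family[j] & truth$chrom == loci$chrom[j] &
                   (abs(truth$bp5 - pos[1L]) <= match_window |
                      abs(truth$bp3 - pos[length(pos)]) <= match_window))
    if (length(hit)) loci_truth[j] <- hit[1L]
  }
  ok <- !is.na(loci_truth)
  confusion <- table(truth_class = truth$class[loci_truth[ok]],
                     label = loci$label[ok])
  ts_as_private <- sum(truth$class[loci_truth[ok]] == "tumor_specific" &
                         loci$label[ok] == "private_germline")
  private_as_ts <- sum(truth$class[loci_truth[ok]] == "private_germline" &
                         loci$label[ok] == "tumor_specific_candidate")

  list(n_truth = n_ins, n_eligible = sum(eligible),
       recall_eligible = recall_eligible,
       breakpoint_exact_both = bp_exact, tsd_exact = tsd_exact,
       polya_within2 = polya_ok,
       inversion_sensitivity = inversion_sensitivity,
       chimera_locus_calls = chim_calls,
       chimera_drop_rate = chimera_drop_rate,
       n_chimera_dropped_any = n_chim_dropped,
       true_junction_chimera_drops = true_junction_chimera_drops,
       confusion = confusion,
       tumor_specific_called_private = ts_as_private,
       private_called_tumor_specific = private_as_ts)
}
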