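# Shared simulated datasets, built once per test session. The default
# cohort mirrors the package's standard study conditions: 1 Mb genome,
# 3 donors (T/NT pairs), 40 implanted insertions, 50x junction depth,
# 0.2 percent read error, fixed seed.

.sim_cache <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (!exists("full", .sim_cache)) {
    cfg <- sim_config(seed = 101L)
    ds <- sim_dataset(cfg)
    run <- run_pipeline(ds)
    .sim_cache$full <- list(cfg = cfg, ds = ds, run = run,
                            eval = evaluate_run(run, ds))
  }
  .sim_cache$full
}

# A small, fast cohort for unit-level end-to-end checks.
small_cohort <- function() {
  if (!exists("small", .sim_cache)) {
    cfg <- sim_config(genome_len = 2e5, n_decoys = 2L, n_donors = 2L,
                      n_germline = 3L, n_private = 3L, n_tumor_specific = 2L,
                      depth_per_junction = 25L, background_pairs = 100L,
                      seed = 7L)
    ds <- sim_dataset(cfg)
    run <- run_pipeline(ds)
    .sim_cache$small <- list(cfg = cfg, ds = ds, run = run,
                             eval = evaluate_run(run, ds))
  }
  .sim_cache$small
}

# The deterministic synthetic consensus library used throughout.
test_library <- function() sim_consensus_library()
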