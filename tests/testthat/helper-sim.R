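## One small simulated system shared across test files (built once per run).
.sim_cache <- new.env()

small_sim <- function() {
  if (!is.null(.sim_cache$sim)) return(.sim_cache$sim)
  cfg <- sim_config(seed = 42, n_chroms = 2, chrom_length = 8e5,
                    n_genes = 40, n_deletions_L = 16, n_deletions_S = 32,
                    n_p300 = 30, n_kolo = 10, pseudogene_fraction = 0.3,
                    nahr_fraction = 1)
  .sim_cache$sim <- simulate_system(cfg, file.path(tempdir(), "allofrac_sim"))
  .sim_cache$sim
}

## precision/recall of calls against the truth ledger, by retained genome
recovery_stats <- function(calls, truth) {
  tr <- truth[truth$retained_genome == attr(calls, "retained_genome"), ]
  key_t <- paste(tr$retained_chrom, tr$retained_start, tr$retained_end)
  key_c <- paste(calls$retained_chrom, calls$retained_start, calls$retained_end)
  list(precision = mean(key_c %in% key_t), recall = mean(key_t %in% key_c),
       n_calls = length(key_c), n_truth = length(key_t))
}
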