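# Shared fixture builders (all fixtures are generated in code).

fixture_library <- function(seed = 1L, ...) {
  build_toy_germline(20, 10, 6, seed = seed, ...)
}

# a compact library whose rearrangements are short enough for 150 bp mates
# to overlap and merge
fixture_short_library <- function(seed = 1L) {
  build_toy_germline(8, 5, 4, seed = seed,
                     v_len = c(150L, 180L), d_len = c(12L, 20L),
                     j_len = c(40L, 50L))
}

fixture_pair_tables <- function(seed, mode, n_reads = 20000L) {
  lib <- fixture_library(seed = derive_for_test(seed, 1))
  cfg <- simulation_config(seed = seed, mode = mode)
  sim <- simulate_tumor_pair(cfg, lib)
  list(
    diag = population_subclone_table(sim$diagnosis, n_reads,
                                     seed = derive_for_test(seed, 2)),
    relapse = population_subclone_table(sim$relapse, n_reads,
                                        seed = derive_for_test(seed, 3)),
    truth = sim$truth, lib = lib)
}

derive_for_test <- function(seed, k) (seed * 131 + k * 7) %% 100000 + 1

with_seed_chars <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
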