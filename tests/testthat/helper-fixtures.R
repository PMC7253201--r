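# Shared study-condition fixtures, computed once per test run and cached.
# The heavy acceptance experiments (branch-length fits at 1x and 10x over
# 10 seeds) are reused by several criteria.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

study_tree <- function() {
  cache_get("study_tree", function() build_unbalanced_timetree(16, 3))
}

# JC and GTR+G fits plus truth for 10 replicate seeds at one multiplier
study_fits <- function(multiplier, master_seed = 100, n_seeds = 10) {
  key <- sprintf("fits_m%g_s%d", multiplier, master_seed)
  cache_get(key, function() {
    tr <- study_tree()
    lapply(seq_len(n_seeds), function(s) {
      cfg <- simulation_config(rate_multiplier = multiplier,
                               seed = derive_seed(master_seed, s))
      aln <- evolve_alignment(tr, cfg)
      fit_c <- fit_branch_lengths(
        tr, aln,
        substitution_model("GTR", pi = unname(empirical_base_freqs(aln)),
                           gamma_shape = 0.25))
      fit_s <- fit_branch_lengths(tr, aln, substitution_model("JC"))
      list(cfg = cfg, truth = true_branch_lengths(tr, cfg),
           fit_complex = fit_c, fit_simple = fit_s)
    })
  })
}

small_sim <- function(n_tips = 8, seq_length = 1000, seed = 11,
                      rate_multiplier = 1) {
  key <- sprintf("sim_%d_%d_%d_%g", n_tips, seq_length, seed, rate_multiplier)
  cache_get(key, function() {
    tr <- build_unbalanced_timetree(n_tips, 3)
    cfg <- simulation_config(n_tips = n_tips, seq_length = seq_length,
                             seed = seed, rate_multiplier = rate_multiplier)
    list(tree = tr, cfg = cfg, aln = evolve_alignment(tr, cfg))
  })
}
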