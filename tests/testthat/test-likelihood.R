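test_that("identical sequences on a zero-length tree give lnL = -L log 4 under JC", {
  tr <- read_newick("((A:0,B:0):0,C:0);")
  aln <- alignment(c(A = "ACGTACG", B = "ACGTACG", C = "ACGTACG"))
  expect_equal(log_likelihood(tr, aln, substitution_model("JC")),
               -7 * log(4), tolerance = 1e-12)
})

test_that("pruning matches exhaustive enumeration on small trees", {
  # spot-check here (3 tips, two families); the full sweep over all 3- and
  # 4-tip topologies and every family runs in the acceptance suite
  trees <- random_length_topologies(3, seed = 5)
  aln <- random_alignment(c("t1", "t2", "t3"), 6, seed = 6)
  for (tr in trees[1:2]) {
    for (model in list(oracle_models()$GTR, with_gamma(oracle_models()$K2))) {
      expect_equal(log_likelihood(tr, aln, model), enum_loglik(tr, aln, model),
                   tolerance = 1e-8)
    }
  }
})

test_that("pattern compression is consistent: duplicated columns add their lnL", {
  sim <- small_sim(n_tips = 5, seq_length = 40, seed = 8)
  tr <- true_branch_lengths(sim$tree, sim$cfg)
  model <- substitution_model("HKY", pi = c(0.3, 0.3, 0.2, 0.2),
                              rates = c(kappa = 3))
  aln <- sim$aln
  col1 <- aln[, 1, drop = FALSE]
  dup <- alignment(cbind(unclass(aln), col1))
  lnl_col <- log_likelihood(tr, alignment(col1), model)
  expect_equal(log_likelihood(tr, dup, model),
               log_likelihood(tr, aln, model) + lnl_col, tolerance = 1e-9)
})

test_that("ambiguous states integrate over compatible bases", {
  tr <- read_newick("((A:0.1,B:0.2):0.1,C:0.3);")
  model <- substitution_model("JC")
  a1 <- alignment(c(A = "A", B = "N", C = "-"))
  # with both partners ambiguous the site is uninformative: P(A) = 1/4
  expect_equal(log_likelihood(tr, a1, model), log(0.25), tolerance = 1e-12)
})

test_that("own pruning agrees with the phangorn likelihood on fitted trees", {
  sim <- small_sim(n_tips = 6, seq_length = 400, seed = 15)
  model <- substitution_model("GTR", pi = unname(empirical_base_freqs(sim$aln)),
                              gamma_shape = 0.25)
  fit <- fit_branch_lengths(sim$tree, sim$aln, model)
  expect_equal(log_likelihood(fit$tree, sim$aln, fit$model), fit$lnL,
               tolerance = 1e-6)
})

test_that("discrete gamma with one category equals the plain model", {
  sim <- small_sim(n_tips = 5, seq_length = 60, seed = 23)
  tr <- true_branch_lengths(sim$tree, sim$cfg)
  plain <- substitution_model("K2", rates = c(kappa = 2))
  g1 <- substitution_model("K2", rates = c(kappa = 2), gamma_shape = 0.3,
                           gamma_categories = 1)
  expect_identical(log_likelihood(tr, sim$aln, g1),
                   log_likelihood(tr, sim$aln, plain))
})

test_that("two-sequence ML distance equals the closed form", {
  aln <- alignment(c(A = strrep("ACGT", 50), B = paste0(strrep("ACGT", 45),
                                                        strrep("AAAA", 5))))
  p <- mean(aln["A", ] != aln["B", ])
  tr <- read_newick("(A:0.1,B:0.1);")
  fit <- fit_branch_lengths(tr, aln, substitution_model("JC"))
  expect_equal(sum(fit$tree$edge.length), -0.75 * log(1 - 4 * p / 3),
               tolerance = 1e-5)
  ident <- alignment(c(A = "ACGTACGT", B = "ACGTACGT"))
  fit0 <- fit_branch_lengths(tr, ident, substitution_model("JC"))
  expect_lt(sum(fit0$tree$edge.length), 1e-6)
})

test_that("branch-length fits recover the clocklike truth", {
  sim <- small_sim(n_tips = 8, seq_length = 1000, seed = 11)
  model <- substitution_model("GTR", pi = unname(empirical_base_freqs(sim$aln)),
                              gamma_shape = 0.25)
  fit <- fit_branch_lengths(sim$tree, sim$aln, model)
  truth <- true_branch_lengths(sim$tree, sim$cfg)
  r <- regression_through_origin(truth$edge.length, fit$tree$edge.length)
  expect_gt(r$r_squared, 0.9)
  expect_gt(r$slope, 0.75)
  expect_lt(r$slope, 1.25)
  expect_true(all(fit$tree$edge.length >= 0))
  # topology preserved through the unrooted fit and re-rooting
  expect_identical(fit$tree$edge, sim$tree$edge)
})

test_that("optimized lnL is nondecreasing along the nesting ladder", {
  sim <- small_sim(n_tips = 6, seq_length = 400, seed = 15)
  fams <- c("JC", "K2", "HKY", "TN", "GTR")
  lnls <- vapply(fams, function(f) {
    pi <- if (f %in% c("JC", "K2")) rep(0.25, 4)
          else unname(empirical_base_freqs(sim$aln))
    fit_branch_lengths(sim$tree, sim$aln, substitution_model(f, pi = pi))$lnL
  }, 1.0)
  expect_true(all(diff(lnls) >= -1e-4))
  # adding free gamma can only help
  g <- fit_branch_lengths(sim$tree, sim$aln,
                          substitution_model("JC", gamma_shape = 0.5))
  expect_gte(g$lnL, lnls[["JC"]] - 1e-4)
})

test_that("delta_lnL follows the sign conventions", {
  sim <- small_sim(n_tips = 6, seq_length = 400, seed = 15)
  fit_jc <- fit_branch_lengths(sim$tree, sim$aln, substitution_model("JC"))
  fit_gtr <- fit_branch_lengths(
    sim$tree, sim$aln,
    substitution_model("GTR", pi = unname(empirical_base_freqs(sim$aln)),
                       gamma_shape = 0.25))
  expect_equal(delta_lnL(fit_jc, fit_jc), 0)
  expect_gt(delta_lnL(fit_gtr, fit_jc), 0)
  expect_lte(delta_lnL(fit_jc, fit_gtr), 0)
  other <- small_sim(n_tips = 5, seq_length = 60, seed = 23)
  fit_other <- fit_branch_lengths(other$tree, other$aln, substitution_model("JC"))
  expect_error(delta_lnL(fit_jc, fit_other), "same alignment")
})

test_that("UNREST nests GTR and stays inside its parameter box", {
  sim <- small_sim(n_tips = 6, seq_length = 300, seed = 21)
  fit_u <- fit_unrest(sim$tree, sim$aln)
  fit_g <- fit_branch_lengths(
    sim$tree, sim$aln,
    substitution_model("GTR", pi = unname(empirical_base_freqs(sim$aln))))
  expect_gte(fit_u$lnL, fit_g$lnL - 1e-6)
  rates <- fit_u$model$rates
  expect_true(all(rates > 0))
  # the root-edge pair is re-split by the package convention afterwards, so
  # only nonnegativity is guaranteed there; all lengths respect the upper box
  expect_true(all(fit_u$tree$edge.length >= 0))
  expect_true(all(fit_u$tree$edge.length <= 20))
})

test_that("UNREST branch lengths stay linear against JC on clocklike data", {
  sim <- small_sim(n_tips = 8, seq_length = 1000, seed = 21)
  fit_u <- fit_unrest(sim$tree, sim$aln)
  fit_j <- fit_branch_lengths(sim$tree, sim$aln, substitution_model("JC"))
  r <- regression_through_origin(fit_u$tree$edge.length, fit_j$tree$edge.length)
  expect_gt(r$r_squared, 0.9)
})
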