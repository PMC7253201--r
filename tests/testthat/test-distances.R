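test_that("pair counts classify matches, transitions and transversions", {
  pc <- pair_counts("ACGT", "GCGA")
  expect_equal(pc$valid_sites, 4)
  expect_equal(pc$diff, 2)
  expect_equal(pc$transitions, 1) # A<->G
  expect_equal(pc$transversions, 1) # T<->A
  expect_equal(pair_counts("ACGT", "ACGT")$diff, 0)
  # pairwise deletion: gap/N columns vanish
  pc2 <- pair_counts("AC-TN", "ACGTA")
  expect_equal(pc2$valid_sites, 3)
  expect_equal(nt_distance(pair_counts("AAAA", "----"), "JC"), NA_real_)
})

test_that("closed-form distances match frozen hand calculations", {
  mk <- function(n, diff, P1, P2, freq = c(A = .25, C = .25, G = .25, T = .25)) {
    structure(list(valid_sites = n, diff = diff, transitions = P1 + P2,
                   transversions = diff - P1 - P2, P1 = P1, P2 = P2,
                   freq = freq), class = "pair_counts")
  }
  # p = 0 -> d = 0 under every model
  for (m in c("p", "JC", "K2", "TN"))
    expect_equal(nt_distance(mk(100, 0, 0, 0), m), 0)
  # JC at p = 0.3: -0.75 log(0.6)
  expect_equal(nt_distance(mk(10, 3, 2, 1), "JC"), -0.75 * log(0.6),
               tolerance = 1e-12)
  # K2 at P = 0.1, Q = 0.1: -0.5 log(0.7) - 0.25 log(0.8)
  expect_equal(nt_distance(mk(10, 2, 1, 0), "K2"),
               -0.5 * log(0.7) - 0.25 * log(0.8), tolerance = 1e-12)
  # JC saturation p >= 3/4 is undefined, never negative or infinite
  expect_equal(nt_distance(mk(4, 3, 1, 1), "JC"), NA_real_)
  expect_equal(nt_distance(mk(100, 80, 30, 30), "JC"), NA_real_)
})

test_that("estimators invert their expected-proportion functions", {
  # forward: exact expected pair-state proportions at divergence d from the
  # joint distribution diag(pi) expm(Qd) (independent eigen route);
  # backward: the closed-form estimator must recover d
  models <- list(
    JC = list(model = substitution_model("JC"), est = "JC"),
    K2 = list(model = substitution_model("K2", rates = c(kappa = 4)), est = "K2"),
    TN = list(model = substitution_model("TN", pi = c(0.31, 0.33, 0.11, 0.25),
                                         rates = c(kappa1 = 3, kappa2 = 6)),
              est = "TN")
  )
  d_grid <- c(1e-4, 0.01, 0.1, 0.5, 1, 2, 3.5, 5)
  for (spec in models) {
    for (alpha in list(NULL, 0.25, 1)) {
      for (d in d_grid) {
        cts <- expected_pair_counts(spec$model, d, gamma_shape = alpha)
        est <- nt_distance(cts, spec$est, gamma_shape = alpha)
        expect_equal(est, d, tolerance = 1e-10,
                     label = sprintf("%s alpha=%s d=%g", spec$est,
                                     deparse(alpha), d))
      }
    }
  }
})

test_that("JC expected-p function and correction are mutual inverses", {
  for (d in seq(0, 5, by = 0.25)) {
    p <- jc_expected_p(d)
    cts <- structure(list(valid_sites = 1, diff = p, transitions = p / 2,
                          transversions = p / 2, P1 = p / 4, P2 = p / 4,
                          freq = c(A = .25, C = .25, G = .25, T = .25)),
                     class = "pair_counts")
    expect_equal(nt_distance(cts, "JC"), d, tolerance = 1e-10)
    expect_equal(nt_distance(cts, "JC", gamma_shape = 0.25),
                 0.75 * 0.25 * ((1 - 4 * p / 3)^(-4) - 1), tolerance = 1e-10)
  }
})

test_that("gamma corrections converge to the plain forms as alpha grows", {
  mk <- function(p) structure(
    list(valid_sites = 1, diff = p, transitions = p / 2, transversions = p / 2,
         P1 = p / 4, P2 = p / 4, freq = c(A = .25, C = .25, G = .25, T = .25)),
    class = "pair_counts")
  for (p in c(0.05, 0.2, 0.5)) {
    for (m in c("JC", "K2", "TN"))
      expect_equal(nt_distance(mk(p), m, gamma_shape = 1e6),
                   nt_distance(mk(p), m), tolerance = 1e-4)
  }
})

test_that("distance matrices agree with the reference implementation", {
  sim <- small_sim()
  aln <- sim$aln
  bin <- ape::as.DNAbin(tolower(unclass(aln)))
  # TN93 gets a looser bound: the reference uses alignment-wide base
  # frequencies where this package uses the frequencies of each pair
  for (pair in list(c("JC", "JC69", 1e-6), c("K2", "K80", 1e-6),
                    c("TN", "TN93", 5e-3))) {
    mine <- distance_matrix(aln, pair[1])
    ref <- as.matrix(ape::dist.dna(bin, model = pair[2],
                                   pairwise.deletion = TRUE))
    expect_equal(unclass(mine)[rownames(ref), colnames(ref)], ref,
                 tolerance = as.numeric(pair[3]), ignore_attr = TRUE,
                 label = pair[2])
  }
})

test_that("matrix summaries behave on small and degenerate input", {
  aln2 <- alignment(c(x = "ACGTACGTAC", y = "ACGTACGAAC"))
  D <- distance_matrix(aln2, "JC")
  expect_equal(sum(upper.tri(D)), 1)
  expect_equal(diag(unclass(D)), c(x = 0, y = 0))
  s <- percent_difference_summary(D, D)
  expect_equal(s$mean_percent, 0)
  aln3 <- alignment(c(x = "ACGTACGTAC", y = "ACGTACGAAC", z = "TCGTACGAAC"))
  D3 <- distance_matrix(aln3, "JC")
  s3 <- percent_difference_summary(D3, D3)
  expect_equal(s3$mean_percent, 0)
  expect_equal(s3$sd_percent, 0)
})

test_that("JC underestimates relative to TN+G on divergent simulated data", {
  sim <- small_sim(rate_multiplier = 10, seed = 13)
  d_jc <- suppressWarnings(distance_matrix(sim$aln, "JC"))
  d_tn <- suppressWarnings(distance_matrix(sim$aln, "TN", gamma_shape = 0.25))
  up <- upper.tri(d_jc)
  ok <- !is.na(d_jc[up]) & !is.na(d_tn[up])
  expect_true(all(d_jc[up][ok] <= d_tn[up][ok] + 1e-6))
  # curvilinear saturation: the JC-vs-TN relation bends downwards
  o <- order(d_tn[up][ok])
  x <- d_tn[up][ok][o]; y <- d_jc[up][ok][o]
  second_diff <- diff(diff(y) / diff(x))
  expect_lt(mean(second_diff), 0)
})
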