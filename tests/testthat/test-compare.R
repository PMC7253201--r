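test_that("through-origin regression matches hand arithmetic", {
  f <- regression_through_origin(c(1, 2, 3), c(2, 4, 6))
  expect_equal(f$slope, 2)
  expect_equal(f$r_squared, 1)
  f2 <- regression_through_origin(1:7, 1:7)
  expect_equal(c(f2$slope, f2$r_squared), c(1, 1))
  # slope 6/5, R^2 36/40
  f3 <- regression_through_origin(c(1, 2), c(2, 2))
  expect_equal(f3$slope, 1.2)
  expect_equal(f3$r_squared, 0.9)
  expect_error(regression_through_origin(c(0, 0), c(1, 2)), "undefined")
  expect_error(regression_through_origin(1, 2), "at least 2")
})

test_that("proportional data always regress to (c, 1)", {
  x <- withr::with_seed(3, stats::runif(25, 0.1, 5))
  for (c_ in c(0.2, 1, 17)) {
    f <- regression_through_origin(x, c_ * x)
    expect_equal(f$slope, c_, tolerance = 1e-12)
    expect_equal(f$r_squared, 1, tolerance = 1e-12)
  }
  expect_equal(glance(regression_through_origin(x, 2 * x))$n, 25)
})

test_that("mrae is a percent mean relative absolute error", {
  expect_equal(as.numeric(mrae(c(5, 5), c(5, 5))), 0)
  expect_equal(as.numeric(mrae(c(11, 18), c(10, 20))), 10)
  # scale invariance
  expect_equal(as.numeric(mrae(c(11, 18) * 7, c(10, 20) * 7)), 10)
  # zero complex times are excluded and counted
  m <- mrae(c(11, 18, 4), c(10, 20, 0))
  expect_equal(as.numeric(m), 10)
  expect_equal(attr(m, "n_excluded"), 1)
  expect_error(mrae(c(1, 2), c(0, 0)), "positive")
  expect_gte(as.numeric(mrae(c(1, 5), c(2, 3))), 0)
})

test_that("stratified slopes handle uniform and degenerate strata", {
  d <- tibble::tibble(x = rep(1:4, 3), y = rep(1:4, 3),
                      stratum = rep(c("a", "b", "c"), each = 4))
  out <- stratified_slopes(d)
  expect_equal(out$slope, rep(1, 3))
  single <- tibble::tibble(x = c(1, 2, 3), y = c(1, 2, 9),
                           stratum = c("a", "a", "lone"))
  out2 <- stratified_slopes(single)
  expect_true(is.na(out2$slope[out2$stratum == "lone"]))
  expect_equal(out2$n[out2$stratum == "lone"], 1)
})

test_that("interval overlap statistics use closed intervals", {
  s <- tibble::tibble(node = 1, lo = 1, hi = 3, point = 2)
  c_ <- tibble::tibble(node = 1, lo = 2, hi = 4, point = 3)
  out <- interval_overlap_stats(s, c_)
  expect_equal(unlist(out[1, 1:3], use.names = FALSE), c(1, 1, 1))
  # disjoint
  out2 <- interval_overlap_stats(
    tibble::tibble(node = 1, lo = 1, hi = 2, point = 1.5),
    tibble::tibble(node = 1, lo = 3, hi = 4, point = 3.5))
  expect_equal(unlist(out2[1, 1:3], use.names = FALSE), c(0, 0, 0))
  # boundary touch counts as overlap; containment at the boundary too
  out3 <- interval_overlap_stats(
    tibble::tibble(node = 1, lo = 1, hi = 2, point = 2),
    tibble::tibble(node = 1, lo = 2, hi = 3, point = 2))
  expect_equal(out3$intervals_overlap, 1)
  expect_equal(out3$complex_contains_simple_point, 1)
  expect_equal(out3$simple_contains_complex_point, 1)
  expect_error(interval_overlap_stats(s, tibble::tibble(node = 9, lo = 1,
                                                        hi = 2, point = 1)),
               "node sets")
})

test_that("comparison report regressions and tidier are coherent", {
  sim <- small_sim(n_tips = 8, seq_length = 1000, seed = 11)
  fit_c <- fit_branch_lengths(
    sim$tree, sim$aln,
    substitution_model("GTR", pi = unname(empirical_base_freqs(sim$aln)),
                       gamma_shape = 0.25))
  fit_s <- fit_branch_lengths(sim$tree, sim$aln, substitution_model("JC"))
  rep <- comparison_report(fit_s, fit_c)
  expect_lt(rep$branch_length_regression$slope, 1)
  expect_gt(rep$node_age_regression$r_squared, 0.9)
  expect_gt(rep$delta_lnL, 0)
  td <- tidy(rep)
  expect_true(all(c("statistic", "stratum", "value") %in% names(td)))
  expect_equal(td$value[td$statistic == "mrae_percent"], rep$mrae_percent)
  # self-comparison is exactly the identity
  self <- comparison_report(fit_c, fit_c)
  expect_equal(self$branch_length_regression$slope, 1)
  expect_equal(self$mrae_percent, 0)
  expect_equal(self$delta_lnL, 0)
})

test_that("model ladder reproduces the reference row and nesting order", {
  sim <- small_sim(n_tips = 6, seq_length = 400, seed = 15)
  tab <- model_ladder_experiment(sim$aln, sim$tree,
                                 families = c("JC", "K2", "GTR"))
  expect_equal(nrow(tab), 6)
  ref_row <- tab[tab$family == "GTR" & tab$gamma, ]
  expect_equal(ref_row$age_slope, 1, tolerance = 0.02)
  expect_gt(ref_row$age_r_squared, 0.999)
  # lnL nondecreasing in the nested no-gamma ladder
  nog <- tab[!tab$gamma, ]
  expect_true(all(diff(nog$lnL[match(c("JC", "K2", "GTR"), nog$family)]) >= -1e-4))
  expect_true(all(tab$age_r_squared >= 0.9))
})

test_that("subsampling experiment is nested, deterministic and degenerate at full size", {
  sim <- small_sim(n_tips = 12, seq_length = 300, seed = 19)
  res <- subsampling_experiment(sim$aln, sim$tree, sizes = c(6, 12),
                                n_reps = 3, seed = 5, models = "JC")
  expect_equal(nrow(res), 6)
  # full taxon set: no sampling left, zero dispersion across replicates
  full <- res$r_squared[res$size == 12]
  expect_equal(max(full) - min(full), 0)
  res2 <- subsampling_experiment(sim$aln, sim$tree, sizes = c(6, 12),
                                 n_reps = 3, seed = 5, models = "JC")
  expect_equal(res$r_squared, res2$r_squared)
  expect_error(subsampling_experiment(sim$aln, sim$tree, sizes = c(6, 13),
                                      n_reps = 2, seed = 1), "exceeds")
  expect_error(subsampling_experiment(sim$aln, sim$tree, sizes = c(12, 6),
                                      n_reps = 2, seed = 1), "increasing")
})

test_that("plot builders return ggplot objects", {
  sim <- small_sim(n_tips = 6, seq_length = 400, seed = 15)
  fit_c <- fit_branch_lengths(
    sim$tree, sim$aln,
    substitution_model("GTR", pi = unname(empirical_base_freqs(sim$aln)),
                       gamma_shape = 0.25))
  fit_s <- fit_branch_lengths(sim$tree, sim$aln, substitution_model("JC"))
  rep <- comparison_report(fit_s, fit_c)
  expect_s3_class(autoplot(rep), "ggplot")
  expect_s3_class(plot_through_origin(fit_c$tree$edge.length,
                                      fit_s$tree$edge.length), "ggplot")
  expect_s3_class(plot_age_comparison(relative_times(fit_s$tree),
                                      relative_times(fit_c$tree)), "ggplot")
})
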