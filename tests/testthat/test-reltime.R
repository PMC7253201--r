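test_that("clocklike input returns the true relative ages", {
  ch <- relative_times(read_newick("((A:1,B:1):1,C:2);"), normalize = FALSE)
  ages <- tidy(ch)
  expect_equal(ages$age[ages$is_tip], rep(0, 3))
  expect_setequal(round(ages$age[!ages$is_tip], 10), c(2, 1))
  chn <- relative_times(read_newick("((A:1,B:1):1,C:2);"))
  expect_setequal(round(relchron:::internal_ages(chn), 10),
                  round(c(2 / 3, 1 / 3), 10))
})

test_that("the relative-rate recursion matches the hand-worked example", {
  # H(inner) = ((2+0) + (1+0))/2 = 1.5; L = 1 + 1.5 = 2.5;
  # H(root) = (2.5 + 2)/2 = 2.25; age(inner) = 2.25 * 1.5/2.5 = 1.35
  ch <- relative_times(read_newick("((A:2,B:1):1,C:2);"), normalize = FALSE)
  expect_equal(sort(relchron:::internal_ages(ch)), c(1.35, 2.25))
  chn <- relative_times(read_newick("((A:2,B:1):1,C:2);"))
  expect_equal(sort(relchron:::internal_ages(chn)), c(0.375, 0.625))
})

test_that("normalized ages are invariant to rescaling all branch lengths", {
  tr <- withr::with_seed(31, ape::rtree(12))
  base <- relative_times(tr)$ages
  for (c_ in c(0.01, 3, 250)) {
    scaled <- tr
    scaled$edge.length <- tr$edge.length * c_
    expect_equal(relative_times(scaled)$ages, base, tolerance = 1e-12)
  }
})

test_that("relative times are exact on clocklike trees of any shape", {
  for (seed in 1:20) {
    n <- withr::with_seed(seed, sample(4:30, 1))
    tt <- withr::with_seed(seed + 1000, ape::rcoal(n))
    rate <- withr::with_seed(seed + 2000, stats::runif(1, 0.01, 2))
    ptree <- tt
    ptree$edge.length <- tt$edge.length * rate
    ch <- relative_times(ptree, normalize = FALSE)
    true_age <- node_ages(tt)$age
    # equal up to the single global rate
    expect_equal(ch$ages, true_age * rate, tolerance = 1e-10)
  }
})

test_that("degenerate and invalid inputs are handled explicitly", {
  zero <- read_newick("((A:0,B:0):0,C:0);")
  expect_warning(ch <- relative_times(zero), "zero")
  expect_true(all(ch$ages == 0))
  poly <- ape::read.tree(text = "((A:1,B:1,C:1):1,D:2);")
  expect_error(relative_times(poly), "binary")
  tr <- read_newick("((A:1,B:1):1,OUT:2);")
  expect_error(relative_times(tr, outgroup = "OUT"), "outgroup")
  pruned <- prune_outgroup(tr, "OUT")
  # a 2-tip remainder is a degenerate cherry but still dates
  expect_s3_class(relative_times(pruned, outgroup = "OUT"), "chronogram")
})

test_that("branch durations telescope to the root age", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  ch <- relative_times(tr, normalize = FALSE)
  bt <- branch_times(ch)
  expect_true(all(bt$duration >= 0))
  inner <- 5L
  expect_equal(bt$duration[bt$child == inner], 1)
  expect_equal(bt$duration[bt$child == 3L], 2) # tip branch of C spans root age
  # durations along every root-to-tip path sum to the root age
  for (tip in 1:3) {
    path <- tip
    total <- 0
    while (path != 4L) {
      i <- which(tr$edge[, 2] == path)
      total <- total + bt$duration[i]
      path <- tr$edge[i, 1]
    }
    expect_equal(total, 2)
  }
})

test_that("bootstrap intervals contain the point estimate and honour the seed", {
  sim <- small_sim(n_tips = 6, seq_length = 300, seed = 21)
  model <- substitution_model("JC")
  # resampling disabled: every replicate identical, zero-width intervals
  stub <- bootstrap_intervals(sim$tree, sim$aln, model, n_reps = 2, seed = 1,
                              resample = FALSE)
  expect_equal(stub$intervals$lo, stub$ages, tolerance = 1e-12)
  expect_equal(stub$intervals$hi, stub$ages, tolerance = 1e-12)

  b1 <- bootstrap_intervals(sim$tree, sim$aln, model, n_reps = 10, seed = 42)
  expect_true(all(b1$intervals$lo <= b1$ages + 1e-12))
  expect_true(all(b1$intervals$hi >= b1$ages - 1e-12))
  b2 <- bootstrap_intervals(sim$tree, sim$aln, model, n_reps = 10, seed = 42)
  expect_identical(b1$intervals, b2$intervals)
  td <- tidy(b1)
  expect_true(all(c("lo", "hi") %in% names(td)))
})

test_that("bootstrap intervals cover the truth on clocklike simulations", {
  sim <- small_sim(n_tips = 8, seq_length = 1000, seed = 11)
  b <- bootstrap_intervals(sim$tree, sim$aln, substitution_model("JC"),
                           n_reps = 40, seed = 7)
  tt <- node_ages(sim$tree)
  truth <- tt$age / sum(tt$age[!tt$is_tip])
  internal <- which(!tt$is_tip)
  covered <- mean(b$intervals$lo[internal] - 1e-9 <= truth[internal] &
                  truth[internal] <= b$intervals$hi[internal] + 1e-9)
  expect_gte(covered, 0.7)
})
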