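#' Linear regression through the origin
#'
#' Fits `y = b x` with no intercept: `b = sum(xy) / sum(x^2)`. The coefficient
#' of determination is the squared uncentered correlation
#' `(sum(xy))^2 / (sum(x^2) sum(y^2))`, which is bounded in `[0, 1]` and
#' symmetric in x and y.
#'
#' @param x,y Paired finite numeric vectors (n >= 2).
#' @return An object of class `rto_fit` with fields `slope`, `r_squared`, `n`.
#' @examples
#' regression_through_origin(c(1, 2, 3), c(2, 4, 6)) # slope 2, R^2 1
#' @export
regression_through_origin <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must be paired.")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) abort("need at least 2 finite pairs.")
  sxx <- sum(x^2)
  if (sxx == 0) abort("sum(x^2) is zero; through-origin slope undefined.")
  sxy <- sum(x * y)
  syy <- sum(y^2)
  structure(
    list(slope = sxy / sxx,
         r_squared = if (syy == 0) as.numeric(sxy == 0) else (sxy^2) / (sxx * syy),
         n = length(x)),
    class = "rto_fit"
  )
}

#' @export
print.rto_fit <- function(x, ...) {
  cat(sprintf("<through-origin fit: slope %.4f, R^2 %.4f, n %d>\n",
              x$slope, x$r_squared, x$n))
  invisible(x)
}

#' @rdname tidiers
#' @method tidy rto_fit
#' @export
tidy.rto_fit <- function(x, ...) {
  tibble(term = "slope", estimate = x$slope)
}

#' @rdname tidiers
#' @method glance rto_fit
#' @export
glance.rto_fit <- function(x, ...) {
  tibble(slope = x$slope, r_squared = x$r_squared, n = x$n)
}

#' Mean relative absolute error between paired node times, in percent
#'
#' `100/n * sum(|t_s - t_c| / t_c)` over nodes with `t_c > 0` (the
#' complex-model time is the denominator); nodes with `t_c = 0` are excluded
#' and counted in the `n_excluded` attribute. Invariant under joint rescaling
#' of both vectors.
#'
#' @param times_simple,times_complex Paired node times.
#' @return Percent MRAE (single numeric) with attribute `n_excluded`.
#' @export
mrae <- function(times_simple, times_complex) {
  if (length(times_simple) != length(times_complex))
    abort("time vectors must be paired.")
  ok <- is.finite(times_simple) & is.finite(times_complex) & times_complex > 0
  if (!any(ok)) abort("no nodes with positive complex-model time.")
  val <- 100 * mean(abs(times_simple[ok] - times_complex[ok]) / times_complex[ok])
  structure(val, n_excluded = sum(!ok))
}

#' Through-origin slopes within strata
#'
#' One regression per stratum (e.g. branch category or depth region, computed
#' on the complex-model estimates). Strata with fewer than 2 points are
#' reported with `NA` slope rather than raising.
#'
#' @param data A data frame with numeric columns `x` and `y` and a `stratum`
#'   column (factor or character).
#' @return A tibble with `stratum`, `slope`, `r_squared`, `n`.
#' @export
stratified_slopes <- function(data) {
  stopifnot(all(c("x", "y", "stratum") %in% names(data)))
  lv <- if (is.factor(data$stratum)) levels(data$stratum) else unique(data$stratum)
  purrr::map_dfr(lv, function(s) {
    d <- data[data$stratum == s, , drop = FALSE]
    if (nrow(d) < 2 || sum(d$x^2) == 0) {
      tibble(stratum = s, slope = NA_real_, r_squared = NA_real_, n = nrow(d))
    } else {
      f <- regression_through_origin(d$x, d$y)
      tibble(stratum = s, slope = f$slope, r_squared = f$r_squared, n = f$n)
    }
  })
}

#' Interval overlap statistics between two sets of node-age intervals
#'
#' Over matched nodes: the proportion of pairs of closed intervals that
#' intersect (boundary touching counts), the proportion where the
#' complex-model interval contains the simple-model point estimate, and vice
#' versa.
#'
#' @param simple,complex Data frames with columns `node`, `lo`, `hi`, `point`
#'   (one row per node; same node sets).
#' @return A one-row tibble: `intervals_overlap`,
#'   `complex_contains_simple_point`, `simple_contains_complex_point`, `n`.
#' @export
interval_overlap_stats <- function(simple, complex) {
  need <- c("node", "lo", "hi", "point")
  stopifnot(all(need %in% names(simple)), all(need %in% names(complex)))
  if (!setequal(simple$node, complex$node))
    abort("interval tables cover different node sets.")
  s <- simple[order(simple$node), ]
  c_ <- complex[order(complex$node), ]
  if (any(s$lo > s$hi) || any(c_$lo > c_$hi)) abort("intervals must have lo <= hi.")
  tibble(
    intervals_overlap = mean(s$lo <= c_$hi & c_$lo <= s$hi),
    complex_contains_simple_point = mean(c_$lo <= s$point & s$point <= c_$hi),
    simple_contains_complex_point = mean(s$lo <= c_$point & c_$point <= s$hi),
    n = nrow(s)
  )
}

#' Full comparison report between simple- and complex-model estimates
#'
#' Packages the comparison statistics for a pair of fitted trees on the same
#' topology: the global through-origin regression of branch lengths
#' (simple ~ complex), MRAE of normalized relative node ages, slopes
#' stratified by branch category (lengths and branch durations) and by depth
#' region (node-to-tip distances and node ages), and — when both interval
#' tables are supplied — interval overlap proportions. All strata are defined
#' on the complex-model estimates.
#'
#' @param fit_simple,fit_complex Two [fit_branch_lengths()] results on the
#'   same topology.
#' @param intervals_simple,intervals_complex Optional interval tables (see
#'   [interval_overlap_stats()]).
#' @param shallow_frac,deep_frac Depth-region boundaries (fractions of root
#'   age of the complex-model chronogram).
#' @return An object of class `relchron_report` (a list of tibbles and
#'   scalars; see [tidy.relchron_report()]).
#' @export
comparison_report <- function(fit_simple, fit_complex,
                              intervals_simple = NULL, intervals_complex = NULL,
                              shallow_frac = 0.3, deep_frac = 0.7) {
  stopifnot(inherits(fit_simple, "ml_fit"), inherits(fit_complex, "ml_fit"))
  ts <- fit_simple$tree
  tc <- fit_complex$tree
  if (!identical(ts$edge, tc$edge) || !identical(ts$tip.label, tc$tip.label))
    abort("fits must share one topology object.")
  # branch lengths
  reg <- regression_through_origin(tc$edge.length, ts$edge.length)
  # chronograms (normalized)
  ch_s <- relative_times(ts)
  ch_c <- relative_times(tc)
  age_s <- internal_ages(ch_s)
  age_c <- internal_ages(ch_c)
  reg_ages <- regression_through_origin(age_c, age_s)
  m <- mrae(age_s, age_c)
  # branch strata on the complex tree
  bc <- classify_branches(tc)
  strat_len <- stratified_slopes(tibble(
    x = tc$edge.length, y = ts$edge.length, stratum = bc$category))
  bt_s <- branch_times(ch_s)$duration
  bt_c <- branch_times(ch_c)$duration
  strat_bt <- stratified_slopes(tibble(x = bt_c, y = bt_s, stratum = bc$category))
  # depth strata on the complex chronogram
  chron_tree <- tc
  chron_tree$edge.length <- bt_c
  dr <- classify_node_depths(chron_tree, shallow_frac, deep_frac)
  ntd_s <- node_to_tip_distances(ts)
  ntd_c <- node_to_tip_distances(tc)
  strat_ntd <- stratified_slopes(tibble(
    x = ntd_c$distance, y = ntd_s$distance,
    stratum = dr$region[match(ntd_c$node, dr$node)]))
  strat_age <- stratified_slopes(tibble(
    x = age_c, y = age_s,
    stratum = dr$region[match(seq_along(age_c) + n_tips(tc), dr$node)]))
  overlap <- if (!is.null(intervals_simple) && !is.null(intervals_complex))
    interval_overlap_stats(intervals_simple, intervals_complex) else NULL
  structure(
    list(
      models = c(simple = paste0(fit_simple$model$family,
                                 if (is.null(fit_simple$model$gamma)) "" else "+G"),
                 complex = paste0(fit_complex$model$family,
                                  if (is.null(fit_complex$model$gamma)) "" else "+G")),
      branch_length_regression = glance(reg),
      node_age_regression = glance(reg_ages),
      mrae_percent = as.numeric(m),
      mrae_excluded = attr(m, "n_excluded"),
      slopes_by_branch_category = list(lengths = strat_len, branch_times = strat_bt),
      slopes_by_depth_region = list(node_to_tip = strat_ntd, ages = strat_age),
      overlap = overlap,
      delta_lnL = fit_complex$lnL - fit_simple$lnL
    ),
    class = "relchron_report"
  )
}

#' @export
print.relchron_report <- function(x, ...) {
  cat(sprintf("<comparison report: %s (simple) vs %s (complex)>\n",
              x$models[["simple"]], x$models[["complex"]]))
  cat(sprintf("  branch lengths : slope %.4f, R^2 %.4f (n=%d)\n",
              x$branch_length_regression$slope,
              x$branch_length_regression$r_squared,
              x$branch_length_regression$n))
  cat(sprintf("  node ages      : slope %.4f, R^2 %.4f; MRAE %.2f%%\n",
              x$node_age_regression$slope, x$node_age_regression$r_squared,
              x$mrae_percent))
  cat(sprintf("  delta lnL (complex - simple): %.2f\n", x$delta_lnL))
  invisible(x)
}

#' Tidy a comparison report
#'
#' @param x A `relchron_report`.
#' @param ... Unused.
#' @return A long tibble with columns `statistic`, `stratum`, `value`.
#' @rdname tidiers
#' @method tidy relchron_report
#' @export
tidy.relchron_report <- function(x, ...) {
  rows <- list(
    tibble(statistic = "branch_length_slope", stratum = "all",
           value = x$branch_length_regression$slope),
    tibble(statistic = "branch_length_r_squared", stratum = "all",
           value = x$branch_length_regression$r_squared),
    tibble(statistic = "node_age_slope", stratum = "all",
           value = x$node_age_regression$slope),
    tibble(statistic = "node_age_r_squared", stratum = "all",
           value = x$node_age_regression$r_squared),
    tibble(statistic = "mrae_percent", stratum = "all", value = x$mrae_percent),
    tibble(statistic = "delta_lnL", stratum = "all", value = x$delta_lnL),
    dplyr::transmute(x$slopes_by_branch_category$lengths,
                     statistic = "branch_length_slope",
                     stratum = as.character(.data$stratum), value = .data$slope),
    dplyr::transmute(x$slopes_by_branch_category$branch_times,
                     statistic = "branch_time_slope",
                     stratum = as.character(.data$stratum), value = .data$slope),
    dplyr::transmute(x$slopes_by_depth_region$node_to_tip,
                     statistic = "node_to_tip_slope",
                     stratum = as.character(.data$stratum), value = .data$slope),
    dplyr::transmute(x$slopes_by_depth_region$ages,
                     statistic = "node_age_slope",
                     stratum = as.character(.data$stratum), value = .data$slope)
  )
  if (!is.null(x$overlap)) {
    rows <- c(rows, list(tibble(
      statistic = c("intervals_overlap", "complex_contains_simple_point",
                    "simple_contains_complex_point"),
      stratum = "all",
      value = c(x$overlap$intervals_overlap,
                x$overlap$complex_contains_simple_point,
                x$overlap$simple_contains_complex_point)
    )))
  }
  dplyr::bind_rows(rows)
}

#' Model-ladder experiment
#'
#' Fits branch lengths under each family in the ladder JC, K2, HKY, TN, GTR,
#' each with and without gamma rate heterogeneity, computes the normalized
#' relative chronogram for each, and regresses its internal-node ages (and
#' branch lengths) against the reference model's (GTR+Gamma by default).
#'
#' @param aln Alignment matrix.
#' @param tree Rooted binary topology.
#' @param reference_model Reference [substitution_model()] (default GTR+G
#'   with shape free, 4 categories).
#' @param families Ladder families (default `c("JC","K2","HKY","TN","GTR")`).
#' @param gamma_shape Starting shape for the +Gamma fits (default 0.5; the
#'   shape is optimized).
#' @return A tibble with one row per (family, gamma): `family`, `gamma`,
#'   `lnL`, `age_slope`, `age_r_squared`, `length_slope`, `length_r_squared`.
#' @export
model_ladder_experiment <- function(aln, tree,
                                    reference_model = substitution_model(
                                      "GTR", pi = unname(empirical_base_freqs(aln)),
                                      gamma_shape = 0.5),
                                    families = c("JC", "K2", "HKY", "TN", "GTR"),
                                    gamma_shape = 0.5) {
  fit_ref <- fit_branch_lengths(tree, aln, reference_model)
  ch_ref <- relative_times(fit_ref$tree)
  age_ref <- internal_ages(ch_ref)
  grid <- tidyr::expand_grid(family = families, gamma = c(FALSE, TRUE))
  purrr::pmap_dfr(grid, function(family, gamma) {
    mod <- substitution_model(
      family,
      pi = if (family %in% c("JC", "K2")) rep(0.25, 4)
           else unname(empirical_base_freqs(aln)),
      gamma_shape = if (gamma) gamma_shape else NULL
    )
    fit <- fit_branch_lengths(tree, aln, mod)
    ch <- relative_times(fit$tree)
    ra <- regression_through_origin(age_ref, internal_ages(ch))
    rl <- regression_through_origin(fit_ref$tree$edge.length, fit$tree$edge.length)
    tibble(family = family, gamma = gamma, lnL = fit$lnL,
           age_slope = ra$slope, age_r_squared = ra$r_squared,
           length_slope = rl$slope, length_r_squared = rl$r_squared)
  })
}

#' Nested-subsampling dispersion experiment
#'
#' Measures how the linearity between simple- and reference-model branch
#' lengths tightens as more taxa are sampled. Per replicate, a random taxon
#' permutation defines nested subsets at the requested sizes (larger sets
#' contain smaller ones; designated outgroup taxa are always included). For
#' each subset and each simple model, branch lengths are fitted on the induced
#' subtree and regressed through the origin against the reference
#' (GTR+Gamma) branch lengths fitted on the same subtree.
#'
#' To keep per-subset cost down, the reference model's exchangeabilities and
#' gamma shape are estimated once on the full alignment and held fixed across
#' subsets (only branch lengths are re-optimized), as are each simple family's
#' free parameters.
#'
#' @param aln Alignment matrix.
#' @param tree Rooted binary topology for the full taxon set.
#' @param sizes Increasing ingroup sizes.
#' @param n_reps Number of nested-sampling replicates (default 20).
#' @param seed Integer seed.
#' @param models Simple-model families to compare (default: the whole ladder
#'   JC, K2, HKY, TN, GTR; pass `"JC"` alone for the fastest contrast).
#' @param gamma_shape Starting gamma shape for the reference fit.
#' @param outgroup Tip labels always kept in every subset.
#' @return A tibble: `replicate`, `size`, `model`, `r_squared`, `slope`.
#' @export
subsampling_experiment <- function(aln, tree, sizes, n_reps = 20, seed,
                                   models = c("JC", "K2", "HKY", "TN", "GTR"),
                                   gamma_shape = 0.5,
                                   outgroup = character(0)) {
  if (missing(seed)) abort("`seed` is mandatory.")
  if (is.unsorted(sizes, strictly = TRUE)) abort("`sizes` must be increasing.")
  ingroup <- setdiff(tree$tip.label, outgroup)
  if (max(sizes) > length(ingroup)) abort("largest size exceeds available ingroup taxa.")
  # alignment-level reference parameters, estimated once
  ref_model <- substitution_model("GTR", pi = unname(empirical_base_freqs(aln)),
                                  gamma_shape = gamma_shape)
  ref_fit <- fit_branch_lengths(tree, aln, ref_model)
  ref_model <- ref_fit$model
  simple_models <- lapply(stats::setNames(models, models), function(fam) {
    mod <- substitution_model(
      fam,
      pi = if (fam %in% c("JC", "K2")) rep(0.25, 4)
           else unname(empirical_base_freqs(aln)))
    if (fam == "JC") mod else fit_branch_lengths(tree, aln, mod)$model
  })
  out <- purrr::map_dfr(seq_len(n_reps), function(rep_i) {
    perm <- with_seed(derive_seed(seed, rep_i), sample(ingroup))
    purrr::map_dfr(sizes, function(sz) {
      taxa <- c(perm[seq_len(sz)], outgroup)
      sub_tree <- ape::keep.tip(tree, taxa)
      sub_aln <- aln[sub_tree$tip.label, , drop = FALSE]
      class(sub_aln) <- c("relchron_alignment", "matrix", "array")
      fit_ref <- fit_branch_lengths(sub_tree, sub_aln, ref_model,
                                    free_params = FALSE, free_alpha = FALSE)
      purrr::map_dfr(models, function(fam) {
        fit_m <- fit_branch_lengths(sub_tree, sub_aln, simple_models[[fam]],
                                    free_params = FALSE, free_alpha = FALSE)
        r <- regression_through_origin(fit_ref$tree$edge.length,
                                       fit_m$tree$edge.length)
        tibble(replicate = rep_i, size = sz, model = fam,
               r_squared = r$r_squared, slope = r$slope)
      })
    })
  })
  class(out) <- c("relchron_subsampling", class(out))
  out
}
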