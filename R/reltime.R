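#' Calibration-free relative divergence times
#'
#' Estimates relative node ages from a rooted tree with branch lengths in
#' substitutions/site, using a relative-rate recursion: bottom-up, every tip
#' has mean lineage depth `H = 0`, and an internal node with children `j, k`
#' over branches `b_j, b_k` gets `H = ((b_j + H_j) + (b_k + H_k)) / 2` — each
#' lineage's depth is rate-adjusted by averaging the two sister estimates.
#' Top-down, the root's age is its `H`, and each child's age is the parent
#' age scaled by `H_child / (b_child + H_child)` (its share of the lineage
#' depth). On clocklike input this recovers the true relative ages exactly.
#' This is a RelTime-style estimator (arithmetic-mean variant), not a clone
#' of any particular implementation.
#'
#' Ages are dimensionless; with `normalize = TRUE` they are scaled so the
#' internal-node ages sum to 1, which makes chronograms from different models
#' directly comparable.
#'
#' @param tree Rooted binary `phylo` with nonnegative branch lengths; any
#'   outgroup must already be pruned (see [prune_outgroup()]).
#' @param normalize Scale ages so internal-node ages sum to 1 (default TRUE).
#' @param outgroup Optional character vector; if any of these taxa are still
#'   in the tree the call is refused.
#' @return An object of class `chronogram`: list with `tree` (topology),
#'   `ages` (per-node relative ages, tips 0), `normalization` (the sum of raw
#'   internal ages), `intervals` (NULL until [bootstrap_intervals()]).
#' @export
relative_times <- function(tree, normalize = TRUE, outgroup = NULL) {
  validate_phylotree(tree)
  if (!is.null(outgroup) && any(outgroup %in% tree$tip.label))
    abort("tree still contains outgroup taxa; prune them before dating.")
  nt <- n_tips(tree)
  nn <- nt + tree$Nnode
  H <- lineage_depths(tree)
  if (all(H[(nt + 1):nn] == 0)) {
    warn("all branch lengths are zero; all relative ages are 0.")
    ages <- rep(0, nn)
    norm <- 1
  } else {
    ages <- rep(NA_real_, nn)
    ages[seq_len(nt)] <- 0
    root <- root_node(tree)
    ages[root] <- H[root]
    for (i in reorder_edges_preorder(tree)) {
      par <- tree$edge[i, 1]; chd <- tree$edge[i, 2]
      if (chd <= nt) { ages[chd] <- 0; next }
      Lc <- tree$edge.length[i] + H[chd]
      if (Lc == 0) {
        warn("zero-length lineage: child age collapses to 0.")
        ages[chd] <- 0
      } else {
        ages[chd] <- ages[par] * H[chd] / Lc
      }
    }
    norm <- sum(ages[(nt + 1):nn])
    if (normalize && norm > 0) ages <- ages / norm
  }
  structure(
    list(tree = tree, ages = ages, normalization = norm,
         normalized = isTRUE(normalize), intervals = NULL),
    class = "chronogram"
  )
}

#' @export
print.chronogram <- function(x, ...) {
  cat(sprintf("<chronogram: %d tips, root age %.4g%s%s>\n",
              n_tips(x$tree), x$ages[root_node(x$tree)],
              if (x$normalized) " (normalized)" else "",
              if (is.null(x$intervals)) "" else ", with intervals"))
  invisible(x)
}

#' @rdname tidiers
#' @method tidy chronogram
#' @export
tidy.chronogram <- function(x, ...) {
  nt <- n_tips(x$tree)
  nn <- nt + x$tree$Nnode
  out <- tibble(
    node = seq_len(nn),
    label = c(x$tree$tip.label, rep("", x$tree$Nnode)),
    is_tip = seq_len(nn) <= nt,
    age = x$ages
  )
  if (!is.null(x$intervals)) {
    out$lo <- x$intervals$lo[out$node]
    out$hi <- x$intervals$hi[out$node]
  }
  out
}

# internal-node ages of a chronogram, in node-id order
internal_ages <- function(chron) {
  nt <- n_tips(chron$tree)
  chron$ages[(nt + 1):(nt + chron$tree$Nnode)]
}

#' Branch durations of a chronogram
#'
#' @param chron A [relative_times()] result.
#' @return A tibble with `parent`, `child`, `duration`
#'   (`age(parent) - age(child)`, >= 0).
#' @export
branch_times <- function(chron) {
  stopifnot(inherits(chron, "chronogram"))
  tibble(
    parent = chron$tree$edge[, 1],
    child = chron$tree$edge[, 2],
    duration = chron$ages[chron$tree$edge[, 1]] - chron$ages[chron$tree$edge[, 2]]
  )
}

#' Bootstrap intervals for relative node ages
#'
#' Site-resampling bootstrap: resample alignment columns with replacement,
#' refit branch lengths under the same model, recompute relative times, and
#' take percentile intervals per node. The observed point estimate is included
#' in the replicate pool, so every interval contains the point estimate.
#'
#' @param tree Rooted binary topology.
#' @param aln Alignment matrix.
#' @param model A [substitution_model()].
#' @param n_reps Number of bootstrap replicates (>= 2).
#' @param seed Integer seed (replicate seeds are derived with [derive_seed()]).
#' @param level Interval level (default 0.95).
#' @param resample Set `FALSE` to disable resampling (all replicates identical;
#'   degenerate zero-width intervals — useful for testing the machinery).
#' @param normalize Passed to [relative_times()].
#' @return A `chronogram` whose `intervals` element holds `lo` and `hi` per
#'   node plus `level`, `n_reps` and `n_failed` (degenerate replicates).
#' @export
bootstrap_intervals <- function(tree, aln, model, n_reps = 100, seed,
                                level = 0.95, resample = TRUE,
                                normalize = TRUE) {
  if (missing(seed)) abort("`seed` is mandatory.")
  if (n_reps < 2) abort("`n_reps` must be >= 2.")
  point_fit <- fit_branch_lengths(tree, aln, model)
  point <- relative_times(point_fit$tree, normalize = normalize)
  nn <- n_tips(tree) + tree$Nnode
  ages <- matrix(NA_real_, nrow = n_reps + 1L, ncol = nn)
  ages[1, ] <- point$ages
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    sites <- if (resample)
      with_seed(derive_seed(seed, r), sample.int(ncol(aln), ncol(aln), replace = TRUE))
    else seq_len(ncol(aln))
    rep_res <- tryCatch({
      fit <- fit_branch_lengths(tree, subset_sites(aln, sites), model)
      relative_times(fit$tree, normalize = normalize)$ages
    }, error = function(e) NULL)
    if (is.null(rep_res)) n_failed <- n_failed + 1L else ages[r + 1L, ] <- rep_res
  }
  a <- (1 - level) / 2
  lo <- apply(ages, 2, stats::quantile, probs = a, na.rm = TRUE, names = FALSE)
  hi <- apply(ages, 2, stats::quantile, probs = 1 - a, na.rm = TRUE, names = FALSE)
  out <- point
  out$intervals <- list(lo = pmin(lo, point$ages), hi = pmax(hi, point$ages),
                        level = level, n_reps = n_reps, n_failed = n_failed)
  out
}
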