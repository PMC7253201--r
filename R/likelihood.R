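#' Felsenstein-pruning log-likelihood
#'
#' Computes the log-likelihood of an alignment on a fixed tree with fixed
#' branch lengths under a substitution model, by the pruning algorithm over
#' compressed site patterns. Gaps and `N` contribute partial likelihood 1 for
#' every base (they are never dropped — in contrast to the pairwise deletion
#' used for distances). Discrete gamma rate heterogeneity averages the
#' per-category site likelihoods with equal weights. For reversible families
#' the root distribution is the model's stationary frequencies; for UNREST it
#' is the model's `pi` (by default the empirical composition).
#'
#' @param tree Rooted or unrooted `phylo` with branch lengths (>= 0).
#' @param aln Alignment matrix whose taxa match the tree's tips.
#' @param model A [substitution_model()].
#' @param .pat Internal: precomputed pattern compression (skips validation).
#' @return The log-likelihood (single numeric).
#' @export
log_likelihood <- function(tree, aln, model, .pat = NULL) {
  assert_tree(tree)
  if (is.null(tree$edge.length)) abort("tree has no branch lengths.")
  if (any(tree$edge.length < 0)) abort("branch lengths must be >= 0.")
  if (is.null(.pat)) {
    if (ncol(aln) < 1 || nrow(aln) < 2) abort("alignment is empty.")
    check_tree_alignment(tree, aln)
  }
  pat <- .pat %||% compress_patterns(aln[tree$tip.label, , drop = FALSE])
  Q <- rate_matrix(model)
  root_freq <- if (model$family == "UNREST") model$pi else stationary_freqs(model)
  rates <- if (is.null(model$gamma)) 1
           else discrete_gamma_rates(model$gamma$shape, model$gamma$k)
  k <- length(rates)
  ord <- rev(reorder_edges_preorder(tree))
  site_log <- matrix(NA_real_, nrow = k, ncol = ncol(pat$patterns))
  for (ci in seq_len(k)) {
    site_log[ci, ] <- pruning_site_loglik(tree, pat$patterns, Q, root_freq,
                                          rate = rates[ci],
                                          unrest = model$family == "UNREST",
                                          pi = stationary_freqs(model),
                                          edges_post = ord)
  }
  if (k == 1) sum(site_log[1, ] * pat$weights)
  else sum(apply(site_log, 2, logsumexp) * pat$weights) - sum(pat$weights) * log(k)
}

# compress alignment columns into unique patterns with weights;
# patterns: integer matrix taxa x npat with NA for gap/N
compress_patterns <- function(aln) {
  code <- encode_alignment(aln)
  key <- apply(code, 2, paste, collapse = ",")
  ux <- !duplicated(key)
  w <- as.vector(table(factor(key, levels = key[ux])))
  list(patterns = code[, ux, drop = FALSE], weights = w)
}

# per-pattern log-likelihood at one rate category
pruning_site_loglik <- function(tree, patterns, Q, root_freq, rate, unrest, pi,
                                edges_post = NULL) {
  nt <- nrow(patterns)
  np <- ncol(patterns)
  nn <- nt + tree$Nnode
  # transition matrix per edge
  Plist <- vector("list", nrow(tree$edge))
  if (unrest) {
    # non-symmetric Q: eigendecomposition in complex arithmetic when well
    # conditioned, matrix exponential otherwise
    ed <- tryCatch(q_eigen(Q), error = function(e) NULL)
    use_eigen <- !is.null(ed) && rcond(abs(ed$U)) > 1e-10
    for (i in seq_len(nrow(tree$edge))) {
      t_i <- tree$edge.length[i] * rate
      Plist[[i]] <- if (use_eigen)
        clean_P(ed$U %*% (exp(ed$values * t_i) * ed$Uinv))
      else clean_P(as.matrix(Matrix::expm(Q * t_i)))
    }
  } else {
    ed <- q_eigen(Q, pi)
    for (i in seq_len(nrow(tree$edge)))
      Plist[[i]] <- clean_P(ed$U %*% (exp(ed$values * tree$edge.length[i] * rate) * ed$Uinv))
  }
  partial <- vector("list", nn)
  logscale <- rep(0, np)
  for (i in seq_len(nt)) {
    m <- matrix(0, 4, np)
    st <- patterns[i, ]
    amb <- is.na(st)
    if (any(amb)) m[, amb] <- 1
    if (any(!amb)) m[cbind(st[!amb], which(!amb))] <- 1
    partial[[i]] <- m
  }
  if (is.null(edges_post)) edges_post <- rev(reorder_edges_preorder(tree))
  # process edges child-before-parent; accumulate product at parent
  for (i in edges_post) {
    par <- tree$edge[i, 1]; chd <- tree$edge[i, 2]
    contrib <- Plist[[i]] %*% partial[[chd]]
    if (is.null(partial[[par]])) partial[[par]] <- contrib
    else partial[[par]] <- partial[[par]] * contrib
    # rescale parent partials when complete? rescale opportunistically
    mx <- matrixStats_colmax(partial[[par]])
    if (any(mx < 1e-200)) {
      sc <- pmax(mx, 1e-300)
      partial[[par]] <- sweep(partial[[par]], 2, sc, "/")
      logscale <- logscale + log(sc)
    }
  }
  root <- n_tips(tree) + 1L
  lik <- as.vector(root_freq %*% partial[[root]])
  log(lik) + logscale
}

matrixStats_colmax <- function(m) {
  apply(m, 2, max)
}

clean_P <- function(P) {
  P <- Re(P)
  P[P < 0] <- 0
  P / rowSums(P)
}

map_family_phangorn <- function(family) {
  switch(family, JC = "JC", K2 = "K80", HKY = "HKY", TN = "TrN", GTR = "GTR",
         abort(paste0("no phangorn model for family ", family)))
}

#' Maximum-likelihood branch lengths on a fixed topology
#'
#' Optimizes branch lengths (and, by default, free model parameters:
#' exchangeabilities for K2/HKY/TN/GTR and the gamma shape when a +Gamma model
#' is requested with `free_alpha = TRUE`) on the given rooted topology. Base
#' frequencies are empirical counts by default (equal for JC/K2).
#'
#' Reversible-model likelihoods only identify the *sum* of the two
#' root-adjacent branch lengths, so the optimization runs on the unrooted
#' topology and the fitted root-edge total is then split so that the two root
#' children's mean lineage depths balance (the same depth recursion used by
#' [relative_times()]); the split is exact on clocklike data.
#'
#' @param tree Rooted binary `phylo` topology (branch lengths ignored).
#' @param aln Alignment matrix.
#' @param model A [substitution_model()]; its `gamma` slot decides whether a
#'   +Gamma fit is performed (with `model$gamma$shape` as the starting value).
#' @param free_params Optimize exchangeabilities (ignored for JC)?
#' @param free_alpha Optimize the gamma shape (ignored without gamma)?
#' @return An object of class `ml_fit`: `tree` (rooted, fitted lengths),
#'   `model` (with fitted parameters), `lnL`, `convergence` (list), `taxa`.
#' @export
fit_branch_lengths <- function(tree, aln, model, free_params = TRUE,
                               free_alpha = TRUE) {
  assert_rooted_binary(tree)
  check_tree_alignment(tree, aln)
  stopifnot(inherits(model, "substitution_model"))
  if (model$family == "UNREST")
    return(fit_unrest(tree, aln, gamma = model$gamma))
  if (n_tips(tree) == 2) return(fit_two_taxa(tree, aln, model))

  dat <- phangorn::phyDat(aln, type = "DNA")
  utree <- ape::unroot(tree)
  utree$edge.length <- rep(0.1, nrow(utree$edge))
  bf <- if (model$family %in% c("JC", "K2")) rep(0.25, 4)
        else unname(empirical_base_freqs(aln))
  k <- if (is.null(model$gamma)) 1L else model$gamma$k
  shape <- if (is.null(model$gamma)) 1 else model$gamma$shape
  fit0 <- phangorn::pml(utree, dat, bf = bf, k = k, shape = shape)
  opt_q <- free_params && model$family != "JC"
  opt_g <- !is.null(model$gamma) && free_alpha
  fit <- phangorn::optim.pml(
    fit0, model = map_family_phangorn(model$family),
    optEdge = TRUE, optQ = opt_q, optBf = FALSE, optGamma = opt_g,
    optRooted = FALSE,
    control = phangorn::pml.control(trace = 0, epsilon = 1e-8, maxit = 50)
  )
  fitted_model <- model_from_pml(model, fit)
  rooted <- reroot_fitted(tree, fit$tree)
  structure(
    list(tree = rooted, model = fitted_model, lnL = as.numeric(stats::logLik(fit)),
         convergence = list(engine = "phangorn::optim.pml", maxit = 50,
                            epsilon = 1e-8, converged = TRUE),
         taxa = sort(rownames(aln)), n_sites = ncol(aln)),
    class = "ml_fit"
  )
}

# carry fitted phangorn parameters back into a substitution_model
model_from_pml <- function(model, fit) {
  out <- model
  # phangorn Q order: ac, ag, at, cg, ct, gt (lower-triangle order acgt)
  q <- fit$Q
  names(q) <- c("ac", "ag", "at", "cg", "ct", "gt")
  if (model$family != "JC") {
    q <- q / q[["gt"]] %||% q
    out$rates[] <- switch(model$family,
      K2 = c(1, q[["ag"]], 1, 1, q[["ag"]], 1),
      HKY = c(1, q[["ag"]], 1, 1, q[["ag"]], 1),
      TN = c(1, q[["ag"]], 1, 1, q[["ct"]], 1),
      GTR = unname(q[c("ac", "ag", "at", "cg", "ct", "gt")])
    )
  }
  out$pi <- stats::setNames(fit$bf, BASES)
  if (model$family %in% c("JC", "K2")) out$pi <- stats::setNames(rep(0.25, 4), BASES)
  if (!is.null(model$gamma)) out$gamma$shape <- fit$shape
  out
}

# tip set below each edge of a rooted tree, as a key string
edge_clade_keys <- function(tree) {
  desc <- descendant_tips(tree)
  vapply(seq_len(nrow(tree$edge)), function(i) {
    paste(sort(tree$tip.label[desc[[tree$edge[i, 2]]]]), collapse = "|")
  }, "")
}

# transfer fitted unrooted edge lengths onto the original rooted topology,
# splitting the root edge by balancing mean lineage depths
reroot_fitted <- function(rooted, fitted_unrooted) {
  nt <- n_tips(rooted)
  rkeys <- edge_clade_keys(rooted)
  all_tips <- sort(rooted$tip.label)
  fdesc <- descendant_tips(fitted_unrooted)
  fkeys <- vapply(seq_len(nrow(fitted_unrooted$edge)), function(i) {
    tips <- sort(fitted_unrooted$tip.label[fdesc[[fitted_unrooted$edge[i, 2]]]])
    paste(tips, collapse = "|")
  }, "")
  fkeys_comp <- vapply(seq_len(nrow(fitted_unrooted$edge)), function(i) {
    tips <- sort(fitted_unrooted$tip.label[fdesc[[fitted_unrooted$edge[i, 2]]]])
    paste(setdiff(all_tips, tips), collapse = "|")
  }, "")
  root <- root_node(rooted)
  root_edges <- which(rooted$edge[, 1] == root)
  out <- rooted
  out$edge.length <- rep(NA_real_, nrow(rooted$edge))
  for (i in seq_len(nrow(rooted$edge))) {
    if (i %in% root_edges) next
    j <- match(rkeys[i], fkeys)
    if (is.na(j)) j <- match(rkeys[i], fkeys_comp)
    if (is.na(j)) abort("internal error: could not match an edge between trees.")
    out$edge.length[i] <- fitted_unrooted$edge.length[j]
  }
  # the two root edges correspond to one unrooted edge (or, if the root child
  # is the unrooted trifurcation, to that child's edges): find total length
  k1 <- rkeys[root_edges[1]]
  j <- match(k1, fkeys)
  if (is.na(j)) j <- match(k1, fkeys_comp)
  if (is.na(j)) abort("internal error: could not locate the root edge.")
  total <- fitted_unrooted$edge.length[j]
  out$edge.length[root_edges] <- c(total, 0)
  balance_root_split(out)
}

# re-split the two root-adjacent branch lengths (keeping their sum) so the
# two root children's mean lineage depths balance: b1 + H(c1) = b2 + H(c2).
# This is the package's root convention; exact on clocklike trees.
balance_root_split <- function(tree) {
  root_edges <- which(tree$edge[, 1] == root_node(tree))
  total <- sum(tree$edge.length[root_edges])
  h <- lineage_depths(tree, skip_edges = root_edges)
  c1 <- tree$edge[root_edges[1], 2]
  c2 <- tree$edge[root_edges[2], 2]
  b1 <- (total + h[c2] - h[c1]) / 2
  b1 <- min(max(b1, 0), total)
  tree$edge.length[root_edges[1]] <- b1
  tree$edge.length[root_edges[2]] <- total - b1
  tree
}

# mean lineage depth H per node under the pairwise-mean recursion
# (H(tip) = 0; H(node) = mean over children of (branch + H(child)))
lineage_depths <- function(tree, skip_edges = integer(0)) {
  nn <- n_tips(tree) + tree$Nnode
  H <- rep(0, nn)
  edges_post <- rev(reorder_edges_preorder(tree))
  acc <- vector("list", nn)
  for (i in edges_post) {
    par <- tree$edge[i, 1]; chd <- tree$edge[i, 2]
    b <- if (i %in% skip_edges) 0 else tree$edge.length[i]
    acc[[par]] <- c(acc[[par]], b + H[chd])
    H[par] <- mean(acc[[par]])
  }
  H
}

# two-taxon special case: optimize the single path length directly
fit_two_taxa <- function(tree, aln, model) {
  f <- function(d) {
    tr <- tree
    tr$edge.length <- rep(d / 2, 2)
    log_likelihood(tr, aln, model)
  }
  opt <- stats::optimize(f, c(1e-8, 20), maximum = TRUE, tol = 1e-10)
  out <- tree
  out$edge.length <- rep(opt$maximum / 2, 2)
  structure(
    list(tree = out, model = model, lnL = opt$objective,
         convergence = list(engine = "optimize", converged = TRUE),
         taxa = sort(rownames(aln)), n_sites = ncol(aln)),
    class = "ml_fit"
  )
}

#' Log-likelihood difference between two fits
#'
#' `lnL(complex) - lnL(simple)`; positive when the complex model fits the data
#' better. Both fits must come from the same alignment and topology.
#'
#' @param fit_complex,fit_simple Two [fit_branch_lengths()] results.
#' @return A single numeric.
#' @export
delta_lnL <- function(fit_complex, fit_simple) {
  stopifnot(inherits(fit_complex, "ml_fit"), inherits(fit_simple, "ml_fit"))
  if (!identical(fit_complex$taxa, fit_simple$taxa) ||
      !identical(fit_complex$n_sites, fit_simple$n_sites))
    abort("fits are not on the same alignment/topology.")
  fit_complex$lnL - fit_simple$lnL
}

#' Fit the unrestricted (non-reversible) model
#'
#' Twelve free off-diagonal rates, normalized to one expected substitution per
#' site at stationarity; root state distribution fixed at the empirical base
#' composition. Branch lengths and rates are optimized jointly (L-BFGS-B on
#' log scale) on the rooted tree — unlike reversible models, the likelihood
#' here depends on the root position.
#'
#' @param tree Rooted binary topology.
#' @param aln Alignment matrix.
#' @param gamma Optional gamma spec `list(shape=, k=)` (as in
#'   [substitution_model()]'s `gamma` slot).
#' @return An `ml_fit`.
#' @export
fit_unrest <- function(tree, aln, gamma = NULL) {
  assert_rooted_binary(tree)
  check_tree_alignment(tree, aln)
  emp <- empirical_base_freqs(aln)
  ne <- nrow(tree$edge)
  pat <- compress_patterns(aln[tree$tip.label, , drop = FALSE])
  make_model <- function(logr) {
    substitution_model("UNREST", pi = emp,
                       rates = c(1, exp(logr)),
                       gamma_shape = if (is.null(gamma)) NULL else gamma$shape,
                       gamma_categories = if (is.null(gamma)) 4L else gamma$k)
  }
  # warm start from the nested GTR fit: UNREST with q_ij = r_ij * pi_j and
  # the GTR branch lengths reproduces the GTR optimum exactly, so the
  # optimizer can only improve on it
  gtr_model <- substitution_model("GTR", pi = emp,
                                  gamma_shape = if (is.null(gamma)) NULL else gamma$shape,
                                  gamma_categories = if (is.null(gamma)) 4L else gamma$k)
  gtr_fit <- fit_branch_lengths(tree, aln, gtr_model)
  if (!is.null(gamma)) gamma$shape <- gtr_fit$model$gamma$shape
  Qg <- rate_matrix(substitution_model("GTR", pi = emp,
                                       rates = gtr_fit$model$rates))
  # row-major off-diagonal order as used by the UNREST constructor
  q0 <- as.vector(t(Qg))[as.vector(t(row(Qg) != col(Qg)))]
  q0 <- q0 / q0[1]
  start_len <- pmin(pmax(gtr_fit$tree$edge.length, 1e-8), 20)
  par0 <- c(log(start_len), log(q0[-1]))
  nll <- function(par) {
    tr <- tree
    tr$edge.length <- exp(par[seq_len(ne)])
    m <- make_model(par[ne + seq_len(11)])
    ll <- tryCatch(log_likelihood(tr, aln, m, .pat = pat),
                   error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  opt <- stats::optim(par0, nll, method = "L-BFGS-B",
                      lower = c(rep(log(1e-8), ne), rep(log(1e-4), 11)),
                      upper = c(rep(log(20), ne), rep(log(1e4), 11)),
                      control = list(maxit = 500, factr = 1e7))
  out <- tree
  out$edge.length <- exp(opt$par[seq_len(ne)])
  model <- make_model(opt$par[ne + seq_len(11)])
  # the root split is weakly identified under UNREST: finish with a 1-D
  # search over the split (never decreases the likelihood) ...
  root_edges <- which(tree$edge[, 1] == root_node(tree))
  total <- sum(out$edge.length[root_edges])
  split_lnL <- function(b1) {
    tr <- out
    tr$edge.length[root_edges] <- c(b1, total - b1)
    log_likelihood(tr, aln, model, .pat = pat)
  }
  lnL_best <- -opt$value
  if (total > 0) {
    sp <- stats::optimize(split_lnL, c(0, total), maximum = TRUE, tol = 1e-8)
    if (sp$objective >= lnL_best) {
      lnL_best <- sp$objective
      out$edge.length[root_edges] <- c(sp$maximum, total - sp$maximum)
    }
  }
  # ... then present the near-flat split with the package's balanced-root
  # convention so branch lengths are comparable across model families
  balanced <- balance_root_split(out)
  lnL_balanced <- log_likelihood(balanced, aln, model, .pat = pat)
  if (lnL_balanced >= lnL_best - 0.5) {
    out <- balanced
  }
  structure(
    list(tree = out, model = model, lnL = lnL_best,
         convergence = list(engine = "optim/L-BFGS-B",
                            converged = opt$convergence == 0,
                            iterations = opt$counts[["function"]]),
         taxa = sort(rownames(aln)), n_sites = ncol(aln)),
    class = "ml_fit"
  )
}

#' @export
print.ml_fit <- function(x, ...) {
  cat(sprintf("<ML fit: %s%s, %d taxa, %d sites, lnL = %.3f>\n",
              x$model$family,
              if (is.null(x$model$gamma)) "" else "+G",
              length(x$taxa), x$n_sites, x$lnL))
  invisible(x)
}

#' @rdname tidiers
#' @method tidy ml_fit
#' @export
tidy.ml_fit <- function(x, ...) {
  tibble(
    parent = x$tree$edge[, 1],
    child = x$tree$edge[, 2],
    child_label = ifelse(x$tree$edge[, 2] <= n_tips(x$tree),
                         x$tree$tip.label[x$tree$edge[, 2]], ""),
    length = x$tree$edge.length
  )
}

#' @rdname tidiers
#' @method glance ml_fit
#' @export
glance.ml_fit <- function(x, ...) {
  tibble(
    family = x$model$family,
    gamma = !is.null(x$model$gamma),
    alpha = if (is.null(x$model$gamma)) NA_real_ else x$model$gamma$shape,
    lnL = x$lnL,
    n_taxa = length(x$taxa),
    n_sites = x$n_sites,
    converged = isTRUE(x$convergence$converged)
  )
}
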