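#' The default GTR+Gamma simulation model
#'
#' GTR with biased base composition (T = 0.25, C = 0.33, A = 0.31, G = 0.11),
#' transition/transversion exchangeability bias of 4 (AG = CT = 4, all other
#' exchangeabilities 1), and gamma rate heterogeneity with shape 0.25. This is
#' the generating model for the package's clocklike simulations.
#'
#' @param gamma_shape Gamma shape (default 0.25).
#' @return A [substitution_model()].
#' @export
default_sim_model <- function(gamma_shape = 0.25) {
  substitution_model(
    "GTR",
    pi = c(A = 0.31, C = 0.33, G = 0.11, T = 0.25),
    rates = c(ag = 4, ct = 4),
    gamma_shape = gamma_shape
  )
}

#' Simulation configuration
#'
#' Bundles everything needed to simulate one clocklike alignment: the tree
#' shape, the clock, the substitution model and the seed. Defaults are the
#' package's baseline study conditions: a 16-tip completely unbalanced
#' (caterpillar) timetree with root age 3 time units, a strict clock of 0.1
#' substitutions/site/time-unit, a rate multiplier of 1, 5,000 sites and the
#' GTR+Gamma model of [default_sim_model()]. The multiplier ladder used by
#' [run_simstudy()] accelerates the clock 2-10 fold.
#'
#' @param n_tips Number of tips (>= 3).
#' @param root_age Root age in time units (> 0).
#' @param base_rate Clock rate, substitutions/site/time-unit (>= 0).
#' @param rate_multiplier Dimensionless acceleration of the clock (>= 0).
#' @param seq_length Number of sites (>= 1).
#' @param model Generating [substitution_model()].
#' @param seed Mandatory integer seed; there is no silent entropy.
#' @param per_branch_rate_factors Optional numeric vector of per-branch rate
#'   multipliers in the tree's edge order (default all 1; strict clock).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_tips = 16L, root_age = 3, base_rate = 0.1,
                              rate_multiplier = 1, seq_length = 5000L,
                              model = default_sim_model(), seed,
                              per_branch_rate_factors = NULL) {
  if (missing(seed)) abort("`seed` is mandatory in a simulation_config.")
  if (n_tips < 3) abort("`n_tips` must be >= 3.")
  if (root_age <= 0) abort("`root_age` must be > 0.")
  if (base_rate < 0) abort("`base_rate` must be >= 0.")
  if (rate_multiplier < 0) abort("`rate_multiplier` must be >= 0.")
  if (seq_length < 1) abort("`seq_length` must be >= 1.")
  stopifnot(inherits(model, "substitution_model"))
  structure(
    list(n_tips = as.integer(n_tips), root_age = root_age,
         base_rate = base_rate, rate_multiplier = rate_multiplier,
         seq_length = as.integer(seq_length), model = model,
         seed = as.integer(seed),
         per_branch_rate_factors = per_branch_rate_factors),
    class = "simulation_config"
  )
}

#' Build a completely unbalanced (caterpillar) timetree
#'
#' Every internal node subtends exactly one tip, except the shallowest node
#' which is a cherry. Internal node ages are uniformly spaced:
#' `root_age * k / (n_tips - 1)` for `k = n_tips - 1, ..., 1`, so the 16-tip,
#' root-age-3 default has internal ages 3.0, 2.8, ..., 0.2. Tips are labelled
#' `t1` (attached at the root) through `t<n>`.
#'
#' @param n_tips Number of tips (>= 3).
#' @param root_age Root age in time units.
#' @return An ultrametric `phylo` with branch lengths in time units.
#' @export
build_unbalanced_timetree <- function(n_tips, root_age) {
  if (n_tips < 3) abort("`n_tips` must be >= 3.")
  if (root_age <= 0) abort("`root_age` must be > 0.")
  n <- as.integer(n_tips)
  n_int <- n - 1L
  ages <- root_age * (n_int:1) / n_int # internal node ages, root first
  # internal node ids n+1 (root) .. 2n-1 (cherry)
  edge <- matrix(0L, nrow = 2L * n - 2L, ncol = 2)
  len <- numeric(2L * n - 2L)
  e <- 0L
  for (k in seq_len(n_int)) {
    node <- n + k
    age <- ages[k]
    if (k < n_int) {
      # tip child t_k and internal child node+1
      e <- e + 1L; edge[e, ] <- c(node, k); len[e] <- age
      e <- e + 1L; edge[e, ] <- c(node, node + 1L); len[e] <- age - ages[k + 1]
    } else {
      # cherry: tips t_{n-1}, t_n
      e <- e + 1L; edge[e, ] <- c(node, n - 1L); len[e] <- age
      e <- e + 1L; edge[e, ] <- c(node, n); len[e] <- age
    }
  }
  tr <- structure(
    list(edge = edge, edge.length = len, Nnode = n_int,
         tip.label = paste0("t", seq_len(n))),
    class = "phylo", order = "cladewise"
  )
  validate_timetree(tr)
  tr
}

# per-edge expected substitutions/site implied by a config (before site rates)
edge_expected_lengths <- function(tree, cfg) {
  f <- cfg$per_branch_rate_factors %||% rep(1, nrow(tree$edge))
  if (length(f) != nrow(tree$edge))
    abort("`per_branch_rate_factors` must have one entry per edge.")
  tree$edge.length * cfg$base_rate * cfg$rate_multiplier * f
}

#' True branch lengths implied by a simulation configuration
#'
#' Each branch's length is its time span times the clock rate
#' (`base_rate * rate_multiplier`, times any per-branch factor) — the expected
#' number of substitutions per site, i.e. the ground truth against which
#' estimated branch lengths can be compared.
#'
#' @param tree Timetree (branch lengths in time units).
#' @param cfg A [simulation_config()].
#' @return A `phylo` with branch lengths in substitutions/site.
#' @export
true_branch_lengths <- function(tree, cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  assert_tree(tree)
  out <- tree
  out$edge.length <- edge_expected_lengths(tree, cfg)
  out
}

#' Simulate a clocklike nucleotide alignment
#'
#' Evolves sequences down a timetree under the configured substitution model.
#' The root sequence is drawn from the model's stationary frequencies; each
#' site draws one continuous-gamma rate factor (shape alpha, mean 1) that is
#' shared across the whole tree; each branch then substitutes states according
#' to `exp(Q * b)` with `b = time span x base_rate x rate_multiplier x site
#' factor x branch factor`. Deterministic given `cfg$seed`.
#'
#' @param tree Timetree with branch lengths in time units.
#' @param cfg A [simulation_config()]; `cfg$n_tips` must match the tree.
#' @return An alignment matrix (tips x sites).
#' @export
evolve_alignment <- function(tree, cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  assert_rooted_binary(tree)
  if (n_tips(tree) != cfg$n_tips)
    abort("`cfg$n_tips` does not match the tree.")
  model <- cfg$model
  Q <- rate_matrix(model)
  pi0 <- stationary_freqs(model)
  ed <- if (model$family == "UNREST") q_eigen(Q) else q_eigen(Q, pi0)
  L <- cfg$seq_length
  blens <- edge_expected_lengths(tree, cfg)

  with_seed(cfg$seed, {
    site_rate <- if (is.null(model$gamma)) rep(1, L)
                 else stats::rgamma(L, shape = model$gamma$shape, rate = model$gamma$shape)
    nn <- n_tips(tree) + tree$Nnode
    states <- matrix(NA_integer_, nrow = nn, ncol = L)
    root <- root_node(tree)
    states[root, ] <- sample.int(4L, L, replace = TRUE, prob = pi0)
    for (i in reorder_edges_preorder(tree)) {
      par <- tree$edge[i, 1]; chd <- tree$edge[i, 2]
      t_site <- blens[i] * site_rate
      states[chd, ] <- evolve_states(states[par, ], t_site, ed)
    }
    m <- matrix(BASES[states[seq_len(n_tips(tree)), , drop = FALSE]],
                nrow = n_tips(tree))
    rownames(m) <- tree$tip.label
    alignment(m)
  })
}

# sample child states given parent states and per-site branch lengths,
# using the precomputed eigendecomposition of Q
evolve_states <- function(parent, t_site, ed) {
  L <- length(parent)
  E <- exp(outer(t_site, ed$values)) # L x 4
  W <- ed$U[parent, , drop = FALSE] * E # L x 4
  P <- W %*% ed$Uinv # L x 4: row s = P(t_s)[parent_s, ]
  P <- Re(P)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  c1 <- P[, 1]; c2 <- c1 + P[, 2]; c3 <- c2 + P[, 3]
  u <- stats::runif(L)
  1L + (u > c1) + (u > c2) + (u > c3)
}
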