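# Independent oracles used across the suite. These deliberately avoid the
# package's pruning/eigen code paths: likelihoods by exhaustive enumeration
# over internal-state assignments with transition matrices from Matrix::expm,
# and expected pair-state proportions from the joint distribution
# J(d) = diag(pi) expm(Q d), gamma-averaged analytically on the eigenvalues.

# log-likelihood by brute-force enumeration (tiny trees only)
enum_loglik <- function(tree, aln, model) {
  Q <- relchron::rate_matrix(model)
  root_freq <- if (model$family == "UNREST") model$pi
               else relchron::stationary_freqs(model)
  rates <- if (is.null(model$gamma)) 1
           else relchron::discrete_gamma_rates(model$gamma$shape, model$gamma$k)
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  internal <- (nt + 1):nn
  code <- match(aln[tree$tip.label, , drop = FALSE], c("A", "C", "G", "T"))
  dim(code) <- c(nt, ncol(aln))
  grid <- as.matrix(expand.grid(rep(list(1:4), length(internal))))
  site_lik <- numeric(ncol(aln))
  for (r in rates) {
    Pl <- lapply(seq_len(nrow(tree$edge)), function(i)
      as.matrix(Matrix::expm(Q * tree$edge.length[i] * r)))
    for (site in seq_len(ncol(aln))) {
      lik_r <- 0
      for (g in seq_len(nrow(grid))) {
        state <- integer(nn)
        state[seq_len(nt)] <- code[, site]
        state[internal] <- grid[g, ]
        pr <- root_freq[state[nt + 1]]
        for (i in seq_len(nrow(tree$edge))) {
          a <- state[tree$edge[i, 1]]; b <- state[tree$edge[i, 2]]
          if (is.na(b)) next # ambiguous tip: sums over all states = row sum 1
          pr <- pr * Pl[[i]][a, b]
        }
        lik_r <- lik_r + pr
      }
      site_lik[site] <- site_lik[site] + lik_r / length(rates)
    }
  }
  sum(log(site_lik))
}

# expected pair-state joint distribution at divergence d for a reversible
# model, optionally gamma-averaged: replaces exp(lambda d) terms with
# (1 - lambda d / alpha)^(-alpha)
expected_pair_joint <- function(model, d, gamma_shape = NULL) {
  Q <- relchron::rate_matrix(model)
  pi <- relchron::stationary_freqs(model)
  es <- eigen(Q)
  U <- es$vectors; Uinv <- solve(U)
  lam <- es$values
  g <- if (is.null(gamma_shape)) exp(lam * d)
       else (1 - lam * d / gamma_shape)^(-gamma_shape)
  J <- diag(pi) %*% Re(U %*% diag(g) %*% Uinv)
  dimnames(J) <- list(c("A","C","G","T"), c("A","C","G","T"))
  J
}

# expected pair_counts (fractional, exact) at divergence d
expected_pair_counts <- function(model, d, gamma_shape = NULL) {
  J <- expected_pair_joint(model, d, gamma_shape)
  p1 <- J["A","G"] + J["G","A"]
  p2 <- J["C","T"] + J["T","C"]
  diff <- 1 - sum(diag(J))
  freq <- (rowSums(J) + colSums(J)) / 2
  structure(
    list(valid_sites = 1, diff = diff, transitions = p1 + p2,
         transversions = diff - p1 - p2, P1 = p1, P2 = p2, freq = freq),
    class = "pair_counts"
  )
}

# all rooted binary topologies on n labelled tips, with random branch lengths
random_length_topologies <- function(n, seed) {
  trees <- phangorn::allTrees(n, rooted = TRUE)
  withr::with_seed(seed, lapply(trees, function(tr) {
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.02, 0.7)
    tr
  }))
}

random_alignment <- function(taxa, n_sites, seed) {
  withr::with_seed(seed, {
    m <- matrix(sample(c("A", "C", "G", "T"), length(taxa) * n_sites,
                       replace = TRUE),
                nrow = length(taxa))
    rownames(m) <- taxa
    relchron::alignment(m)
  })
}

oracle_models <- function() {
  list(
    JC = substitution_model("JC"),
    K2 = substitution_model("K2", rates = c(kappa = 3)),
    HKY = substitution_model("HKY", pi = c(0.31, 0.33, 0.11, 0.25),
                             rates = c(kappa = 3)),
    TN = substitution_model("TN", pi = c(0.31, 0.33, 0.11, 0.25),
                            rates = c(kappa1 = 3, kappa2 = 5)),
    GTR = substitution_model("GTR", pi = c(0.31, 0.33, 0.11, 0.25),
                             rates = c(ac = 1.2, ag = 3.5, at = 0.7,
                                       cg = 1.4, ct = 4.2, gt = 1)),
    UNREST = substitution_model("UNREST", pi = c(0.3, 0.3, 0.2, 0.2),
                                rates = c(1, 2, 0.5, 1.5, 3, 0.8,
                                          1.1, 0.9, 2.2, 0.6, 1.7, 1))
  )
}

with_gamma <- function(model, shape = 0.4, k = 4L) {
  model$gamma <- list(shape = shape, k = k)
  model
}
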