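MODEL_FAMILIES <- c("JC", "K2", "HKY", "TN", "GTR", "UNREST")

# base order used throughout: A, C, G, T
BASES <- c("A", "C", "G", "T")

#' Specify a nucleotide substitution model
#'
#' Families form the usual nesting ladder JC < K2 < HKY < TN < GTR < UNREST:
#' JC has equal rates and frequencies; K2 adds a transition/transversion bias;
#' HKY adds unequal base frequencies; TN separates purine (A<->G) and
#' pyrimidine (C<->T) transition rates; GTR has six free symmetric
#' exchangeabilities; UNREST has twelve free rates and need not be
#' time-reversible. Optional gamma rate heterogeneity multiplies each site's
#' rate by a mean-1 gamma variate with shape `gamma_shape` (continuous in
#' simulation; discretised into `gamma_categories` equal-probability
#' categories, each represented by its bin mean, for likelihood computation).
#'
#' @param family One of `"JC","K2","HKY","TN","GTR","UNREST"`.
#' @param pi Base frequencies in A,C,G,T order (ignored and forced to 1/4 for
#'   JC and K2). For UNREST, `pi` is used as the root distribution; the
#'   process's stationary distribution is derived from the rate matrix.
#' @param rates For reversible families, named exchangeabilities among
#'   `ac, ag, at, cg, ct, gt` (missing entries default to 1); `kappa` may be
#'   given instead for K2/HKY (sets `ag = ct = kappa`), and `kappa1`/`kappa2`
#'   for TN. For UNREST, a length-12 vector of off-diagonal rates in row-major
#'   A,C,G,T order.
#' @param gamma_shape Gamma shape alpha (> 0), or `NULL` for no rate
#'   heterogeneity.
#' @param gamma_categories Number of discrete gamma categories used by
#'   likelihood computations (default 4).
#' @param normalize If `TRUE` (default), scale the rate matrix so branch
#'   lengths are expected substitutions per site.
#' @return An object of class `substitution_model`.
#' @examples
#' substitution_model("K2", rates = c(kappa = 4))
#' substitution_model("GTR", pi = c(0.31, 0.33, 0.11, 0.25),
#'                    rates = c(ag = 4, ct = 4), gamma_shape = 0.25)
#' @export
substitution_model <- function(family, pi = rep(0.25, 4), rates = NULL,
                               gamma_shape = NULL, gamma_categories = 4L,
                               normalize = TRUE) {
  family <- match.arg(toupper(family), MODEL_FAMILIES)
  pi <- as.numeric(pi)
  if (length(pi) != 4 || any(pi <= 0) || abs(sum(pi) - 1) > 1e-8)
    abort("`pi` must be 4 positive frequencies summing to 1 (A,C,G,T order).")
  if (family %in% c("JC", "K2")) pi <- rep(0.25, 4)
  names(pi) <- BASES

  if (family == "UNREST") {
    if (is.null(rates) || length(rates) != 12 || any(rates < 0))
      abort("UNREST needs 12 nonnegative off-diagonal rates (row-major A,C,G,T).")
    exch <- as.numeric(rates)
  } else {
    exch <- c(ac = 1, ag = 1, at = 1, cg = 1, ct = 1, gt = 1)
    if (!is.null(rates)) {
      rates <- as.list(rates)
      if (!is.null(rates$kappa)) { rates$ag <- rates$kappa; rates$ct <- rates$kappa; rates$kappa <- NULL }
      if (!is.null(rates$kappa1)) { rates$ag <- rates$kappa1; rates$kappa1 <- NULL }
      if (!is.null(rates$kappa2)) { rates$ct <- rates$kappa2; rates$kappa2 <- NULL }
      bad <- setdiff(names(rates), names(exch))
      if (length(bad)) abort(paste0("unknown rate name(s): ", paste(bad, collapse = ", ")))
      exch[names(rates)] <- as.numeric(rates)
    }
    # family restrictions
    exch <- switch(family,
      JC  = c(ac = 1, ag = 1, at = 1, cg = 1, ct = 1, gt = 1),
      K2  = c(ac = 1, ag = unname(exch["ag"]), at = 1, cg = 1, ct = unname(exch["ag"]), gt = 1),
      HKY = c(ac = 1, ag = unname(exch["ag"]), at = 1, cg = 1, ct = unname(exch["ag"]), gt = 1),
      TN  = c(ac = 1, ag = unname(exch["ag"]), at = 1, cg = 1, ct = unname(exch["ct"]), gt = 1),
      GTR = exch
    )
    if (any(exch <= 0)) abort("exchangeabilities must be positive.")
  }

  if (!is.null(gamma_shape)) {
    if (!is.numeric(gamma_shape) || gamma_shape <= 0) abort("`gamma_shape` must be > 0.")
    gamma <- list(shape = gamma_shape, k = as.integer(gamma_categories))
    if (gamma$k < 1) abort("`gamma_categories` must be >= 1.")
  } else gamma <- NULL

  structure(
    list(family = family, pi = pi, rates = exch, gamma = gamma,
         normalize = isTRUE(normalize)),
    class = "substitution_model"
  )
}

#' @export
print.substitution_model <- function(x, ...) {
  g <- if (is.null(x$gamma)) "" else sprintf("+G(alpha=%g, k=%d)", x$gamma$shape, x$gamma$k)
  cat(sprintf("<substitution model %s%s>\n", x$family, g))
  cat("  pi:", paste(sprintf("%s=%.4g", BASES, x$pi), collapse = " "), "\n")
  invisible(x)
}

#' Rate matrix of a substitution model
#'
#' Builds the 4x4 instantaneous rate matrix Q (rows sum to zero). For
#' reversible families `Q[i,j] = r[ij] * pi[j]`; for UNREST the twelve rates
#' are used directly. When the model is normalized, Q is rescaled so that the
#' expected substitution rate at stationarity is 1, i.e. branch lengths are in
#' expected substitutions per site.
#'
#' @param model A [substitution_model()].
#' @return A 4x4 matrix with dimnames A,C,G,T.
#' @export
rate_matrix <- function(model) {
  stopifnot(inherits(model, "substitution_model"))
  Q <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  if (model$family == "UNREST") {
    Q[row(Q) != col(Q)] <- 0
    k <- 1
    for (i in 1:4) for (j in 1:4) if (i != j) { Q[i, j] <- model$rates[k]; k <- k + 1 }
  } else {
    r <- model$rates
    pairs <- rbind(c(1, 2, r["ac"]), c(1, 3, r["ag"]), c(1, 4, r["at"]),
                   c(2, 3, r["cg"]), c(2, 4, r["ct"]), c(3, 4, r["gt"]))
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1]; j <- pairs[p, 2]; rr <- pairs[p, 3]
      Q[i, j] <- rr * model$pi[j]
      Q[j, i] <- rr * model$pi[i]
    }
  }
  diag(Q) <- -rowSums(Q)
  if (model$normalize) {
    f <- stationary_freqs_Q(Q)
    mu <- -sum(f * diag(Q))
    if (mu <= 0) abort("degenerate rate matrix: zero total rate.")
    Q <- Q / mu
  }
  Q
}

# stationary distribution of a rate matrix (left null vector)
stationary_freqs_Q <- function(Q) {
  ev <- eigen(t(Q))
  i <- which.min(abs(ev$values))
  v <- Re(ev$vectors[, i])
  v <- v / sum(v)
  if (any(v < -1e-9)) abort("rate matrix has no valid stationary distribution.")
  pmax(v, 0) / sum(pmax(v, 0))
}

#' Stationary base frequencies of a model
#'
#' For reversible families these are the model's `pi`; for UNREST they are
#' computed from the rate matrix.
#'
#' @param model A [substitution_model()].
#' @return Named frequency vector (A,C,G,T).
#' @export
stationary_freqs <- function(model) {
  if (model$family == "UNREST") {
    f <- stationary_freqs_Q(rate_matrix(model))
    names(f) <- BASES
    f
  } else model$pi
}

# eigendecomposition of Q, exploiting reversibility when available
q_eigen <- function(Q, pi = NULL) {
  if (!is.null(pi)) {
    # symmetrize: B = D^{1/2} Q D^{-1/2} is symmetric for reversible Q
    d <- sqrt(pi)
    B <- diag(d) %*% Q %*% diag(1 / d)
    B <- (B + t(B)) / 2
    es <- eigen(B, symmetric = TRUE)
    U <- diag(1 / d) %*% es$vectors
    Uinv <- t(es$vectors) %*% diag(d)
    list(values = es$values, U = U, Uinv = Uinv, real = TRUE)
  } else {
    es <- eigen(Q)
    list(values = es$values, U = es$vectors, Uinv = solve(es$vectors), real = FALSE)
  }
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model A [substitution_model()].
#' @param t Branch length (>= 0), in the model's branch-length units.
#' @return A 4x4 stochastic matrix.
#' @export
transition_matrix <- function(model, t) {
  if (t < 0) abort("branch length must be >= 0.")
  Q <- rate_matrix(model)
  if (model$family == "UNREST") {
    P <- as.matrix(Matrix::expm(Q * t))
  } else {
    ed <- q_eigen(Q, stationary_freqs(model))
    P <- ed$U %*% diag(exp(ed$values * t)) %*% ed$Uinv
  }
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(BASES, BASES)
  P
}

#' Discrete gamma category rates
#'
#' Rates for `k` equal-probability categories of a mean-1 gamma distribution
#' with shape `alpha`; each category's rate is the conditional mean of its
#' quantile bin, so the category rates average exactly 1.
#'
#' @param alpha Gamma shape (> 0).
#' @param k Number of categories (>= 1).
#' @return Numeric vector of `k` rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, k = 4L) {
  stopifnot(alpha > 0, k >= 1)
  if (k == 1) return(1)
  b <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  p <- stats::pgamma(b, shape = alpha + 1, rate = alpha)
  k * diff(p)
}
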