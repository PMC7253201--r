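#' Pairwise site-pattern counts for two aligned sequences
#'
#' Sites where either sequence has a gap (`-`) or ambiguity (`N`) are excluded
#' (pairwise deletion). Transitions are A<->G (purine, counted separately as
#' `P1`) and C<->T (pyrimidine, `P2`); all other mismatches are transversions.
#' Base frequencies over the valid sites of the pair (averaged across the two
#' sequences) are carried along for the Tamura-Nei estimator.
#'
#' @param seq_i,seq_j Character vectors of aligned states (equal length), or
#'   single strings.
#' @return A list of class `pair_counts`: `valid_sites`, `diff`,
#'   `transitions`, `transversions`, `P1`, `P2`, `freq` (A,C,G,T).
#' @export
pair_counts <- function(seq_i, seq_j) {
  if (length(seq_i) == 1 && nchar(seq_i[1]) > 1) seq_i <- strsplit(toupper(seq_i), "")[[1]]
  if (length(seq_j) == 1 && nchar(seq_j[1]) > 1) seq_j <- strsplit(toupper(seq_j), "")[[1]]
  if (length(seq_i) != length(seq_j)) abort("sequences must have equal length.")
  ci <- match(seq_i, BASES)
  cj <- match(seq_j, BASES)
  pair_counts_coded(ci, cj)
}

pair_counts_coded <- function(ci, cj) {
  ok <- !is.na(ci) & !is.na(cj)
  ci <- ci[ok]; cj <- cj[ok]
  n <- length(ci)
  mism <- ci != cj
  # A=1 C=2 G=3 T=4: transitions are {1,3} and {2,4}
  p1 <- sum(mism & ((ci == 1 & cj == 3) | (ci == 3 & cj == 1)))
  p2 <- sum(mism & ((ci == 2 & cj == 4) | (ci == 4 & cj == 2)))
  d <- sum(mism)
  freq <- (tabulate(ci, 4) + tabulate(cj, 4)) / (2 * max(n, 1))
  names(freq) <- BASES
  structure(
    list(valid_sites = n, diff = d, transitions = p1 + p2,
         transversions = d - p1 - p2, P1 = p1, P2 = p2, freq = freq),
    class = "pair_counts"
  )
}

# gamma-corrected negative log: -ln(x) plain, alpha*(x^(-1/alpha)-1) with gamma
neg_log_g <- function(x, alpha) {
  if (x <= 0) return(NA_real_)
  if (is.null(alpha)) -log(x) else alpha * (x^(-1 / alpha) - 1)
}

#' Evolutionary distance from pair counts
#'
#' Closed-form multiple-hit corrections. `"p"` is the uncorrected proportion
#' of differing sites; `"JC"` is the Jukes-Cantor correction
#' `d = -3/4 ln(1 - 4p/3)`; `"K2"` the Kimura two-parameter correction on
#' transition/transversion proportions; `"TN"` the Tamura-Nei correction,
#' which additionally separates purine and pyrimidine transitions and uses
#' the pair's base frequencies. With `gamma_shape = alpha`, every `-ln(x)`
#' term becomes `alpha * (x^(-1/alpha) - 1)` (gamma-distributed rate
#' variation). A saturated pair (any logarithm/power argument <= 0) yields
#' `NA` — never a negative or infinite distance.
#'
#' @param counts A [pair_counts()] object.
#' @param model One of `"p"`, `"JC"`, `"K2"`, `"TN"`.
#' @param gamma_shape Optional gamma shape alpha (> 0) for the +Gamma variants.
#' @return Distance in substitutions/site, or `NA_real_` if undefined.
#' @export
nt_distance <- function(counts, model = c("JC", "p", "K2", "TN"),
                        gamma_shape = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(counts, "pair_counts"))
  if (!is.null(gamma_shape) && gamma_shape <= 0) abort("`gamma_shape` must be > 0.")
  n <- counts$valid_sites
  if (n == 0) return(NA_real_)
  p <- counts$diff / n
  if (model == "p") return(p)
  if (model == "JC") {
    return((3 / 4) * neg_log_g(1 - 4 * p / 3, gamma_shape))
  }
  P <- counts$transitions / n
  Q <- counts$transversions / n
  if (model == "K2") {
    a <- neg_log_g(1 - 2 * P - Q, gamma_shape)
    b <- neg_log_g(1 - 2 * Q, gamma_shape)
    if (is.na(a) || is.na(b)) return(NA_real_)
    return(0.5 * a + 0.25 * b)
  }
  # TN93
  f <- counts$freq
  pA <- f["A"]; pC <- f["C"]; pG <- f["G"]; pT <- f["T"]
  pR <- pA + pG; pY <- pC + pT
  if (pR <= 0 || pY <= 0 || pA * pG == 0 || pC * pT == 0) return(NA_real_)
  P1 <- counts$P1 / n
  P2 <- counts$P2 / n
  k1 <- 2 * pA * pG / pR
  k2 <- 2 * pT * pC / pY
  k3 <- 2 * (pR * pY - pA * pG * pY / pR - pT * pC * pR / pY)
  w1 <- 1 - P1 / k1 - Q / (2 * pR)
  w2 <- 1 - P2 / k2 - Q / (2 * pY)
  w3 <- 1 - Q / (2 * pR * pY)
  a1 <- neg_log_g(w1, gamma_shape)
  a2 <- neg_log_g(w2, gamma_shape)
  a3 <- neg_log_g(w3, gamma_shape)
  if (is.na(a1) || is.na(a2) || is.na(a3)) return(NA_real_)
  d <- k1 * a1 + k2 * a2 + k3 * a3
  unname(max(d, 0))
}

#' Pairwise distance matrix for an alignment
#'
#' Applies [nt_distance()] to every pair with pairwise deletion of gap and
#' ambiguous sites. Saturated (undefined) pairs are `NA` in the matrix, with
#' one warning summarising how many; they are excluded from downstream
#' summaries but counted.
#'
#' @param aln Alignment matrix (>= 2 sequences).
#' @param model Distance model (see [nt_distance()]).
#' @param gamma_shape Optional gamma shape.
#' @return A symmetric matrix (class `relchron_distmat`) with zero diagonal,
#'   `NA` for undefined pairs, and attributes `model`, `gamma_shape`,
#'   `n_undefined`.
#' @export
distance_matrix <- function(aln, model = "JC", gamma_shape = NULL) {
  if (nrow(aln) < 2) abort("need at least 2 sequences.")
  code <- encode_alignment(aln)
  n <- nrow(aln)
  D <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  n_undef <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- nt_distance(pair_counts_coded(code[i, ], code[j, ]),
                       model = model, gamma_shape = gamma_shape)
      if (is.na(d)) n_undef <- n_undef + 1L
      D[i, j] <- D[j, i] <- d
    }
  }
  if (n_undef > 0)
    warn(sprintf("%d saturated pair(s) have undefined %s distance.", n_undef, model))
  structure(D, class = c("relchron_distmat", "matrix", "array"),
            model = model, gamma_shape = gamma_shape, n_undefined = n_undef)
}

#' Long-format pairwise distances
#'
#' @param D A distance matrix from [distance_matrix()].
#' @return A tibble with columns `taxon_i`, `taxon_j`, `distance` (one row per
#'   unordered pair; `NA` for saturated pairs).
#' @export
tidy_distances <- function(D) {
  idx <- which(upper.tri(D), arr.ind = TRUE)
  tibble(
    taxon_i = rownames(D)[idx[, 1]],
    taxon_j = colnames(D)[idx[, 2]],
    distance = D[idx]
  )
}

#' Percent difference between simple- and complex-model distances
#'
#' For every pair defined under both models, computes
#' `100 * (d_complex - d_simple) / d_complex` (positive when the simple model
#' underestimates) and summarises with the mean and SD.
#'
#' @param d_simple,d_complex Distance matrices over the same taxa.
#' @return A one-row tibble: `mean_percent`, `sd_percent`, `n_pairs`,
#'   `n_excluded`.
#' @export
percent_difference_summary <- function(d_simple, d_complex) {
  if (!identical(dim(d_simple), dim(d_complex)) ||
      !identical(rownames(d_simple), rownames(d_complex)))
    abort("distance matrices must cover the same taxa in the same order.")
  up <- upper.tri(d_simple)
  ds <- d_simple[up]; dc <- d_complex[up]
  ok <- !is.na(ds) & !is.na(dc) & dc > 0
  pd <- 100 * (dc[ok] - ds[ok]) / dc[ok]
  tibble(
    mean_percent = mean(pd),
    sd_percent = stats::sd(pd),
    n_pairs = sum(ok),
    n_excluded = sum(!ok)
  )
}

#' Expected proportion of differing sites under JC
#'
#' The inverse of the Jukes-Cantor correction:
#' `p(d) = 3/4 (1 - exp(-4d/3))`, or its gamma analog
#' `p(d) = 3/4 (1 - (1 + 4d/(3 alpha))^(-alpha))`.
#'
#' @param d True distance (substitutions/site).
#' @param gamma_shape Optional gamma shape.
#' @return Expected p-distance.
#' @export
jc_expected_p <- function(d, gamma_shape = NULL) {
  if (is.null(gamma_shape)) 0.75 * (1 - exp(-4 * d / 3))
  else 0.75 * (1 - (1 + 4 * d / (3 * gamma_shape))^(-gamma_shape))
}
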