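ALN_STATES <- c("A", "C", "G", "T", "-", "N")

#' Build a nucleotide alignment
#'
#' Alignments are plain character matrices (rows = taxa, columns = sites) over
#' the alphabet `A, C, G, T, -, N`, with unique taxon names as row names.
#'
#' @param sequences Named character vector of equal-length sequence strings,
#'   or a character matrix with row names.
#' @return A character matrix of class `c("relchron_alignment","matrix")`.
#' @export
alignment <- function(sequences) {
  if (is.matrix(sequences)) {
    m <- toupper(sequences)
  } else {
    stopifnot(is.character(sequences))
    if (is.null(names(sequences))) abort("sequences must be named by taxon.")
    lens <- nchar(sequences)
    if (length(unique(lens)) != 1) abort("all sequences must have identical length.")
    if (lens[1] < 1) abort("alignment must have at least one site.")
    m <- do.call(rbind, strsplit(toupper(sequences), ""))
    rownames(m) <- names(sequences)
  }
  if (is.null(rownames(m))) abort("alignment rows must be named by taxon.")
  if (anyDuplicated(rownames(m))) abort("taxon names must be unique.")
  bad <- setdiff(unique(as.vector(m)), ALN_STATES)
  if (length(bad))
    abort(paste0("unsupported alignment state(s): ", paste(bad, collapse = ", ")))
  class(m) <- c("relchron_alignment", class(m))
  m
}

#' @export
print.relchron_alignment <- function(x, ...) {
  cat(sprintf("<alignment: %d taxa x %d sites>\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Read a FASTA alignment
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return An alignment matrix (see [alignment()]).
#' @export
read_fasta <- function(path) {
  dna <- ape::read.FASTA(path)
  m <- toupper(as.character(as.matrix(dna)))
  alignment(m)
}

#' Write a FASTA alignment
#'
#' Sequences are wrapped at 80 columns; output is byte-deterministic for a
#' given alignment.
#'
#' @param aln Alignment matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    s <- paste0(aln[i, ], collapse = "")
    chunks <- substring(s, seq(1, nchar(s), 80), pmin(seq(1, nchar(s), 80) + 79, nchar(s)))
    writeLines(c(paste0(">", rownames(aln)[i]), chunks), con, sep = "\n")
  }
  invisible(path)
}

#' Subset alignment sites
#'
#' @param aln Alignment matrix.
#' @param sites Integer vector of column indices (repeats allowed, e.g. for a
#'   bootstrap resample).
#' @return The site-subset alignment.
#' @export
subset_sites <- function(aln, sites) {
  stopifnot(all(sites >= 1), all(sites <= ncol(aln)))
  out <- aln[, sites, drop = FALSE]
  class(out) <- c("relchron_alignment", "matrix", "array")
  out
}

# integer encoding A=1 C=2 G=3 T=4, NA for gap/ambiguity
encode_alignment <- function(aln) {
  code <- match(aln, c("A", "C", "G", "T"))
  dim(code) <- dim(aln)
  rownames(code) <- rownames(aln)
  code
}

#' Empirical base frequencies of an alignment
#'
#' Frequencies of A, C, G, T over all unambiguous sites, pooled across taxa.
#'
#' @param aln Alignment matrix.
#' @return Named numeric vector (A, C, G, T), summing to 1.
#' @export
empirical_base_freqs <- function(aln) {
  code <- encode_alignment(aln)
  tab <- tabulate(code, nbins = 4)
  if (sum(tab) == 0) abort("alignment has no unambiguous bases.")
  f <- tab / sum(tab)
  names(f) <- c("A", "C", "G", "T")
  f
}

check_tree_alignment <- function(tree, aln) {
  if (!setequal(tree$tip.label, rownames(aln)))
    abort("tree tips and alignment taxa do not match.")
  invisible(TRUE)
}
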