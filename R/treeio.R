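#' Read a rooted tree from a Newick string
#'
#' Thin, validating wrapper around [ape::read.tree()]. Trees are kept rooted
#' throughout the package; unrooted input is rejected rather than silently
#' re-rooted, and duplicate tip labels are an error. Branch lengths are
#' optional (a bare topology is usable wherever only the topology matters).
#'
#' @param text A Newick string, e.g. `"((A:1,B:1):1,C:2);"`.
#' @return A rooted `phylo` object (class from the ape package).
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' @seealso [write_newick()]
#' @export
read_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  tr <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) abort(paste0("Newick parse error: ", conditionMessage(e)))
  )
  if (is.null(tr)) abort("Newick parse error: input could not be parsed.")
  if (anyDuplicated(tr$tip.label))
    abort(paste0("duplicate tip name(s): ",
                 paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", ")))
  if (!ape::is.rooted(tr))
    abort("tree is unrooted; this package keeps trees rooted throughout.")
  tr
}

#' Write a tree as a Newick string
#'
#' @param tree A `phylo` object.
#' @param digits Significant digits for branch lengths.
#' @return A Newick string (with trailing `;`).
#' @export
write_newick <- function(tree, digits = 12) {
  ape::write.tree(tree, digits = digits)
}

assert_tree <- function(tree) {
  if (!inherits(tree, "phylo")) abort("expected a `phylo` tree object.")
  invisible(tree)
}

assert_rooted_binary <- function(tree) {
  assert_tree(tree)
  if (!ape::is.rooted(tree)) abort("tree must be rooted.")
  if (!ape::is.binary(tree)) abort("tree must be fully resolved (binary).")
  invisible(tree)
}

root_node <- function(tree) n_tips(tree) + 1L # ape convention

n_tips <- function(tree) length(tree$tip.label)

# children of each node as a list indexed by node id (tips -> integer(0))
children_list <- function(tree) {
  nn <- n_tips(tree) + tree$Nnode
  ch <- vector("list", nn)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    ch[[p]] <- c(ch[[p]], tree$edge[i, 2])
  }
  ch
}

# depth of every node from the root, summing edge lengths
node_depths <- function(tree) {
  assert_tree(tree)
  if (is.null(tree$edge.length)) abort("tree has no branch lengths.")
  nn <- n_tips(tree) + tree$Nnode
  depth <- rep(NA_real_, nn)
  root <- n_tips(tree) + 1L
  depth[root] <- 0
  ord <- reorder_edges_preorder(tree)
  for (i in ord) {
    depth[tree$edge[i, 2]] <- depth[tree$edge[i, 1]] + tree$edge.length[i]
  }
  depth
}

# edge indices in an order where parents are visited before children
reorder_edges_preorder <- function(tree) {
  tr <- ape::reorder.phylo(tree, "cladewise")
  # reorder.phylo returns edges cladewise; map back to original edge indices
  key_orig <- paste(tree$edge[, 1], tree$edge[, 2])
  key_new <- paste(tr$edge[, 1], tr$edge[, 2])
  match(key_new, key_orig)
}

postorder_nodes <- function(tree) {
  # internal nodes ordered children-before-parents
  ord <- rev(reorder_edges_preorder(tree))
  nodes <- unique(c(tree$edge[ord, 2], n_tips(tree) + 1L))
  nodes[nodes > n_tips(tree)]
}

#' Node ages of a time tree
#'
#' For an ultrametric tree whose branch lengths are time spans, returns the
#' age of every node (time before present; tips have age 0, the root has the
#' largest age).
#'
#' @param tree An ultrametric `phylo` with branch lengths in time units.
#' @param tol Tolerance for the ultrametricity check, relative to root age.
#' @return A tibble with columns `node`, `label` (tip label or `""`),
#'   `is_tip`, and `age`.
#' @export
node_ages <- function(tree, tol = 1e-6) {
  assert_tree(tree)
  depth <- node_depths(tree)
  nt <- n_tips(tree)
  tip_depth <- depth[seq_len(nt)]
  root_age <- max(tip_depth)
  if (root_age > 0 && diff(range(tip_depth)) > tol * root_age)
    abort("tree is not ultrametric in time: tip depths differ.")
  age <- root_age - depth
  age[seq_len(nt)] <- 0
  nn <- nt + tree$Nnode
  tibble(
    node = seq_len(nn),
    label = c(tree$tip.label, rep("", tree$Nnode)),
    is_tip = seq_len(nn) <= nt,
    age = age
  )
}

validate_timetree <- function(tree, tol = 1e-6) {
  assert_rooted_binary(tree)
  ages <- node_ages(tree, tol = tol)
  # parent strictly older than child
  page <- ages$age[tree$edge[, 1]]
  cage <- ages$age[tree$edge[, 2]]
  if (any(page <= cage))
    abort("time tree invariant violated: a parent node is not older than its child.")
  invisible(tree)
}

validate_phylotree <- function(tree) {
  assert_rooted_binary(tree)
  if (is.null(tree$edge.length)) abort("tree has no branch lengths.")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    abort("branch lengths must be finite and nonnegative.")
  invisible(tree)
}

descendant_tips <- function(tree) {
  # list: node id -> integer vector of descendant tip ids (tips include self)
  nt <- n_tips(tree)
  nn <- nt + tree$Nnode
  desc <- vector("list", nn)
  for (i in seq_len(nt)) desc[[i]] <- i
  for (node in postorder_nodes(tree)) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    desc[[node]] <- sort(unlist(desc[kids]))
  }
  desc
}

#' Mean node-to-tip distance
#'
#' The sum of the path lengths from an internal node to each of its descendant
#' tips, divided by the number of descendant tips. Path lengths are in the
#' units of the tree's branch lengths (substitutions/site for an ML tree).
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param node Internal node id (ape numbering: tips are `1..n`, internal
#'   nodes `n+1..2n-1`).
#' @return A single numeric distance.
#' @export
node_to_tip_distance <- function(tree, node) {
  assert_tree(tree)
  if (is.null(tree$edge.length)) abort("tree has no branch lengths.")
  nt <- n_tips(tree)
  if (node <= nt) abort("`node` is a tip; node-to-tip distance is defined for internal nodes.")
  depth <- node_depths(tree)
  tips <- descendant_tips(tree)[[node]]
  mean(depth[tips] - depth[node])
}

#' Node-to-tip distances for all internal nodes
#'
#' @inheritParams node_to_tip_distance
#' @return A tibble with columns `node`, `n_tips` (descendant tip count) and
#'   `distance`.
#' @export
node_to_tip_distances <- function(tree) {
  assert_tree(tree)
  if (is.null(tree$edge.length)) abort("tree has no branch lengths.")
  nt <- n_tips(tree)
  depth <- node_depths(tree)
  desc <- descendant_tips(tree)
  nodes <- (nt + 1L):(nt + tree$Nnode)
  tibble(
    node = nodes,
    n_tips = vapply(desc[nodes], length, 1L),
    distance = vapply(nodes, function(v) mean(depth[desc[[v]]] - depth[v]), 1.0)
  )
}

#' Classify branches as short, intermediate or long
#'
#' Branches longer than one standard deviation above the mean branch length
#' are "long"; branches shorter than the mean are "short"; the rest are
#' "intermediate". The SD is the sample SD (n-1 denominator). Ties (length
#' exactly equal to the mean, or to mean + SD) fall in "intermediate" because
#' both defining inequalities are strict. With zero spread all branches sit at
#' the mean and are "intermediate".
#'
#' @param tree A rooted `phylo` with branch lengths (at least 2 branches).
#' @return A tibble with columns `parent`, `child`, `length`, `category`
#'   (factor: short < intermediate < long).
#' @export
classify_branches <- function(tree) {
  assert_tree(tree)
  if (is.null(tree$edge.length)) abort("tree has no branch lengths.")
  len <- tree$edge.length
  if (length(len) < 2) abort("need at least 2 branches to classify.")
  m <- mean(len)
  s <- stats::sd(len)
  cat <- ifelse(len > m + s, "long", ifelse(len < m, "short", "intermediate"))
  tibble(
    parent = tree$edge[, 1],
    child = tree$edge[, 2],
    length = len,
    category = factor(cat, levels = c("short", "intermediate", "long"))
  )
}

#' Classify internal nodes into shallow, intermediate and deep regions
#'
#' Regions are defined as fractions of the root age: nodes no older than
#' `shallow_frac * root_age` are shallow, nodes at least `deep_frac * root_age`
#' old are deep, the rest intermediate. The default deep threshold is 70% of
#' the root age; 50% is the conventional fallback when no internal node is
#' older than 70% of the root.
#'
#' @param tree An ultrametric `phylo` in time units (see [node_ages()]).
#' @param shallow_frac,deep_frac Region boundaries as fractions of root age;
#'   `0 < shallow_frac < deep_frac <= 1`.
#' @return A tibble with columns `node`, `age`, `region` (factor:
#'   shallow < intermediate < deep) over internal nodes.
#' @export
classify_node_depths <- function(tree, shallow_frac = 0.3, deep_frac = 0.7) {
  if (!(shallow_frac > 0 && shallow_frac < deep_frac && deep_frac <= 1))
    abort("need 0 < shallow_frac < deep_frac <= 1.")
  ages <- node_ages(tree)
  root_age <- max(ages$age)
  internal <- dplyr::filter(ages, !.data$is_tip)
  region <- ifelse(internal$age <= shallow_frac * root_age, "shallow",
            ifelse(internal$age >= deep_frac * root_age, "deep", "intermediate"))
  tibble(
    node = internal$node,
    age = internal$age,
    region = factor(region, levels = c("shallow", "intermediate", "deep"))
  )
}

#' Drop outgroup taxa before dating
#'
#' Relative-time estimation in this package operates on the ingroup only;
#' outgroups used for rooting are pruned first.
#'
#' @param tree A rooted `phylo`.
#' @param outgroup Character vector of tip labels to remove.
#' @return The pruned tree.
#' @export
prune_outgroup <- function(tree, outgroup) {
  assert_tree(tree)
  missing <- setdiff(outgroup, tree$tip.label)
  if (length(missing))
    abort(paste0("outgroup taxa not in tree: ", paste(missing, collapse = ", ")))
  ape::drop.tip(tree, outgroup)
}
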