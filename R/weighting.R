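#' Sequence weights
#'
#' Per-sequence prior weights that counteract uneven clade representation in
#' the alignment: sequences in crowded clades share a smaller allocation, so
#' near-duplicate sequences cannot mask the signal carried by rare ones.
#' Weights are non-negative and normalised to sum to 1.
#'
#' @param values Non-negative numeric vector, one entry per alignment row.
#' @param ids Optional identifiers (alignment order).
#' @return A `sequence_weights` numeric vector summing to 1.
#' @export
sequence_weights <- function(values, ids = names(values)) {
  values <- as.numeric(values)
  if (!length(values)) stop_sdr("empty weight vector", class = "sdrcov_empty_input_error")
  if (any(values < 0)) stop_sdr("negative sequence weight")
  s <- sum(values)
  if (s <= 0) stop_sdr("at least one sequence weight must be positive")
  structure(values / s, names = ids, class = "sequence_weights")
}

#' Uniform sequence weights
#'
#' @param n Number of sequences (>= 1), or a [domain_alignment] whose row
#'   count and ids are used.
#' @return A [sequence_weights] vector with every entry `1/n`.
#' @export
uniform_weights <- function(n) {
  ids <- NULL
  if (inherits(n, "domain_alignment")) { ids <- rownames(n); n <- nrow(n) }
  if (length(n) != 1L || n < 1L)
    stop_sdr("n must be a single count >= 1", class = "sdrcov_empty_input_error")
  sequence_weights(rep(1 / n, n), ids = ids)
}

#' Read explicit sequence weights
#'
#' Reads a two-column table (id, weight), matches the rows to the alignment
#' id order and normalises the weights to sum to 1.
#'
#' @param path Path to a whitespace/tab-delimited two-column file.
#' @param ids Alignment identifiers; every id must appear exactly once.
#' @return A [sequence_weights] vector in `ids` order.
#' @export
read_weights <- function(path, ids) {
  if (!file.exists(path)) stop_sdr("weights file not found: %s", path)
  tab <- utils::read.table(path, header = FALSE, col.names = c("id", "weight"),
                           colClasses = c("character", "numeric"))
  missing <- setdiff(ids, tab$id)
  extra <- setdiff(tab$id, ids)
  if (length(missing) || length(extra))
    stop_sdr("weight/alignment id mismatch (missing: %s; extra: %s)",
             paste(missing, collapse = ","), paste(extra, collapse = ","))
  w <- tab$weight[match(ids, tab$id)]
  if (any(w < 0)) stop_sdr("negative weight for id '%s'", ids[which(w < 0)[1L]])
  sequence_weights(w, ids = ids)
}

#' Pairwise fractional-identity distance matrix
#'
#' Distance 1 - identity, where identity is the fraction of columns at which
#' two rows carry the same non-gap residue (gapped columns count as
#' mismatches).  Used to build the default UPGMA guide tree.
#'
#' @param aln A [domain_alignment].
#' @return A `dist` object over the alignment rows.
#' @keywords internal
identity_dist <- function(aln) {
  n <- nrow(aln)
  d <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      d[i, j] <- d[j, i] <- 1 - sequence_identity(aln[i, ], aln[j, ])
  stats::as.dist(d)
}

#' Tree-proportional sequence weights
#'
#' Distributes a total weight of 1 from the root of a phylogenetic tree down
#' to the leaves: at every internal node the incoming weight is split among
#' the child subtrees in proportion to each subtree's total branch length
#' (the child edge plus all branches below it), so that sequences in crowded
#' clades share a smaller allocation.  When every subtree length at a node
#' is zero the split falls back to leaf counts, which makes a zero-length
#' tree yield uniform weights.
#'
#' When no tree is supplied a UPGMA guide tree is built internally from
#' pairwise fractional-identity distances (gaps counted as mismatches), with
#' rows ordered lexicographically by id before clustering so ties resolve
#' reproducibly.
#'
#' @param alignment A [domain_alignment].
#' @param tree Optional `phylo` tree (ape) whose tip labels equal the
#'   alignment ids.
#' @return A [sequence_weights] vector in alignment order.
#' @export
tree_weights <- function(alignment, tree = NULL) {
  ids <- rownames(alignment)
  if (length(ids) == 1L) return(sequence_weights(1, ids = ids))
  if (is.null(tree)) {
    ord <- order(ids)
    d <- identity_dist(domain_alignment(unclass(alignment)[ord, , drop = FALSE],
                                        ids = ids[ord]))
    hc <- stats::hclust(d, method = "average")
    tree <- ape::as.phylo(hc)
  }
  if (!inherits(tree, "phylo")) stop_sdr("tree must be an ape 'phylo' object")
  missing <- setdiff(ids, tree$tip.label)
  extra <- setdiff(tree$tip.label, ids)
  if (length(missing) || length(extra))
    stop_sdr("tree leaves and alignment ids differ (missing from tree: %s; extra in tree: %s)",
             paste(missing, collapse = ","), paste(extra, collapse = ","))
  w <- .apportion_tree_weights(tree)
  sequence_weights(w[ids], ids = ids)
}

# Recursive top-down apportioning on an ape phylo: the weight arriving at a
# node is split among children proportionally to subtree total branch length
# (child edge included); all-zero lengths fall back to leaf counts.
.apportion_tree_weights <- function(tree) {
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  elen <- tree$edge.length
  if (is.null(elen)) elen <- rep(0, nrow(edge))
  children <- split(seq_len(nrow(edge)), edge[, 1L])
  root <- ntip + 1L

  n_leaves <- numeric(ntip + tree$Nnode)
  sub_len <- numeric(ntip + tree$Nnode)
  fill <- function(node) {
    kid_edges <- children[[as.character(node)]]
    if (is.null(kid_edges)) { n_leaves[node] <<- 1; sub_len[node] <<- 0; return(invisible()) }
    for (e in kid_edges) {
      kid <- edge[e, 2L]
      fill(kid)
      n_leaves[node] <<- n_leaves[node] + n_leaves[kid]
      sub_len[node] <<- sub_len[node] + sub_len[kid] + elen[e]
    }
  }
  fill(root)

  wt <- numeric(ntip + tree$Nnode)
  wt[root] <- 1
  push <- function(node) {
    kid_edges <- children[[as.character(node)]]
    if (is.null(kid_edges)) return(invisible())
    kids <- edge[kid_edges, 2L]
    share <- sub_len[kids] + elen[kid_edges]
    if (sum(share) <= 0) share <- n_leaves[kids]
    wt[kids] <<- wt[node] * share / sum(share)
    for (kid in kids) push(kid)
  }
  push(root)
  stats::setNames(wt[seq_len(ntip)], tree$tip.label)
}
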