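# Tree-trace evolutionary conservation from a multiple sequence alignment.
#
# This is a simplified tree-trace calculator: homolog retrieval and
# Gibbs-like sequence sampling are replaced by uniform random subsampling of
# the alignment (seeded), with neighbor-joining trees built on
# percent-identity distances. File-based scores
# (conservation_from_file) are the high-fidelity alternative when a full
# evolutionary pipeline is available.

#' Read an aligned FASTA file as a character matrix
#'
#' @param path aligned FASTA (amino acids; gaps as \code{-}).
#' @return character matrix, rows named by sequence id.
#' @export
read_alignment <- function(path) {
  aln <- ape::read.FASTA(path, type = "AA")
  mat <- toupper(as.character(as.matrix(aln)))
  rownames(mat) <- names(aln)
  mat
}

# fraction of differing (non-pairwise-gap) columns between aligned rows
percent_identity_dist <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- mat[i, ] != "-" & mat[j, ] != "-"
      d[i, j] <- d[j, i] <-
        if (any(ok)) mean(mat[i, ok] != mat[j, ok]) else 1
    }
  }
  stats::as.dist(d)
}

#' Tree-trace conservation of the query sequence
#'
#' For each phylogenetic tree and each query position, the trace is the
#' topological level (0 at the query leaf, L at the root, where L is the
#' query leaf's root distance in levels) of the highest ancestral node
#' whose entire subtree conserves the query's amino acid at that position,
#' normalised by L so values lie in [0, 1]. A column conserved across the
#' whole tree scores 1; an amino acid private to the query scores 0. The
#' final score is the mean trace over all trees.
#'
#' @param alignment character matrix from \code{\link{read_alignment}} (or
#'   a path to an aligned FASTA file).
#' @param trees an \code{ape} \code{phylo} or \code{multiPhylo} object, or
#'   NULL to build \code{n_trees} neighbor-joining trees from
#'   percent-identity distances on uniform random subsamples of the
#'   alignment (midpoint-rooted; the query is always included).
#' @param query_id row name of the query sequence.
#' @param n_trees number of internally built trees (default 10).
#' @param sample_size sequences per subsample (default \code{min(50, n)}).
#' @param seed RNG seed for the subsampling (required when \code{trees} is
#'   NULL).
#' @return numeric vector of conservation scores in [0, 1], one per query
#'   residue (alignment columns where the query is non-gap, in order).
#' @export
tree_trace_conservation <- function(alignment, trees = NULL, query_id,
                                    n_trees = 10, sample_size = NULL,
                                    seed = NULL) {
  if (is.character(alignment) && length(alignment) == 1) {
    alignment <- read_alignment(alignment)
  }
  if (nrow(alignment) < 3) {
    stop("alignment must contain at least 3 sequences")
  }
  if (!query_id %in% rownames(alignment)) {
    stop("query '", query_id, "' absent from alignment")
  }
  if (is.null(trees)) {
    if (is.null(seed)) stop("a seed is required when trees are built internally")
    sample_size <- sample_size %||% min(50, nrow(alignment))
    sample_size <- min(sample_size, nrow(alignment))
    trees <- build_sample_trees(alignment, query_id, n_trees, sample_size,
                                seed)
  }
  if (inherits(trees, "phylo")) trees <- list(trees)
  traces <- lapply(trees, function(tr) {
    if (!ape::is.rooted(tr)) tr <- phangorn::midpoint(tr)
    tree_trace_one(alignment, tr, query_id)
  })
  scores <- Reduce(`+`, traces) / length(traces)
  qpos <- which(alignment[query_id, ] != "-")
  unname(scores[qpos])
}

build_sample_trees <- function(alignment, query_id, n_trees, sample_size,
                               seed) {
  ids <- rownames(alignment)
  others <- setdiff(ids, query_id)
  set.seed(seed)
  lapply(seq_len(n_trees), function(k) {
    take <- c(query_id,
              sample(others, min(sample_size - 1, length(others))))
    sub <- alignment[take, , drop = FALSE]
    tr <- ape::nj(percent_identity_dist(sub))
    phangorn::midpoint(tr)
  })
}

# per-column trace (full alignment width) for one rooted tree
tree_trace_one <- function(alignment, tree, query_id) {
  tips <- tree$tip.label
  if (!all(tips %in% rownames(alignment))) {
    stop("tree leaves must be a subset of the alignment sequence ids")
  }
  if (!query_id %in% tips) stop("query leaf absent from tree")
  ncol_a <- ncol(alignment)
  qrow <- alignment[query_id, ]
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  qtip <- match(query_id, tips)
  root <- tree$edge[1, 1]
  # ancestor chain from the query leaf to the root
  chain <- integer(0)
  node <- qtip
  while (node != root) {
    node <- parent[node]
    chain <- c(chain, node)
  }
  L <- length(chain)
  if (L == 0) stop("degenerate tree: query leaf is the root")
  sub <- alignment[tips, , drop = FALSE]
  match_q <- sweep(sub == matrix(qrow, nrow(sub), ncol_a, byrow = TRUE),
                   2, qrow != "-", "&")
  # conserved[l, p]: does the entire subtree of ancestor level l match the
  # query amino acid at column p
  trace <- numeric(ncol_a)
  desc <- descendant_tips(tree)
  conserved_prev <- rep(TRUE, ncol_a)  # level 0: the leaf itself
  level_reached <- integer(ncol_a)
  active <- qrow != "-"
  for (l in seq_len(L)) {
    tipset <- desc[[chain[l]]]
    ok <- active & conserved_prev &
      (colSums(match_q[tipset, , drop = FALSE]) == length(tipset))
    level_reached[ok] <- l
    conserved_prev <- ok
    if (!any(ok)) break
  }
  trace <- level_reached / L
  trace[!active] <- 0
  trace
}

# tip indices under each internal node (postorder accumulation)
descendant_tips <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  desc <- vector("list", n_node)
  for (i in seq_len(n_tip)) desc[[i]] <- i
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1]
    ch <- edge[k, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}
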