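#' Neighbor-joining tree from a distance or identity matrix
#'
#' Classic neighbor-joining agglomeration (Saitou-Nei, with the standard
#' Q-criterion and Studier-Keppler updates), written in-package so the tree
#' construction is fully specified: at each step the pair minimising
#' \eqn{Q_{ij} = (n-2) d_{ij} - r_i - r_j} is joined (ties resolved towards
#' the smallest row/column index), branch lengths follow the usual
#' three-point formulas, and the final three nodes are resolved exactly.
#' For an \linkS4class{IdentityMatrix}, distances are
#' \eqn{(100 - identity)/100}.
#'
#' @param x an \linkS4class{IdentityMatrix}, a symmetric numeric distance
#'   matrix, or a \code{dist}.
#' @return Unrooted binary tree of class \code{phylo} (ape), with branch
#'   lengths (possibly negative, as classic NJ allows).
#' @examples
#' d <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' njTree(d)
#' @export
njTree <- function(x) {
  D <- if (is(x, "IdentityMatrix")) (100 - x@.Data) / 100 else as.matrix(x)
  n <- nrow(D)
  if (n < 3L) stop("need at least three taxa")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8, check.attributes = FALSE)))
    stop("distance matrix is not symmetric")
  labels <- rownames(D)
  if (is.null(labels)) labels <- sprintf("t%d", seq_len(n))
  diag(D) <- 0

  # tips are phylo nodes 1..n; n+1 is the final trifurcating node; further
  # internal nodes count up from n+2
  nodeIds <- seq_len(n)
  nextInternal <- n + 2L
  edges <- matrix(0L, 0L, 2L)
  lens <- numeric(0)
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    hit <- which(Q == min(Q), arr.ind = TRUE)
    hit <- hit[hit[, 1L] < hit[, 2L], , drop = FALSE]
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
    i <- hit[1L, 1L]; j <- hit[1L, 2L]
    dij <- D[i, j]
    vi <- 0.5 * dij + (r[i] - r[j]) / (2 * (m - 2))
    vj <- dij - vi
    u <- nextInternal
    nextInternal <- nextInternal + 1L
    edges <- rbind(edges, c(u, nodeIds[i]), c(u, nodeIds[j]))
    lens <- c(lens, vi, vj)
    newd <- 0.5 * (D[i, ] + D[j, ] - dij)
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    dimnames(D) <- NULL
    nodeIds <- c(nodeIds[keep], u)
  }
  # closed-form resolution of the last three nodes
  a <- 0.5 * (D[1, 2] + D[1, 3] - D[2, 3])
  b <- 0.5 * (D[1, 2] + D[2, 3] - D[1, 3])
  cc <- 0.5 * (D[1, 3] + D[2, 3] - D[1, 2])
  root <- n + 1L
  edges <- rbind(edges, c(root, nodeIds[1L]), c(root, nodeIds[2L]),
                 c(root, nodeIds[3L]))
  lens <- c(lens, a, b, cc)
  tree <- list(edge = edges, edge.length = lens, tip.label = labels,
               Nnode = nextInternal - n - 1L)
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  # round-trip through Newick to canonicalise the internal node numbering
  ape::read.tree(text = ape::write.tree(tree))
}

#' Path-length (patristic) distances of a tree
#'
#' Sum of branch lengths along the path between every pair of tips; the
#' quantity neighbor joining preserves exactly for additive input
#' distances.
#'
#' @param tree a \code{phylo}.
#' @return Symmetric numeric matrix over the tip labels.
#' @export
treePathDistances <- function(tree) {
  m <- ape::dist.nodes(tree)
  ntip <- length(tree$tip.label)
  out <- m[seq_len(ntip), seq_len(ntip)]
  dimnames(out) <- list(tree$tip.label, tree$tip.label)
  out
}

#' Tip bipartitions induced by the internal edges of a tree
#'
#' Utility for topology checks: each internal edge splits the tips into two
#' sets; the set on the child side is returned, sorted.
#'
#' @param tree a \code{phylo}.
#' @return List of character vectors.
#' @export
treeSplits <- function(tree) {
  ntip <- length(tree$tip.label)
  out <- list()
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2L]
    if (child <= ntip) next
    tips <- ape::extract.clade(tree, child)$tip.label
    out[[length(out) + 1L]] <- sort(tips)
  }
  out
}
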