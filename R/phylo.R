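# Phylogenetic machinery: Abouheif proximities, Moran eigenvectors, and the
# branch-level incidence tables that feed the phylogenetic Hill estimators.

#' Tree depth (max root-to-tip distance)
#' @param tree A rooted `phylo` with branch lengths.
#' @return The maximum root-to-tip distance.
#' @export
tree_depth <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  max(ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))])
}

.check_ultrametric <- function(tree, tol = 1e-6) {
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  if (diff(range(depths)) > tol * max(depths)) {
    abort("tree is not ultrametric within tolerance")
  }
  invisible(TRUE)
}

# ancestors of each tip, from parent up to the root (internal nodes only)
.tip_ancestors <- function(tree) {
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ape::Ntip(tree) + 1L
  lapply(seq_len(ape::Ntip(tree)), function(tip) {
    path <- integer(0)
    node <- tip
    while (node != root) {
      node <- parent[node]
      path <- c(path, node)
    }
    path
  })
}

#' Abouheif phylogenetic proximity
#'
#' Classic Abouheif proximity ("oriAbouheif" construction, no
#' normalization): for tips i and j,
#' `prox(i, j) = 1 / prod(dd(n))` over the interior nodes `n` on the nodal
#' path between i and j (their most recent common ancestor included), where
#' `dd(n)` is the number of direct descendants of `n`. The diagonal is zero
#' and no row normalization is applied.
#'
#' @param tree A rooted `phylo` (binary or polytomous) with >= 2 tips.
#' @return A symmetric species x species matrix with zero diagonal.
#' @export
abouheif_proximity <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- ape::Ntip(tree)
  if (n < 2) abort("abouheif_proximity needs at least 2 tips")
  dd <- tabulate(tree$edge[, 1], nbins = max(tree$edge))
  anc <- .tip_ancestors(tree)
  prox <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      # mrca = first shared ancestor; path = disjoint ancestor stretches + mrca
      shared <- intersect(anc[[i]], anc[[j]])
      mrca <- shared[1]
      path_nodes <- c(setdiff(anc[[i]], shared), setdiff(anc[[j]], shared), mrca)
      prox[i, j] <- prox[j, i] <- 1 / prod(dd[path_nodes])
    }
  }
  prox
}

#' Moran eigenvectors of a phylogenetic proximity matrix
#'
#' Eigenvectors of the doubly centered proximity matrix, ordered by
#' descending eigenvalue; these carry the phylogenetic correlation
#' structure at decreasing scales and serve as predictors in trait
#' imputation. At most `n - 1` non-trivial vectors exist after centering.
#'
#' @param prox Symmetric proximity matrix (e.g. [abouheif_proximity()]).
#' @param k Number of leading eigenvectors requested (default 30); the
#'   result has `min(k, n - 1)` columns.
#' @return An `n x min(k, n - 1)` matrix; columns named `ME1`, `ME2`, ...
#' @export
moran_eigenvectors <- function(prox, k = 30) {
  if (k < 1) abort("k must be >= 1")
  prox <- as.matrix(prox)
  if (!isSymmetric(unname(prox), tol = 1e-8)) abort("proximity matrix must be symmetric")
  n <- nrow(prox)
  # work in the orthogonal complement of the constant vector so every
  # returned eigenvector is exactly centered, even under eigenvalue ties
  Q <- qr.Q(qr(cbind(rep(1, n), diag(n))))[, -1, drop = FALSE]
  eig <- eigen(crossprod(Q, prox %*% Q), symmetric = TRUE)
  keep <- seq_len(min(k, n - 1))
  out <- Q %*% eig$vectors[, keep, drop = FALSE]
  dimnames(out) <- list(rownames(prox), paste0("ME", keep))
  out
}

# Precompute the tip-membership structure of every branch. Returns a list
# with the edge table and a tips x edges logical membership matrix.
.branch_structure <- function(tree) {
  n_tip <- ape::Ntip(tree)
  n_edge <- nrow(tree$edge)
  anc <- .tip_ancestors(tree)
  # edge index by child node
  edge_of <- integer(max(tree$edge))
  edge_of[tree$edge[, 2]] <- seq_len(n_edge)
  member <- matrix(FALSE, n_tip, n_edge)
  for (tip in seq_len(n_tip)) {
    nodes <- c(tip, anc[[tip]])
    nodes <- nodes[nodes != (n_tip + 1L)] # drop root (no incoming edge)
    member[tip, edge_of[nodes]] <- TRUE
  }
  rownames(member) <- tree$tip.label
  list(lengths = tree$edge.length, member = member)
}

# Branch-level incidence summaries from a unit x species logical matrix.
# Y: units containing >= 1 descendant tip (union incidence);
# Z: sum of descendant tip incidences; sumsq: sum over units of the squared
# per-unit descendant count (exact second-moment ingredient for q = 2).
.branch_stats <- function(struct, X) {
  missing_sp <- setdiff(colnames(X), rownames(struct$member))
  if (length(missing_sp) > 0) {
    abort(paste0("species not in tree: ", paste(missing_sp, collapse = ", ")))
  }
  M <- struct$member[colnames(X), , drop = FALSE]
  counts <- X %*% M # units x edges descendant counts
  tibble(
    branch = seq_along(struct$lengths),
    length = struct$lengths,
    Y = as.integer(colSums(counts > 0)),
    Z = as.integer(colSums(counts)),
    sumsq = colSums(counts^2)
  )
}

#' Branch incidence frequencies for an assemblage
#'
#' For every branch of the tree, counts the selected sampling units in which
#' at least one descendant tip was detected (`Y`), together with the sum
#' (`Z`) and per-unit sum of squares (`sumsq`) of descendant-tip detection
#' counts, which the order-2 phylogenetic estimator needs. Branches with no
#' detected descendants are retained with zero frequency.
#'
#' @param tree A rooted ultrametric `phylo` whose tips cover all detected
#'   species.
#' @param x An `incidence_matrix`.
#' @inheritParams to_frequencies
#' @param tol Relative ultrametricity tolerance.
#' @return A tibble of class `branch_freq` with columns `branch`, `length`,
#'   `Y`, `Z`, `sumsq` and attributes `T` (units) and `depth` (tree depth).
#' @export
branch_frequencies <- function(tree, x, treatment = NULL, plots = NULL,
                               units = NULL, tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"), inherits(x, "incidence_matrix"))
  .check_ultrametric(tree, tol)
  X <- .incidence_logical(x, treatment = treatment, plots = plots, units = units)
  out <- .branch_stats(.branch_structure(tree), X)
  attr(out, "T") <- nrow(X)
  attr(out, "depth") <- tree_depth(tree)
  class(out) <- c("branch_freq", class(out))
  out
}
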