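#' Allele-sharing (identity-by-state) distance between samples
#'
#' For each pair of samples, over the sites where both are called, the
#' number of alleles shared per site is 2 for identical homozygotes, 1
#' whenever one genotype is heterozygous and the other differs (2 for two
#' heterozygotes), and 0 for opposite homozygotes; the distance is
#' \code{1 - shared / (2 * sites compared)}, i.e. one minus the IBS
#' proportion. With genotype codes 0/1/2, shared alleles per site equal
#' \code{2 - |g_a - g_b|}.
#'
#' @param x a \code{\link{variant_table}}
#' @return list with \code{dist}: symmetric matrix of pairwise distances in
#'   [0, 1] with zero diagonal, and \code{n_sites}: matrix of per-pair
#'   counts of sites compared
#' @export
allele_sharing_distance <- function(x) {
  samp <- samples(x)
  n <- length(samp)
  d <- matrix(0, n, n, dimnames = list(samp, samp))
  cnt <- matrix(0L, n, n, dimnames = list(samp, samp))
  for (i in seq_len(n)) {
    cnt[i, i] <- sum(!is.na(x$gt[, i]))
    for (j in seq_len(n)[-seq_len(i)]) {
      a <- x$gt[, i]; b <- x$gt[, j]
      ok <- !is.na(a) & !is.na(b)
      if (!any(ok))
        stop("no comparable sites between ", samp[i], " and ", samp[j])
      shared <- 2L - abs(a[ok] - b[ok])
      d[i, j] <- d[j, i] <- 1 - sum(shared) / (2 * sum(ok))
      cnt[i, j] <- cnt[j, i] <- sum(ok)
    }
  }
  list(dist = d, n_sites = cnt)
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard NJ agglomeration under the Q-matrix criterion. On an additive
#' distance matrix the output tree's leaf-to-leaf path lengths reproduce
#' the input distances exactly. Two determinism rules: ties in the Q
#' minimisation are broken by the lowest (row, column) pair in the current
#' label order, and a negative branch-length estimate is clamped to zero
#' with the deficit absorbed by its sibling branch (keeping the pair's
#' summed length, and the tree's path lengths on clean inputs, intact).
#'
#' @param d symmetric distance matrix with row/column names (>= 3 taxa)
#' @return an unrooted \code{ape} \code{phylo} tree
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("neighbour joining needs at least 3 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", 1:n)
  stopifnot(isSymmetric(unname(d)))
  labels <- rownames(d)        # newick fragment per active cluster
  clamp_pair <- function(bi, bj) {
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    c(max(bi, 0), max(bj, 0))
  }
  while (nrow(d) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    # ties broken by the lexicographically lowest (row, col) pair
    best <- c(NA, NA); best_q <- Inf
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      if (q[i, j] < best_q) { best_q <- q[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    bi <- 0.5 * d[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    bj <- d[i, j] - bi
    b <- clamp_pair(bi, bj)
    new_lab <- sprintf("(%s:%.15g,%s:%.15g)", labels[i], b[1],
                       labels[j], b[2])
    du <- 0.5 * (d[i, ] + d[j, ] - d[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    labels <- c(labels[keep], new_lab)
    rownames(d2) <- colnames(d2) <- paste0("c", seq_len(m - 1))
    d <- d2
  }
  # final three clusters joined at a central node (three-point formulas)
  b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  b <- pmax(c(b1, b2, b3), 0)
  nwk <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                 labels[1], b[1], labels[2], b[2], labels[3], b[3])
  ape::read.tree(text = nwk)
}

# undirected adjacency list of a phylo tree: for node k, a matrix of
# (neighbour, edge length) rows
tree_adjacency <- function(tree) {
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  adj <- vector("list", n_nodes)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]; w <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  adj
}

# unique path between two nodes: data.frame of nodes visited and the
# cumulative distance at each, by depth-first search
tree_path <- function(adj, from, to) {
  n <- length(adj)
  parent <- rep(NA_integer_, n); pdist <- rep(NA_real_, n)
  stack <- from; visited <- rep(FALSE, n); visited[from] <- TRUE
  while (length(stack) > 0) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v == to) break
    nb <- adj[[v]]
    for (k in seq_len(NROW(nb))) {
      u <- nb[k, 1]
      if (!visited[u]) {
        visited[u] <- TRUE; parent[u] <- v; pdist[u] <- nb[k, 2]
        stack <- c(stack, u)
      }
    }
  }
  nodes <- to; v <- to
  while (!is.na(parent[v])) { v <- parent[v]; nodes <- c(v, nodes) }
  cum <- c(0, cumsum(pdist[nodes[-1]]))
  data.frame(node = nodes, cum = cum)
}

# serialise the tree as a rooted newick from a virtual root placed on the
# edge (a, b) at distance `da` from a and `db` from b; if da or db is 0 the
# root coincides with that node
root_at_point <- function(tree, adj, a, b, da, db) {
  labels <- tree$tip.label
  subtree <- function(v, from, blen) {
    nb <- adj[[v]]
    kids <- nb[nb[, 1] != from, , drop = FALSE]
    if (NROW(kids) == 0) {
      sprintf("%s:%.15g", labels[v], blen)
    } else {
      inner <- vapply(seq_len(NROW(kids)), function(k)
        subtree(kids[k, 1], v, kids[k, 2]), character(1))
      sprintf("(%s):%.15g", paste(inner, collapse = ","), blen)
    }
  }
  if (da <= 0 || db <= 0) {
    at <- if (da <= 0) a else b
    nb <- adj[[at]]
    parts <- vapply(seq_len(NROW(nb)), function(k)
      subtree(nb[k, 1], at, nb[k, 2]), character(1))
    if (at <= ape::Ntip(tree))       # rooting at a leaf keeps it as a child
      parts <- c(parts, sprintf("%s:0", labels[at]))
    nwk <- sprintf("(%s);", paste(parts, collapse = ","))
  } else {
    nwk <- sprintf("(%s,%s);", subtree(a, b, da), subtree(b, a, db))
  }
  ape::read.tree(text = nwk)
}

#' Midpoint-root an unrooted tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path. All
#' leaf pairs are examined; ties on the diameter are broken by tip label
#' order. If the midpoint falls exactly on an internal node the tree is
#' rooted there; a tree whose branches are all zero-length has no defined
#' midpoint and is rooted at an arbitrary internal node with a warning.
#'
#' @param tree an unrooted \code{ape} \code{phylo} with branch lengths
#' @return the rooted \code{phylo}; the leaf set is unchanged
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  adj <- tree_adjacency(tree)
  ntip <- ape::Ntip(tree)
  if (sum(tree$edge.length) == 0) {
    warning("all branch lengths are zero; rooting at an internal node")
    return(root_at_point(tree, adj, ntip + 1L, ntip + 1L, 0, 0))
  }
  ord <- order(tree$tip.label)
  best <- c(NA, NA); best_d <- -Inf
  dmat <- stats::cophenetic(tree)
  for (ii in 1:(ntip - 1)) for (jj in (ii + 1):ntip) {
    i <- ord[ii]; j <- ord[jj]
    dij <- dmat[tree$tip.label[i], tree$tip.label[j]]
    if (dij > best_d + 1e-12) { best_d <- dij; best <- c(i, j) }
  }
  path <- tree_path(adj, best[1], best[2])
  half <- best_d / 2
  k <- max(which(path$cum <= half + 1e-12))
  if (abs(path$cum[k] - half) < 1e-12) {
    root_at_point(tree, adj, path$node[k], path$node[k], 0, 0)
  } else {
    a <- path$node[k]; b <- path$node[k + 1]
    root_at_point(tree, adj, a, b, half - path$cum[k], path$cum[k + 1] - half)
  }
}
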