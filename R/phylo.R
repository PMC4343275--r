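#' Hamming distance matrix from a binary presence matrix
#'
#' Samples are compared as binary mutation vectors; the distance between two
#' samples is the number of variants at which they differ. To anchor the
#' lineage at the normal, include D as an all-absent column (its distance to
#' a tumor is then the size of that tumor's somatic set).
#'
#' @param pm logical/0-1 matrix, variants x samples.
#' @return Symmetric numeric matrix of class `dist`-like (plain matrix) with
#'   sample dimnames.
#' @export
hamming_matrix <- function(pm) {
  m <- as.matrix(pm) * 1
  labs <- colnames(m)
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sum(m[, i] != m[, j])
    }
  }
  d
}

#' Euclidean distance matrix from per-bin copy ratios
#'
#' @param ratios numeric matrix, bins x samples, on a common bin axis.
#' @return Symmetric distance matrix with sample dimnames.
#' @export
euclidean_matrix <- function(ratios) {
  if (is.null(colnames(ratios))) stop("ratios must have sample columns")
  labs <- colnames(ratios)
  n <- ncol(ratios)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sqrt(sum((ratios[, i] - ratios[, j])^2))
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration: at each step the pair minimizing
#' `Q(i,j) = (n-2) d(i,j) - r(i) - r(j)` is joined, with branch lengths
#' `l(i) = d(i,j)/2 + (r(i) - r(j)) / (2(n-2))` and the usual reduction
#' formula. Ties go to the lexicographically smallest pair in the current
#' taxon order. Returns an unrooted `phylo` tree.
#'
#' @param d symmetric distance matrix with at least 3 labeled taxa.
#' @param clamp_negative clamp negative branch lengths to zero, transferring
#'   the deficit to the sibling edge (raw lengths kept in
#'   `attr(tree, "raw_edge_length")`).
#' @return An object of class `phylo` (see \pkg{ape}).
#' @export
neighbor_joining <- function(d, clamp_negative = TRUE) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  labs <- rownames(d) %||% paste0("t", seq_len(n))
  tips <- seq_len(n)
  next_node <- n + 1L          # ape convention: internal nodes follow tips
  active <- as.list(tips)      # node ids of active rows
  edges <- NULL
  lens <- NULL
  D <- d
  while (length(active) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    q <- (m - 2) * D - outer(r, r, `+`)
    diag(q) <- Inf
    best <- which(q == min(q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- best[1]
    j <- best[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    new_id <- next_node
    next_node <- next_node + 1L
    edges <- rbind(edges, c(new_id, active[[i]]), c(new_id, active[[j]]))
    lens <- c(lens, li, lj)
    newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    active <- c(active[keep], new_id)
  }
  # final three taxa joined at one internal node
  dd <- D
  x <- (dd[1, 2] + dd[1, 3] - dd[2, 3]) / 2
  y <- (dd[1, 2] + dd[2, 3] - dd[1, 3]) / 2
  z <- (dd[1, 3] + dd[2, 3] - dd[1, 2]) / 2
  center <- next_node
  edges <- rbind(edges, c(center, active[[1]]), c(center, active[[2]]),
                 c(center, active[[3]]))
  lens <- c(lens, x, y, z)

  n_internal <- center - n
  # renumber internal nodes so the final center (the basal node) comes first
  map <- seq_len(center)
  internal <- (n + 1L):center
  map[internal] <- n + 1L + (center - internal)
  edges <- matrix(map[edges], ncol = 2)
  ord <- order(edges[, 1], edges[, 2])
  edges <- edges[ord, , drop = FALSE]
  lens <- lens[ord]
  raw <- lens
  if (clamp_negative && any(lens < 0)) {
    for (k in which(lens < 0)) {
      parent <- edges[k, 1]
      sib <- which(edges[, 1] == parent & seq_along(lens) != k)
      if (length(sib) > 0) {
        lens[sib[1]] <- lens[sib[1]] + lens[k]
      }
      lens[k] <- 0
    }
  }
  tree <- structure(list(edge = edges, edge.length = lens,
                         tip.label = labs, Nnode = n_internal),
                    class = "phylo")
  attr(tree, "order") <- NULL
  tree <- ape::reorder.phylo(tree, "cladewise")
  attr(tree, "raw_edge_length") <- raw
  tree
}

#' Re-root a lineage tree at the diploid sample
#'
#' Places the root on the edge adjacent to the given leaf (the diploid
#' normal), yielding a rooted tree in which branch lengths - and hence all
#' leaf-to-leaf path lengths - are preserved. Rerooting an already D-rooted
#' tree is a no-op.
#'
#' @param tree a `phylo` tree containing the leaf.
#' @param leaf leaf label to root by (default `"D"`).
#' @return A rooted `phylo` tree.
#' @export
reroot_at <- function(tree, leaf = "D") {
  if (!leaf %in% tree$tip.label) stop("unknown leaf label: ", leaf)
  un <- ape::unroot(tree)
  ape::root(un, outgroup = leaf, resolve.root = TRUE)
}

#' Does a set of leaves form a clade away from the root?
#'
#' Convenience wrapper used to check lineage topology claims, e.g. that AA
#' and AB are sisters with H attaching closer to the D root.
#'
#' @param tree rooted `phylo` tree.
#' @param leaves character vector of leaf labels.
#' @return Logical.
#' @export
is_clade <- function(tree, leaves) {
  ape::is.monophyletic(tree, leaves)
}
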