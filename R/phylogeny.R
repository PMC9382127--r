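# Distance matrices, neighbour-joining trees with bootstrap support, and
# subgroup cutting. Trees are returned as ape "phylo" objects (unrooted),
# with bootstrap supports (0-100) stored in node.label.
#
# The NJ agglomeration is implemented in-package so the contract is exact:
# Saitou-Nei Q-criterion, ties broken by the lexicographically smallest
# label pair, negative branch lengths clamped to zero with the deficit
# moved to the sister branch.

#' Pairwise distance matrix from a protein multiple alignment
#'
#' Distance is the mismatch proportion over mutually ungapped columns,
#' optionally Poisson-corrected (`-ln(1 - p)`).
#'
#' @param alignment named character vector of equal-length aligned rows
#'   (`-` for gaps), or an `AAStringSet`.
#' @param correction `"poisson"` (default) or `"none"`.
#' @return Symmetric numeric matrix with taxa dimnames.
#' @export
pdistance <- function(alignment, correction = c("poisson", "none")) {
  correction <- match.arg(correction)
  aln <- as_protein_vector(alignment)
  if (length(aln) < 2) stop("alignment needs at least 2 rows")
  if (length(unique(nchar(aln))) != 1) stop("alignment rows differ in length")
  mat <- do.call(rbind, strsplit(aln, ""))
  rownames(mat) <- names(aln)
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  gap <- mat == "-"
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !gap[i, ] & !gap[j, ]
    if (!any(ok))
      stop("no comparable columns between ", names(aln)[i], " and ",
           names(aln)[j])
    p <- mean(mat[i, ok] != mat[j, ok])
    if (correction == "poisson") {
      if (p >= 1)
        stop("saturated pair (p = 1) between ", names(aln)[i], " and ",
             names(aln)[j], "; Poisson correction undefined")
      p <- -log(1 - p)
    }
    d[i, j] <- d[j, i] <- p
  }
  d
}

# As pdistance but capping p below 1 so resampled (bootstrap) replicates
# cannot abort a run on a degenerate column draw.
.pdistance_capped <- function(mat, gap, correction) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !gap[i, ] & !gap[j, ]
    p <- if (any(ok)) mean(mat[i, ok] != mat[j, ok]) else 1 - 1e-6
    if (correction == "poisson") p <- -log(1 - min(p, 1 - 1e-6))
    d[i, j] <- d[j, i] <- p
  }
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard two-point branch-length
#' formulas. Q-criterion ties are broken by the lexicographically smallest
#' label pair for cross-platform determinism; negative branch lengths are
#' clamped to 0 with the deficit added to the sister branch.
#'
#' @param dm symmetric distance matrix with >= 3 labelled taxa.
#' @return Unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) stop("dm must be square")
  if (is.null(rownames(dm))) stop("dm must have taxa labels")
  if (max(abs(dm - t(dm))) > 1e-12) stop("dm must be symmetric")
  if (any(dm < 0)) stop("dm must be nonnegative")
  n_tip <- nrow(dm)
  if (n_tip < 3) stop("need at least 3 taxa")
  tips <- rownames(dm)

  # active nodes: ape numbering (tips 1..n, internals n+1 ..)
  node_id <- seq_len(n_tip)
  labels <- tips
  D <- dm
  edges <- matrix(0L, 0, 2)
  lens <- numeric(0)
  next_internal <- 2L * n_tip - 2L  # count down so root ends at n_tip+1
  add_edge <- function(parent, child, len) {
    edges <<- rbind(edges, c(parent, child))
    lens <<- c(lens, len)
  }

  while (nrow(D) > 3) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # tie-break: lexicographically smallest (labelA, labelB) pair
    keylab <- apply(cand, 1, function(ij) {
      ab <- sort(c(labels[ij[1]], labels[ij[2]]))
      paste(ab, collapse = "\r")
    })
    pick <- cand[order(keylab)[1], ]
    i <- pick[1]; j <- pick[2]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    bi <- max(bi, 0); bj <- max(bj, 0)
    u <- next_internal
    next_internal <- next_internal - 1L
    add_edge(u, node_id[i], bi)
    add_edge(u, node_id[j], bj)
    duk <- pmax((D[i, ] + D[j, ] - D[i, j]) / 2, 0)
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], duk[keep]),
                c(duk[keep], 0))
    labs2 <- c(labels[keep], min(labels[c(i, j)]))
    dimnames(D2) <- list(labs2, labs2)
    node_id <- c(node_id[keep], u)
    labels <- labs2
    D <- D2
  }

  # final three-node star joined at the root (n_tip + 1)
  root <- n_tip + 1L
  a <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  c3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  br <- c(a, b, c3)
  for (k in 1:3) {
    if (br[k] < 0) {
      others <- setdiff(1:3, k)
      br[others] <- br[others] + br[k] / 2
      br[k] <- 0
    }
  }
  br <- pmax(br, 0)
  for (k in 1:3) add_edge(root, node_id[k], br[k])

  n_internal <- n_tip - 2L
  tree <- structure(list(edge = edges, edge.length = lens,
                         tip.label = tips, Nnode = n_internal),
                    class = "phylo", order = "unknown")
  tree <- ape::reorder.phylo(tree, "cladewise")
  tree
}

# Internal bipartitions of an unrooted tree as canonical label strings:
# each internal edge splits the taxa; the side NOT containing the first
# tip label, sorted and collapsed, identifies the split.
tree_bipartitions <- function(tree) {
  n_tip <- length(tree$tip.label)
  ref <- tree$tip.label[1]
  desc <- .edge_descendants(tree)
  out <- character(0)
  for (k in seq_len(nrow(tree$edge))) {
    child <- tree$edge[k, 2]
    if (child <= n_tip) next  # trivial split
    side <- tree$tip.label[desc[[child]]]
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) < 2 || length(side) > n_tip - 2) next
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

# tip sets below each node (indices into tip.label)
.edge_descendants <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  desc <- vector("list", n_node)
  for (i in seq_len(n_tip)) desc[[i]] <- i
  edges <- tree$edge[order(tree$edge[, 1], decreasing = TRUE), , drop = FALSE]
  # postorder accumulation: repeat passes until stable (trees are small)
  done <- FALSE
  while (!done) {
    done <- TRUE
    for (k in seq_len(nrow(edges))) {
      p <- edges[k, 1]; ch <- edges[k, 2]
      if (!is.null(desc[[ch]])) {
        add <- setdiff(desc[[ch]], desc[[p]])
        if (length(add)) { desc[[p]] <- c(desc[[p]], add); done <- FALSE }
      } else done <- FALSE
    }
  }
  desc
}

#' Neighbour-joining tree with bootstrap supports
#'
#' Builds the full-data NJ tree, then resamples alignment columns with
#' replacement `replicates` times; the support of each internal edge is the
#' percentage of replicate trees containing the same bipartition. Supports
#' are attached as `node.label` (root label empty). Fully reproducible for
#' a fixed `seed`.
#'
#' @param alignment named aligned protein rows (see [pdistance()]).
#' @param replicates bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param correction distance correction passed to [pdistance()].
#' @return list with `tree` (phylo, node labels = supports) and `supports`
#'   (named vector keyed by canonical bipartition).
#' @export
nj_bootstrap <- function(alignment, replicates = 1000, seed = 1,
                         correction = c("poisson", "none")) {
  correction <- match.arg(correction)
  stopifnot(replicates >= 1)
  aln <- as_protein_vector(alignment)
  aln <- aln[order(names(aln))]  # taxa-order invariance
  main <- nj_tree(pdistance(aln, correction))
  target <- tree_bipartitions(main)
  counts <- stats::setNames(numeric(length(target)), target)
  mat <- do.call(rbind, strsplit(aln, ""))
  rownames(mat) <- names(aln)
  L <- ncol(mat)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (rep in seq_len(replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    m2 <- mat[, cols, drop = FALSE]
    d <- .pdistance_capped(m2, m2 == "-", correction)
    bt <- nj_tree(d)
    hits <- intersect(tree_bipartitions(bt), target)
    counts[hits] <- counts[hits] + 1
  }
  supports <- 100 * counts / replicates
  # attach supports to internal nodes
  n_tip <- length(main$tip.label)
  desc <- .edge_descendants(main)
  labs <- character(main$Nnode)
  for (k in seq_len(nrow(main$edge))) {
    child <- main$edge[k, 2]
    if (child <= n_tip) next
    side <- main$tip.label[desc[[child]]]
    if (main$tip.label[1] %in% side) side <- setdiff(main$tip.label, side)
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(supports))
      labs[child - n_tip] <- format(round(supports[[key]], 1), trim = TRUE)
  }
  main$node.label <- labs
  list(tree = main, supports = supports)
}

#' Cut an unrooted tree into subgroups
#'
#' Removes the `k - 1` longest internal edges (ties resolved by a canonical
#' ordering on the bipartition labels) and assigns each connected component
#' a subgroup id, numbered by the first taxon (in tip order) each component
#' contains.
#'
#' @param tree an `ape::phylo` tree.
#' @param k number of subgroups, `1 <= k <= leaf count`.
#' @return Named integer vector mapping taxa to subgroup ids `1..k`.
#' @export
cut_subgroups <- function(tree, k) {
  n_tip <- length(tree$tip.label)
  if (k < 1 || k > n_tip) stop("k out of range [1, ", n_tip, "]")
  n_node <- n_tip + tree$Nnode
  desc <- .edge_descendants(tree)
  is_internal <- tree$edge[, 1] > n_tip & tree$edge[, 2] > n_tip
  keylab <- vapply(seq_len(nrow(tree$edge)), function(e) {
    side <- tree$tip.label[desc[[tree$edge[e, 2]]]]
    if (tree$tip.label[1] %in% side) side <- setdiff(tree$tip.label, side)
    paste(sort(side), collapse = "|")
  }, "")
  # priority: internal edges first, then terminal; longer first; canonical
  # bipartition label breaks ties
  ord <- order(!is_internal, -tree$edge.length, keylab)

  taxa_groups <- function(drop) {
    parent <- seq_len(n_node)
    find <- function(x) {
      while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }
      x
    }
    for (e in setdiff(seq_len(nrow(tree$edge)), drop)) {
      a <- find(tree$edge[e, 1]); b <- find(tree$edge[e, 2])
      if (a != b) parent[a] <- b
    }
    vapply(seq_len(n_tip), find, integer(1))
  }

  drop <- integer(0)
  comp <- taxa_groups(drop)
  # cut edges in priority order, skipping cuts that do not split any taxa
  # group, until k groups exist (generic case: the k-1 longest internal
  # edges, exactly the simple rule)
  for (e in ord) {
    if (length(unique(comp)) >= k) break
    trial <- taxa_groups(c(drop, e))
    if (length(unique(trial)) > length(unique(comp))) {
      drop <- c(drop, e)
      comp <- trial
    }
  }
  stats::setNames(match(comp, unique(comp)), tree$tip.label)
}

#' Write a tree with supports to a Newick file
#'
#' @param tree `phylo` object (supports in `node.label` are preserved).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
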