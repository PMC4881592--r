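#' Agglomerative clustering engine
#'
#' Shared engine behind [upgma_tree()] and [single_linkage_tree()].
#' Implements classic agglomerative clustering with either minimum
#' (single) or arithmetic-average (UPGMA) inter-cluster distances, with a
#' deterministic tie rule: among merge candidates at the minimum distance,
#' the pair whose lexicographically smallest leaf label comes first is
#' merged (ties on that broken by the smallest label of the partner
#' cluster). The result uses the `hclust` merge encoding so base plotting
#' and `cutree()` work, with `height` holding the raw inter-cluster merge
#' distance.
#'
#' @param dist symmetric non-negative matrix or `dist`, zero diagonal.
#' @param labels leaf labels (default: dimnames of `dist`).
#' @param method `"single"` or `"average"`.
#' @return object of class `c("linkage_tree", "hclust")`.
#' @keywords internal
agglomerate <- function(dist, labels = NULL, method = c("single", "average")) {
  method <- match.arg(method)
  d <- if (inherits(dist, "dist")) as.matrix(dist) else as.matrix(dist)
  n <- nrow(d)
  if (is.null(labels)) labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (n < 2) mpm_stop("clustering needs at least 2 items")
  if (length(labels) != n) mpm_stop("labels length does not match distance matrix")
  if (anyDuplicated(labels)) mpm_stop("duplicate labels in distance matrix")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    mpm_stop("distance matrix is not symmetric")
  if (any(d < 0)) mpm_stop("distance matrix has negative entries")
  if (any(abs(diag(d)) > 1e-12)) mpm_stop("distance matrix diagonal is not zero")

  # active clusters: id (hclust convention: -leaf or +merge row), size,
  # min leaf label (for tie-breaking), current row index in d
  act_id <- -seq_len(n)
  act_size <- rep(1L, n)
  act_min <- labels
  alive <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  members <- as.list(seq_len(n))   # leaf indices, for ordering

  order_list <- vector("list", n)
  for (i in seq_len(n)) order_list[[i]] <- i

  for (step in seq_len(n - 1L)) {
    idx <- which(alive)
    # minimum off-diagonal distance among alive clusters
    sub <- d[idx, idx, drop = FALSE]
    diag(sub) <- Inf
    mval <- min(sub)
    cand <- which(sub == mval, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # deterministic tie-break on sorted (min label, partner min label)
    key1 <- pmin(act_min[idx[cand[, 1]]], act_min[idx[cand[, 2]]])
    key2 <- pmax(act_min[idx[cand[, 1]]], act_min[idx[cand[, 2]]])
    pick <- order(key1, key2)[1]
    a <- idx[cand[pick, 1]]; b <- idx[cand[pick, 2]]
    # earlier-created cluster is the left child
    left <- if (cluster_age(act_id[a]) <= cluster_age(act_id[b])) a else b
    right <- if (left == a) b else a

    merge[step, ] <- c(act_id[left], act_id[right])
    height[step] <- mval

    # Lance-Williams update into slot `a`; retire slot `b`
    if (method == "single") {
      new_d <- pmin(d[a, ], d[b, ])
    } else {
      new_d <- (act_size[a] * d[a, ] + act_size[b] * d[b, ]) /
        (act_size[a] + act_size[b])
    }
    d[a, ] <- new_d; d[, a] <- new_d; d[a, a] <- 0
    alive[b] <- FALSE
    act_id[a] <- step
    act_size[a] <- act_size[a] + act_size[b]
    act_min[a] <- min(act_min[a], act_min[b])
    order_list[[a]] <- c(order_list[[left]], order_list[[right]])
  }

  structure(
    list(merge = merge, height = height,
         order = order_list[[which(alive)]],
         labels = labels, method = method,
         call = match.call(), dist.method = "user"),
    class = c("linkage_tree", "hclust")
  )
}

# creation "age" of a cluster id: leaves (negative ids) precede merges
cluster_age <- function(id) if (id < 0) 0L else id

#' Single-linkage tree from a distance matrix
#'
#' Agglomerative clustering by the nearest-distance (single linkage)
#' method, the construction used for stem-loop phylogenies here. Merge
#' heights are the raw minimum inter-cluster distances; they are
#' non-decreasing and coincide with the sorted edge weights of the minimum
#' spanning tree of the distance graph.
#'
#' @param dist a symmetric distance matrix, `dist`, or [jc_distance_matrix()]
#'   result.
#' @param labels optional leaf labels.
#' @return an object of class `c("linkage_tree", "hclust")` with elements
#'   `merge`, `height`, `labels` (see [stats::hclust()] for the encoding).
#' @export
single_linkage_tree <- function(dist, labels = NULL) {
  if (inherits(dist, "jc_dist")) {
    labels <- if (is.null(labels)) dist$labels else labels
    dist <- dist$distance
  }
  agglomerate(dist, labels, method = "single")
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat(sprintf("%s-linkage tree: %d leaves, merge heights %.4g .. %.4g\n",
              x$method, length(x$labels), min(x$height), max(x$height)))
  invisible(x)
}

#' Enumerate the clades of a rooted tree
#'
#' A clade is the full set of leaves under one internal node. For a binary
#' tree on `n` leaves there are `n - 1` internal-node clades (including the
#' root). Works on trees built by this package and on `ape::phylo` trees.
#'
#' @param tree a `linkage_tree` or an `ape` `phylo` object.
#' @param include_singletons also return each leaf as a size-1 clade.
#' @return list of character vectors of leaf names, each sorted.
#' @export
enumerate_clades <- function(tree, include_singletons = FALSE) {
  UseMethod("enumerate_clades")
}

#' @export
enumerate_clades.linkage_tree <- function(tree, include_singletons = FALSE) {
  n <- length(tree$labels)
  sets <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    kids <- tree$merge[k, ]
    leaves <- unlist(lapply(kids, function(id) {
      if (id < 0) -id else attr(sets[[id]], "leaf_idx")
    }))
    s <- sort(tree$labels[leaves])
    attr(s, "leaf_idx") <- leaves
    sets[[k]] <- s
  }
  sets <- lapply(sets, function(s) { attributes(s) <- NULL; s })
  if (include_singletons) sets <- c(as.list(sort(tree$labels)), sets)
  sets
}

#' @export
enumerate_clades.phylo <- function(tree, include_singletons = FALSE) {
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  sets <- lapply(parts, function(i) sort(labs[i]))
  sets <- Filter(function(s) length(s) >= 2, sets)
  if (include_singletons) sets <- c(as.list(sort(tree$tip.label)), sets)
  sets
}

#' Serialize a linkage tree as Newick
#'
#' Branch lengths are height differences: each child's branch is its
#' parent's height minus its own height (leaves sit at height 0), so leaf
#' depths reproduce node heights exactly and UPGMA trees serialize as
#' ultrametric trees.
#'
#' @param tree a `linkage_tree`.
#' @param path optional output file; when `NULL` the Newick string is
#'   returned.
#' @return the Newick string, invisibly when written to `path`.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "linkage_tree"))
  h <- tree$height
  rec <- function(id, parent_h) {
    if (id < 0) {
      sprintf("%s:%.10g", tree$labels[-id], parent_h)
    } else {
      kids <- tree$merge[id, ]
      sprintf("(%s,%s):%.10g", rec(kids[1], h[id]), rec(kids[2], h[id]),
              parent_h - h[id])
    }
  }
  root <- nrow(tree$merge)
  kids <- tree$merge[root, ]
  nwk <- sprintf("(%s,%s);", rec(kids[1], h[root]), rec(kids[2], h[root]))
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}

#' Read a Newick tree
#'
#' Thin wrapper over [ape::read.tree()] with an explicit bracket-balance
#' pre-check that reports the character position of the first imbalance.
#'
#' @param path file containing one Newick tree.
#' @return an `ape` `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) mpm_stop("newick file not found: %s", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  for (i in seq_len(nchar(txt))) {
    ch <- substr(txt, i, i)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (depth < 0L)
      mpm_stop("malformed newick: unmatched ')' at position %d", i)
  }
  if (depth != 0L)
    mpm_stop("malformed newick: %d unclosed '(' at end of input", depth)
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) NULL)
  if (is.null(tr)) mpm_stop("malformed newick in %s", path)
  tr
}
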