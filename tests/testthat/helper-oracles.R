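# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain-R dynamic programming, Prim's algorithm,
# root finding, and exhaustive enumeration at tiny n.

# sorted edge weights of the minimum spanning tree (Prim)
oracle_mst_weights <- function(d) {
  n <- nrow(d)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- d[1, ]
  weights <- numeric(0)
  for (k in seq_len(n - 1)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best[cand])]
    weights <- c(weights, unname(best[v]))
    in_tree[v] <- TRUE
    best <- pmin(best, d[v, ])
  }
  sort(weights)
}

# invert p = (3/4)(1 - exp(-4 d / 3)) numerically: an arithmetic route to
# the Jukes-Cantor distance that never evaluates the closed form
oracle_jc_by_inversion <- function(p) {
  vapply(p, function(pp) {
    stats::uniroot(function(d) 0.75 * (1 - exp(-4 * d / 3)) - pp,
                   c(0, 60), tol = .Machine$double.eps)$root
  }, numeric(1))
}

# exhaustive global-alignment enumeration on short strings: returns the
# maximum score and the set of gap-excluded difference proportions
# attained by optimal alignments
oracle_align_enumerate <- function(a, b, match = 5, mismatch = -4, gap = -8) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  results <- new.env()
  results$best <- -Inf; results$p <- numeric(0)
  rec <- function(i, j, score, nmis, ncomp) {
    if (i > length(a) && j > length(b)) {
      if (score > results$best) { results$best <- score; results$p <- numeric(0) }
      if (score == results$best)
        results$p <- unique(c(results$p, nmis / ncomp))
      return(invisible())
    }
    if (i <= length(a) && j <= length(b)) {
      hit <- a[i] == b[j] && a[i] != "N" && b[j] != "N"
      rec(i + 1, j + 1, score + if (hit) match else mismatch,
          nmis + !hit, ncomp + 1)
    }
    if (i <= length(a)) rec(i + 1, j, score + gap, nmis, ncomp)
    if (j <= length(b)) rec(i, j + 1, score + gap, nmis, ncomp)
  }
  rec(1, 1, 0, 0, 0)
  list(score = results$best, p_values = results$p)
}

# plain-R Needleman-Wunsch (linear gap) returning max score, the number
# of optimal alignments, and the p of a diagonal-preferring traceback
oracle_nw <- function(a, b, match = 5, mismatch = -4, gap = -8) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  S <- matrix(-Inf, n + 1, m + 1)
  K <- matrix(0, n + 1, m + 1)       # count of optimal paths
  S[1, ] <- gap * (0:m); S[, 1] <- gap * (0:n)
  K[1, ] <- 1; K[, 1] <- 1
  for (i in seq_len(n)) for (j in seq_len(m)) {
    sub <- if (a[i] == b[j] && a[i] != "N") match else mismatch
    opts <- c(S[i, j] + sub, S[i, j + 1] + gap, S[i + 1, j] + gap)
    S[i + 1, j + 1] <- max(opts)
    K[i + 1, j + 1] <- sum(c(K[i, j], K[i, j + 1], K[i + 1, j])[opts == max(opts)])
  }
  # traceback preferring diagonal, then up, then left
  i <- n; j <- m; nmis <- 0; ncomp <- 0
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0) {
      sub <- if (a[i] == b[j] && a[i] != "N") match else mismatch
      if (S[i + 1, j + 1] == S[i, j] + sub) {
        ncomp <- ncomp + 1; nmis <- nmis + (sub != match)
        i <- i - 1; j <- j - 1; next
      }
    }
    if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] + gap) { i <- i - 1; next }
    j <- j - 1
  }
  list(score = S[n + 1, m + 1], n_optimal = K[n + 1, m + 1],
       p = nmis / ncomp)
}

# random symmetric distance matrix with zero diagonal and generic
# (tie-free, with probability 1) entries
random_distance_matrix <- function(n, labels = NULL) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- stats::runif(n * (n - 1) / 2, 0.05, 1)
  d <- d + t(d)
  if (is.null(labels)) labels <- sprintf("L%02d", seq_len(n))
  dimnames(d) <- list(labels, labels)
  d
}

# synthetic HMDD-like validation table: a random subset of the 1-cells of
# an association matrix, plus optional extra unrelated pairs
synthetic_validation <- function(assoc, keep = 0.5) {
  idx <- which(unclass(assoc) == 1, arr.ind = TRUE)
  take <- idx[stats::runif(nrow(idx)) < keep, , drop = FALSE]
  data.frame(mirna = rownames(assoc)[take[, 1]],
             disease = colnames(assoc)[take[, 2]],
             stringsAsFactors = FALSE)
}

# brute-force biomarker selection: scan every leaf subset (n <= 12),
# keep those that are clades of the serialized tree (via ape) and lie
# inside one group, then drop non-maximal ones
oracle_select <- function(tree, groups, min_set_size = 2) {
  nwk <- write_newick(tree)
  ph <- ape::read.tree(text = nwk)
  parts <- ape::prop.part(ph)
  labs <- attr(parts, "labels")
  clade_keys <- vapply(parts, function(i) paste(sort(labs[i]), collapse = "|"),
                       character(1))
  clade_keys <- c(clade_keys, ph$tip.label)  # singletons are clades too
  leaves <- sort(tree$labels)
  n <- length(leaves)
  out <- list()
  for (g in seq_along(groups$members)) {
    mem <- intersect(groups$members[[g]], leaves)
    qual <- list()
    for (mask in seq_len(2^n - 1)) {
      s <- leaves[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
      if (length(s) < min_set_size) next
      if (!all(s %in% mem)) next
      if (!(paste(s, collapse = "|") %in% clade_keys)) next
      qual[[length(qual) + 1]] <- s
    }
    keep <- Filter(function(s) !any(vapply(qual, function(t)
      length(t) > length(s) && all(s %in% t), logical(1))), qual)
    for (s in keep) out[[length(out) + 1]] <- list(members = s, group_id = g)
  }
  out
}

# clade list of a stats::hclust result, from its merge encoding
hclust_clades <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", n - 1)
  for (k in seq_len(n - 1)) {
    kids <- hc$merge[k, ]
    sets[[k]] <- unlist(lapply(kids, function(id) if (id < 0) -id else sets[[id]]))
  }
  lapply(sets, function(i) sort(hc$labels[i]))
}

# canonical string form of a selection for comparisons
selection_key <- function(sets) {
  sort(vapply(sets, function(s)
    paste(s$group_id, paste(sort(s$members), collapse = ","), sep = ":"),
    character(1)))
}
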