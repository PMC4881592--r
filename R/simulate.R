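#' Simulate stem-loop sequence families
#'
#' Generates `n_families` root sequences of length `root_length` drawn
#' uniformly over A/C/G/U, re-drawing until every pair of roots differs at
#' a proportion of at least `min_inter_root_p` of sites (well-separated
#' families). Each family member is a copy of its root with i.i.d.
#' substitutions at rate `sub_rate` (substituted bases drawn uniformly
#' from the three alternatives, consistent with the Jukes-Cantor model)
#' and, optionally, single-base indels at rate `indel_rate`. Deterministic
#' under a fixed `seed`.
#'
#' This emulates the family structure of miRNA stem-loop panels (e.g. the
#' miR-30 family clustering together in a phylogeny): divergent families
#' with closely related members, at the ~90 nt scale of precursor
#' hairpins.
#'
#' @param n_families number of families.
#' @param family_sizes integer vector of members per family (recycled to
#'   `n_families`).
#' @param root_length root sequence length in nucleotides.
#' @param sub_rate per-site substitution probability within a family.
#' @param indel_rate per-site probability of a single-base insertion or
#'   deletion (default 0).
#' @param min_inter_root_p minimum pairwise site-difference proportion
#'   between roots; must be `< 0.75`.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param max_tries attempts at drawing separated roots before failing.
#' @return list with `sequences` (a `mirna_seqs` RNA set, names
#'   `famF_mM`), `families` (named character vector: sequence ->
#'   family id) and `roots`.
#' @export
simulate_sequences <- function(n_families, family_sizes, root_length = 90,
                               sub_rate = 0.03, indel_rate = 0,
                               min_inter_root_p = 0.5, seed = NULL,
                               max_tries = 1000) {
  stopifnot(n_families >= 1, root_length >= 1,
            sub_rate >= 0, sub_rate <= 1, indel_rate >= 0, indel_rate <= 1,
            min_inter_root_p >= 0, min_inter_root_p < 0.75)
  family_sizes <- rep_len(as.integer(family_sizes), n_families)
  if (any(family_sizes < 1)) mpm_stop("family_sizes must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "U")

  draw_root <- function() sample(bases, root_length, replace = TRUE)
  hamming_p <- function(a, b) mean(a != b)

  roots <- list(draw_root())
  for (f in seq_len(n_families)[-1]) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- draw_root()
      if (all(vapply(roots, hamming_p, numeric(1), b = cand) >= min_inter_root_p)) {
        ok <- TRUE; break
      }
    }
    if (!ok)
      mpm_stop("could not draw %d roots with pairwise p >= %g in %d tries; try a longer root_length",
               n_families, min_inter_root_p, max_tries)
    roots[[f]] <- cand
  }

  mutate <- function(root) {
    s <- root
    hit <- stats::runif(length(s)) < sub_rate
    if (any(hit)) {
      s[hit] <- vapply(s[hit], function(b) sample(setdiff(bases, b), 1),
                       character(1))
    }
    if (indel_rate > 0) {
      out <- character(0)
      for (ch in s) {
        r <- stats::runif(1)
        if (r < indel_rate / 2) next                       # deletion
        out <- c(out, ch)
        if (r >= indel_rate / 2 && r < indel_rate)         # insertion
          out <- c(out, sample(bases, 1))
      }
      s <- if (length(out)) out else sample(bases, 1)
    }
    paste(s, collapse = "")
  }

  seqs <- character(0); fam <- character(0)
  for (f in seq_len(n_families)) {
    for (m in seq_len(family_sizes[f])) {
      nm <- sprintf("fam%d_m%d", f, m)
      seqs[nm] <- mutate(roots[[f]])
      fam[nm] <- sprintf("fam%d", f)
    }
  }
  list(sequences = as_mirna_seqs(seqs, alphabet = "RNA"),
       families = fam,
       roots = vapply(roots, paste, character(1), collapse = ""))
}

#' Simulate a binary association matrix with known group structure
#'
#' Draws `n_patterns` distinct non-zero binary disease patterns and
#' assigns each miRNA to one of them, optionally flipping entries
#' independently at `noise_flip_rate` afterwards. With zero noise the
#' target-group partition recovered by [extract_groups()] equals the
#' generating assignment exactly. Rows that become all-zero after noise
#' are re-drawn (reported on the message stream). Deterministic under a
#' fixed `seed`.
#'
#' @param n_mirnas number of miRNAs (rows).
#' @param n_diseases number of diseases (columns).
#' @param n_patterns number of distinct patterns; at most
#'   `2^n_diseases - 1`.
#' @param pattern_assignment optional integer vector (length `n_mirnas`,
#'   values in `1:n_patterns`) mapping miRNAs to patterns; default cycles
#'   patterns in order so every pattern is used.
#' @param noise_flip_rate per-entry flip probability after assignment.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return list with `assoc` (a `mirna_assoc`, rows `mirN`, columns
#'   `disN`) and `groups` (named integer vector: miRNA -> generating
#'   pattern id).
#' @export
simulate_associations <- function(n_mirnas, n_diseases, n_patterns,
                                  pattern_assignment = NULL,
                                  noise_flip_rate = 0, seed = NULL) {
  stopifnot(n_mirnas >= 1, n_diseases >= 1,
            n_patterns >= 1, n_patterns <= 2^n_diseases - 1,
            noise_flip_rate >= 0, noise_flip_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  # distinct non-zero patterns
  pats <- matrix(0L, 0, n_diseases)
  seen <- character(0)
  while (nrow(pats) < n_patterns) {
    cand <- as.integer(stats::runif(n_diseases) < 0.5)
    if (!sum(cand)) next
    key <- paste(cand, collapse = "")
    if (key %in% seen) next
    seen <- c(seen, key)
    pats <- rbind(pats, cand)
  }
  if (is.null(pattern_assignment)) {
    pattern_assignment <- rep_len(seq_len(n_patterns), n_mirnas)
  }
  stopifnot(length(pattern_assignment) == n_mirnas,
            all(pattern_assignment %in% seq_len(n_patterns)))
  m <- pats[pattern_assignment, , drop = FALSE]
  if (noise_flip_rate > 0) {
    flip <- matrix(stats::runif(length(m)) < noise_flip_rate, nrow(m))
    m <- abs(m - flip * 1L)
    zero <- which(rowSums(m) == 0)
    for (r in zero) {
      mpm_log("re-drawing all-zero row %d produced by noise", r)
      while (sum(m[r, ]) == 0) {
        base <- pats[pattern_assignment[r], ]
        flip_r <- stats::runif(n_diseases) < noise_flip_rate
        m[r, ] <- abs(base - flip_r * 1L)
      }
    }
  }
  storage.mode(m) <- "integer"
  dimnames(m) <- list(sprintf("mir%d", seq_len(n_mirnas)),
                      sprintf("dis%d", seq_len(n_diseases)))
  list(assoc = as_mirna_assoc(m),
       groups = stats::setNames(as.integer(pattern_assignment), rownames(m)))
}
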