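#' miRNA-disease association matrices
#'
#' An association matrix records, for a panel of miRNAs and a set of
#' diseases (here: cancers), which miRNA is a candidate biomarker for which
#' disease. It is stored as a binary integer matrix with miRNAs as rows and
#' diseases as columns, of class `mirna_assoc`.
#'
#' Invariants enforced by the constructor: unique row and column names,
#' entries exactly 0/1, and no all-zero row (a miRNA with no disease
#' association carries no information for grouping and is rejected).
#'
#' @param x a numeric/integer matrix with miRNA row names and disease
#'   column names, entries 0 or 1.
#' @return an object of class `mirna_assoc` (a binary integer matrix).
#' @seealso [read_association_table()], [extract_groups()], [target_vector()]
#' @export
as_mirna_assoc <- function(x) {
  if (!is.matrix(x)) mpm_stop("association input must be a matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    mpm_stop("association matrix needs miRNA row names and disease column names")
  dup_r <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup_r))
    mpm_stop("duplicate miRNA name(s): %s", mpm_join(dup_r))
  dup_c <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup_c))
    mpm_stop("duplicate disease name(s): %s", mpm_join(dup_c))
  if (!all(x %in% c(0L, 1L)))
    mpm_stop("association entries must be exactly 0 or 1")
  zero <- rownames(x)[rowSums(x) == 0]
  if (length(zero))
    mpm_stop("all-zero association row(s): %s", mpm_join(zero))
  storage.mode(x) <- "integer"
  class(x) <- c("mirna_assoc", class(x))
  x
}

#' Read a miRNA-disease association table
#'
#' Reads a TSV/CSV table whose header row is `mirna` followed by disease
#' names, with cells marked `v` or `1` for an association and empty or `0`
#' otherwise (both the mark-up style of published tables and machine-style
#' 0/1 are accepted). A trailing `group` column of printed group numbers, if
#' present, is kept as the `"printed_groups"` attribute and excluded from
#' the matrix.
#'
#' @param path path to the table.
#' @param sep field separator; `NULL` (default) picks tab for `.tsv` and
#'   comma for `.csv`.
#' @return a [as_mirna_assoc()] object; row order follows the file.
#' @export
read_association_table <- function(path, sep = NULL) {
  if (!file.exists(path)) mpm_stop("association table not found: %s", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           colClasses = "character", comment.char = "#",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) mpm_stop("association table needs a miRNA column and >= 1 disease column")
  mirnas <- trimws(raw[[1]])
  body <- raw[, -1, drop = FALSE]
  printed_groups <- NULL
  gcol <- which(tolower(names(body)) %in% c("group", "group number"))
  if (length(gcol)) {
    printed_groups <- as.integer(body[[gcol[1]]])
    body <- body[, -gcol, drop = FALSE]
  }
  cells <- as.matrix(body)
  cells[] <- trimws(cells)
  ok <- matrix(cells %in% c("", "0", "1", "v", "V"), nrow = nrow(cells))
  bad <- which(!ok, arr.ind = TRUE)
  if (nrow(bad))
    mpm_stop("unknown cell token '%s' at row '%s', column '%s'",
             cells[bad[1, 1], bad[1, 2]], mirnas[bad[1, 1]],
             colnames(cells)[bad[1, 2]])
  m <- matrix(as.integer(cells %in% c("1", "v", "V")), nrow = nrow(cells),
              dimnames = list(mirnas, colnames(body)))
  out <- as_mirna_assoc(m)
  if (!is.null(printed_groups)) {
    names(printed_groups) <- mirnas
    attr(out, "printed_groups") <- printed_groups
  }
  out
}

#' @export
print.mirna_assoc <- function(x, ...) {
  cat(sprintf("miRNA-disease association matrix: %d miRNAs x %d diseases\n",
              nrow(x), ncol(x)))
  cat("diseases:", mpm_join(colnames(x)), "\n")
  cat("associations:", sum(x), "\n")
  invisible(x)
}

#' Binary cancer-target vector of one miRNA
#'
#' @param x a `mirna_assoc` matrix.
#' @param mirna miRNA name.
#' @return integer 0/1 vector named by disease, in column order.
#' @examples
#' assoc <- load_fixture("table3")
#' target_vector(assoc, "miR-146")  # (1,0,0,1,0,1,1)
#' @export
target_vector <- function(x, mirna) {
  stopifnot(inherits(x, "mirna_assoc"))
  if (!mirna %in% rownames(x))
    mpm_stop("unknown miRNA: %s", mirna)
  v <- x[mirna, ]
  stats::setNames(as.integer(v), colnames(x))
}

#' Partition miRNAs into target groups
#'
#' A target group is an equivalence class of miRNAs with identical binary
#' disease vectors. Group ids are contiguous from 1 in order of first
#' appearance in the matrix, matching the convention of published group
#' numbering.
#'
#' @param x a `mirna_assoc` matrix.
#' @return an object of class `target_groups`: a list with
#'   `assignment` (named integer vector, miRNA -> group id),
#'   `members` (list of character vectors per group) and
#'   `patterns` (group x disease 0/1 matrix).
#' @examples
#' g <- extract_groups(load_fixture("table3"))
#' length(g$members)  # 41
#' @export
extract_groups <- function(x) {
  stopifnot(inherits(x, "mirna_assoc"))
  key <- apply(unclass(x), 1, paste, collapse = "")
  ids <- match(key, unique(key))
  names(ids) <- rownames(x)
  members <- split(rownames(x), ids)
  names(members) <- NULL
  patterns <- unclass(x)[match(unique(key), key), , drop = FALSE]
  rownames(patterns) <- seq_len(nrow(patterns))
  structure(list(assignment = ids, members = members, patterns = patterns),
            class = "target_groups")
}

#' @export
print.target_groups <- function(x, ...) {
  sizes <- lengths(x$members)
  cat(sprintf("%d target groups over %d miRNAs (sizes %d-%d)\n",
              length(x$members), length(x$assignment), min(sizes), max(sizes)))
  invisible(x)
}

#' @export
as.data.frame.target_groups <- function(x, ...) {
  data.frame(
    group_id = x$assignment,
    mirna = names(x$assignment),
    pattern = apply(x$patterns, 1, paste, collapse = "")[x$assignment],
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Euclidean distances between target vectors
#'
#' Pairwise Euclidean distance between the binary disease vectors of all
#' miRNAs; for 0/1 vectors this is the square root of the number of
#' differing coordinates.
#'
#' @param x a `mirna_assoc` matrix.
#' @return a symmetric distance matrix with miRNA dimnames.
#' @export
vector_distance_matrix <- function(x) {
  stopifnot(inherits(x, "mirna_assoc"))
  as.matrix(stats::dist(unclass(x), method = "euclidean"))
}

#' UPGMA dendrogram over a distance matrix
#'
#' Average-linkage (UPGMA) agglomerative clustering. Node heights follow
#' the ultrametric convention: a merge of two clusters at inter-cluster
#' distance `d` sits at height `d / 2`, so all leaves are equidistant from
#' the root. Ties are broken deterministically (see [enumerate_clades()]
#' for the tree structure and the package vignette for the tie rule).
#'
#' @param dist symmetric non-negative distance matrix with zero diagonal
#'   (a `matrix` or `dist`).
#' @param labels leaf labels; default taken from `dist` dimnames.
#' @return a `linkage_tree` (see [single_linkage_tree()]).
#' @export
upgma_tree <- function(dist, labels = NULL) {
  tr <- agglomerate(dist, labels, method = "average")
  tr$height <- tr$height / 2
  tr
}
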