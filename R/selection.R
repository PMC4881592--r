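#' Select high-confidence biomarker sets
#'
#' The core selection rule: a set of miRNAs is reported as a
#' high-confidence biomarker set when it is simultaneously (a) a complete
#' clade of the stem-loop phylogeny and (b) entirely contained in one
#' target group (miRNAs sharing an identical disease pattern). Among
#' nested qualifying clades the maximal one is reported, so the sets
#' emitted for one group are disjoint; a group whose members fall in
#' several phylogenetic branches yields several sets.
#'
#' `min_set_size = 2` (the default) requires a clade of at least two
#' leaves, i.e. genuinely shared phylogenetic structure. With
#' `min_set_size = 1`, single leaves whose maximal in-group clade is
#' themselves are also emitted. Independently,
#' `include_singleton_groups = TRUE` emits the lone member of each
#' one-miRNA group as a set (such a member can never satisfy the
#' two-leaf clade rule, yet published selections contain such singletons;
#' both behaviours are exposed because neither is derivable from the
#' other).
#'
#' Group members missing from the tree (no sequence available) are
#' reported on the message stream and excluded.
#'
#' @param tree a `linkage_tree` (or `ape` `phylo`) whose leaves are miRNA
#'   names; typically from [single_linkage_tree()].
#' @param groups a `target_groups` object from [extract_groups()].
#' @param min_set_size minimum clade size to report (>= 1).
#' @param include_singleton_groups also emit the lone members of
#'   single-miRNA groups.
#' @return object of class `biomarker_selection`: list with `sets` (each a
#'   list with `members`, `group_id`, `pattern`, `supporting_clade`),
#'   `selected_mirnas`, `excluded` (group members absent from the tree)
#'   and `params`.
#' @export
select_biomarkers <- function(tree, groups, min_set_size = 2,
                              include_singleton_groups = FALSE) {
  stopifnot(inherits(groups, "target_groups"))
  if (!is.numeric(min_set_size) || min_set_size < 1)
    mpm_stop("min_set_size must be >= 1")
  leaves <- if (inherits(tree, "phylo")) tree$tip.label else tree$labels
  all_members <- names(groups$assignment)
  if (!length(intersect(leaves, all_members)))
    mpm_stop("tree leaves and group members share no miRNA names")
  excluded <- setdiff(all_members, leaves)
  if (length(excluded))
    mpm_log("excluding %d miRNA(s) with no sequence in the tree: %s",
            length(excluded), mpm_join(excluded))

  clades <- enumerate_clades(tree, include_singletons = min_set_size <= 1)
  sets <- list()
  for (g in seq_along(groups$members)) {
    mem <- setdiff(groups$members[[g]], excluded)
    if (!length(mem)) next
    inside <- Filter(function(cl) all(cl %in% mem) &&
                       length(cl) >= min_set_size, clades)
    # maximal among nested qualifying clades (laminar, so maxima are disjoint)
    keep <- !vapply(seq_along(inside), function(i) {
      any(vapply(seq_along(inside), function(j) {
        i != j && length(inside[[j]]) > length(inside[[i]]) &&
          all(inside[[i]] %in% inside[[j]])
      }, logical(1)))
    }, logical(1))
    inside <- unique(inside[keep])
    if (include_singleton_groups && length(groups$members[[g]]) == 1 &&
        !length(inside) && mem %in% leaves) {
      inside <- list(mem)
    }
    for (cl in inside) {
      sets[[length(sets) + 1L]] <- list(
        members = cl, group_id = g,
        pattern = stats::setNames(groups$patterns[g, ],
                                  colnames(groups$patterns)),
        supporting_clade = cl)
    }
  }
  structure(list(sets = sets,
                 selected_mirnas = sort(unique(unlist(lapply(sets, `[[`, "members")))),
                 excluded = excluded,
                 params = list(min_set_size = min_set_size,
                               include_singleton_groups = include_singleton_groups)),
            class = "biomarker_selection")
}

#' @export
print.biomarker_selection <- function(x, ...) {
  cat(sprintf("biomarker selection: %d miRNAs in %d sets (min set size %d%s)\n",
              length(x$selected_mirnas), length(x$sets),
              x$params$min_set_size,
              if (x$params$include_singleton_groups) ", singleton groups included" else ""))
  if (length(x$excluded))
    cat(sprintf("excluded (no sequence): %s\n", mpm_join(x$excluded)))
  invisible(x)
}

#' @export
summary.biomarker_selection <- function(object, ...) {
  tab <- report_to_table(object)
  print(object)
  if (nrow(tab)) print(tab[, c("mirnas", "cancers")], right = FALSE)
  invisible(tab)
}

#' Tabulate a biomarker selection
#'
#' One row per biomarker set: comma-joined members and the disease names
#' of the shared target pattern. Rows are ordered by pattern cardinality
#' ascending, then lexicographically by pattern and members, so output is
#' deterministic.
#'
#' @param report a `biomarker_selection`.
#' @param disease_names optional disease name order; default from the
#'   patterns stored in the report.
#' @return data.frame with columns `mirnas`, `cancers`, `group_id`,
#'   `pattern`, `supporting_clade`.
#' @export
report_to_table <- function(report, disease_names = NULL) {
  stopifnot(inherits(report, "biomarker_selection"))
  if (!length(report$sets))
    return(data.frame(mirnas = character(), cancers = character(),
                      group_id = integer(), pattern = character(),
                      supporting_clade = character(),
                      stringsAsFactors = FALSE))
  rows <- lapply(report$sets, function(s) {
    dn <- if (is.null(disease_names)) names(s$pattern) else disease_names
    data.frame(
      mirnas = mpm_join(s$members),
      cancers = mpm_join(dn[s$pattern[dn] == 1]),
      group_id = s$group_id,
      pattern = paste(s$pattern, collapse = ""),
      supporting_clade = mpm_join(s$supporting_clade),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  card <- vapply(report$sets, function(s) sum(s$pattern), numeric(1))
  out[order(card, out$pattern, out$mirnas), , drop = FALSE]
}

#' @export
as.data.frame.biomarker_selection <- function(x, ...) report_to_table(x)
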