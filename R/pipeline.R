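#' Select and evaluate miRNA biomarkers from associations and sequences
#'
#' The main driver. Given a candidate miRNA-disease association matrix
#' and the miRNAs' stem-loop sequences it
#' \enumerate{
#'   \item partitions miRNAs into target groups (identical disease
#'     vectors) and builds the UPGMA dendrogram over Euclidean distances
#'     between the binary vectors;
#'   \item computes pairwise Jukes-Cantor distances between the stem-loop
#'     sequences (after global alignment) and builds the single-linkage
#'     phylogenetic tree;
#'   \item reports every maximal clade lying entirely inside one target
#'     group as a high-confidence biomarker set;
#'   \item optionally scores the selection against a validation
#'     association table with per-disease sensitivity `D/B` and
#'     specificity `(C-D)/(A-B)`.
#' }
#'
#' @param assoc a `mirna_assoc` matrix (see [read_association_table()]).
#' @param seqs a `mirna_seqs` set; names must match the association row
#'   names, directly or through `name_map`.
#' @param validation optional data.frame of validated (`mirna`,
#'   `disease`) pairs.
#' @param baseline optional baseline metrics (see [evaluate_selection()]).
#' @param align [alignment_params()] for the pairwise alignments.
#' @param min_set_size,include_singleton_groups see [select_biomarkers()].
#' @param saturation_cap see [jc_distance_matrix()].
#' @param name_map optional data.frame (`mirna`, `stem_loop`) renaming
#'   sequence records from stem-loop identifiers to association-table
#'   miRNA names.
#' @return object of class `phylomark`: list with `assoc`, `groups`,
#'   `target_tree` (UPGMA `linkage_tree`), `jc` (the `jc_dist`), `tree`
#'   (single-linkage `linkage_tree`), `selection`
#'   (`biomarker_selection`) and `evaluation` (or `NULL`).
#' @examples
#' sim_s <- simulate_sequences(3, 4, seed = 7)
#' sim_a <- simulate_associations(12, 7, 3,
#'   pattern_assignment = rep(1:3, each = 4), seed = 7)
#' rownames(sim_a$assoc) <- names(sim_s$sequences)
#' fit <- phylomark(sim_a$assoc, sim_s$sequences)
#' summary(fit)
#' @export
phylomark <- function(assoc, seqs, validation = NULL, baseline = NULL,
                      align = alignment_params(), min_set_size = 2,
                      include_singleton_groups = FALSE, saturation_cap = 5,
                      name_map = NULL) {
  stopifnot(inherits(assoc, "mirna_assoc"), inherits(seqs, "mirna_seqs"))
  if (!is.null(name_map)) {
    i <- match(names(seqs), name_map$stem_loop)
    hit <- !is.na(i)
    nm <- names(seqs)
    nm[hit] <- name_map$mirna[i[hit]]
    seqs <- as_mirna_seqs(stats::setNames(unclass(seqs), nm),
                          alphabet = attr(seqs, "alphabet"))
  }
  groups <- extract_groups(assoc)
  target_tree <- upgma_tree(vector_distance_matrix(assoc))
  jc <- jc_distance_matrix(seqs, align = align,
                           saturation_cap = saturation_cap)
  tree <- single_linkage_tree(jc)
  selection <- select_biomarkers(tree, groups, min_set_size = min_set_size,
                                 include_singleton_groups = include_singleton_groups)
  evaluation <- if (!is.null(validation))
    evaluate_selection(assoc, selection, validation, baseline = baseline)
  structure(list(assoc = assoc, groups = groups, target_tree = target_tree,
                 jc = jc, tree = tree, selection = selection,
                 evaluation = evaluation, call = match.call()),
            class = "phylomark")
}

#' @export
print.phylomark <- function(x, ...) {
  cat("miRNA biomarker selection (target groups x stem-loop phylogeny)\n")
  print(x$assoc)
  print(x$groups)
  print(x$selection)
  if (!is.null(x$evaluation)) {
    cat("evaluation:\n")
    print(x$evaluation)
  }
  invisible(x)
}

#' @export
summary.phylomark <- function(object, ...) {
  print(object)
  cat("\nbiomarker sets:\n")
  tab <- report_to_table(object$selection)
  if (nrow(tab)) print(tab[, c("mirnas", "cancers")], right = FALSE)
  invisible(tab)
}

#' @export
plot.phylomark <- function(x, which = c("phylogeny", "targets"), ...) {
  which <- match.arg(which)
  tr <- if (which == "phylogeny") x$tree else x$target_tree
  plot(stats::as.dendrogram(tr),
       main = if (which == "phylogeny") "stem-loop single-linkage tree"
              else "target-vector UPGMA dendrogram", ...)
  invisible(x)
}

#' Run the full pipeline against files on disk
#'
#' File-level front end to [phylomark()]. Reads the association table,
#' FASTA and (optionally) validation table named in `config`, runs the
#' selection, and writes `groups.tsv`, `target_dendrogram.nwk`,
#' `tree.nwk`, `distances.tsv`, `selection.tsv`, `evaluation.tsv` (when a
#' validation table is given) and a `manifest.json` recording input
#' checksums, parameters and the package version, into `config$out_dir`.
#' Re-running with identical inputs and configuration reproduces the
#' artifacts byte for byte.
#'
#' @param config a named list (or path to a JSON file holding one) with
#'   elements `association`, `fasta`, optional `validation`, `baseline`,
#'   `name_map` (file paths), optional `align` (list with `match`,
#'   `mismatch`, `gap`), `min_set_size`, `include_singleton_groups`,
#'   `saturation_cap`, `seed`, and `out_dir`.
#' @return the `phylomark` fit, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  need <- c("association", "fasta", "out_dir")
  miss <- setdiff(need, names(config))
  if (length(miss)) mpm_stop("config is missing: %s", mpm_join(miss))
  ins <- unlist(config[intersect(names(config),
                                 c("association", "fasta", "validation",
                                   "baseline", "name_map"))])
  absent <- ins[!file.exists(ins)]
  if (length(absent)) mpm_stop("input file(s) not found: %s", mpm_join(absent))
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  if (!is.null(config$seed)) set.seed(config$seed)

  al <- do.call(alignment_params, as.list(config$align %||% list()))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      mpm_stop("stage '%s' failed: %s", name, conditionMessage(e)))
    mpm_log("stage %-10s %.2fs", name, proc.time()[["elapsed"]] - t0)
    out
  }
  assoc <- stage("load", read_association_table(config$association))
  seqs <- stage("fasta", read_fasta(config$fasta))
  validation <- if (!is.null(config$validation))
    stage("validation", read_validation(config$validation))
  baseline <- if (!is.null(config$baseline))
    utils::read.table(config$baseline, header = TRUE, sep = "\t",
                      comment.char = "#", stringsAsFactors = FALSE)
  name_map <- if (!is.null(config$name_map))
    utils::read.table(config$name_map, header = TRUE, sep = "\t",
                      comment.char = "#", stringsAsFactors = FALSE)

  fit <- stage("fit", phylomark(
    assoc, seqs, validation = validation, baseline = baseline, align = al,
    min_set_size = config$min_set_size %||% 2,
    include_singleton_groups = isTRUE(config$include_singleton_groups),
    saturation_cap = config$saturation_cap %||% 5,
    name_map = name_map))

  out <- function(f) file.path(config$out_dir, f)
  utils::write.table(as.data.frame(fit$groups), out("groups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_newick(fit$target_tree, out("target_dendrogram.nwk"))
  write_newick(fit$tree, out("tree.nwk"))
  write_distance_matrix(fit$jc, out("distances.tsv"), format = "tsv")
  utils::write.table(report_to_table(fit$selection), out("selection.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(fit$evaluation))
    utils::write.table(as.data.frame(fit$evaluation), out("evaluation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    package = "mirphylomark",
    version = as.character(utils::packageVersion("mirphylomark")),
    inputs = as.list(tools::md5sum(ins)),
    config = config[setdiff(names(config), "out_dir")])
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(fit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
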