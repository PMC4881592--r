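#' Packaged reference fixtures
#'
#' Loads the reference tables shipped with the package:
#' \describe{
#'   \item{`"table3"`}{the 90 miRNA x 7 cancer candidate association
#'     matrix (a `mirna_assoc`), including the published group-number
#'     column as attribute `"printed_groups"`;}
#'   \item{`"table2"`}{per-cancer evaluation counts A/B/C/D with the
#'     published sensitivity/specificity values;}
#'   \item{`"baseline"`}{the published microarray-only baseline metrics
#'     for colon and pancreatic cancer, with the printed increase rates;}
#'   \item{`"name_map"`}{miRNA-name to stem-loop-identifier resolutions
#'     (e.g. miR-92 -> hsa-mir-92a-1);}
#'   \item{`"mir211_fasta"`}{path to a one-record FASTA with the
#'     hsa-mir-211 stem-loop (MI0000287).}
#' }
#'
#' @param name fixture identifier.
#' @return see above; `"mir211_fasta"` returns a file path.
#' @examples
#' dim(load_fixture("table3"))  # 90 x 7
#' @export
load_fixture <- function(name) {
  files <- c(table3 = "table3_associations.tsv",
             table2 = "table2_counts.tsv",
             baseline = "baseline_metrics.tsv",
             name_map = "name_map.tsv",
             mir211_fasta = "hsa-mir-211.fa")
  if (!name %in% names(files))
    mpm_stop("unknown fixture '%s'; available: %s", name,
             mpm_join(names(files)))
  path <- system.file("extdata", files[[name]], package = "mirphylomark",
                      mustWork = TRUE)
  switch(name,
    table3 = read_association_table(path),
    table2 = {
      x <- utils::read.table(path, header = TRUE, sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE)
      class(x) <- c("evaluation_counts", class(x))
      x
    },
    baseline = utils::read.table(path, header = TRUE, sep = "\t",
                                 comment.char = "#", stringsAsFactors = FALSE),
    name_map = utils::read.table(path, header = TRUE, sep = "\t",
                                 comment.char = "#", stringsAsFactors = FALSE),
    mir211_fasta = path)
}
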