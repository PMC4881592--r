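#' Read a validation association table
#'
#' Two-column TSV (`mirna`, `disease`) of experiment-supported
#' miRNA-disease pairs, the format of curated disease-association
#' databases. Duplicate pairs are rejected.
#'
#' @param path TSV file.
#' @return data.frame with columns `mirna` and `disease`.
#' @export
read_validation <- function(path) {
  if (!file.exists(path)) mpm_stop("validation table not found: %s", path)
  v <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                         comment.char = "#", stringsAsFactors = FALSE)
  names(v) <- tolower(names(v))
  if (!all(c("mirna", "disease") %in% names(v)))
    mpm_stop("validation table needs columns 'mirna' and 'disease'")
  v <- v[, c("mirna", "disease")]
  if (any(v == "" | is.na(v))) mpm_stop("empty names in validation table")
  if (anyDuplicated(v)) mpm_stop("duplicate validation pair(s)")
  v
}

#' Tally per-disease evaluation counts
#'
#' For each disease `d` computes the four counts used to score a
#' selection against a validation set:
#' \describe{
#'   \item{A}{candidate miRNAs for `d` (the baseline, pre-screening list);}
#'   \item{B}{candidates confirmed by the validation set;}
#'   \item{C}{miRNAs selected by the method for `d` (members of sets whose
#'     target pattern includes `d`);}
#'   \item{D}{selected and confirmed.}
#' }
#'
#' @param candidates per-disease candidate lists: a `mirna_assoc` matrix
#'   (column `d` gives the candidates of disease `d`) or a named list of
#'   character vectors.
#' @param selection a `biomarker_selection`.
#' @param validation data.frame of validated (`mirna`, `disease`) pairs,
#'   as from [read_validation()].
#' @return data.frame of class `evaluation_counts` with columns `disease`,
#'   `A`, `B`, `C`, `D`.
#' @export
tally_counts <- function(candidates, selection, validation) {
  stopifnot(inherits(selection, "biomarker_selection"))
  if (inherits(candidates, "mirna_assoc")) {
    candidates <- lapply(stats::setNames(colnames(candidates), colnames(candidates)),
                         function(d) rownames(candidates)[candidates[, d] == 1])
  }
  if (is.null(names(candidates))) mpm_stop("candidates must be named by disease")
  sel_diseases <- unique(unlist(lapply(selection$sets, function(s)
    names(s$pattern)[s$pattern == 1])))
  missing <- setdiff(sel_diseases, names(candidates))
  if (length(missing))
    mpm_stop("disease(s) in selection but absent from candidates: %s",
             mpm_join(missing))
  validated <- split(validation$mirna, validation$disease)
  selected_for <- function(d) {
    unique(unlist(lapply(selection$sets, function(s)
      if (!is.na(s$pattern[d]) && s$pattern[d] == 1) s$members)))
  }
  rows <- lapply(names(candidates), function(d) {
    cand <- unique(candidates[[d]])
    conf <- intersect(cand, validated[[d]])
    sel <- selected_for(d)
    data.frame(disease = d, A = length(cand), B = length(conf),
               C = length(sel), D = length(intersect(sel, conf)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("evaluation_counts", class(out))
  out
}

#' Sensitivity of a selection (validated-recall form)
#'
#' `D / B`: among candidate miRNAs confirmed by the validation database,
#' the fraction also selected by the method. Undefined (`NA`) when no
#' candidate is confirmed (`B = 0`).
#'
#' @param counts an `evaluation_counts` data.frame (or any data.frame with
#'   columns `B` and `D`).
#' @return numeric vector named by disease; `NA` where undefined.
#' @examples
#' sensitivity(data.frame(disease = "Colon", A = 42, B = 21, C = 19, D = 10))
#' @export
sensitivity <- function(counts) {
  s <- ifelse(counts$B > 0, counts$D / counts$B, NA_real_)
  stats::setNames(s, counts$disease)
}

#' Specificity of a selection (selected-unconfirmed form)
#'
#' `(C - D) / (A - B)`: among candidate miRNAs *not* confirmed by the
#' validation database, the fraction selected by the method. Note this is
#' the published formula, which is \emph{not} the standard true-negative
#' rate; `standard = TRUE` returns the complementary true-negative rate
#' `1 - (C - D) / (A - B)` instead. Undefined (`NA`) when every candidate
#' is confirmed (`A = B`).
#'
#' @param counts an `evaluation_counts` data.frame.
#' @param standard return the standard true-negative rate instead of the
#'   published ratio.
#' @return numeric vector named by disease; `NA` where undefined.
#' @export
specificity <- function(counts, standard = FALSE) {
  s <- ifelse(counts$A > counts$B,
              (counts$C - counts$D) / (counts$A - counts$B), NA_real_)
  if (standard) s <- 1 - s
  stats::setNames(s, counts$disease)
}

#' Relative increase rate of a metric
#'
#' `(new - old) / old`, the relative improvement of a metric over a
#' baseline. Undefined (`NA`) for non-positive baselines.
#'
#' @param new,old numeric vectors (recycled).
#' @return signed proportion; multiply by 100 for percent.
#' @examples
#' 100 * increase_rate(0.64, 0.437)  # 46.45...
#' @export
increase_rate <- function(new, old) {
  ifelse(old > 0, (new - old) / old, NA_real_)
}

#' Evaluate a biomarker selection against a validation set
#'
#' Convenience wrapper combining [tally_counts()], [sensitivity()] and
#' [specificity()], with optional baseline metrics to report increase
#' rates against.
#'
#' @inheritParams tally_counts
#' @param baseline optional data.frame with columns `disease`,
#'   `sensitivity`, `specificity` giving baseline-method metrics.
#' @return data.frame of class `biomarker_evaluation` with the counts,
#'   both metrics, and (when `baseline` is given) per-disease increase
#'   rates in percent.
#' @export
evaluate_selection <- function(candidates, selection, validation,
                               baseline = NULL) {
  counts <- tally_counts(candidates, selection, validation)
  out <- counts
  out$sensitivity <- as.numeric(sensitivity(counts))
  out$specificity <- as.numeric(specificity(counts))
  if (!is.null(baseline)) {
    i <- match(out$disease, baseline$disease)
    out$sensitivity_increase_pct <-
      100 * increase_rate(out$sensitivity, baseline$sensitivity[i])
    out$specificity_increase_pct <-
      100 * increase_rate(out$specificity, baseline$specificity[i])
  }
  class(out) <- c("biomarker_evaluation", "data.frame")
  out
}

#' @export
print.biomarker_evaluation <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1)) & !names(y) %in% c("A", "B", "C", "D")
  y[num] <- lapply(y[num], function(v) {
    out <- format(round_half_up(v, digits), drop0trailing = TRUE)
    out[is.na(v)] <- "undefined"
    out
  })
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
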