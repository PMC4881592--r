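#' Read stem-loop sequences from FASTA
#'
#' Reads a multi-record FASTA (wrapped or unwrapped) of nucleotide
#' sequences, normalizes case and the U/T alphabet, and returns a named
#' character vector of class `mirna_seqs`. The record name is the first
#' whitespace-delimited token of the header, which for miRBase-style
#' headers is the stem-loop identifier (e.g. `hsa-mir-211`).
#'
#' @param path FASTA file.
#' @param alphabet `"RNA"` (default; T -> U) or `"DNA"` (U -> T).
#' @return named character vector of class `mirna_seqs`, input order
#'   preserved, with attribute `alphabet`.
#' @examples
#' fa <- read_fasta(system.file("extdata", "hsa-mir-211.fa",
#'                              package = "mirphylomark"))
#' nchar(fa)  # 110
#' @export
read_fasta <- function(path, alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) mpm_stop("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1)
  if (any(is.na(ids) | ids == ""))
    mpm_stop("FASTA record with empty header in %s", path)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) mpm_stop("duplicate FASTA header(s): %s", mpm_join(dup))
  seqs <- toupper(as.character(set))
  empty <- ids[nchar(seqs) == 0]
  if (length(empty)) mpm_stop("empty sequence for record(s): %s", mpm_join(empty))
  seqs <- if (alphabet == "RNA") chartr("T", "U", seqs) else chartr("U", "T", seqs)
  bad <- grepl(if (alphabet == "RNA") "[^ACGUN]" else "[^ACGTN]", seqs)
  if (any(bad))
    mpm_stop("non-nucleotide characters in record(s): %s", mpm_join(ids[bad]))
  as_mirna_seqs(stats::setNames(seqs, ids), alphabet = alphabet)
}

#' Construct a sequence set
#'
#' @param x named character vector of nucleotide sequences.
#' @param alphabet `"RNA"` or `"DNA"`.
#' @return object of class `mirna_seqs`.
#' @export
as_mirna_seqs <- function(x, alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  if (is.null(names(x)) || any(names(x) == ""))
    mpm_stop("sequences must be named")
  if (anyDuplicated(names(x)))
    mpm_stop("duplicate sequence name(s): %s",
             mpm_join(unique(names(x)[duplicated(names(x))])))
  if (any(nchar(x) == 0)) mpm_stop("empty sequence(s) not allowed")
  structure(x, alphabet = alphabet, class = "mirna_seqs")
}

#' @export
print.mirna_seqs <- function(x, ...) {
  cat(sprintf("%d %s sequences, lengths %d-%d\n", length(x),
              attr(x, "alphabet"), min(nchar(x)), max(nchar(x))))
  invisible(x)
}

#' @export
`[.mirna_seqs` <- function(x, i) {
  as_mirna_seqs(unclass(x)[i], alphabet = attr(x, "alphabet"))
}

#' Alignment scoring parameters
#'
#' Scoring for the pairwise global (Needleman-Wunsch) alignment used
#' before distance estimation: match reward, mismatch penalty and a linear
#' per-position gap penalty. The defaults mirror NUC44-style nucleotide
#' scoring. `N` aligns but always scores (and counts) as a mismatch.
#'
#' @param match match score (default 5).
#' @param mismatch mismatch score (default -4).
#' @param gap linear gap penalty per gapped position (default -8).
#' @return list of class `alignment_params`.
#' @export
alignment_params <- function(match = 5, mismatch = -4, gap = -8) {
  stopifnot(is.numeric(match), is.numeric(mismatch), is.numeric(gap))
  structure(list(match = match, mismatch = mismatch, gap = gap),
            class = "alignment_params")
}

# substitution matrix over A,C,G,T,N: N never matches anything, itself included
align_submat <- function(align) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(align$mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- align$match
  m["N", "N"] <- align$mismatch
  m
}

# normalize to DNA alphabet for Biostrings alignment
to_dna <- function(x) chartr("U", "T", toupper(unclass(x)))

# p-distance from two aligned strings of equal length (gaps as "-")
p_from_alignment <- function(pa, sa) {
  a <- strsplit(pa, "")[[1]]
  b <- strsplit(sa, "")[[1]]
  comp <- a != "-" & b != "-"
  n_comp <- sum(comp)
  if (n_comp == 0) mpm_stop("no comparable (gap-free) aligned columns")
  diff <- comp & (a != b | a == "N" | b == "N")
  sum(diff) / n_comp
}

#' Pairwise p-distance between two sequences
#'
#' Globally aligns the two sequences (Needleman-Wunsch under the given
#' scoring) and returns the proportion of differing sites among aligned
#' columns where neither sequence has a gap. `N` counts as a difference
#' against every base including `N`.
#'
#' @param a,b nucleotide sequences (character scalars, RNA or DNA).
#' @param align an [alignment_params()] object.
#' @return proportion in `[0, 1]`.
#' @examples
#' pairwise_p_distance("ACGU", "ACGA")  # 0.25
#' @export
pairwise_p_distance <- function(a, b, align = alignment_params()) {
  if (nchar(a) == 0 || nchar(b) == 0) mpm_stop("sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(to_dna(a)), Biostrings::DNAString(to_dna(b)),
    type = "global", substitutionMatrix = align_submat(align),
    gapOpening = 0, gapExtension = -align$gap)
  p_from_alignment(as.character(Biostrings::alignedPattern(aln)),
                   as.character(Biostrings::alignedSubject(aln)))
}

#' Jukes-Cantor evolutionary distance
#'
#' Converts a site-difference proportion `p` into an expected number of
#' substitutions per site under the Jukes-Cantor model,
#' `d = -(3/4) * log(1 - (4/3) * p)`, which corrects the observed
#' proportion for multiple hits. The formula is undefined ("saturated")
#' for `p >= 0.75`, the expected difference proportion between unrelated
#' sequences under the model.
#'
#' @param p numeric vector of proportions in `[0, 1]`.
#' @param on_saturation `"error"` (default) or `"cap"`.
#' @param saturation_cap finite distance substituted for saturated pairs
#'   when `on_saturation = "cap"`.
#' @return numeric vector of distances (substitutions/site), `>= p`.
#' @examples
#' jukes_cantor(0.1)  # 0.1073256
#' @export
jukes_cantor <- function(p, on_saturation = c("error", "cap"),
                         saturation_cap = 5) {
  on_saturation <- match.arg(on_saturation)
  if (any(p < 0 | p > 1)) mpm_stop("p must lie in [0, 1]")
  sat <- p >= 0.75
  if (any(sat) && on_saturation == "error")
    mpm_stop("Jukes-Cantor distance undefined for p >= 0.75 (got %s)",
             mpm_join(format(p[sat])))
  d <- numeric(length(p))
  d[sat] <- saturation_cap
  d[!sat] <- -0.75 * log1p(-(4 / 3) * p[!sat])
  d
}

#' Jukes-Cantor distance matrix for a sequence set
#'
#' All pairwise p-distances (via global alignment, see
#' [pairwise_p_distance()]) converted to Jukes-Cantor distances. Saturated
#' pairs (`p >= 0.75`) are recorded and assigned the `saturation_cap`
#' distance so downstream clustering stays finite; each such pair is
#' reported on the message stream.
#'
#' @param seqs a `mirna_seqs` set of at least two sequences.
#' @param align an [alignment_params()] object.
#' @param saturation_cap distance substituted for saturated pairs
#'   (default 5 substitutions/site, far beyond realistic stem-loop
#'   divergence).
#' @return object of class `jc_dist`: list with `labels`, `distance`
#'   (symmetric matrix), `p` (site-difference proportions) and
#'   `saturated_pairs` (two-column character matrix).
#' @export
jc_distance_matrix <- function(seqs, align = alignment_params(),
                               saturation_cap = 5) {
  stopifnot(inherits(seqs, "mirna_seqs"))
  n <- length(seqs)
  if (n < 2) mpm_stop("need at least 2 sequences")
  labs <- names(seqs)
  dna <- Biostrings::DNAStringSet(to_dna(seqs))
  submat <- align_submat(align)
  p <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    aln <- Biostrings::pairwiseAlignment(
      dna[js], dna[[i]], type = "global", substitutionMatrix = submat,
      gapOpening = 0, gapExtension = -align$gap)
    pa <- as.character(Biostrings::alignedPattern(aln))
    sa <- as.character(Biostrings::alignedSubject(aln))
    p[i, js] <- p[js, i] <- mapply(p_from_alignment, pa, sa, USE.NAMES = FALSE)
  }
  sat_idx <- which(p >= 0.75 & upper.tri(p), arr.ind = TRUE)
  saturated <- cbind(labs[sat_idx[, 1]], labs[sat_idx[, 2]])
  colnames(saturated) <- c("a", "b")
  if (nrow(saturated))
    mpm_log("saturated pair(s) capped at %g: %s", saturation_cap,
            mpm_join(paste(saturated[, 1], saturated[, 2], sep = "~")))
  d <- jukes_cantor(p, on_saturation = "cap", saturation_cap = saturation_cap)
  dim(d) <- dim(p); dimnames(d) <- dimnames(p)
  diag(d) <- 0
  structure(list(labels = labs, distance = d, p = p,
                 saturated_pairs = saturated, align = align,
                 saturation_cap = saturation_cap),
            class = "jc_dist")
}

#' @export
print.jc_dist <- function(x, ...) {
  off <- x$distance[upper.tri(x$distance)]
  cat(sprintf("Jukes-Cantor distance matrix: %d sequences, range %.4g-%.4g, %d saturated pair(s)\n",
              length(x$labels), min(off), max(off), nrow(x$saturated_pairs)))
  invisible(x)
}

#' Export a distance matrix
#'
#' Writes a `jc_dist` (or plain matrix) as PHYLIP square format or TSV.
#'
#' @param x a `jc_dist` or symmetric matrix with dimnames.
#' @param path output file.
#' @param format `"phylip"` or `"tsv"`.
#' @export
write_distance_matrix <- function(x, path, format = c("phylip", "tsv")) {
  format <- match.arg(format)
  m <- if (inherits(x, "jc_dist")) x$distance else as.matrix(x)
  if (format == "tsv") {
    utils::write.table(data.frame(label = rownames(m), m, check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    lines <- c(sprintf("%5d", nrow(m)),
               vapply(seq_len(nrow(m)), function(i) {
                 paste0(formatC(rownames(m)[i], width = -10),
                        paste(sprintf("%.8f", m[i, ]), collapse = "  "))
               }, character(1)))
    writeLines(lines, path)
  }
  invisible(path)
}
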