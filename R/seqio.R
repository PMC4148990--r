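#' Read a FASTA file into a sequence tibble
#'
#' Sequences are uppercased on ingest; for `alphabet = "dna"`, `U` is mapped
#' to `T` and characters outside `A/C/G/T/N` are rejected or mapped to `N`
#' per `on_invalid`. Record order is preserved.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"dna"` or `"protein"`.
#' @param on_invalid for DNA, what to do with characters outside the alphabet:
#'   `"error"` (default) or `"N"`.
#' @return a tibble with columns `id` (first whitespace-delimited token of the
#'   header) and `seq`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ac", "gt", ">b", "TT"), fa)
#' read_fasta(fa)
read_fasta <- function(path, alphabet = c("dna", "protein"),
                       on_invalid = c("error", "N")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  seqs <- as.character(set)
  seqs <- if (alphabet == "dna") {
    normalize_nuc(seqs, on_invalid = match.arg(on_invalid))
  } else {
    normalize_prot(seqs)
  }
  tibble(id = ids, seq = unname(seqs))
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs a tibble/data frame with columns `id` and `seq`.
#' @param path output path.
#' @param width line-fold width (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  set <- Biostrings::BStringSet(stats::setNames(seqs$seq, seqs$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# genetic code table 11 (bacterial); the codon table itself matches the
# standard code -- table 11 differs only in its initiation-codon set, and
# non-ATG starts are deliberately rendered as their table amino acid here
# (documented divergence from annotation practice; see the methods vignette).
genetic_code_table <- function(table = 11) {
  Biostrings::getGeneticCode(as.character(table))
}

#' Translate a coding sequence
#'
#' Translates a complete CDS under NCBI genetic code table 11 (bacterial) by
#' straight codon lookup: non-ATG start codons are rendered as their table
#' amino acid (not forced to `M`), codons containing `N` become `X`, a single
#' terminal stop is stripped, and an internal stop is an error.
#'
#' @param nuc a nucleotide string (length divisible by 3).
#' @param table NCBI genetic code table id (default `11`).
#' @return the protein string.
#' @export
#' @examples
#' translate_cds("ATGAAATAA")  # "MK"
#' translate_cds("ATGANA")     # "MX"
translate_cds <- function(nuc, table = 11) {
  nuc <- normalize_nuc(nuc)
  n <- nchar(nuc)
  if (n == 0) stop("empty CDS", call. = FALSE)
  if (n %% 3 != 0) {
    stop("CDS length ", n, " not divisible by 3", call. = FALSE)
  }
  codons <- substring(nuc, seq(1, n, 3), seq(3, n, 3))
  code <- genetic_code_table(table)
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"  # codons containing N
  if (any(aa[-length(aa)] == "*")) {
    stop("internal stop codon at codon ",
         which(aa[-length(aa)] == "*")[1], call. = FALSE)
  }
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

#' Nucleotide composition statistics
#'
#' @param seqs a character vector of nucleotide strings, or a tibble with a
#'   `seq` column (as returned by [read_fasta()]).
#' @return a one-row tibble with `total_bp`, `gc_bp` and `gc_pct`
#'   (`100 * gc_bp / total_bp`, rounded half-up to 2 decimals). `N` bases
#'   count toward `total_bp` only.
#' @export
#' @examples
#' gc_stats(c("GGCC", "ATAT"))
gc_stats <- function(seqs) {
  if (is.data.frame(seqs)) seqs <- seqs$seq
  if (length(seqs) == 0) stop("at least one sequence required", call. = FALSE)
  seqs <- normalize_nuc(seqs)
  total_bp <- sum(nchar(seqs))
  if (total_bp == 0) stop("zero total length", call. = FALSE)
  gc_bp <- sum(nchar(gsub("[^GC]", "", seqs)))
  tibble(total_bp = total_bp, gc_bp = gc_bp,
         gc_pct = pct_of(gc_bp, total_bp))
}
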