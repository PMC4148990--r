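#' Affine-gap Needleman-Wunsch global alignment
#'
#' Optimal global alignment of two sequences under a [scoring_scheme()],
#' computed by the Gotoh three-state recurrence with full traceback. End gaps
#' are penalized (true global alignment). The traceback is deterministic:
#' ties prefer the diagonal move, then a gap in `b`, then a gap in `a`.
#'
#' Identity accounting follows the total-column convention:
#' `identity_pct = 100 * n_identical / length`, where `length` counts every
#' alignment column including gap columns, and a column only counts as
#' identical when both symbols are equal and neither is the neutral symbol
#' (`N`/`X`). Set `denominator = "ungapped"` to divide by non-gap columns
#' instead.
#'
#' @param a,b sequence strings (non-empty).
#' @param scheme a [scoring_scheme()]; default nucleotide.
#' @param denominator `"columns"` (default, gap columns included) or
#'   `"ungapped"`.
#' @return an `agios_alignment`: list with `aligned_a`, `aligned_b`, `score`
#'   (integer, on the scheme's doubled scale), `length`, `n_identical`,
#'   `identity_pct`.
#' @export
#' @examples
#' aln <- global_align("ACGTACGT", "ACGAACGT")
#' aln$identity_pct  # 87.5
global_align <- function(a, b, scheme = nucleotide_scheme(),
                         denominator = c("columns", "ungapped")) {
  denominator <- match.arg(denominator)
  stopifnot(is.character(a), is.character(b))
  if (nchar(a) == 0 || nchar(b) == 0) {
    stop("empty sequence in global_align", call. = FALSE)
  }
  ia <- encode_seq(a, scheme) - 1L  # 0-based codes for the C++ core
  ib <- encode_seq(b, scheme) - 1L
  res <- gotoh_align_cpp(ia, ib, scheme$submat,
                         scheme$gap_open, scheme$gap_extend)
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  col_a <- ifelse(res$ia == 0, "-", ca[pmax(res$ia, 1)])
  col_b <- ifelse(res$ib == 0, "-", cb[pmax(res$ib, 1)])
  len <- length(col_a)
  ident <- col_a == col_b & col_a != "-" &
    !col_a %in% c(scheme$neutral %||% character(0))
  n_id <- sum(ident)
  denom <- if (denominator == "columns") len else sum(col_a != "-" & col_b != "-")
  structure(
    list(aligned_a = paste(col_a, collapse = ""),
         aligned_b = paste(col_b, collapse = ""),
         score = res$score, length = len, n_identical = n_id,
         identity_pct = 100 * n_id / denom,
         scheme_kind = scheme$kind),
    class = "agios_alignment"
  )
}

#' Percent identity between two sequences
#'
#' Identity of the optimal global alignment under `scheme`. Symmetric in its
#' arguments: the pair is put in canonical (lexicographic) order before
#' aligning, so co-optimal tracebacks cannot make `identity_between(a, b)`
#' differ from `identity_between(b, a)`.
#'
#' @inheritParams global_align
#' @return percent identity in `[0, 100]` (full precision; round at render).
#' @export
identity_between <- function(a, b, scheme = nucleotide_scheme()) {
  if (b < a) { tmp <- a; a <- b; b <- tmp }
  global_align(a, b, scheme)$identity_pct
}

#' @export
print.agios_alignment <- function(x, width = 60, ...) {
  cat("<agios_alignment> ", x$scheme_kind, ", score ", x$score,
      " (2x scale), ", x$length, " columns, ", x$n_identical,
      " identical (", round_half_up(x$identity_pct, 1), "%)\n", sep = "")
  for (o in seq(1, x$length, width)) {
    cat(substr(x$aligned_a, o, o + width - 1), "\n",
        substr(x$aligned_b, o, o + width - 1), "\n\n", sep = "")
  }
  invisible(x)
}

#' @describeIn global_align one-row tibble of alignment statistics.
#' @param x an `agios_alignment`.
#' @param ... unused.
#' @method tidy agios_alignment
#' @export
tidy.agios_alignment <- function(x, ...) {
  tibble(score = x$score, length = x$length, n_identical = x$n_identical,
         identity_pct = x$identity_pct)
}

#' Write an alignment as an aligned-FASTA pair (debug aid)
#'
#' @param aln an `agios_alignment`.
#' @param path output path.
#' @param ids ids for the two rows.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, ids = c("a", "b")) {
  write_fasta(tibble(id = ids, seq = c(aln$aligned_a, aln$aligned_b)), path)
}
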