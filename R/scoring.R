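#' Scoring schemes for global alignment
#'
#' A scheme bundles a symmetric substitution matrix with affine gap
#' penalties. Half-point penalties are handled by doubling every score
#' internally, so the dynamic programme stays in integers; reported alignment
#' scores are on this doubled scale (`scale = 2`), which is documented
#' wherever scores surface. A gap run of length L costs
#' `gap_open + L * gap_extend` (on the same scale).
#'
#' Defaults mirror the most widely replicated Needleman-Wunsch settings
#' (EMBOSS needle): nucleotide match +5 / mismatch -4, gap open 10, gap
#' extend 0.5; protein BLOSUM62 with the same gap penalties. The neutral
#' symbols `N` (nucleotide) and `X` (protein) score 0 against everything and
#' never count as identical.
#'
#' @param kind `"nucleotide"` or `"protein"`.
#' @param substitution square symmetric numeric matrix with identical
#'   row/column names (the alphabet), on the natural (undoubled) scale.
#' @param gap_open,gap_extend non-negative penalties on the natural scale;
#'   `gap_extend <= gap_open`.
#' @param neutral symbol scoring 0 against everything (fallback for symbols
#'   absent from the matrix); `NULL` to disable fallback.
#' @return a `scoring_scheme` object.
#' @export
scoring_scheme <- function(kind, substitution, gap_open, gap_extend,
                           neutral = NULL) {
  stopifnot(is.matrix(substitution),
            nrow(substitution) == ncol(substitution),
            identical(rownames(substitution), colnames(substitution)),
            gap_open >= 0, gap_extend >= 0, gap_extend <= gap_open)
  if (!isTRUE(all.equal(substitution, t(substitution)))) {
    stop("substitution matrix must be symmetric", call. = FALSE)
  }
  sub2 <- round(2 * substitution)
  storage.mode(sub2) <- "integer"
  structure(
    list(kind = kind, alphabet = rownames(substitution),
         submat = sub2, gap_open = as.integer(round(2 * gap_open)),
         gap_extend = as.integer(round(2 * gap_extend)),
         neutral = neutral, scale = 2L),
    class = "scoring_scheme"
  )
}

#' @describeIn scoring_scheme default nucleotide scheme (match/mismatch).
#' @param match,mismatch nucleotide match and mismatch scores.
#' @export
nucleotide_scheme <- function(match = 5, mismatch = -4, gap_open = 10,
                              gap_extend = 0.5) {
  ab <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(ab, ab))
  diag(m) <- match
  m["N", ] <- 0
  m[, "N"] <- 0
  scoring_scheme("nucleotide", m, gap_open, gap_extend, neutral = "N")
}

#' @describeIn scoring_scheme default protein scheme (BLOSUM62).
#' @export
protein_scheme <- function(gap_open = 10, gap_extend = 0.5) {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  m <- m[rownames(m) != "*", colnames(m) != "*"]
  m["X", ] <- 0
  m[, "X"] <- 0
  scoring_scheme("protein", m, gap_open, gap_extend, neutral = "X")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("<scoring_scheme> ", x$kind, ": ", length(x$alphabet),
      "-letter alphabet, gap open ", x$gap_open / 2, ", extend ",
      x$gap_extend / 2, " (integer DP on 2x scale)\n", sep = "")
  invisible(x)
}

# map a sequence string to 1-based matrix indices; unknown symbols fall back
# to the scheme's neutral symbol, or error if fallback is disabled
encode_seq <- function(s, scheme) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  idx <- match(chars, scheme$alphabet)
  if (anyNA(idx)) {
    if (is.null(scheme$neutral)) {
      stop("symbol(s) with no matrix entry: ",
           paste(unique(chars[is.na(idx)]), collapse = " "), call. = FALSE)
    }
    idx[is.na(idx)] <- match(scheme$neutral, scheme$alphabet)
  }
  idx
}
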