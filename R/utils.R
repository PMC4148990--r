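#' Round half away from zero
#'
#' Fixed-precision rounding used for every reported percentage: exact halves
#' round up (`0.125 -> 0.13` at 2 dp), unlike [base::round()]'s banker's
#' rounding. All table renderers in the package go through this helper so
#' printed percentages recompute exactly from printed counts.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up to `digits` decimals.
#' @export
#' @examples
#' round_half_up(2.5, 0)   # 3, where round(2.5) gives 2
#' round_half_up(50.385, 2)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # nudge guards against representation error in x * p for decimal inputs
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Percentage of a count over a denominator, rounded half-up
#' @param count,total numeric scalars or vectors.
#' @param digits decimal places (default 2).
#' @return `100 * count / total` rounded half-up.
#' @export
pct_of <- function(count, total, digits = 2) {
  round_half_up(100 * count / total, digits)
}

#' Reverse complement of a nucleotide string
#'
#' Accepts only `A`, `C`, `G`, `T`, `N` (the package's ingest alphabet).
#'
#' @param s character vector of nucleotide strings.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' reverse_complement("ATGAAATAA")
reverse_complement <- function(s) {
  comp <- chartr("ACGTN", "TGCAN", s)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""), character(1))
}

# normalise a raw sequence string: uppercase, U -> T; characters outside the
# alphabet are mapped to N (on_invalid = "N") or rejected.
normalize_nuc <- function(s, on_invalid = c("error", "N")) {
  on_invalid <- match.arg(on_invalid)
  s <- chartr("u", "t", s)
  s <- toupper(chartr("U", "T", s))
  bad <- gsub("[ACGTN]", "", s)
  if (any(nzchar(bad))) {
    if (on_invalid == "error") {
      stop("invalid nucleotide character(s): ",
           paste(unique(strsplit(paste(bad, collapse = ""), "")[[1]]),
                 collapse = " "), call. = FALSE)
    }
    s <- gsub("[^ACGTN]", "N", s)
  }
  s
}

normalize_prot <- function(s) {
  s <- toupper(s)
  sub("\\*$", "", s)  # strip one terminal stop marker if present
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# thousands separator used only at render time
fmt_thousands <- function(x) formatC(x, format = "d", big.mark = ",")
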