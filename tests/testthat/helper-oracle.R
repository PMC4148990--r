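# Brute-force alignment oracle: enumerate every monotone global alignment
# path and take the best affine score. Independent of the Gotoh dynamic
# programme it cross-checks (no recurrence, no traceback) -- just exhaustive
# path enumeration. A path is a string over D (diagonal), U (consume a, gap
# in b), L (consume b, gap in a); a gap run of length L costs
# open + L * extend, matching the package's stated convention.

.path_cache <- new.env(parent = emptyenv())

enumerate_paths <- function(n, m) {
  key <- paste(n, m)
  if (!is.null(.path_cache[[key]])) return(.path_cache[[key]])
  rec <- function(i, j) {
    if (i == 0 && j == 0) return("")
    out <- character(0)
    if (i > 0 && j > 0) out <- paste0(rec(i - 1, j - 1), "D")
    if (i > 0) out <- c(out, paste0(rec(i - 1, j), "U"))
    if (j > 0) out <- c(out, paste0(rec(i, j - 1), "L"))
    out
  }
  paths <- rec(n, m)
  .path_cache[[key]] <- paths
  paths
}

# affine gap cost of a move string: each maximal run of U's or L's opens one
# gap; cost = open + run_length * extend
path_gap_cost <- function(moves, open, extend) {
  runs <- rle(strsplit(moves, "")[[1]])
  gap_runs <- runs$lengths[runs$values != "D"]
  sum(open + gap_runs * extend)
}

# (i, j) pairs matched by the path's diagonal moves
path_diag_cells <- function(moves) {
  mv <- strsplit(moves, "")[[1]]
  i <- cumsum(mv != "L")
  j <- cumsum(mv != "U")
  cbind(i = i[mv == "D"], j = j[mv == "D"])
}

# oracle score of one pair (chars as integer codes into submat)
oracle_score <- function(ai, bi, submat, open, extend) {
  paths <- enumerate_paths(length(ai), length(bi))
  best <- -Inf
  for (p in paths) {
    cells <- path_diag_cells(p)
    s <- sum(submat[cbind(ai[cells[, "i"]], bi[cells[, "j"]])]) -
      path_gap_cost(p, open, extend)
    if (s > best) best <- s
  }
  best
}

# vectorised oracle over ALL nucleotide pairs of lengths (n, m): returns the
# optimal score for every (a, b) in row-major order over the 4^n x 4^m grid
# of sequences (A=1, C=2, G=3, T=4, lexicographic by code)
oracle_scores_all <- function(n, m, submat, open, extend) {
  enum_strings <- function(len) {
    as.matrix(rev(expand.grid(rev(replicate(len, 1:4, simplify = FALSE)))))
  }
  A <- enum_strings(n)   # 4^n x n codes
  B <- enum_strings(m)
  na <- nrow(A); nb <- nrow(B)
  ai <- rep(seq_len(na), each = nb)
  bi <- rep(seq_len(nb), times = na)
  best <- rep(-Inf, na * nb)
  for (p in enumerate_paths(n, m)) {
    cells <- path_diag_cells(p)
    s <- rep(-path_gap_cost(p, open, extend), na * nb)
    for (r in seq_len(nrow(cells))) {
      s <- s + submat[cbind(A[ai, cells[r, "i"]], B[bi, cells[r, "j"]])]
    }
    best <- pmax(best, s)
  }
  list(scores = best, A = A, B = B, ai = ai, bi = bi)
}

# re-score a returned gapped alignment column by column with affine
# bookkeeping; independent check that the traceback is consistent with the
# reported score
rescore_alignment <- function(aln, scheme) {
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  stopifnot(length(ca) == length(cb), !any(ca == "-" & cb == "-"))
  score <- 0
  state <- "M"
  for (k in seq_along(ca)) {
    if (ca[k] != "-" && cb[k] != "-") {
      ia <- match(ca[k], scheme$alphabet)
      ib <- match(cb[k], scheme$alphabet)
      score <- score + scheme$submat[ia, ib]
      state <- "M"
    } else {
      new_state <- if (cb[k] == "-") "U" else "L"
      score <- score - scheme$gap_extend -
        (if (state != new_state) scheme$gap_open else 0)
      state <- new_state
    }
  }
  score
}

random_nuc <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
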