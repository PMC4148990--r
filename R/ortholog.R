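#' Candidate ortholog pairs by shared amino-acid k-mers
#'
#' A cheap prefilter ahead of the all-vs-all dynamic programme: only protein
#' pairs sharing at least `min_shared` distinct k-mers are aligned. This is a
#' heuristic superset filter, not a guarantee (its retention on diverging
#' synthetic genomes is a tested property); it can be disabled everywhere it
#' is used.
#'
#' @param protsA,protsB tibbles with `id`, `seq` (protein).
#' @param k k-mer length (`>= 3`).
#' @param min_shared minimum number of distinct shared k-mers.
#' @return tibble with `id_a`, `id_b`.
#' @export
candidate_pairs <- function(protsA, protsB, k = 5, min_shared = 2) {
  stopifnot(k >= 3)
  kmer_tbl <- function(prots) {
    purrr::map_dfr(seq_len(nrow(prots)), function(i) {
      s <- prots$seq[i]
      n <- nchar(s)
      if (n < k) return(NULL)
      tibble(id = prots$id[i],
             kmer = unique(substring(s, 1:(n - k + 1), k:n)))
    })
  }
  ta <- kmer_tbl(protsA)
  tb <- kmer_tbl(protsB)
  if (nrow(ta) == 0 || nrow(tb) == 0) {
    return(tibble(id_a = character(), id_b = character()))
  }
  ta <- dplyr::rename(ta, id_a = "id")
  tb <- dplyr::rename(tb, id_b = "id")
  dplyr::inner_join(ta, tb, by = "kmer",
                    relationship = "many-to-many") %>%
    dplyr::count(.data$id_a, .data$id_b) %>%
    dplyr::filter(.data$n >= min_shared) %>%
    dplyr::select("id_a", "id_b")
}

# align every candidate pair once; both RBH directions read from this table
align_candidates <- function(protsA, protsB, scheme, pairs) {
  if (nrow(pairs) == 0) {
    return(tibble(id_a = character(), id_b = character(), score = double(),
                  identity_pct = double(), coverage_pct = double()))
  }
  seq_a <- stats::setNames(protsA$seq, protsA$id)
  seq_b <- stats::setNames(protsB$seq, protsB$id)
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    a <- seq_a[[pairs$id_a[i]]]
    b <- seq_b[[pairs$id_b[i]]]
    aln <- global_align(a, b, scheme)
    ca <- strsplit(aln$aligned_a, "")[[1]]
    cb <- strsplit(aln$aligned_b, "")[[1]]
    both <- sum(ca != "-" & cb != "-")
    tibble(id_a = pairs$id_a[i], id_b = pairs$id_b[i], score = aln$score,
           identity_pct = aln$identity_pct,
           coverage_pct = 100 * both / min(nchar(a), nchar(b)))
  })
}

# per-query best passing hit; score ties -> lexicographically smallest subject
best_of <- function(hits, query_col, subject_col, min_identity, min_coverage) {
  hits <- dplyr::filter(hits, .data$identity_pct >= min_identity,
                        .data$coverage_pct >= min_coverage)
  if (nrow(hits) == 0) return(hits)
  hits %>%
    dplyr::group_by(.data[[query_col]]) %>%
    dplyr::group_modify(function(g, key) {
      top <- g[g$score == max(g$score), , drop = FALSE]
      if (nrow(top) > 1) {
        message("best-hit score tie for ", key[[1]], ": ",
                paste(sort(top[[subject_col]]), collapse = ", "),
                " -> keeping lexicographically smallest")
        top <- top[order(top[[subject_col]]), , drop = FALSE]
      }
      top[1, , drop = FALSE]
    }) %>%
    dplyr::ungroup()
}

#' Best protein hits of each query against a subject set
#'
#' For every query protein, the subject with the maximal global-alignment
#' score among hits passing the identity and coverage thresholds (coverage is
#' measured over the shorter protein). Queries with no passing hit are absent
#' from the result. Score ties are resolved to the lexicographically smallest
#' subject id (and reported via `message()`).
#'
#' @inheritParams candidate_pairs
#' @param scheme protein [scoring_scheme()].
#' @param min_identity,min_coverage percent thresholds (defaults 25 and 50,
#'   the published defaults of the Proteinortho BLAST stage).
#' @param prefilter use [candidate_pairs()] first (`FALSE` aligns all pairs).
#' @param k,min_shared prefilter parameters.
#' @return tibble with `query_id`, `subject_id`, `score`, `identity_pct`,
#'   `coverage_pct`.
#' @export
best_hits <- function(protsA, protsB, scheme = protein_scheme(),
                      min_identity = 25, min_coverage = 50,
                      prefilter = TRUE, k = 5, min_shared = 2) {
  pairs <- if (prefilter) candidate_pairs(protsA, protsB, k, min_shared) else
    tidyr::expand_grid(id_a = protsA$id, id_b = protsB$id)
  hits <- align_candidates(protsA, protsB, scheme, pairs)
  best_of(hits, "id_a", "id_b", min_identity, min_coverage) %>%
    dplyr::select(query_id = "id_a", subject_id = "id_b", "score",
                  "identity_pct", "coverage_pct")
}

#' Reciprocal-best-hit orthologs between two genomes
#'
#' The ortholog-detection stage of AGIOS: proteins of the two genomes are
#' globally aligned (affine-gap Needleman-Wunsch, BLOSUM62 by default) and a
#' gene pair (a, b) is orthologous when b is a's best passing hit in genome B
#' and a is b's best passing hit in genome A. The matching is one-to-one by
#' construction and invariant (transposed) under swapping the genomes.
#'
#' @param genomeA,genomeB `agios_genome` objects with at least one valid
#'   (translatable) gene each.
#' @inheritParams best_hits
#' @return an `agios_ortholog_set`: `genome_a_id`, `genome_b_id`, `n_pairs`,
#'   and `pairs`, a tibble with `gene_a`, `gene_b`, `score`, `identity_pct`,
#'   `coverage_pct`.
#' @export
reciprocal_best_hits <- function(genomeA, genomeB, scheme = protein_scheme(),
                                 min_identity = 25, min_coverage = 50,
                                 prefilter = TRUE, k = 5, min_shared = 2) {
  ga <- valid_genes(genomeA)
  gb <- valid_genes(genomeB)
  if (nrow(ga) == 0 || nrow(gb) == 0) {
    stop("genome with zero valid proteins: ",
         if (nrow(ga) == 0) genomeA$genome_id else genomeB$genome_id,
         call. = FALSE)
  }
  protsA <- tibble(id = ga$gene_id, seq = ga$prot)
  protsB <- tibble(id = gb$gene_id, seq = gb$prot)
  pairs <- if (prefilter) candidate_pairs(protsA, protsB, k, min_shared) else
    tidyr::expand_grid(id_a = protsA$id, id_b = protsB$id)
  hits <- align_candidates(protsA, protsB, scheme, pairs)
  ba <- best_of(hits, "id_a", "id_b", min_identity, min_coverage)
  bb <- best_of(hits, "id_b", "id_a", min_identity, min_coverage)
  rbh <- dplyr::inner_join(
    dplyr::select(ba, gene_a = "id_a", gene_b = "id_b", "score",
                  "identity_pct", "coverage_pct"),
    dplyr::select(bb, gene_a = "id_a", gene_b = "id_b"),
    by = c("gene_a", "gene_b")
  ) %>%
    dplyr::arrange(.data$gene_a)
  stopifnot(!anyDuplicated(rbh$gene_a), !anyDuplicated(rbh$gene_b))
  structure(
    list(genome_a_id = genomeA$genome_id, genome_b_id = genomeB$genome_id,
         pairs = rbh, n_pairs = nrow(rbh)),
    class = "agios_ortholog_set"
  )
}

#' @export
print.agios_ortholog_set <- function(x, ...) {
  cat("<agios_ortholog_set> ", x$genome_a_id, " vs ", x$genome_b_id, ": ",
      x$n_pairs, " reciprocal best hits\n", sep = "")
  invisible(x)
}

#' @describeIn reciprocal_best_hits ortholog pairs as a tibble.
#' @param x an `agios_ortholog_set`.
#' @param ... unused.
#' @method tidy agios_ortholog_set
#' @export
tidy.agios_ortholog_set <- function(x, ...) x$pairs

#' Read/write an ortholog set as TSV
#'
#' The header comment line carries the genome ids so the file round-trips.
#'
#' @param x an `agios_ortholog_set`.
#' @param path file path.
#' @return `write_orthologs()`: `path` invisibly; `read_orthologs()`: the
#'   ortholog set.
#' @export
write_orthologs <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# genome_a=%s\tgenome_b=%s",
                     x$genome_a_id, x$genome_b_id), con)
  utils::write.table(x$pairs, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_orthologs
#' @export
read_orthologs <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec("genome_a=([^\t]+)\tgenome_b=(.+)$", hdr))[[1]]
  pairs <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1,
                             stringsAsFactors = FALSE)
  structure(
    list(genome_a_id = m[2], genome_b_id = m[3], pairs = as_tibble(pairs),
         n_pairs = nrow(pairs)),
    class = "agios_ortholog_set"
  )
}
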