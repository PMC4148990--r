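#' AGIOS for one genome pair
#'
#' Average Genomic Identity of Orthologous gene Sequences: every
#' reciprocal-best-hit ortholog pair is aligned at the nucleotide level
#' (full ORF-to-ORF global alignment) and the unweighted arithmetic mean of
#' the per-pair percent identities summarises the genome pair. A
#' length-weighted mean is also carried in the result for verbose reporting
#' but the headline statistic is the per-ORF mean.
#'
#' @param genomeA,genomeB `agios_genome` objects.
#' @param orthologs an `agios_ortholog_set` computed between exactly these
#'   genomes, or `NULL` to compute one with [reciprocal_best_hits()].
#' @param nuc_scheme nucleotide [scoring_scheme()] for the ORF alignments.
#' @param ... passed to [reciprocal_best_hits()] when `orthologs` is `NULL`.
#' @return an `agios_result`: `genome_a_id`, `genome_b_id`, `n_orthologs`,
#'   `mean_identity_pct` (`NA` -- never 0 -- when there are no ortholog
#'   pairs), `mean_identity_weighted_pct`, and `per_pair`, a tibble with
#'   `gene_a`, `gene_b`, `aln_columns`, `identity_pct`.
#' @export
agios_pair <- function(genomeA, genomeB, orthologs = NULL,
                       nuc_scheme = nucleotide_scheme(), ...) {
  if (is.null(orthologs)) {
    orthologs <- reciprocal_best_hits(genomeA, genomeB, ...)
  }
  if (!setequal(c(orthologs$genome_a_id, orthologs$genome_b_id),
                c(genomeA$genome_id, genomeB$genome_id))) {
    stop("ortholog set was computed for different genomes", call. = FALSE)
  }
  flip <- orthologs$genome_a_id != genomeA$genome_id
  nuc_a <- stats::setNames(genomeA$genes$nuc, genomeA$genes$gene_id)
  nuc_b <- stats::setNames(genomeB$genes$nuc, genomeB$genes$gene_id)
  pairs <- orthologs$pairs
  if (flip) pairs <- dplyr::rename(pairs, gene_a = "gene_b", gene_b = "gene_a")

  per_pair <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    a <- unname(nuc_a[pairs$gene_a[i]])
    b <- unname(nuc_b[pairs$gene_b[i]])
    if (is.na(a) || is.na(b)) {
      stop("ortholog pair references gene without nucleotide ORF", call. = FALSE)
    }
    if (b < a) {  # canonical order: identity symmetric under genome swap
      aln <- global_align(b, a, nuc_scheme)
    } else {
      aln <- global_align(a, b, nuc_scheme)
    }
    tibble(gene_a = pairs$gene_a[i], gene_b = pairs$gene_b[i],
           aln_columns = aln$length, identity_pct = aln$identity_pct)
  })
  n <- nrow(per_pair)
  structure(
    list(genome_a_id = genomeA$genome_id, genome_b_id = genomeB$genome_id,
         n_orthologs = n,
         mean_identity_pct = if (n > 0) mean(per_pair$identity_pct) else NA_real_,
         mean_identity_weighted_pct = if (n > 0) {
           stats::weighted.mean(per_pair$identity_pct, per_pair$aln_columns)
         } else NA_real_,
         per_pair = per_pair),
    class = "agios_result"
  )
}

#' @export
print.agios_result <- function(x, ...) {
  cat("<agios_result> ", x$genome_a_id, " vs ", x$genome_b_id, ": ",
      x$n_orthologs, " orthologs, mean identity ",
      if (is.na(x$mean_identity_pct)) "NA" else
        format(round_half_up(x$mean_identity_pct, 1), nsmall = 1),
      "%\n", sep = "")
  invisible(x)
}

#' @describeIn agios_pair per-ortholog-pair identities as a tibble.
#' @param x an `agios_result`.
#' @param ... unused.
#' @method tidy agios_result
#' @export
tidy.agios_result <- function(x, ...) x$per_pair

#' @describeIn agios_pair one-row summary tibble.
#' @method glance agios_result
#' @export
glance.agios_result <- function(x, ...) {
  tibble(genome_a_id = x$genome_a_id, genome_b_id = x$genome_b_id,
         n_orthologs = x$n_orthologs,
         mean_identity_pct = x$mean_identity_pct,
         mean_identity_weighted_pct = x$mean_identity_weighted_pct)
}

#' AGIOS comparison matrix over a set of genomes
#'
#' All unordered genome pairs are compared once and assembled in the
#' conventional comparison-table layout: the diagonal carries each genome's
#' valid protein-coding gene count, the upper triangle the mean percent
#' identity of orthologous ORFs, the lower triangle the ortholog-pair count.
#'
#' @param genomes list of `agios_genome` objects (>= 2, unique ids).
#' @param nuc_scheme,prot_scheme scoring schemes for the ORF and protein
#'   stages.
#' @param min_identity,min_coverage RBH thresholds (see [best_hits()]).
#' @param prefilter,k,min_shared prefilter settings (see [candidate_pairs()]).
#' @return an `agios_matrix`: `genome_ids`, `diagonal` (gene counts),
#'   `identity` and `n_orthologs` (full square matrices, `NA` diagonal), and
#'   `results`, the list of [agios_pair()] results.
#' @export
agios_matrix <- function(genomes, nuc_scheme = nucleotide_scheme(),
                         prot_scheme = protein_scheme(),
                         min_identity = 25, min_coverage = 50,
                         prefilter = TRUE, k = 5, min_shared = 2) {
  if (length(genomes) < 2) stop(">= 2 genomes required", call. = FALSE)
  ids <- vapply(genomes, function(g) g$genome_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate genome ids", call. = FALSE)
  n <- length(genomes)
  ident <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  nort <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  results <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      res <- agios_pair(genomes[[i]], genomes[[j]], nuc_scheme = nuc_scheme,
                        scheme = prot_scheme, min_identity = min_identity,
                        min_coverage = min_coverage, prefilter = prefilter,
                        k = k, min_shared = min_shared)
      ident[i, j] <- ident[j, i] <- res$mean_identity_pct
      nort[i, j] <- nort[j, i] <- res$n_orthologs
      results[[paste(ids[i], ids[j], sep = "|")]] <- res
    }
  }
  structure(
    list(genome_ids = ids,
         diagonal = vapply(genomes, function(g) nrow(valid_genes(g)),
                           integer(1)),
         identity = ident, n_orthologs = nort, results = results),
    class = "agios_matrix"
  )
}

#' @export
print.agios_matrix <- function(x, ...) {
  cat("<agios_matrix> ", length(x$genome_ids), " genomes\n", sep = "")
  print(as_wide_matrix(x), quote = FALSE)
  invisible(x)
}

# 6B-style wide character matrix: diagonal gene counts (thousands separators),
# upper identities at 1 dp, lower ortholog counts
as_wide_matrix <- function(x) {
  n <- length(x$genome_ids)
  out <- matrix("", n, n, dimnames = list(x$genome_ids, x$genome_ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- if (i == j) fmt_thousands(x$diagonal[i]) else if (i < j) {
        if (is.na(x$identity[i, j])) "NA" else
          format(round_half_up(x$identity[i, j], 1), nsmall = 1)
      } else fmt_thousands(x$n_orthologs[i, j])
    }
  }
  out
}

#' @describeIn agios_matrix long tibble of all pairwise results.
#' @param x an `agios_matrix`.
#' @param ... unused.
#' @method tidy agios_matrix
#' @export
tidy.agios_matrix <- function(x, ...) {
  purrr::map_dfr(x$results, glance)
}

#' @describeIn agios_matrix heat-map of the mean-identity matrix; ortholog
#'   counts are printed in the lower triangle, gene counts on the diagonal.
#' @param object an `agios_matrix`.
#' @method autoplot agios_matrix
#' @export
autoplot.agios_matrix <- function(object, ...) {
  n <- length(object$genome_ids)
  long <- tidyr::expand_grid(i = seq_len(n), j = seq_len(n)) %>%
    dplyr::mutate(
      genome_a = factor(object$genome_ids[.data$i], levels = object$genome_ids),
      genome_b = factor(object$genome_ids[.data$j],
                        levels = rev(object$genome_ids)),
      identity = ifelse(.data$i == .data$j, NA,
                        object$identity[cbind(.data$i, .data$j)]),
      label = dplyr::case_when(
        .data$i == .data$j ~ fmt_thousands(object$diagonal[.data$i]),
        .data$i < .data$j ~ format(round_half_up(
          object$identity[cbind(.data$i, .data$j)], 1), nsmall = 1),
        TRUE ~ fmt_thousands(object$n_orthologs[cbind(.data$i, .data$j)])
      )
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$genome_a, y = .data$genome_b,
                                     fill = .data$identity)) +
    ggplot2::geom_tile(color = "grey60") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_viridis_c(na.value = "grey92",
                                  name = "mean identity (%)") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "AGIOS: mean nucleotide identity of orthologous ORFs") +
    ggplot2::theme_minimal()
}

#' Write/read an AGIOS matrix as wide TSV
#'
#' Full-precision values: the diagonal holds gene counts, the upper triangle
#' mean identities (unrounded), the lower triangle ortholog counts. Rendering
#' (1 dp, thousands separators) happens only in [render_table6()].
#'
#' @param x an `agios_matrix`.
#' @param path file path.
#' @return `write_agios_matrix()`: `path` invisibly; `read_agios_matrix()`: a
#'   list with `genome_ids`, `diagonal`, `identity`, `n_orthologs` (an
#'   `agios_matrix` without per-pair results).
#' @export
write_agios_matrix <- function(x, path) {
  n <- length(x$genome_ids)
  num <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num[i, j] <- if (i == j) x$diagonal[i] else if (i < j)
      x$identity[i, j] else x$n_orthologs[i, j]
  }
  df <- data.frame(genome_id = x$genome_ids, num, check.names = FALSE)
  names(df) <- c("genome_id", x$genome_ids)
  utils::write.table(format(df, digits = 17, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_agios_matrix
#' @export
read_agios_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- df$genome_id
  num <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(num) <- "double"
  n <- length(ids)
  ident <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  nort <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diagonal <- integer(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) diagonal[i] <- as.integer(num[i, j])
    else if (i < j) ident[i, j] <- ident[j, i] <- num[i, j]
    else nort[i, j] <- nort[j, i] <- num[i, j]
  }
  structure(list(genome_ids = ids, diagonal = diagonal, identity = ident,
                 n_orthologs = nort, results = NULL),
            class = "agios_matrix")
}

#' Render the genome-comparison report
#'
#' Produces the two-part comparison report conventional in taxono-genomic
#' descriptions: a per-genome metadata table (genome size in Mb at 2 dp, G+C
#' percent) and the comparison matrix (diagonal: gene counts; upper: mean
#' identities at 1 dp; lower: ortholog counts with thousands separators).
#' All rounding is half-up and applies at render time only.
#'
#' @param x an `agios_matrix`.
#' @param metadata tibble with `genome_id`, `size_bp`, `gc_pct`; ids must
#'   match the matrix ids.
#' @return list with `metadata` (rendered tibble), `matrix` (character
#'   matrix) and `text` (aligned-text lines).
#' @export
render_table6 <- function(x, metadata) {
  if (length(x$genome_ids) < 2) stop(">= 2 genomes required", call. = FALSE)
  if (!setequal(metadata$genome_id, x$genome_ids)) {
    stop("metadata ids do not match matrix ids", call. = FALSE)
  }
  metadata <- metadata[match(x$genome_ids, metadata$genome_id), ]
  meta <- tibble(
    genome_id = metadata$genome_id,
    size_mb = format(round_half_up(metadata$size_bp / 1e6, 2), nsmall = 2),
    gc_pct = format(round_half_up(metadata$gc_pct, 2), nsmall = 2)
  )
  wide <- as_wide_matrix(x)
  meta_lines <- c("Genome\tSize (Mb)\tG+C (%)",
                  sprintf("%s\t%s\t%s", meta$genome_id, meta$size_mb,
                          meta$gc_pct))
  mat_lines <- c(paste(c("", x$genome_ids), collapse = "\t"),
                 vapply(seq_len(nrow(wide)), function(i) {
                   paste(c(x$genome_ids[i], wide[i, ]), collapse = "\t")
                 }, character(1)))
  txt <- c("Per-genome properties", meta_lines, "",
           paste0("Comparison matrix (diagonal: protein-coding genes; ",
                  "upper: mean % identity of orthologous ORFs; ",
                  "lower: ortholog pairs)"),
           mat_lines)
  list(metadata = meta, matrix = wide, text = txt)
}
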