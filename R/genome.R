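#' Construct a genome object
#'
#' The unit of comparison for AGIOS: contig sequences plus an ordered table of
#' protein-coding genes. Gene coordinates are held 0-based half-open
#' internally; file interfaces (GFF3) convert from 1-based inclusive. Genes
#' whose CDS length is not divisible by 3 or whose translation hits an
#' internal stop are kept but flagged invalid and excluded from AGIOS.
#'
#' @param genome_id genome identifier.
#' @param contigs tibble with `id`, `seq` (may have zero rows for CDS-only
#'   genomes).
#' @param genes tibble with `gene_id`, `contig_id`, `start`, `end`, `strand`,
#'   `nuc`, `prot`, `valid`, `note`.
#' @return an `agios_genome` object.
#' @export
new_genome <- function(genome_id, contigs, genes) {
  stopifnot(is.character(genome_id), length(genome_id) == 1)
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id in genome ", genome_id, call. = FALSE)
  }
  src <- if (nrow(contigs) > 0) contigs$seq else genes$nuc
  comp <- if (length(src) > 0) gc_stats(src) else
    tibble(total_bp = 0L, gc_bp = 0L, gc_pct = NA_real_)
  structure(
    list(genome_id = genome_id, contigs = contigs, genes = genes,
         total_bp = comp$total_bp, gc_bp = comp$gc_bp),
    class = "agios_genome"
  )
}

#' Load an annotated genome
#'
#' Exactly one gene source applies: a GFF3 with CDS features (coordinates
#' 1-based inclusive, converted internally; minus-strand CDS
#' reverse-complemented), a CDS FASTA (no coordinates -- `start`/`end` are
#' `NA`), or, when neither is given, the naive six-frame ORF finder
#' [find_orfs()] as a fallback. The fallback is plumbing for un-annotated
#' input, not a gene caller of annotation quality.
#'
#' @param fasta genome FASTA path (may be `NULL` if `cds_fasta` is given;
#'   composition is then computed over the CDS set).
#' @param gff optional GFF3 path; CDS features are used, `ID` attribute as
#'   `gene_id`.
#' @param cds_fasta optional FASTA of CDS nucleotide sequences.
#' @param genome_id identifier; defaults to the FASTA basename.
#' @param min_orf_nt minimum ORF length for the fallback finder.
#' @param n_run_exclude ORFs overlapping a run of at least this many `N`s are
#'   excluded by the fallback finder (assembly-gap proxy); `Inf` disables.
#' @return an `agios_genome`.
#' @export
load_genome <- function(fasta, gff = NULL, cds_fasta = NULL, genome_id = NULL,
                        min_orf_nt = 300, n_run_exclude = 10) {
  if (!is.null(gff) && !is.null(cds_fasta)) {
    stop("supply at most one of gff / cds_fasta", call. = FALSE)
  }
  contigs <- if (!is.null(fasta)) read_fasta(fasta, "dna") else
    tibble(id = character(), seq = character())
  genome_id <- genome_id %||%
    sub("\\.(fa|fasta|fna)$", "", basename(fasta %||% cds_fasta))

  if (!is.null(gff)) {
    genes <- genes_from_gff(contigs, gff)
  } else if (!is.null(cds_fasta)) {
    cds <- read_fasta(cds_fasta, "dna")
    genes <- purrr::pmap_dfr(cds, function(id, seq) {
      gene_row(id, NA_character_, NA_integer_, NA_integer_, "+", seq)
    })
  } else {
    if (nrow(contigs) == 0) stop("no gene source supplied", call. = FALSE)
    genes <- purrr::pmap_dfr(contigs, function(id, seq) {
      find_orfs(seq, min_nt = min_orf_nt, contig_id = id,
                n_run_exclude = n_run_exclude)
    })
  }
  new_genome(genome_id, contigs, genes)
}

# build one gene row, translating and flagging invalid CDS
gene_row <- function(gene_id, contig_id, start, end, strand, nuc) {
  valid <- TRUE; note <- NA_character_; prot <- NA_character_
  if (nchar(nuc) %% 3 != 0) {
    valid <- FALSE
    note <- "length not divisible by 3"
    warning("gene ", gene_id, ": CDS length not divisible by 3; flagged",
            call. = FALSE)
  } else {
    prot <- tryCatch(translate_cds(nuc), error = function(e) {
      valid <<- FALSE
      note <<- conditionMessage(e)
      NA_character_
    })
  }
  tibble(gene_id = gene_id, contig_id = contig_id,
         start = as.integer(start), end = as.integer(end), strand = strand,
         nuc = nuc, prot = prot, valid = valid, note = note)
}

genes_from_gff <- function(contigs, gff) {
  gr <- rtracklayer::import(gff, format = "gff3")
  gr <- gr[tolower(as.character(gr$type)) == "cds"]
  if (length(gr) == 0) return(empty_gene_tbl())
  ids <- as.character(gr$ID)
  if (all(is.na(ids))) ids <- paste0("cds", seq_along(gr))
  clen <- stats::setNames(nchar(contigs$seq), contigs$id)
  purrr::map_dfr(seq_along(gr), function(i) {
    contig_id <- as.character(GenomicRanges::seqnames(gr))[i]
    if (!contig_id %in% names(clen)) {
      stop("GFF CDS ", ids[i], " references unknown contig ", contig_id,
           call. = FALSE)
    }
    s1 <- GenomicRanges::start(gr)[i]   # 1-based inclusive
    e1 <- GenomicRanges::end(gr)[i]
    if (s1 < 1 || e1 > clen[[contig_id]]) {
      stop("GFF CDS ", ids[i], " (", s1, "..", e1,
           ") outside contig ", contig_id, " bounds", call. = FALSE)
    }
    start <- s1 - 1L                    # 0-based half-open
    end <- e1
    strand <- as.character(GenomicRanges::strand(gr))[i]
    if (!strand %in% c("+", "-")) strand <- "+"
    nuc <- substr(contigs$seq[contigs$id == contig_id], s1, e1)
    if (strand == "-") nuc <- reverse_complement(nuc)
    gene_row(ids[i], contig_id, start, end, strand, nuc)
  })
}

#' Naive six-frame ORF finder
#'
#' Plumbing for genomes supplied without annotation (explicitly not a gene
#' caller of Prodigal quality). In each of the six frames an ORF runs from
#' the first start codon (`ATG`/`GTG`/`TTG`) following a stop (or the frame
#' start) to the next in-frame stop, stop codon included. ORFs shorter than
#' `min_nt` are discarded; same-strand overlaps are resolved by keeping the
#' longer ORF (ties: leftmost). ORFs overlapping a run of `n_run_exclude` or
#' more `N`s are dropped as likely assembly gaps.
#'
#' @param contig a nucleotide string (or one-row tibble with `seq`).
#' @param min_nt minimum ORF length in nt; must be `>= 6` and divisible by 3.
#' @param contig_id contig identifier used in gene ids.
#' @param n_run_exclude minimum `N`-run length that disqualifies an ORF.
#' @return a gene tibble (possibly zero rows) as in [new_genome()].
#' @export
find_orfs <- function(contig, min_nt = 300, contig_id = "contig",
                      n_run_exclude = 10) {
  if (is.data.frame(contig)) contig <- contig$seq[1]
  stopifnot(min_nt >= 6, min_nt %% 3 == 0)
  contig <- normalize_nuc(contig)
  L <- nchar(contig)
  stops <- c("TAA", "TAG", "TGA")
  starts <- c("ATG", "GTG", "TTG")

  scan_strand <- function(s, strand) {
    hits <- list()
    for (frame in 0:2) {
      n_cod <- (nchar(s) - frame) %/% 3
      if (n_cod < 2) next
      pos <- frame + seq(1, by = 3, length.out = n_cod)
      codons <- substring(s, pos, pos + 2)
      open_at <- NA_integer_  # codon index of current ORF start
      seen_stop <- TRUE       # frame start counts as after-a-stop
      for (k in seq_len(n_cod)) {
        cd <- codons[k]
        if (cd %in% stops) {
          if (!is.na(open_at)) {
            hits[[length(hits) + 1]] <-
              c(start = pos[open_at] - 1L, end = pos[k] + 2L)  # 0-based h.o.
          }
          open_at <- NA_integer_
          seen_stop <- TRUE
        } else if (is.na(open_at) && seen_stop && cd %in% starts) {
          open_at <- k
          seen_stop <- FALSE
        }
      }
    }
    if (length(hits) == 0) return(NULL)
    df <- as.data.frame(do.call(rbind, hits))
    df$strand <- strand
    df
  }

  fwd <- scan_strand(contig, "+")
  rev_ <- scan_strand(reverse_complement(contig), "-")
  if (!is.null(rev_)) {
    # map reverse-strand coordinates back to the forward axis
    tmp <- L - rev_$end
    rev_$end <- L - rev_$start
    rev_$start <- tmp
  }
  orfs <- rbind(fwd, rev_)
  if (is.null(orfs) || nrow(orfs) == 0) return(empty_gene_tbl())
  orfs$len <- orfs$end - orfs$start
  orfs <- orfs[orfs$len >= min_nt, , drop = FALSE]
  if (nrow(orfs) == 0) return(empty_gene_tbl())

  # drop ORFs spanning long N runs (assembly-gap proxy)
  if (is.finite(n_run_exclude)) {
    runs <- gregexpr(sprintf("N{%d,}", n_run_exclude), contig)[[1]]
    if (runs[1] != -1) {
      r_start <- as.integer(runs) - 1L
      r_end <- r_start + attr(runs, "match.length")
      keep <- vapply(seq_len(nrow(orfs)), function(i) {
        !any(orfs$start[i] < r_end & r_start < orfs$end[i])
      }, logical(1))
      orfs <- orfs[keep, , drop = FALSE]
    }
  }
  if (nrow(orfs) == 0) return(empty_gene_tbl())

  # same-strand overlap: keep the longer, ties leftmost
  resolve <- function(df) {
    df <- df[order(-df$len, df$start), , drop = FALSE]
    kept <- df[0, ]
    for (i in seq_len(nrow(df))) {
      if (!any(df$start[i] < kept$end & kept$start < df$end[i])) {
        kept <- rbind(kept, df[i, ])
      }
    }
    kept
  }
  orfs <- do.call(rbind, lapply(split(orfs, orfs$strand), resolve))
  orfs <- orfs[order(orfs$start, orfs$strand), , drop = FALSE]

  purrr::map_dfr(seq_len(nrow(orfs)), function(i) {
    nuc <- substr(contig, orfs$start[i] + 1, orfs$end[i])
    if (orfs$strand[i] == "-") nuc <- reverse_complement(nuc)
    gene_row(sprintf("%s_orf%03d", contig_id, i), contig_id,
             orfs$start[i], orfs$end[i], orfs$strand[i], nuc)
  })
}

empty_gene_tbl <- function() {
  tibble(gene_id = character(), contig_id = character(), start = integer(),
         end = integer(), strand = character(), nuc = character(),
         prot = character(), valid = logical(), note = character())
}

#' Valid protein-coding genes of a genome
#'
#' Genes that translate cleanly (frame-complete, no internal stop): the set
#' AGIOS compares and the count reported on the comparison-matrix diagonal.
#'
#' @param genome an `agios_genome`.
#' @return the gene tibble restricted to valid genes.
#' @export
valid_genes <- function(genome) {
  stopifnot(inherits(genome, "agios_genome"))
  dplyr::filter(genome$genes, .data$valid)
}

#' @export
print.agios_genome <- function(x, ...) {
  cat("<agios_genome> ", x$genome_id, "\n",
      "  contigs: ", nrow(x$contigs), "  total_bp: ", x$total_bp,
      "  G+C: ", pct_of(x$gc_bp, max(x$total_bp, 1)), "%\n",
      "  genes: ", nrow(x$genes), " (", sum(x$genes$valid), " valid)\n",
      sep = "")
  invisible(x)
}

#' @describeIn new_genome gene table of a genome as a tibble.
#' @param x an `agios_genome`.
#' @param ... unused.
#' @method tidy agios_genome
#' @export
tidy.agios_genome <- function(x, ...) x$genes

#' @describeIn new_genome one-row genome summary (id, contig count, size,
#'   G+C, gene counts).
#' @method glance agios_genome
#' @export
glance.agios_genome <- function(x, ...) {
  tibble(genome_id = x$genome_id, n_contigs = nrow(x$contigs),
         total_bp = x$total_bp, gc_bp = x$gc_bp,
         gc_pct = pct_of(x$gc_bp, max(x$total_bp, 1)),
         n_genes = nrow(x$genes), n_valid_genes = sum(x$genes$valid))
}
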