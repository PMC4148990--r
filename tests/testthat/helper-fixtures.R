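# Published annotation figures for Gorillibacterium massiliense strain G5
# (genome CBQR000000000), used as golden inputs for the stats calculators.

gmassiliense_counts <- list(
  genome_size_bp = 5546433, gc_bp = 2794611, coding_bp = 4888209,
  total_genes = 5221, rna_genes = 76, protein_coding_genes = 5145,
  genes_with_function = 3865, genes_in_cogs = 3881,
  n_orfans = 272, n_hypothetical = 680
)

# 26-row COG category counts (letters + unassigned "-")
gmassiliense_cog_counts <- c(
  J = 201, A = 0, K = 483, L = 166, B = 1, D = 43, Y = 0, V = 119, T = 313,
  M = 205, N = 73, Z = 5, W = 0, U = 50, O = 121, C = 180, G = 560, E = 355,
  F = 93, H = 130, I = 108, P = 248, Q = 113, R = 648, S = 328, `-` = 1264
)

# published percentages, same order as cog_categories()
gmassiliense_cog_pcts <- c(
  J = 3.91, A = 0, K = 9.39, L = 3.23, B = 0.02, D = 0.84, Y = 0, V = 2.31,
  T = 6.08, M = 3.98, N = 1.42, Z = 0.10, W = 0, U = 0.97, O = 2.35,
  C = 3.50, G = 10.88, E = 6.90, F = 1.81, H = 2.53, I = 2.10, P = 4.82,
  Q = 2.20, R = 12.59, S = 6.38, `-` = 24.57
)

# sequencing-run arithmetic: 142.7 Mb over 387,157 passed-filter reads
gmassiliense_run <- list(total_mb = 142.7, n_reads = 387157,
                         mean_read_len_bp = 369)

# tiny two-gene genome written to disk as FASTA + GFF3; gene2 on the minus
# strand; returns list(fasta, gff, genome expectations)
write_tiny_genome <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  # contig: spacer + gene1(+) + spacer + rc(gene2) + spacer
  gene1 <- "ATGAAATTTGGGTAA"             # MKFG
  gene2 <- "ATGCCCGGGAAATAG"             # MPGK
  contig <- paste0("TTTTT", gene1, "AAAAA", reverse_complement(gene2),
                   "CCCCC")
  fa <- file.path(dir, "tiny.fasta")
  writeLines(c(">c1", contig), fa)
  gff <- file.path(dir, "tiny.gff3")
  writeLines(c(
    "##gff-version 3",
    sprintf("c1\ttest\tCDS\t%d\t%d\t.\t+\t0\tID=gene1", 6, 5 + nchar(gene1)),
    sprintf("c1\ttest\tCDS\t%d\t%d\t.\t-\t0\tID=gene2",
            5 + nchar(gene1) + 5 + 1,
            5 + nchar(gene1) + 5 + nchar(gene2))
  ), gff)
  list(fasta = fa, gff = gff, contig = contig, gene1 = gene1, gene2 = gene2)
}

# gene table wrapping bare protein sequences (nucleotide field is a dummy of
# matching codon count; only the protein stage reads it in these tests)
fake_genes <- function(prots) {
  tibble::tibble(
    gene_id = prots$id, contig_id = NA_character_,
    start = NA_integer_, end = NA_integer_, strand = "+",
    nuc = strrep("ACG", nchar(prots$seq)), prot = prots$seq,
    valid = TRUE, note = NA_character_
  )
}

empty_gene_tbl_for_tests <- function() agios:::empty_gene_tbl()

`%||%` <- function(a, b) if (is.null(a)) b else a
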