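#' The 25 COG functional categories
#'
#' Single-letter Clusters of Orthologous Groups categories in the canonical
#' reporting order, plus the `-` row for genes not assigned to any COG.
#'
#' @return tibble with `code` and `description`, 26 rows.
#' @export
cog_categories <- function() {
  tibble(
    code = c("J", "A", "K", "L", "B", "D", "Y", "V", "T", "M", "N", "Z",
             "W", "U", "O", "C", "G", "E", "F", "H", "I", "P", "Q", "R",
             "S", "-"),
    description = c(
      "Translation, ribosomal structure and biogenesis",
      "RNA processing and modification",
      "Transcription",
      "Replication, recombination and repair",
      "Chromatin structure and dynamics",
      "Cell cycle control, mitosis and meiosis",
      "Nuclear structure",
      "Defense mechanisms",
      "Signal transduction mechanisms",
      "Cell wall/membrane biogenesis",
      "Cell motility",
      "Cytoskeleton",
      "Extracellular structures",
      "Intracellular trafficking and secretion",
      "Posttranslational modification, protein turnover, chaperones",
      "Energy production and conversion",
      "Carbohydrate transport and metabolism",
      "Amino acid transport and metabolism",
      "Nucleotide transport and metabolism",
      "Coenzyme transport and metabolism",
      "Lipid transport and metabolism",
      "Inorganic ion transport and metabolism",
      "Secondary metabolites biosynthesis, transport and catabolism",
      "General function prediction only",
      "Function unknown",
      "Not in COGs"
    )
  )
}

gene_class_vocab <- c("protein_coding", "rRNA_16S", "rRNA_23S", "rRNA_5S",
                      "tRNA")

#' Annotation summary from counts
#'
#' Builds the conventional nucleotide-content / gene-count summary table from
#' raw counts. All percentages are `100 * count / denominator` rounded
#' half-up to 2 decimals: base-pair rows are relative to the genome size,
#' gene-class rows to the total gene count, and the function / COG / ORFan /
#' hypothetical rows to the protein-coding gene count.
#'
#' @param genome_size_bp,gc_bp,coding_bp base-pair counts.
#' @param total_genes,rna_genes,protein_coding_genes gene counts
#'   (`total = rna + protein_coding` is enforced).
#' @param genes_with_function,genes_in_cogs,n_orfans,n_hypothetical optional
#'   protein-coding subsets (`NA` rows are omitted).
#' @return tibble with `attribute`, `value`, `pct_of_total`.
#' @export
#' @examples
#' annotation_summary(5546433, 2794611, 4888209, 5221, 76, 5145,
#'                    genes_with_function = 3865, genes_in_cogs = 3881,
#'                    n_orfans = 272, n_hypothetical = 680)
annotation_summary <- function(genome_size_bp, gc_bp, coding_bp,
                               total_genes, rna_genes, protein_coding_genes,
                               genes_with_function = NA,
                               genes_in_cogs = NA,
                               n_orfans = NA, n_hypothetical = NA) {
  if (total_genes != rna_genes + protein_coding_genes) {
    stop("total_genes must equal rna_genes + protein_coding_genes",
         call. = FALSE)
  }
  if (coding_bp > genome_size_bp) {
    stop("coding_bp exceeds genome size", call. = FALSE)
  }
  rows <- tibble(
    attribute = c("Genome size (bp)", "DNA G+C content (bp)",
                  "DNA coding region (bp)", "Total genes", "RNA genes",
                  "Protein-coding genes", "Genes with function prediction",
                  "Genes assigned to COGs", "ORFan genes",
                  "Hypothetical proteins"),
    value = c(genome_size_bp, gc_bp, coding_bp, total_genes, rna_genes,
              protein_coding_genes, genes_with_function, genes_in_cogs,
              n_orfans, n_hypothetical),
    denom = c(genome_size_bp, genome_size_bp, genome_size_bp, total_genes,
              total_genes, total_genes, rep(protein_coding_genes, 4))
  )
  rows %>%
    dplyr::filter(!is.na(.data$value)) %>%
    dplyr::mutate(pct_of_total = pct_of(.data$value, .data$denom)) %>%
    dplyr::select("attribute", "value", "pct_of_total")
}

#' Annotation summary of a genome
#'
#' Computes the counts behind [annotation_summary()] from a genome, per-gene
#' class labels and coding intervals. The coding base-pair count is the
#' length of the union of the coding intervals (overlaps merged before
#' summing).
#'
#' @param genome an `agios_genome`.
#' @param gene_classes tibble with `gene_id`, `class`; classes must come from
#'   `protein_coding`, `rRNA_16S`, `rRNA_23S`, `rRNA_5S`, `tRNA`.
#' @param coding_intervals tibble with `start`, `end` (0-based half-open, on
#'   genome coordinates); `NULL` derives them from gene coordinates.
#' @param genes_with_function,genes_in_cogs,n_orfans,n_hypothetical optional
#'   counts passed through.
#' @return tibble as in [annotation_summary()].
#' @export
summarize_annotation <- function(genome, gene_classes,
                                 coding_intervals = NULL,
                                 genes_with_function = NA,
                                 genes_in_cogs = NA, n_orfans = NA,
                                 n_hypothetical = NA) {
  bad <- setdiff(unique(gene_classes$class), gene_class_vocab)
  if (length(bad) > 0) {
    stop("unknown gene class label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(coding_intervals)) {
    g <- dplyr::filter(genome$genes, !is.na(.data$start))
    coding_intervals <- tibble(start = g$start, end = g$end)
  }
  coding_bp <- if (nrow(coding_intervals) == 0) 0L else {
    ir <- IRanges::reduce(IRanges::IRanges(start = coding_intervals$start + 1L,
                                           end = coding_intervals$end))
    sum(IRanges::width(ir))
  }
  n_prot <- sum(gene_classes$class == "protein_coding")
  n_rna <- sum(gene_classes$class != "protein_coding")
  annotation_summary(
    genome_size_bp = genome$total_bp, gc_bp = genome$gc_bp,
    coding_bp = coding_bp, total_genes = nrow(gene_classes),
    rna_genes = n_rna, protein_coding_genes = n_prot,
    genes_with_function = genes_with_function,
    genes_in_cogs = genes_in_cogs, n_orfans = n_orfans,
    n_hypothetical = n_hypothetical
  )
}

#' COG functional-category table
#'
#' Tabulates per-gene COG assignments into the 26-row category table. A gene
#' with several category letters increments each of them (so lettered counts
#' may sum to more than the gene count); genes with no assignment fall under
#' `-`. The percentage denominator is the protein-coding gene count.
#'
#' @param assignments tibble with `gene_id` and `codes` (comma-joined
#'   category letters, empty string or `NA` for unassigned). Genes absent
#'   from the table count as unassigned only if listed; pass every
#'   protein-coding gene for a complete `-` row.
#' @param n_protein_coding denominator for the percentages.
#' @return tibble with `code`, `count`, `pct`, `description`.
#' @export
cog_table <- function(assignments, n_protein_coding) {
  cats <- cog_categories()
  letters_only <- setdiff(cats$code, "-")
  codes <- strsplit(ifelse(is.na(assignments$codes), "",
                           assignments$codes), ",")
  codes <- lapply(codes, function(x) unique(trimws(x[nzchar(trimws(x))])))
  bad <- setdiff(unlist(codes), letters_only)
  if (length(bad) > 0) {
    stop("unknown COG code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  counts <- table(factor(unlist(codes), levels = letters_only))
  n_unassigned <- sum(lengths(codes) == 0)
  cog_table_from_counts(
    stats::setNames(c(as.integer(counts), n_unassigned), cats$code),
    n_protein_coding
  )
}

#' @describeIn cog_table build the table from precomputed per-category counts
#'   (named integer vector over the 26 codes; missing codes count 0).
#' @param counts named integer vector of per-category counts.
#' @export
cog_table_from_counts <- function(counts, n_protein_coding) {
  cats <- cog_categories()
  bad <- setdiff(names(counts), cats$code)
  if (length(bad) > 0) {
    stop("unknown COG code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  full <- stats::setNames(rep(0L, nrow(cats)), cats$code)
  full[names(counts)] <- as.integer(counts)
  tibble(code = cats$code, count = unname(full),
         pct = pct_of(unname(full), n_protein_coding),
         description = cats$description)
}

#' Classify genes as ORFans from a homology-hit table
#'
#' A gene is an ORFan when it has no qualifying database hit: long
#' alignments (more than `len_cut_aa` amino acids) qualify at E-value below
#' `e_long`, shorter alignments only at the stricter `e_short`. Genes with no
#' hits at all are ORFans by definition. The boundary length `len_cut_aa`
#' itself falls in the stricter short tier.
#'
#' @param hits tibble with `gene_id`, `subject_id`, `e_value`, `aln_len_aa`
#'   (possibly zero rows per gene).
#' @param gene_ids the full gene universe; genes without any hit row are
#'   classified too. Defaults to the genes present in `hits`.
#' @param e_long,e_short E-value thresholds for the two length tiers.
#' @param len_cut_aa alignment-length cut separating the tiers (aa).
#' @return tibble with `gene_id`, `class` (`"ORFan"` or `"known"`).
#' @export
classify_orfans <- function(hits, gene_ids = NULL, e_long = 1e-3,
                            e_short = 1e-5, len_cut_aa = 80) {
  if (any(hits$e_value <= 0)) stop("e_value must be positive", call. = FALSE)
  gene_ids <- gene_ids %||% unique(hits$gene_id)
  qual <- hits %>%
    dplyr::filter((.data$aln_len_aa > len_cut_aa & .data$e_value < e_long) |
                    (.data$aln_len_aa <= len_cut_aa & .data$e_value < e_short))
  tibble(gene_id = gene_ids,
         class = ifelse(gene_ids %in% qual$gene_id, "known", "ORFan"))
}

#' Taxonomic rank call from 16S rRNA identity
#'
#' Applies the conventional 16S identity thresholds: below the genus
#' threshold (95.0%, Stackebrandt & Ebers) the isolate is a new-genus
#' candidate; between genus and species thresholds (species default 98.7%) a
#' new-species candidate; at or above the species threshold a same-species
#' candidate. Boundaries are inclusive upward (exactly 95.0 is
#' new-species-candidate).
#'
#' @param identity_pct percent identity in `[0, 100]`.
#' @param nearest_taxon optional name of the closest validly published taxon.
#' @param genus_threshold,species_threshold percent thresholds.
#' @return one-row tibble with `identity_pct`, `nearest_taxon`, `call`.
#' @export
#' @examples
#' delineate_rank(93.72, "Paenibacillus turicensis")
delineate_rank <- function(identity_pct, nearest_taxon = NA_character_,
                           genus_threshold = 95.0,
                           species_threshold = 98.7) {
  if (identity_pct < 0 || identity_pct > 100) {
    stop("identity_pct out of [0, 100]", call. = FALSE)
  }
  call <- if (identity_pct < genus_threshold) "new-genus-candidate"
  else if (identity_pct < species_threshold) "new-species-candidate"
  else "same-species-candidate"
  tibble(identity_pct = identity_pct, nearest_taxon = nearest_taxon,
         call = call)
}

#' 16S rRNA percent identity with auto-orientation
#'
#' Global-alignment identity between two small-subunit rRNA sequences under
#' the default nucleotide scheme. The second sequence is tried on both
#' strands and the higher identity kept, so reverse-complemented inputs give
#' the same answer. A sanity warning is emitted outside the typical 16S
#' length range (1,200-1,800 nt).
#'
#' @param a,b nucleotide strings.
#' @param scheme nucleotide [scoring_scheme()].
#' @return percent identity.
#' @export
sixteen_s_identity <- function(a, b, scheme = nucleotide_scheme()) {
  if (is.data.frame(a)) a <- a$seq[1]
  if (is.data.frame(b)) b <- b$seq[1]
  lens <- nchar(c(a, b))
  if (any(lens < 1200 | lens > 1800)) {
    warning("sequence length outside the typical 16S range (1,200-1,800 nt)",
            call. = FALSE)
  }
  max(identity_between(a, b, scheme),
      identity_between(a, reverse_complement(b), scheme))
}
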