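test_that("annotation summary reproduces every published percentage", {
  cc <- gmassiliense_counts
  s <- annotation_summary(cc$genome_size_bp, cc$gc_bp, cc$coding_bp,
                          cc$total_genes, cc$rna_genes,
                          cc$protein_coding_genes,
                          cc$genes_with_function, cc$genes_in_cogs,
                          cc$n_orfans, cc$n_hypothetical)
  pct <- stats::setNames(s$pct_of_total, s$attribute)
  expect_equal(pct[["Genome size (bp)"]], 100)
  expect_equal(pct[["DNA G+C content (bp)"]], 50.39)
  expect_equal(pct[["DNA coding region (bp)"]], 88.13)
  expect_equal(pct[["Total genes"]], 100)
  expect_equal(pct[["RNA genes"]], 1.46)
  expect_equal(pct[["Protein-coding genes"]], 98.54)
  expect_equal(pct[["Genes with function prediction"]], 75.12)
  expect_equal(pct[["Genes assigned to COGs"]], 75.43)
  expect_equal(pct[["ORFan genes"]], 5.29)
  expect_equal(pct[["Hypothetical proteins"]], 13.22)
})

test_that("annotation summary is self-consistent under re-computation", {
  cc <- gmassiliense_counts
  s <- annotation_summary(cc$genome_size_bp, cc$gc_bp, cc$coding_bp,
                          cc$total_genes, cc$rna_genes,
                          cc$protein_coding_genes,
                          cc$genes_with_function, cc$genes_in_cogs,
                          cc$n_orfans, cc$n_hypothetical)
  denoms <- c(rep(cc$genome_size_bp, 3), rep(cc$total_genes, 3),
              rep(cc$protein_coding_genes, 4))
  expect_equal(s$pct_of_total, pct_of(s$value, denoms))
  expect_error(annotation_summary(100, 50, 40, 10, 3, 5), "must equal")
  expect_error(annotation_summary(100, 50, 400, 10, 3, 7), "exceeds")
})

test_that("coding bp is the merged-interval union", {
  g <- new_genome("G", tibble::tibble(id = "c1", seq = strrep("ACGT", 250)),
                  empty_gene_tbl_for_tests())
  classes <- tibble::tibble(gene_id = c("a", "b"),
                            class = c("protein_coding", "protein_coding"))
  s <- summarize_annotation(g, classes,
                            coding_intervals = tibble::tibble(
                              start = c(0, 50), end = c(100, 150)))
  expect_equal(s$value[s$attribute == "DNA coding region (bp)"], 150)
  expect_equal(s$pct_of_total[s$attribute == "DNA coding region (bp)"], 15)
  expect_error(
    summarize_annotation(g, tibble::tibble(gene_id = "a", class = "nonsense")),
    "unknown gene class")
})

test_that("COG table reproduces all 26 published rows", {
  tb <- cog_table_from_counts(gmassiliense_cog_counts,
                              gmassiliense_counts$protein_coding_genes)
  expect_equal(tb$code, names(gmassiliense_cog_pcts))
  expect_equal(tb$count, unname(gmassiliense_cog_counts))
  expect_equal(tb$pct, unname(gmassiliense_cog_pcts))
  # spot anchors
  expect_equal(tb$pct[tb$code == "G"], 10.88)
  expect_equal(tb$pct[tb$code == "-"], 24.57)
  expect_equal(tb$description[tb$code == "G"],
               "Carbohydrate transport and metabolism")
})

test_that("cog_table counts multi-category genes in each category", {
  asg <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                        codes = c("G,E", "G", NA))
  tb <- cog_table(asg, 3)
  expect_equal(tb$count[tb$code == "G"], 2)
  expect_equal(tb$count[tb$code == "E"], 1)
  expect_equal(tb$count[tb$code == "-"], 1)
  expect_equal(sum(tb$count), 4)  # 3 genes, one counted twice
  expect_error(cog_table(tibble::tibble(gene_id = "g", codes = "G,@"), 1),
               "unknown COG")
  # empty assignments: everything under "-"
  tb0 <- cog_table(tibble::tibble(gene_id = paste0("g", 1:10),
                                  codes = NA_character_), 10)
  expect_equal(tb0$count[tb0$code == "-"], 10)
  expect_equal(sum(tb0$count[tb0$code != "-"]), 0)
})

test_that("ORFan rule: two-tier E-value thresholds, no-hit genes are ORFans", {
  hits <- tibble::tibble(
    gene_id = c("long_ok", "short_weak", "short_ok"),
    subject_id = "s",
    e_value = c(1e-4, 1e-4, 1e-6),
    aln_len_aa = c(100, 50, 50)
  )
  out <- classify_orfans(hits, gene_ids = c("long_ok", "short_weak",
                                            "short_ok", "nohit"))
  cls <- stats::setNames(out$class, out$gene_id)
  expect_equal(cls[["long_ok"]], "known")     # >80 aa at E < 1e-3
  expect_equal(cls[["short_weak"]], "ORFan")  # <=80 aa needs E < 1e-5
  expect_equal(cls[["short_ok"]], "known")
  expect_equal(cls[["nohit"]], "ORFan")
  # boundary length 80 falls in the strict tier
  b <- classify_orfans(tibble::tibble(gene_id = "b", subject_id = "s",
                                      e_value = 1e-4, aln_len_aa = 80))
  expect_equal(b$class, "ORFan")
})

test_that("classify_orfans is monotone: adding a hit never creates an ORFan", {
  withr::local_seed(83)
  for (r in 1:20) {
    n <- sample(1:5, 1)
    hits <- tibble::tibble(
      gene_id = "g",
      subject_id = paste0("s", seq_len(n)),
      e_value = 10^runif(n, -8, 0),
      aln_len_aa = sample(20:200, n, replace = TRUE)
    )
    before <- classify_orfans(hits)$class
    extra <- dplyr::bind_rows(hits, tibble::tibble(
      gene_id = "g", subject_id = "new", e_value = 10^runif(1, -8, 0),
      aln_len_aa = sample(20:200, 1)))
    after <- classify_orfans(extra)$class
    if (before == "known") expect_equal(after, "known")
  }
})

test_that("rank delineation matches the strain G5 decision and boundaries", {
  expect_equal(delineate_rank(93.72)$call, "new-genus-candidate")
  expect_equal(delineate_rank(95.0)$call, "new-species-candidate")
  expect_equal(delineate_rank(98.7)$call, "same-species-candidate")
  expect_equal(delineate_rank(100)$call, "same-species-candidate")
  expect_equal(delineate_rank(94.99)$call, "new-genus-candidate")
  expect_error(delineate_rank(101), "out of")
  rc <- delineate_rank(93.72, "Paenibacillus turicensis")
  expect_equal(rc$nearest_taxon, "Paenibacillus turicensis")
})

test_that("16S identity: planted substitutions and strand auto-orientation", {
  withr::local_seed(89)
  s <- random_nuc(1500)
  expect_equal(sixteen_s_identity(s, s), 100)

  ch <- strsplit(s, "")[[1]]
  pos <- sample(1500, 5)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  s5 <- paste(ch, collapse = "")
  id <- sixteen_s_identity(s, s5)
  expect_equal(id, 100 * 1495 / 1500)           # 99.67 at 2 dp
  expect_equal(round_half_up(id, 2), 99.67)
  # reverse-complemented query: auto-orientation recovers the same identity
  expect_equal(sixteen_s_identity(s, reverse_complement(s5)), id)
  expect_warning(sixteen_s_identity(random_nuc(600), random_nuc(600)),
                 "16S range")
})
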