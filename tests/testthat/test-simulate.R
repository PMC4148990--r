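test_that("generation is deterministic in the seed", {
  p <- evolution_params(n_genes = 10, seed = 1)
  a1 <- generate_ancestor(p)
  a2 <- generate_ancestor(p)
  expect_identical(a1$contigs$seq, a2$contigs$seq)
  expect_identical(a1$genes$nuc, a2$genes$nuc)
  e1 <- evolve_pair(a1, p)
  e2 <- evolve_pair(a2, p)
  expect_identical(e1$derived$contigs$seq, e2$derived$contigs$seq)
  expect_identical(e1$truth, e2$truth)
  # a different seed changes the output
  p2 <- evolution_params(n_genes = 10, seed = 2)
  expect_false(identical(generate_ancestor(p2)$contigs$seq, a1$contigs$seq))
})

test_that("parameter validation rejects infeasible settings", {
  expect_error(evolution_params(n_genes = 0))
  expect_error(evolution_params(gene_len_range = c(6, 6)))
  expect_error(evolution_params(gene_len_range = c(10, 12)))  # not codon-mult
  expect_error(evolution_params(sub_rate = 1))
})

test_that("generated genes are well-formed CDS at the target composition", {
  p <- evolution_params(n_genes = 100, gene_len_range = c(900, 900),
                        gc_target = 0.5, seed = 97)
  g <- generate_ancestor(p)
  genes <- tidy(g)
  expect_equal(nrow(genes), 100)
  expect_true(all(genes$valid))
  expect_true(all(substr(genes$nuc, 1, 3) == "ATG"))
  expect_true(all(substr(genes$nuc, 898, 900) %in% c("TAA", "TAG", "TGA")))
  # realized GC within 2 percentage points of target at this length
  comp <- gc_stats(genes$nuc)
  expect_lt(abs(comp$gc_pct - 50), 2)
  # coordinates reproduce gene sequences off the contig
  for (i in sample(100, 10)) {
    expect_equal(substr(g$contigs$seq, genes$start[i] + 1, genes$end[i]),
                 genes$nuc[i])
  }
})

test_that("sub_rate 0 leaves retained genes identical with identity 1", {
  p <- evolution_params(n_genes = 10, sub_rate = 0, seed = 103)
  anc <- generate_ancestor(p)
  ev <- evolve_pair(anc, p)
  expect_true(all(ev$truth$realized_subs == 0))
  expect_true(all(ev$truth$expected_identity == 1))
  anc_seqs <- stats::setNames(anc$genes$nuc, anc$genes$gene_id)
  der_seqs <- stats::setNames(ev$derived$genes$nuc, ev$derived$genes$gene_id)
  expect_equal(unname(der_seqs[ev$truth$gene_der]),
               unname(anc_seqs[ev$truth$gene_anc]))
})

test_that("realized substitution fraction concentrates around sub_rate", {
  p <- evolution_params(n_genes = 50, gene_len_range = c(900, 900),
                        sub_rate = 0.05, seed = 107)
  anc <- generate_ancestor(p)
  ev <- evolve_pair(anc, p)
  frac <- ev$truth$realized_subs / ev$truth$len_anc
  se <- sqrt(0.05 * 0.95 / 900) / sqrt(50)
  expect_lt(abs(mean(frac) - 0.05), 3 * se)
  # all derived genes remain translatable (stop re-rolling worked)
  expect_true(all(ev$derived$genes$valid))
})

test_that("realized_subs is re-derivable by alignment for indel-free genes", {
  # at the default 5% divergence the gap-free alignment is optimal, so the
  # differing-column count equals the recorded substitution count exactly
  p <- evolution_params(n_genes = 10, sub_rate = 0.05, seed = 109)
  anc <- generate_ancestor(p)
  ev <- evolve_pair(anc, p)
  anc_seqs <- stats::setNames(anc$genes$nuc, anc$genes$gene_id)
  der_seqs <- stats::setNames(ev$derived$genes$nuc, ev$derived$genes$gene_id)
  for (i in seq_len(nrow(ev$truth))) {
    a <- anc_seqs[[ev$truth$gene_anc[i]]]
    b <- der_seqs[[ev$truth$gene_der[i]]]
    # exact re-derivation: indel-free pairs have equal length, so the
    # substitution count is the site-wise (Hamming) difference
    ham <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_equal(ham, ev$truth$realized_subs[i])
    # the optimal alignment agrees up to rare repeat-induced shifts, which
    # can only trade a mismatch against a (penalised) gap pair
    aln <- global_align(a, b)
    expect_lte(abs((aln$length - aln$n_identical) - ham), 2)
  }
})

test_that("gene loss and gain counts are exact (round half-up)", {
  p <- evolution_params(n_genes = 50, sub_rate = 0.01, loss_frac = 0.2,
                        gain_frac = 0.1, seed = 113)
  anc <- generate_ancestor(p)
  ev <- evolve_pair(anc, p)
  expect_equal(sum(is.na(ev$truth$gene_der)), 10)
  expect_equal(nrow(ev$derived$genes), 50 - 10 + 5)
  # half-up at .5: loss_frac 0.1 of 15 genes -> 2 (1.5 rounds up)
  p2 <- evolution_params(n_genes = 15, loss_frac = 0.1, seed = 113)
  ev2 <- evolve_pair(generate_ancestor(p2), p2)
  expect_equal(sum(is.na(ev2$truth$gene_der)), 2)
})

test_that("expected_identity accessor: arithmetic and lost-gene error", {
  p <- evolution_params(n_genes = 10, sub_rate = 0.05, loss_frac = 0.2,
                        seed = 127)
  anc <- generate_ancestor(p)
  ev <- evolve_pair(anc, p)
  kept <- ev$truth$gene_anc[!is.na(ev$truth$gene_der)][1]
  row <- ev$truth[ev$truth$gene_anc == kept, ]
  expect_equal(expected_identity(ev$truth, kept),
               (row$len_anc - row$realized_subs) / row$len_anc)
  lost <- ev$truth$gene_anc[is.na(ev$truth$gene_der)][1]
  expect_error(expected_identity(ev$truth, lost), "lost")
  expect_error(expected_identity(ev$truth, "nope"), "unknown")
})

test_that("indels are codon-length and the column-trace identity is honoured", {
  p <- evolution_params(n_genes = 20, sub_rate = 0, indel_rate = 1,
                        indel_len = 3, seed = 131)
  anc <- generate_ancestor(p)
  ev <- evolve_pair(anc, p)
  with_indel <- ev$truth[!is.na(ev$truth$indel_type), ]
  expect_gt(nrow(with_indel), 0)
  expect_true(all(with_indel$indel_len_nt %% 3 == 0))
  # derived genes still translate
  expect_true(all(ev$derived$genes$valid))
  # column-trace arithmetic: deletion of L from len N at 0 subs -> (N-L)/N
  dels <- with_indel[with_indel$indel_type == "del", ]
  if (nrow(dels) > 0) {
    expect_equal(dels$expected_identity,
                 (dels$len_anc - dels$indel_len_nt) / dels$len_anc)
  }
  ins <- with_indel[with_indel$indel_type == "ins", ]
  if (nrow(ins) > 0) {
    expect_equal(ins$expected_identity,
                 ins$len_anc / (ins$len_anc + ins$indel_len_nt))
  }
})

test_that("end-to-end: RBH + AGIOS recover truth under moderate divergence", {
  # the toolkit's flagship integration check at a scaled-down size
  p <- evolution_params(n_genes = 15, sub_rate = 0.15, loss_frac = 0.3,
                        seed = 137)
  anc <- generate_ancestor(p)
  ev <- evolve_pair(anc, p)
  os <- reciprocal_best_hits(anc, ev$derived)
  n_true <- sum(!is.na(ev$truth$gene_der))
  truth_map <- stats::setNames(ev$truth$gene_der, ev$truth$gene_anc)
  correct <- sum(truth_map[os$pairs$gene_a] == os$pairs$gene_b, na.rm = TRUE)
  expect_gte(correct / n_true, 0.95)
  res <- agios_pair(anc, ev$derived, os)
  truth_mean <- 100 * mean(ev$truth$expected_identity, na.rm = TRUE)
  expect_lt(abs(res$mean_identity_pct - truth_mean), 1)
})
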