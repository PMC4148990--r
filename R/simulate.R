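# sample() that never falls into the 1:n trap when x has length 1
resample <- function(x, ...) x[sample.int(length(x), ...)]

# run code under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Parameters for the synthetic genome-pair simulator
#'
#' Defines one evolutionary scenario: an ancestor genome of `n_genes` random
#' complete CDS and a derived genome obtained by per-site substitution,
#' codon-length indels, gene loss and gene gain. Defaults are the scenario
#' used throughout the package's validation: 50 genes of 900 nt at balanced
#' (50%) G+C, substitutions only.
#'
#' @param n_genes number of ancestor genes (> 0).
#' @param gene_len_range min/max gene length in nt, multiples of 3, min >= 9
#'   (start codon + >= 1 codon + stop).
#' @param sub_rate per-site substitution probability in `[0, 1)`; the
#'   substituted base is uniform over the three alternatives (no transition
#'   bias).
#' @param indel_rate per-gene probability of one codon-length indel.
#' @param indel_len mean indel length in codons (geometric).
#' @param loss_frac fraction of ancestor genes deleted in the derived genome
#'   (count = fraction times `n_genes`, rounded half-up).
#' @param gain_frac fraction of novel genes appended to the derived genome,
#'   generated independently of the ancestor.
#' @param gc_target target G+C fraction of generated sequence.
#' @param intergenic_len_range min/max intergenic spacer length in nt.
#' @param seed RNG seed; every simulator output is a pure function of these
#'   parameters including the seed.
#' @return an `evolution_params` list.
#' @export
evolution_params <- function(n_genes = 50, gene_len_range = c(900, 900),
                             sub_rate = 0.05, indel_rate = 0, indel_len = 3,
                             loss_frac = 0, gain_frac = 0, gc_target = 0.5,
                             intergenic_len_range = c(50, 200), seed = 1) {
  stopifnot(n_genes >= 1, length(gene_len_range) == 2,
            gene_len_range[1] >= 9, gene_len_range[2] >= gene_len_range[1],
            all(gene_len_range %% 3 == 0),
            sub_rate >= 0, sub_rate < 1, indel_rate >= 0, indel_rate <= 1,
            indel_len >= 1, loss_frac >= 0, loss_frac <= 1,
            gain_frac >= 0, gc_target > 0, gc_target < 1)
  structure(list(n_genes = n_genes, gene_len_range = gene_len_range,
                 sub_rate = sub_rate, indel_rate = indel_rate,
                 indel_len = indel_len, loss_frac = loss_frac,
                 gain_frac = gain_frac, gc_target = gc_target,
                 intergenic_len_range = intergenic_len_range,
                 seed = as.integer(seed)),
            class = "evolution_params")
}

BASES <- c("A", "C", "G", "T")
STOPS <- c("TAA", "TAG", "TGA")

base_probs <- function(gc) c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2,
                             T = (1 - gc) / 2)

# n random non-stop codons at the target composition
random_codons <- function(n, gc) {
  if (n == 0) return(character(0))
  p <- base_probs(gc)
  draw <- function(m) {
    b <- matrix(sample(BASES, 3 * m, replace = TRUE, prob = p), ncol = 3)
    paste0(b[, 1], b[, 2], b[, 3])
  }
  cod <- draw(n)
  while (any(cod %in% STOPS)) {
    i <- which(cod %in% STOPS)
    cod[i] <- draw(length(i))
  }
  cod
}

random_gene <- function(len_nt, gc) {
  paste0("ATG",
         paste(random_codons(len_nt / 3 - 2, gc), collapse = ""),
         resample(STOPS, 1))
}

random_spacer <- function(len, gc) {
  paste(sample(BASES, len, replace = TRUE, prob = base_probs(gc)),
        collapse = "")
}

#' Generate a synthetic ancestor genome
#'
#' `n_genes` random complete CDS (ATG start, no internal stop, terminal
#' stop), placed in order on a single contig separated by random intergenic
#' spacers. Deterministic for a fixed parameter set.
#'
#' @param params an [evolution_params()].
#' @param genome_id identifier for the genome.
#' @return an `agios_genome` with gene coordinates on the single contig.
#' @export
generate_ancestor <- function(params, genome_id = "ancestor") {
  stopifnot(inherits(params, "evolution_params"))
  with_seed(params$seed, {
    lens <- resample(seq(params$gene_len_range[1], params$gene_len_range[2], 3),
                     params$n_genes, replace = TRUE)
    genes_nuc <- vapply(lens, random_gene, character(1), gc = params$gc_target)
    assemble_genome(genes_nuc, params, genome_id, prefix = "g")
  })
}

# lay genes on one contig with spacers; returns an agios_genome
assemble_genome <- function(genes_nuc, params, genome_id, prefix) {
  n <- length(genes_nuc)
  spacers <- vapply(
    resample(seq(params$intergenic_len_range[1], params$intergenic_len_range[2]),
             n + 1, replace = TRUE),
    random_spacer, character(1), gc = params$gc_target)
  pieces <- character(2 * n + 1)
  pieces[seq(1, 2 * n + 1, 2)] <- spacers
  pieces[seq(2, 2 * n, 2)] <- genes_nuc
  contig <- paste(pieces, collapse = "")
  starts <- cumsum(nchar(pieces)) - nchar(pieces)  # 0-based piece starts
  gene_starts <- starts[seq(2, 2 * n, 2)]
  genes <- purrr::map_dfr(seq_len(n), function(i) {
    gene_row(sprintf("%s%04d", prefix, i), paste0(genome_id, "_c1"),
             gene_starts[i], gene_starts[i] + nchar(genes_nuc[i]), "+",
             genes_nuc[i])
  })
  new_genome(genome_id,
             tibble(id = paste0(genome_id, "_c1"), seq = contig), genes)
}

# mutate one CDS site-wise; internal stops created by mutation are re-rolled.
# Returns list(seq, sub_pos): positions (1-based, ancestor coords) differing.
mutate_gene <- function(nuc, sub_rate) {
  chars <- strsplit(nuc, "")[[1]]
  n <- length(chars)
  mut_pos <- which(stats::runif(n) < sub_rate)
  if (length(mut_pos) == 0) return(list(seq = nuc, sub_pos = integer(0)))
  new <- chars
  for (p in mut_pos) {
    new[p] <- resample(setdiff(BASES, chars[p]), 1)
  }
  # re-roll codons that became internal stops
  n_cod <- n / 3
  for (ci in seq_len(n_cod - 1)) {  # terminal codon may be anything
    idx <- (3 * ci - 2):(3 * ci)
    tries <- 0
    while (paste(new[idx], collapse = "") %in% STOPS && tries < 50) {
      for (p in intersect(mut_pos, idx)) {
        new[p] <- resample(setdiff(BASES, chars[p]), 1)
      }
      tries <- tries + 1
    }
    if (paste(new[idx], collapse = "") %in% STOPS) {
      new[idx] <- chars[idx]  # give up: revert the codon
    }
  }
  list(seq = paste(new, collapse = ""),
       sub_pos = which(new != chars))
}

#' Evolve a derived genome from an ancestor, with full truth bookkeeping
#'
#' Each retained ancestor gene is mutated site-wise with probability
#' `sub_rate` (uniform over the three alternative bases; codons that would
#' become internal stops are re-rolled so every derived gene stays
#' translatable), optionally hit by one codon-length indel, then a
#' `loss_frac` fraction of genes is deleted, `gain_frac` novel genes are
#' appended, gene order is shuffled, and the derived genes are re-laid on a
#' fresh contig. The truth record maps ancestor to derived gene ids and
#' carries realized substitution counts, indels, and the expected alignment
#' identity of each pair under an explicit column trace (gap columns count
#' as non-identical, matching the aligner's total-column convention).
#'
#' @param ancestor an `agios_genome` from [generate_ancestor()].
#' @param params the [evolution_params()] (its `seed`, offset by one, drives
#'   this stage).
#' @param genome_id id for the derived genome.
#' @return list with `derived` (an `agios_genome`) and `truth`, a tibble with
#'   `gene_anc`, `gene_der` (`NA` when lost), `len_anc`, `realized_subs`,
#'   `indel_type`, `indel_len_nt`, `indel_pos`, `expected_identity`.
#' @export
evolve_pair <- function(ancestor, params, genome_id = "derived") {
  stopifnot(inherits(ancestor, "agios_genome"),
            inherits(params, "evolution_params"))
  anc <- valid_genes(ancestor)
  n <- nrow(anc)
  with_seed(params$seed + 1L, {
    perm <- sample(n)
    n_loss <- as.integer(round_half_up(params$loss_frac * n, 0))
    lost <- anc$gene_id[perm[seq_len(n_loss)]]

    truth <- purrr::map_dfr(seq_len(n), function(i) {
      gid <- anc$gene_id[i]
      len <- nchar(anc$nuc[i])
      if (gid %in% lost) {
        return(tibble(gene_anc = gid, gene_der = NA_character_,
                      len_anc = len, realized_subs = NA_integer_,
                      indel_type = NA_character_, indel_len_nt = NA_integer_,
                      indel_pos = NA_integer_, expected_identity = NA_real_,
                      der_seq = NA_character_))
      }
      m <- mutate_gene(anc$nuc[i], params$sub_rate)
      seq <- m$seq
      subs <- m$sub_pos
      indel_type <- NA_character_; indel_len_nt <- NA_integer_
      indel_pos <- NA_integer_
      cols <- len
      n_ident <- len - length(subs)
      if (params$indel_rate > 0 && stats::runif(1) < params$indel_rate) {
        L <- 3L * (1L + stats::rgeom(1, 1 / params$indel_len))
        n_cod <- len / 3
        if (n_cod > L / 3 + 2) {
          indel_type <- resample(c("del", "ins"), 1)
          indel_len_nt <- L
          if (indel_type == "del") {
            # delete L nt of whole codons from the interior
            c0 <- resample(2:(n_cod - L / 3), 1)       # first deleted codon
            indel_pos <- as.integer(3 * (c0 - 1))    # 0-based nt offset
            del_sites <- (indel_pos + 1):(indel_pos + L)
            seq <- paste0(substr(seq, 1, indel_pos),
                          substr(seq, indel_pos + L + 1, len))
            # columns: len total, L gap columns; surviving subs non-identical
            n_ident <- len - L - length(setdiff(subs, del_sites))
            cols <- len
          } else {
            c0 <- resample(2:(n_cod - 1), 1)
            indel_pos <- as.integer(3 * (c0 - 1))
            ins <- paste(random_codons(L / 3, params$gc_target), collapse = "")
            seq <- paste0(substr(seq, 1, indel_pos), ins,
                          substr(seq, indel_pos + 1, len))
            cols <- len + L
            n_ident <- len - length(subs)
          }
        }
      }
      tibble(gene_anc = gid, gene_der = NA_character_, len_anc = len,
             realized_subs = length(subs), indel_type = indel_type,
             indel_len_nt = indel_len_nt, indel_pos = indel_pos,
             expected_identity = n_ident / cols, der_seq = seq)
    })

    retained <- truth[!is.na(truth$der_seq), ]
    n_gain <- as.integer(round_half_up(params$gain_frac * n, 0))
    gained <- if (n_gain > 0) {
      lens <- resample(seq(params$gene_len_range[1], params$gene_len_range[2], 3),
                       n_gain, replace = TRUE)
      vapply(lens, random_gene, character(1), gc = params$gc_target)
    } else character(0)

    der_seqs <- c(retained$der_seq, gained)
    ord <- sample(length(der_seqs))
    der_ids <- sprintf("d%04d", seq_along(der_seqs))
    # derived id for each retained ancestor gene after the shuffle
    slot <- match(seq_along(der_seqs), ord)
    truth$gene_der[match(retained$gene_anc, truth$gene_anc)] <-
      der_ids[slot[seq_len(nrow(retained))]]
    derived <- assemble_genome(der_seqs[ord], params, genome_id, prefix = "d")
    list(derived = derived,
         truth = dplyr::select(truth, -"der_seq"))
  })
}

#' Expected alignment identity of a truth-mapped gene
#'
#' For indel-free genes this is `(length - realized_subs) / length`; for
#' genes with an indel it is the identical-column fraction of the
#' truth-constructed column trace.
#'
#' @param truth the truth tibble from [evolve_pair()].
#' @param gene_id an ancestor gene id.
#' @return identity fraction in `[0, 1]`.
#' @export
expected_identity <- function(truth, gene_id) {
  row <- truth[truth$gene_anc == gene_id, ]
  if (nrow(row) == 0) stop("unknown gene: ", gene_id, call. = FALSE)
  if (is.na(row$gene_der)) stop("gene was lost: ", gene_id, call. = FALSE)
  row$expected_identity
}
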