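---
title: "AGIOS: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AGIOS: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agios)
```

## The statistic

AGIOS (Average Genomic Identity of Orthologous gene Sequences) summarises
the relatedness of two annotated prokaryotic genomes in three steps:

1. **Ortholog detection.** Every protein of genome A is globally aligned
   against candidate proteins of genome B (affine-gap Needleman–Wunsch,
   BLOSUM62). A gene pair (a, b) is accepted as orthologous when each is the
   other's best-scoring hit passing minimum identity and coverage thresholds
   — a reciprocal best hit (RBH).
2. **ORF alignment.** For each ortholog pair the *nucleotide* coding
   sequences are globally aligned under a match/mismatch scheme.
3. **Averaging.** The AGIOS value for the genome pair is the unweighted
   arithmetic mean of the per-pair percent identities. Across more than two
   genomes, results are assembled into a comparison matrix whose diagonal
   holds gene counts, upper triangle mean identities, and lower triangle
   ortholog counts.

The statistic is intended for taxono-genomic comparisons in the range where
16S rRNA identity is no longer decisive; it complements, rather than
replaces, ANI-style measures, and it deliberately operates on annotated
gene sequences instead of genome fragments.

## Alignment model

The aligner is a three-state (Gotoh) dynamic programme: states for a match
column, a gap in the second sequence, and a gap in the first. End gaps are
penalised, making the alignment truly global. The defaults mirror the most
widely replicated Needleman–Wunsch parameterisation (EMBOSS needle):

| parameter | nucleotide | protein |
|---|---|---|
| substitution | match +5 / mismatch −4 | BLOSUM62 |
| gap open | 10 | 10 |
| gap extend | 0.5 | 0.5 |

Two conventions needed pinning because they vary between implementations:

* **Gap cost.** A gap run of length $L$ costs $\mathrm{open} + L \cdot
  \mathrm{extend}$. Half-point penalties are handled by doubling all scores
  internally so the dynamic programme stays in exact integer arithmetic;
  reported scores are on that doubled scale (documented on the result
  object).
* **Identity denominator.** `identity_pct` divides the identical-column
  count by *all* alignment columns, gap columns included (the EMBOSS
  "Identity" convention). An ungapped-column denominator is available via
  `denominator = "ungapped"`.

Tie-breaking in the traceback prefers the diagonal move, then a gap in the
second sequence, then a gap in the first, which makes every alignment
deterministic. Because distinct co-optimal alignments can in principle
differ in gap placement, `identity_between()` canonicalises the argument
order before aligning, so identity is exactly symmetric — a property the
AGIOS symmetry invariant relies on. The neutral symbols `N` (nucleotide)
and `X` (protein) score zero against everything and are never counted as
identities.

The correctness reference for the aligner is a brute-force oracle that
enumerates every monotone alignment path and scores it with the same gap
convention; the test suite compares the two exhaustively for all nucleotide
pairs up to length 4 and on hundreds of random longer pairs, and separately
re-scores every returned traceback column by column.

## Ortholog detection parameters

The RBH stage stands in for the published pipeline's use of Proteinortho,
whose exact version and parameters were never stated; it is a replacement,
not a wrapper. Thresholds default to minimum 25 % identity and 50 %
coverage — the published defaults of Proteinortho's BLAST stage — with
coverage measured over the shorter protein so it is symmetric. Because the
statistic is defined pairwise, no multi-genome graph clustering is
performed.

An optional k-mer prefilter (shared distinct amino-acid 5-mers, at least 2)
keeps the all-vs-all alignment stage desk-scale. It is a heuristic: its
retention of true ortholog pairs on diverging synthetic genomes is a tested
property (≥ 99 % at 5 % amino-acid divergence), not a guarantee, and
`prefilter = FALSE` disables it. Score ties are broken toward the
lexicographically smallest subject id and reported, keeping runs
deterministic and order-independent.

## Annotation statistics, ORFans, and rank thresholds

The annotation summary reproduces the conventional genome-description
table: base-pair quantities are percentages of genome size, gene-class
counts percentages of total genes, and the function / COG / ORFan /
hypothetical rows percentages of protein-coding genes. All percentages are
rounded **half-up** to two decimals; this convention reproduces every cell
of the published tables the package's golden tests encode. Coding base
pairs are the length of the union of coding intervals (overlaps merged
first, via IRanges).

A gene is classified as an **ORFan** when it lacks any qualifying database
hit: alignments longer than 80 amino acids qualify at E < 10⁻³, shorter
ones only at E < 10⁻⁵. The published phrasing describes the *hit*
qualification thresholds; an ORFan is the absence of such a hit, and the
boundary length of exactly 80 aa falls in the stricter tier ("greater than
80" being the long-tier condition). The rule is monotone by construction:
adding hits can never create an ORFan.

16S rRNA identities feed the conventional rank thresholds: below 95.0 %
(Stackebrandt & Ebers) a new-genus candidate, at or above 98.7 % a
same-species candidate, new-species candidate in between; boundaries are
inclusive upward. The species threshold is supplied as a configurable
convention — the motivating analysis only exercises the genus threshold.
16S comparisons try both strands and keep the higher identity, so
reverse-complemented inputs are handled automatically.

## The synthetic genome generator

Validation runs on truth-known genome pairs rather than downloads. The
generator emits an ancestor of `n_genes` random complete CDS (ATG start, no
internal stop, terminal stop; by default 50 genes of 900 nt at 50 % G+C,
placed on one contig with 50–200 nt spacers) and evolves a derived genome
by:

* per-site substitution with probability `sub_rate`, uniform over the three
  alternative bases (no transition bias — the simplest null);
* optional single codon-length indels per gene (frames stay intact because
  AGIOS consumes CDS);
* gene loss and gain (counts rounded half-up; gained genes are generated
  independently so they should not attract reciprocal best hits);
* gene-order shuffling and re-labelling.

Codons that a substitution would turn into internal stops are re-rolled, so
every derived gene remains translatable. The truth record keeps the
ancestor→derived gene map, per-gene realized substitution counts, indel
traces, and the expected alignment identity under an explicit column trace
(gap columns count as non-identical, matching the aligner's denominator).

What the generator does *not* emulate: codon-usage bias, selection,
rearrangement beyond order shuffling, paralogous families, and sequencing
error. Passing tests therefore demonstrate correctness of the machinery on
an idealised substitution/indel process, not annotation-quality robustness
on real assemblies.

Two numerical notes. First, for indel-free genes the recorded substitution
count equals the Hamming distance to the ancestor gene by construction;
the *alignment* reproduces it exactly in the default 5 %-divergence regime,
but with codon repeats a 3-nt shift can occasionally beat the gap-free
alignment and shift the differing-column count by a column or two — the
mean identity stays within a small fraction of a percentage point of the
truth average. Second, gap-free optima dominate up to at least 15 %
divergence under the default scheme, which is why recovered AGIOS values
track the truth record so tightly there.

## Problem sizes and defaults used in validation

The shipped tests and the reproduction script run at deliberately modest
sizes chosen to exercise every code path while staying comfortable on a
single CPU: genomes of 6–50 genes of 900 nt, divergence sweeps over
substitution rates 0.01–0.15, exhaustive alignment-oracle comparison up to
length 4 plus hundreds of sampled longer pairs. These sizes are the
package's own validation choices; the statistic itself has no intrinsic
size limit beyond the O(nm) alignment cost, and the optional
`compare_published_genomes.R` script demonstrates full genome-scale use for
users who download the four published assemblies.

## Degenerate inputs and edge policies

* A genome pair with zero passing ortholog pairs reports `NA` (never 0) as
  its mean identity; renderers print `NA`.
* Genes whose CDS length is not a codon multiple, or whose translation hits
  an internal stop, are flagged invalid, kept in the gene table, and
  excluded from AGIOS and from the matrix diagonal.
* Non-ATG start codons translate to their table-11 amino acid rather than
  being forced to methionine — a documented simplification (annotation
  pipelines conventionally force M); it is irrelevant to identity values
  and keeps translation a pure codon lookup.
* The fallback six-frame ORF finder is plumbing for unannotated FASTA
  input, explicitly not a gene caller: first start codon after a stop to
  the next in-frame stop, minimum length 300 nt, same-strand overlaps
  resolved toward the longer ORF (ties leftmost). Because assemblies
  represent gaps as `N` runs, ORFs overlapping runs of ≥ 10 `N`s are
  excluded (configurable); this is a proxy — the underlying gap-exclusion
  criterion in the motivating pipeline was never defined.
* Rounding to printed precision happens only at render time; all TSV
  artifacts carry full-precision values and re-parse losslessly.

## Known limitations

* The published comparison-matrix values for the four real genomes are not
  asserted anywhere: they depend on unstated ortholog-detection and
  alignment parameters, and reproducing them requires downloading the
  assemblies. The optional script documents the qualitative expectation
  (all pairwise values in the 60–70 % band, the query genome closest to
  *P. elgii*) and makes no numeric claim.
* RBH orthology is one-to-one; recent paralogs collapse to a single pair,
  which can bias per-genome ortholog counts low relative to family-aware
  methods.
* The aligner is a straightforward O(nm) implementation; it is not banded
  or vectorised, which is ample at gene scale and adequate (minutes) at
  full-genome scale.
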