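---
title: "Methods: genome similarity statistics for bacterial taxonomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome similarity statistics for bacterial taxonomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agios)
```

## The problem

When a bacterial isolate is proposed as a new species, the classical
wet-lab criterion (DNA–DNA hybridization) is increasingly replaced by
genome-sequence comparison. This package implements the sequence side of
that workflow for draft genomes of the kind produced for new gut-microbiota
isolates: 16S rRNA identity screening, a genome-wide
similarity statistic over orthologous genes (AGIOS), a distance-based
phylogeny, and the bookkeeping tables (genome statistics, COG category
profiles) that genome-description papers print.

## The AGIOS statistic

For annotated genomes $A$ and $B$ with protein-coding gene sets
$G_A, G_B$:

1. **Orthology.** Candidate pairs are proteins sharing at least 2
   5-mers (a seeding prefilter that makes the all-vs-all comparison of two
   ~2,000-gene proteomes feasible on one CPU; it replaces BLAST-style
   seeding and is the one deliberate fidelity gap in this stage). Candidates
   are scored by Smith–Waterman under BLOSUM62 (gap open 11, extend 1) and
   kept if score $\geq$ the scheme's value for a 25-residue exact match,
   identity $\geq 25\%$, and coverage $\geq 50\%$ of the shorter protein.
   Orthologs are **reciprocal best hits**; ties on score are broken by
   higher identity, then lexicographically by subject id, so the map is
   deterministic and one-to-one. Co-ortholog groups are not modelled.
2. **Identity.** For each ortholog pair the *nucleotide* gene sequences
   are aligned end-to-end (Needleman–Wunsch, Gotoh affine-gap recurrence;
   match +5, mismatch −4, gap open 10, extend 0.5 — BLAST-like defaults,
   since no community standard exists for this statistic's parameters).
   Percent identity is matches over **all alignment columns** by default;
   `ungapped_columns` and `shorter_seq` denominators are provided because
   published identities rarely state their convention, and the choice
   matters once alignments contain gaps.
3. **Aggregation.** AGIOS is the unweighted arithmetic mean of per-pair
   identities ("mean identity among orthologous ORFs" reads as per-pair
   averaging); a length-weighted option exists. No identity floor is
   applied before averaging. The matrix view places gene counts on the
   diagonal, ortholog counts below and AGIOS percentages above, mirroring
   the published layout.

The two-alphabet flow — orthology on proteins, identity on nucleotides —
is deliberate: protein similarity is the robust signal for homology at
these divergences, while the nucleotide identity is the quantity the
species question is asked of.

### Alignment kernel

The kernel is a three-state Gotoh dynamic program (match state plus one
insertion state per sequence) with gap-run cost `open + L·extend`.
Terminal gaps are penalized in the default global mode (a true
end-to-end alignment); a semiglobal mode with free terminal gaps is
exposed but not used by AGIOS. Traceback ties resolve diagonal > up
(gap in the second sequence) > left, making aligned strings reproducible
byte-for-byte. `N` scores as a mismatch against every base including
`N`, so ambiguous draft-assembly positions can only lower an identity,
never raise it. Ambiguity codes other than `N` are rejected at parse
time: allowing them would silently change alignment scores.

Correctness is checked three independent ways in the test suite: a
plain-R enumeration of all alignments for short pairs, a compiled
brute-force path enumerator (no dynamic programming) swept exhaustively
over two-letter alphabets, and `Biostrings::pairwiseAlignment` on random
pairs.

## 16S screening

`best_match_16s()` ranks references by global-alignment identity and
applies the 98.7% species-delineation convention to the top hit. Two
choices are explicit: the boundary is **strict** (identity exactly at
the threshold does *not* flag novelty — the rule is "lower than the
threshold"), and both orientations of each reference are tried, keeping
the higher identity, because public 16S deposits are inconsistently
stranded. The 92–98% identity range typical *within* a genus is context
for interpretation, not part of the rule.

## Phylogeny

The tree stage consumes an existing multiple alignment (building MSAs is
out of scope). Distances use pairwise deletion — columns gapped (or `N`)
in either member of a pair are excluded for that pair — under p-distance
(default; the usual choice at 16S-level divergences), Jukes–Cantor or
Kimura 2-parameter. Neighbor joining is the Saitou–Nei algorithm (via
ape), with negative branch-length estimates clamped to zero. Bootstrap
resamples columns with replacement; within each replicate, zero-length
internal edges are collapsed before consensus so that signal-free data
yields an unresolved star rather than an arbitrary deterministic
resolution of ties. The consensus keeps bipartitions in strictly more
than 50% of replicates and prints integer percent supports. Outgroup
rooting is display-only. On additive distance matrices NJ provably
recovers the generating tree exactly; the tests exercise this on random
4–8-taxon trees, which is the meaningful machine-checkable property for
this stage since published bootstrap figures are not machine-readable.

## Genome statistics and COG tables

Two formatting conventions are load-bearing for reproducing published
tables and are implemented explicitly: G+C percent is **rounded** to 1
decimal, while every other table percentage is **truncated** to 2
decimals (135/2,003 prints 6.73, not 6.74). The G+C denominator is the
full assembly length including `N`; coding density is the length of the
per-contig **union** of coding intervals, so overlapping or nested genes
are counted once.

COG assignments are input, not computed — reproducing the BLASTP search
needs the external COG database. Percentages use the protein-coding gene
count as denominator (the COG-table convention); the bundled reference
tables for the *Collinsella* comparison set illustrate why the
convention must be stated: for the motivating genome, published gene
totals appear as 2,054 in one table and 2,057 in the text (the text
denominator reproduces the printed ORFan 8.02% and function-prediction
73.06%), and the COG table's category counts sum to 1,370 assigned genes
while its own "not in COGs" row (500 of 2,003) implies 1,503. The
package reports what the supplied inputs imply and documents, rather
than resolves, such inconsistencies. Likewise flagged genes (length not
divisible by 3, internal stops) are retained with `valid = FALSE` and
excluded from orthology by default, since draft annotations commonly
contain pseudogene fragments.

## The synthetic generator

`generate_ancestor()` draws ORFs (ATG start, random non-stop codons at a
target G+C, random stop) with normal-length variation around the mean,
places them on both strands with random intergenic spacers, and
`evolve_genome()` derives a second genome by:

- per-site substitution with probability $p$, always to one of the three
  *other* bases — so expected per-site identity is exactly $1-p$,
  giving the closed form `expected_identity()` used for parameter
  recovery;
- optional indels, frame-preserving by default (lengths multiples of 3
  at codon boundaries, insertions drawn from non-stop codons) so
  proteins stay alignable; a frameshift mode exercises the gene-flagging
  path;
- gene loss (Bernoulli per gene) and gene gain (novel random ORFs), all
  recorded in a ground-truth table;
- repair of start/stop codons destroyed by mutation and of codons
  mutated into internal stops, by reverting to the ancestral codon. This
  keeps gene counts stable for counting tests and biases identity
  upward by only ~0.1–0.5 points at $p \leq 0.1$, well inside the ±1
  point recovery tolerance (a strict mode flags instead of repairing).

Defaults follow the validation conditions used throughout: 100 genes of
mean length 900 bp (a typical bacterial gene length), G+C 0.5, rates
$p \in \{0.01, 0.05, 0.10\}$ spanning within-species to between-species
nucleotide divergence. What the generator does **not** emulate — codon
usage and amino-acid composition realism, transition/transversion bias
(available as an option but off by default so the closed form stays
exact), paralogous families, rearrangement, real intergenic structure —
bounds what passing tests show: they validate the statistics and
algorithms, not the behaviour of real draft assemblies with repeats,
contamination or fragmented genes.

## Numerical and degenerate-input choices

- Coordinates are 0-based half-open internally, 1-based inclusive at
  GFF-style I/O boundaries; the conversion happens exactly once, on
  read/write.
- Zero orthologs yields a flagged result with an undefined (NA) mean,
  not an error; zero-length alignments make percent identity an error
  (there is no defensible value).
- Truncation uses `floor(x·100 + 1e-9)/100`; the epsilon keeps exact
  decimals (20.00) from flooring a unit low in binary floating point.
- Distance matrices must be symmetric, non-negative, zero-diagonal
  (tolerance 1e-8); a pair with no comparable columns is an error naming
  the pair.
- Newick branch lengths round-trip at 6 significant digits.

## Problem sizes

The bundled validation runs at: 100 genes × 900 bp × 5 seeds × 3
substitution rates for AGIOS recovery (RBH recall ≥ 0.99 is asserted at
$p \leq 0.05$); exhaustive alignment-oracle sweeps over all sequence
pairs to length 6 (global) / 4 (local) on a two-letter alphabet plus
seeded random pairs to length 8 — exhaustive enumeration at length 8
across all pairs is combinatorially out of reach, the sampled sweep
checks the same property; and 100 random additive trees of 4–8 taxa for
NJ. These sizes were chosen so a full validation completes in a few
minutes on one CPU while keeping each estimate's Monte-Carlo error well
below the tolerance it is compared against.

## Known limitations

- One-to-one orthology only; lineage-specific duplications collapse to
  a single best pair, which can depress ortholog counts relative to
  tools that report co-ortholog groups.
- The k-mer prefilter can, in principle, miss a true best hit that
  shares fewer than two 5-mers; at the identity levels where orthology
  is claimed (≥25%) this is vanishingly rare for real proteins.
- Published AGIOS-style values carry unavoidable implementation
  tolerance: the original computations did not state gap parameters or
  identity denominators, so independent reimplementations agree only to
  within a couple of percentage points.
- Values tied to deposited assemblies (the published ortholog/AGIOS
  matrix for the *Collinsella* set, the 16S identity to the nearest
  species, the exact assembly length) require downloading the accessions
  listed in `collinsella_reference()$comparison_genomes`; offline they
  are shipped as reference tables, not recomputed.
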