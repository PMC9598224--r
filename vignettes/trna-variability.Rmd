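---
title: "Quantifying mitochondrial tRNA variability across nested cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitochondrial tRNA variability across nested cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnadyn)
```

## The problem

Mitochondrial genomes carry 22 tRNA genes whose cloverleaf secondary
structure constrains how they evolve: stems evolve under base-pairing
pressure, loops tolerate substitutions and indels, and one isotype (the
serine tRNA reading AGY codons) lacks the dihydrouridine arm altogether.
When a family of species is compared with one of its nested radiations,
the question is which tRNAs accumulate variation, where on the structure
that variation falls, and whether the pattern differs between the
family-wide cohort (here called Ci) and the sublineage (Ht). `trnadyn`
implements that comparison end to end: structure annotation,
domain-preserving alignment, site-wise polymorphism scoring with a
count-ranked weighting scheme, cohort-contrasted z-score categories, and
the accompanying population-genetic statistics.

## The cloverleaf model

Every tRNA is partitioned position-by-position into
A-stem5′ | CC | D-stem5′ | D-loop | D-stem3′ | CC | An-stem5′ | An-loop |
An-stem3′ | V-loop | T-stem5′ | T-loop | T-stem3′ | A-stem3′ |
discriminator. The connector (CC) appears in two short blocks: two
nucleotides after the acceptor stem — the standard numbering positions
8–9 — and at most one nucleotide after the D-stem (position 26). Putting
the first connector *before* the D-arm is required for the standard
position numbering to come out right (e.g. a D-stem pair 10·20 with a
3-nt D-loop); a single connector block after the D-arm cannot produce it.
The discriminator is its own label and is grouped with the acceptor domain
in per-domain tallies.

Template-mode annotation (`annotate_domains()` without a structure string)
searches all layouts satisfying the structural constants observed in
vertebrate mitogenomes — A-stem 7 bp, An-stem 5 bp, T-stem 5 bp, D-stem
3–4 bp, An-loop fixed at 7 nt, T-loop 7–9 nt, V-loop 4–6 nt, D-loop
3–10 nt — and returns the layout maximizing the number of complementary
stem pairs (Watson–Crick or G·T wobble) *minus* the number of
non-complementary ones. The penalty term matters: without it, extending a
stem over a position that happens not to pair ties with the shorter stem
and the boundary becomes undecidable. Ties that remain are broken
deterministically: intact D-arm before D-armless, longer D-stem, shorter
D-loop. D-armless layouts replace the D-arm with a short 3–8 nt connector
and an enlarged (up to 16 nt) variable arm, the architecture of metazoan
D-armless serine tRNAs; because this shifts the anticodon position
relative to any D-armed layout of the same length, the anticodon-centering
constraint alone separates the two classes whenever the anticodon is
known. A supplied dot-bracket structure bypasses the search entirely.

G·T stem pairs are genuinely ambiguous in this field's usage — they are
standard wobble pairs, yet comparative studies sometimes count them among
"mismatches". `pairing_mismatches()` therefore reports every non-Watson–
Crick stem pair and flags the G·T ones, so either convention is
recoverable from the same table.

## Alignment and consensus

`align_gene()` aligns one gene across species per domain block: the
homologous domains (from each sequence's own annotation) are aligned
independently by center-star Needleman–Wunsch (match +2, mismatch −1, gap
−2, configurable) and concatenated, so no gap column ever spans a domain
boundary. For two sequences each block is the exact dynamic-programming
optimum; for more it is the usual center-star heuristic, which is entirely
adequate at tRNA scale (~70 nt, blocks of 1–16 nt). A full MAFFT-style
aligner would add nothing at these sizes.

`consensus()` emits, per column, the base reaching the threshold fraction
(default 0.95; 0.5 reproduces a plain majority rule) or else the minimal
IUPAC code covering the bases tied for the maximal count. Base fractions
are taken over non-gap entries, and columns in which more than half the
rows are gaps are omitted from the consensus — the consensus is a
substitution-calling reference, while indels are scored separately —
though such columns stay in the alignment.

## Substitution quantification

Each column is a locus. The most frequent base is the dominant base; on
ties the dominant is the minimal IUPAC code over the tie set, exactly one
member of the tie set (the earliest in A < C < G < T order) is scored as
conserved, and every other base is scored as a transition (S) or
transversion (V) relative to that designate. Gap handling follows the
deletion/insertion asymmetry: gap-bearing sequences are deletions (D) when
gaps are no more frequent than the commonest substitution; when gaps both
outnumber the commonest substitution *and* reach the dominant base's
count, the gap state is taken as dominant and the minority bases are
insertions (I). Two boundary rules are fixed deterministically: a gap
count exactly equal to the commonest substitution resolves to D, and a
column that is monomorphic-plus-gaps is only an insertion column when gaps
actually dominate — without the second condition a column like (A, A, A, –)
would absurdly call the three A's insertions. The whole rule table is
checked in the tests against an independently coded oracle, exhaustively
over every possible column of up to five rows.

Weights follow the count-ranked rule: categories sorted by descending
total count receive 0.00, 0.25, 0.50, 0.75, 1.00 in order, with ties
broken in the fixed order C, V, S, D, I; when the data contain no indel
categories at all, fixed weights apply instead (0.25 per transition, 0.50
per transversion). Whether one weight table is built from all genes
jointly or per gene is a genuine design fork; `quantify_variability()`
defaults to a global table (the published per-category averages are
cohort-wide) and exposes `weight_scope = "per-gene"` for the alternative.

Per-tRNA weighted totals (reported separately for SNP categories S + V and
indel categories D + I), per-domain totals and the per-species weighted
ratio (weighted sum ÷ alignment length) summarize each gene. The
cohort contrast z-transforms the per-gene average weighted ratios within
each cohort; the sign of z assigns hyper (z ≥ 0) or hypo, the four
sign combinations give categories 1–4, and |z| ≥ 1 flags the extreme
genes, mirroring the conventional ±1 standard limits. Classification is
run per cohort — the sublineage's dominant bases are its own, not the
family's.

## Population-genetic statistics

`tajima_d()` implements the standard coefficient chain (a1, a2, b1, b2,
c1, c2, e1, e2) with D = (π − S/a1)/√(e1 S + e2 S(S−1)). Columns
containing gaps or ambiguity codes are excluded entirely (complete
deletion): S, the Watterson estimator and the variance chain need one
consistent site set, so per-pair deletion is not meaningful here.
Significance uses the conventional beta approximation (mean 0, variance 1,
support from the theoretical minimum to maximum of D), two-tailed at 0.05.
D is reported as `NA` when S = 0.

`tstv_bias()` estimates the Tamura–Nei rate ratios per sequence pair in
closed form from the observed proportions of purine transitions (P1),
pyrimidine transitions (P2) and transversions (Q):
k1 = (a1 − gY b)/(gR b), k2 = (a2 − gR b)/(gY b) with
a1 = −log(1 − gR P1/(2 gA gG) − Q/(2 gR)), a2 and b analogous, and
R = (gA gG k1 + gT gC k2)/(gR gY). Estimates are pooled across pairs by a
site-count-weighted mean after a partial-deletion column filter (default:
a column must be unambiguous in ≥95% of rows). Saturated pairs
(non-positive log argument) and transversion-free pairs are skipped with a
warning, and negative sampling fluctuations of k1/k2 are truncated at
zero, so R → 0 for transversion-dominated data rather than going
negative. This is a deliberately transparent substitute for a full
maximum-composite-likelihood fit; its calibration is checked by parameter
recovery on simulation (k1 = k2 = 4 recovered within 15% from an
eight-taxon star with 3500 sites — a single 1000-site pair estimates k
with ~20% sampling error, so the recovery check uses a design with
adequate power).

Distance matrices are TN93 with pairwise deletion and trees are
neighbor-joining (both via `ape` behind this module's interface);
saturated pairs fall back to 1.5× the largest finite distance with a
warning, and `ordered_matrix()` exports the matrix in ladderized tip
order for heatmap use. Maximum-likelihood tree inference and the original
"longest untransformed branch" rooting are out of scope; trees are left
unrooted (root them, e.g. at an outgroup or midpoint, downstream).

## Codon-level accounting

`classify_codon_change()` compares codons under the vertebrate
mitochondrial code (NCBI table 2: TGA = Trp, AGA/AGG = stop, ATA = Met,
via Biostrings): synonymous, nonsynonymous, truncation (substitution into
a stop), deletion (whole-codon gap) or frameshift (partial-codon gap). A
terminal `TA-`/`T--` codon is completed to TAA and flagged
`partial_stop`, the usual mitochondrial polyadenylation convention.
`aa_change_matrix()` tallies each nonsynonymous change X→Y into a 20×20
matrix whose column sums are the forward changes (toward an amino acid)
and row sums the backward changes (away from it); both margins always sum
to the number of nonsynonymous substitutions. `partial_mantel()` uses the
residual-permutation scheme (residuals of A and B on C, rows/columns of
A's residual matrix permuted, one-tailed, 999 permutations by default,
seeded and exactly reproducible); `correlation_battery()` adds
Benjamini–Hochberg adjustment across a battery of Pearson tests.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` draws a coalescent species tree (rescaled to height 1)
and designates as the sublineage the clade whose size best matches
`sublineage_fraction` (default 1/3), preferring clades that can keep a
distinct stem branch of at least 8% of the tree height; the clade's
internal branches are rescaled so the sublineage spans
`sublineage_depth` (default 0.35) of the total height. Defaults are meant
to be realistic for a fish family with a young radiation: 24 species,
root-to-tip substitution expectation 0.08 per site (`subst_rate`),
transition/transversion ratio κ = 2.25 (between the purine and pyrimidine
rate ratios typical of fish mitochondrial tRNAs), base composition
A 0.254 / C 0.225 / G 0.238 / T 0.283, about 1.2 indel events per gene
across the whole tree concentrated in the D-loop (odds 1.0) and V-loop
(0.8) with the T-loop nearly immune (0.05) and stems and the anticodon
loop excluded, and two 120-codon CDS evolved at 0.04 with a 0.2 acceptance
probability for nonsynonymous changes and no internal stops. Per-gene
rate multipliers (`rate_multipliers`, and `ht_rate_multipliers` for
branches inside the sublineage only) create contrasting variability
between cohorts.

The generator is deliberately structure-preserving: substitutions hitting
the A- or An-stem change the pairing partner compensatorily, the D- and
T-arms are held invariant (with no equal bases at distance one or two on
their 5′ strands), and the D-loop's first and last positions are fixed to
T, standing in for the conserved dihydrouridine residues. These choices
are not only biologically motivated (the T-arm is empirically the least
polymorphic structure, stems maintain pairing, D-loops carry conserved U
residues); they also make the cloverleaf layout of every emitted sequence
provably identifiable, which is what lets the test suite demand *exact*
recovery of the generator's true domain boundaries. The flip side defines
what passing tests do **not** show: real tRNAs do accumulate
non-compensated stem polymorphism (acceptor-stem substitutions are common
in fish mitogenomes), real indels are not perfectly loop-confined, and
real base composition drifts. On real data the template annotator can
therefore return a layout that differs from the biological structure at a
stem boundary; supplying dot-bracket structures from a dedicated predictor
is the recommended path there, and is why structure input bypasses the
template search.

The two bundled worked examples (`worked_example()`) reconstruct
three-species trnC and trnD alignments from their printed constraints —
polymorphic positions, substitution types, carrier species, stem
constants, and the noncanonical pairs T5·G61, G10·T20 and C50·A64. The
background bases at all other positions are not printed anywhere; they are
generated deterministically from a fixed internal seed and are arbitrary.
Every statistic asserted about these fixtures depends only on the printed
constraints.

## Numerical choices and degenerate inputs

* All coordinates are 1-based inclusive, matching both GenBank and the
  standard tRNA position numbering.
* Sequences shorter than any feasible layout raise `"unfoldable"`; an
  anticodon that cannot sit at any candidate An-loop center is an error
  in template mode and a warning in structure mode.
* `zscore_categorize()` refuses constant vectors (zero SD); z = 0 counts
  as hyper, a deterministic boundary choice that in practice never fires
  on continuous weighted ratios.
* QC filtering of assembled gene sets (`qc_filter_genes()`) is a declared,
  deterministic stand-in for manual curation of public mitogenomes: a
  species is dropped if it misses an isotype, has a per-isotype length
  outside mean ± 3 SD, or carries > 5% ambiguous bases in a gene. Note
  that a single outlier among n sequences cannot exceed (n−1)/√n SDs, so
  the 3 SD default only has power in cohorts of a few dozen species or
  more; lower `sd_mult` for small cohorts.
* Alignment-score ties in the Needleman–Wunsch traceback prefer the
  diagonal, then deletion, then insertion; center-star merge order is the
  input order. Both make alignments reproducible to the byte.
* GenBank parsing handles the location forms found in mitogenome records
  (`start..end`, `complement(start..end)`); joined locations are skipped
  with a warning. The leucine/serine duplicate genes are disambiguated by
  annotating the gene with each known anticodon and keeping the
  best-scoring layout.

## Problem sizes in the test suite

The suite validates each component at sizes chosen for statistical
resolution: the column-classification oracle comparison is exhaustive over
all 3900 columns of 2–5 rows; Tajima's D is checked to 1e−10 against an
independent direct-formula implementation and its null mean over 100
neutral coalescent replicates (n = 20, θ = 5) must sit within ±0.3 of
zero; Tamura–Nei recovery uses an 8 × 3500 simulation; the partial-Mantel
type-I error is estimated from 200 seeded null runs with 99 permutations
each and must lie in [0.01, 0.10]; and the end-to-end category-recovery
check runs 20 seeded replicates of the default 24-species cohort with a
3× rate multiplier on one gene, requiring category 1 in at least 18.

## Known limitations

* Template annotation infers structure from one sequence under hard
  length constraints; it is not a covariance-model search and will not
  annotate tRNAs with non-canonical architectures beyond the single
  D-armless class.
* Center-star alignment is heuristic for more than two sequences per
  block, and the consensus ignores gap-majority columns by design.
* The Tamura–Nei pooling is a pairwise composite, not a joint likelihood;
  for strongly saturated data it discards pairs rather than modeling
  them.
* The partial Mantel test permutes residual matrices, which is one of
  several published conventions; its p-values are one-tailed (greater).
* No maximum-likelihood or Bayesian phylogenetics, no dN/dS rates, no
  recombination detection, and no plotting: tables and newick/CSV exports
  are the interface to downstream graphics.
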