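---
title: "Comparative mitogenomics with mitocomp: models, methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative mitogenomics with mitocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

# Scope

`mitocomp` analyses annotated circular insect mitochondrial genomes
(mitogenomes): 37 genes — 13 protein-coding genes (PCGs), 22 tRNAs, 2
rRNAs — plus a non-coding A+T-rich control region.  It covers five
analysis stages (nucleotide composition and strand skews, codon usage,
gene-order rearrangement inference, substitution-saturation screening,
partitioned supermatrix assembly), a light distance-based tree estimator
for clade-recovery checks, and a synthetic-mitogenome generator that
exercises every stage without external data.  Sequence alignment, maximum
likelihood / Bayesian tree inference and divergence dating are out of
scope: the package consumes aligned inputs and emits the supermatrices and
partition definitions such external tools take as input.

# Coordinates and circularity

Annotations are held 0-based, half-open, on the forward (majority, "J")
strand; GenBank I/O converts to and from 1-based inclusive coordinates,
writing origin-spanning features as `join(a..L,1..b)` and minority-strand
("N") features as `complement(...)`.  All spacer/overlap logic treats the
genome as a ring, so the file origin is an artifact: rotating a record
changes no reported quantity (this is tested as a property).

# Composition, skews and codon usage

AT skew is $(A-T)/(A+T)$ and GC skew $(G-C)/(G+C)$; zero denominators
yield `NA` rather than a number.  Ambiguity codes are excluded from all
counts.  Partition summaries cover the whole genome, the coding-sense
concatenations of PCGs, tRNAs and rRNAs, the A+T-rich region, and the
three codon positions of the PCGs.  Codon positions are computed on
coding-sense sequences gene by gene (reading frame 0), not on the genomic
strand, because position-specific biases (T at position 2, G at position
1) are reading-frame properties.  The A+T-rich region contributes to the
whole-genome partition and its own, never to the coding partitions.

Codon usage runs under the invertebrate mitochondrial code (translation
table 5, taken from Biostrings); stop codons and trailing partial codons
are excluded, and internal stops raise a warning naming the gene.
Relative synonymous codon usage is
$\mathrm{RSCU}(c) = \text{count}(c)\cdot k_{\text{fam}} / \sum_{\text{fam}}\text{count}$,
with all-zero families reported as 0.  Where several genomes are averaged,
the arithmetic mean of per-genome RSCU values is used.

Stop codons are inferred from length modulo 3: a complete `TAA`/`TAG` in
frame, or the partial stops `T-` and `TA-` (completed to `TAA` by
polyadenylation after transcription).

# Gene-order rearrangement inference

Gene orders are circular signed permutations over the 37-gene alphabet
(sign `+` = J strand).  The reference is the ancestral pancrustacean
arrangement (shared with *Drosophila*), encoded as a package constant and
anchored at cox1.  The event vocabulary is the classical tRNA-rearrangement
triple:

* **transposition** — a gene or contiguous block moves, signs unchanged;
* **inversion** — a block flips in place, reversing order and signs;
* **reverse transposition** — a block moves *and* flips.

Tandem-duplication–random-loss is deliberately out of vocabulary; orders
it would explain surface as a single `unresolved_block` event.

`infer_events()` searches exhaustively for a minimal-cardinality event
sequence.  Both orders are rotated into the reference-anchored frame and
compared as linear words (reflection is never applied — strand identity is
meaningful).  Shared maximal blocks (runs identical in both orders, or
identical up to inversion) are collapsed to single symbols, the reduced
signed permutation is relabelled so the reference becomes the identity,
and a bidirectional breadth-first search meets in the middle, with the
reference-side ball cached across calls.  Words longer than a threshold
are first cut at prefix points where the set of gene indices matches the
set of positions, giving independent discordant windows solved separately;
this decomposition assumes window-wise additivity of the minimum, which
holds on every case we enumerate (the brute-force equivalence below runs
on undecomposed words).  Ties between equal-length solutions are broken by
total genes moved, then by a canonical enumeration order of events
(smallest blocks first); this realizes the "fewest events, then fewest
genes moved" preference deterministically.  If no solution exists within
the depth bound (default 4) or the search exceeds its node budget, the
smallest discordant interval is reported as `unresolved_block` — honesty
over forced parsimony.

The suite verifies, for every signed permutation of up to six genes, that
the returned event count equals the minimum found by an independent
brute-force breadth-first oracle (depth 3), and that replaying the events
on the reference reproduces the query exactly.

## Minimality versus the narrated account

For the Megabelesesinae-type order, the ARNS1EF cluster is a single
reverse transposition of trnR upstream of trnF, as classically described.
For the IQM cluster the classical narration is three single-gene events —
trnQ inverted, trnM and trnI transposed — but that account is not minimal
under this vocabulary: transposing trnI after trnM and then
reverse-transposing trnQ between them reaches M(+) Q(+) I(+) in **two**
events.  `infer_events()` therefore reports three events total for this
order, not four.  We keep the minimal-cardinality contract (it is the
parsimony criterion the whole module is built on) and note that the
narrated account remains a valid, if longer, edit path — `apply_events()`
replays either to the same order.

Shared events across taxa are grouped by kind, genes and target context;
an event carried by every member of a declared clade and by no other taxon
is flagged synapomorphic.

# Substitution-saturation screening

The screen compares uncorrected p-distances (pairwise deletion of gaps and
ambiguity codes) with maximum-likelihood pairwise distances under
GTR+Γ+I.  The rate matrix is built from exchangeabilities and stationary
frequencies, normalized so the expected rate over the non-invariant
mixture is 1 (distances are in substitutions/site), and eigendecomposed
via the $\pi^{1/2}$ symmetrization.  Rate heterogeneity uses four
mean-preserving discrete-gamma categories (category means of
equal-probability bins); invariant sites are a point mass at rate 0.  The
pairwise likelihood is maximized over the distance by bracketed 1-D search
(tolerance $10^{-8}$) with a cap of 10 substitutions/site; a pair still
improving at the cap is returned capped and flagged saturated.  In the
equal-frequency, equal-rate, large-shape limit these distances match the
Jukes–Cantor closed form $-\tfrac{3}{4}\ln(1-\tfrac{4}{3}p)$ to $10^{-3}$
across $p \in \{0.05,\dots,0.7\}$, and corrected distances dominate
p-distances entrywise; both are tested.

`estimate_model()` fits the free parameters (five exchangeabilities
relative to GT, gamma shape, invariant proportion; base frequencies are
empirical) by composite pairwise likelihood: the sum of pairwise
log-likelihoods with each pair's distance profiled out.  Because the
gamma-shape/invariant-proportion ridge is multimodal, the optimizer
alternates full distance re-estimation with Nelder-Mead parameter updates
at fixed distances, from four deterministic starts spread across that
ridge, keeping the best final composite likelihood.  Pairs are subsampled
to at most 60 (deterministically under the given seed) — with 20 taxa the
190 pairs are highly redundant and the subsample keeps a fit under a
minute.  On 20-taxon, ~10 kb simulations the gamma shape is recovered
within 25% relative error (tested); the invariant proportion individually
is weakly identified, which is the known cost of the +I+Γ
parameterization, not an optimizer defect.

One model is estimated (or supplied) per partition and then fixed for all
of that partition's pairwise distances, mirroring single-model-per-dataset
practice.  The screen reports the Pearson correlation (Spearman available)
between corrected and uncorrected distances over the lower triangle;
partitions fall below a configurable threshold (default 0.9) or into the
bottom-3 ranks are flagged.  The bottom-rank rule is what surfaces the
atp8/nad4l/nad6-type exclusion as a property rather than a hard-coded
list.  The pipeline's own screening stage corrects distances under the
configured generator model with partition-empirical frequencies;
`estimate_model()` is exercised separately for parameter recovery, keeping
the screen's runtime linear in the number of partitions.

# Supermatrix assembly

Per-gene aligned inputs are concatenated in a fixed canonical order (PCGs
alphabetical, then tRNAs, then rRNAs — the order is a package convention,
recorded in the scheme).  PCG alignments must be in frame; stop codons
(including the partial `T-`/`TA-` forms) are trimmed with
`strip_stop_codons()` before concatenation.  The four dataset variants
are: `P123RNA` (everything), `P12RNA` (third codon positions dropped),
and the two `exc3genes` variants additionally dropping atp8, nad4l and
nad6.  One partition block is emitted per retained PCG codon position and
per RNA gene — 63 blocks with all positions, 50 without third positions —
written as NEXUS charsets (`charset gene_pos1 = a-b\3;`) or RAxML-style
lines.  Site-count conservation, disjoint exact cover, and
mask/concatenate commutativity are tested invariants.  Missing taxa are
padded with `-`, treated as gaps everywhere downstream.

# Tree estimation for recovery checks

Neighbor joining is implemented in-package with an explicit contract: ties
in the Q-criterion break by lexicographic pair order, and negative branch
lengths are clamped to zero with the deficit moved to the sibling.  On
additive distances it recovers the generating topology exactly (tested
against the generating trees and against ape's implementation).
Monophyly is assessed after outgroup rooting; Robinson–Foulds distances
count bipartitions present in exactly one tree and are checked against a
brute-force bipartition oracle.  NJ on model-corrected distances is
deliberately *not* a substitute for ML/Bayesian inference — it is a
consistent estimator sufficient to test whether simulated clades are
recoverable from the data the pipeline assembles.

# The synthetic-mitogenome generator

The generator emulates sawfly-like mitogenomes so that every stage has
realistic input:

* **Tree.** A pure-birth (Yule) ingroup rescaled to depth 0.3 expected
  substitutions/site (rate-1 sites, root to tip), one tip replaced by a
  4-taxon planted clade, and an outgroup on its own root branch; 20 taxa
  by default.
* **Sequences.** Sites evolve under GTR (+discrete-gamma, shape 0.75,
  four categories; 10% invariant sites) with transition-biased
  exchangeabilities (AG = 5, CT = 8).  Stationary frequencies differ by
  partition class and strand — J-strand PCGs are T-rich in coding sense
  (AT skew ≈ −0.11), N-strand and RNA classes A-rich — which is the
  simplest mechanism reproducing observed partition-level skews; all
  classes target ~82% AT.  Per-gene coding lengths match typical insect
  mitochondrial genes (cox1 1536 bp … atp8 159 bp); tRNAs draw 60–71 bp;
  rRNAs 1300/780 bp.
* **Rate structure.** Codon positions multiply rates by (1, 0.5, 20) and
  atp8/nad4l/nad6 by a further 3, so third positions saturate at the
  default depth while first/second positions retain signal — the regime
  the saturation screen is meant to detect.
* **Coding constraints.** PCGs are generated in frame with an invariant
  ATN start; any codon whose evolution produces an in-frame stop at a tip
  is resimulated (codon-level rejection); the terminator is an invariant
  TAA, or a trailing `T` partial stop for cob and nad4.
* **Genomes.** Genes are laid on the ring in the ancestral order — clade
  members instead receive the order obtained by replaying the planted
  events (by default the MQI and ANS1ERF rearrangements) — with uniform
  0–20 bp intergenic spacers and a 300–800 bp A+T-rich region downstream
  of rrnS.

All randomness flows from one integer seed through fixed stage offsets;
a fixed seed reproduces byte-identical files (tested).  What the generator
does **not** emulate: indels and alignment uncertainty (alignments are
emitted gap-free; gap handling is tested with separately mutated
fixtures), secondary structure, tandem duplications, within-gene
recombination, and compositional non-stationarity along the tree.  Tests
passing on this generator therefore validate the machinery and its
statistical behaviour under the stated model, not robustness to every
artifact of real data.

# Problem sizes and numerical choices

Unit tests run the generator at reduced gene lengths (scale 0.08–0.2,
5–8 taxa) where the tested property does not depend on length; the
acceptance-style checks (saturation ranking, gamma-shape recovery,
clade recovery over 20 seeds) run at the full default conditions —
20 taxa, full-length genes, ~11 kb of P12RNA sites.  The brute-force
equivalence for rearrangement inference enumerates all signed
permutations of up to 6 genes at search depth 3.  Distance optimization
tolerances are $10^{-8}$ (final) and $10^{-6}$ (inside model fitting);
the distance cap is 10 substitutions/site; model fitting subsamples to 60
pairs and uses four starts.  Seeds derived internally stay below $2^{31}$.

# Known limitations

* The rearrangement search is exact only within its depth and node
  budgets; heavily scrambled genomes return `unresolved_block`.
* Composite pairwise likelihood is not the full tree likelihood; it is
  consistent for distances but statistically less efficient for shared
  parameters, and p_inv/alpha are only jointly well determined.
* The saturation flag is a screening heuristic (correlation threshold +
  bottom ranks), not a formal test with a null distribution.
* GenBank parsing targets the feature dialects the package writes and the
  common annotation variants (gene/product/note qualifiers, anticodon
  tags); exotic dialects may need the FASTA + feature-table route.
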