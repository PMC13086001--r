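---
title: "Comparative plastome analysis with plastomics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative plastome analysis with plastomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastomics)
```

This vignette is the package's own account of the methods it implements:
the statistics, their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic-data generators do and do
not emulate, and the design choices made where conventions genuinely
diverge.

## The coordinate frame

Everything region-aware in a plastome analysis hangs off the
quadripartite frame: a large single-copy region (LSC), an inverted
repeat (IRb), a small single-copy region (SSC) and a second inverted
repeat (IRa) that is the exact reverse complement of IRb. `plastomics`
stores the genome linearised at the LSC start — the conventional origin
in which plastome coordinates are reported — and uses 1-based inclusive
intervals throughout (the GFF3 convention). Features and repeat runs are
never traced across the circular origin; genomes assembled with a
different rotation must be rotated before analysis, and
`detect_inverted_repeats()` says so explicitly rather than guessing.

```{r partition}
p <- build_partition(91462, 26659, 18285, 26659)
p
partition_total(p)
```

Reported percentages and ratios use half-up rounding at the printed
precision (`round_half_up()`), because that is how such tables are
conventionally typeset; base R's round-half-even would turn e.g.
86.45833…% of mononucleotide SSRs into 86.4% instead of 86.5%. Raw
full-precision values are always retained alongside the rounded form
(`report_value()`), so rounding never propagates into arithmetic.

## Perfect SSR detection

`detect_ssrs()` reports every maximal perfect tandem repeat whose
*primitive* unit (one that is not itself a repetition of a shorter
string) is 1–6 bp and whose whole-unit repeat count meets the unit-size
threshold. The default thresholds (10, 6, 4, 4, 3, 3) are the MISA
settings standard in plastome surveys; they are expressed in repeat
units, so the shortest reportable loci are 10, 12, 12, 16, 15 and 18 bp.

Three decisions fix the edge cases:

* **Primitive motifs only, at the smallest period.** A 12-bp AT run is
  one dinucleotide locus (AT×6), never a mononucleotide or ATAT locus.
  This keeps the unit-size classes disjoint and the per-class counts
  additive.
* **No canonicalisation.** Motifs are reported as observed on the given
  strand: A- and T-homopolymers are distinct (their ratio is itself a
  statistic), and cyclic variants (TAA/ATA/AAT) are distinct columns in
  cross-species comparisons.
* **Whole units only; N breaks runs.** A locus spans exactly
  `unit_size × repeats` bp; trailing partial units are excluded, and a
  locus straddling a region junction belongs to the region of its start
  coordinate (its region of origin).

Compound SSRs are deliberately not merged: interruption-distance merging
adds structure that downstream counts cannot verify.

The scanner is validated against a brute-force oracle that tests every
(start, unit size) pair independently; the test suite runs that
equivalence on 200 random sequences of 200–5,000 bp spanning GC contents
from 0.15 to 0.5, plus AT-rich stress cases where qualifying runs are
dense.

```{r ssr}
detect_ssrs(paste0("G", strrep("A", 10), "CCTG", strrep("AT", 6), "GG"))
```

## Cross-species cpSSR composition

Motif repertoires are compared as presence/absence: `build_motif_matrix()`
encodes, per species, whether each exact motif string occurs at least
once. Three statistics sit on top:

* the **balance index** `min(n_present, n_absent) / n_species`, which is
  0.5 for a motif splitting the species set in half (maximally
  informative for clustering) and 0 for a fixed motif. This is the
  index sometimes printed under a "Sørensen–Dice" heading in motif
  tables; the name here follows what the formula actually measures.
* **Sørensen dissimilarity** on presence sets, in [0, 1];
* **Ward.D2 clustering** of those dissimilarities via
  `stats::hclust(method = "ward.D2")` — the Lance–Williams update on
  squared dissimilarities with heights reported on the unsquared scale.
  The tests verify merge heights and cophenetic structure against an
  independent oracle that embeds the distances by classical MDS and
  merges greedily by the explicit centroid form of the Ward cost.

Cluster support is assessed with a Mantel permutation test
(`mantel_test()`, via `vegan::mantel`): Pearson correlation over the
upper triangles, one-sided (greater), with the standard
`(1 + #{r_perm ≥ r_obs}) / (1 + n_permutations)` estimator. The seed is
a required argument — permutation p-values that cannot be reproduced
are not results. 999 permutations is the default used throughout. The
comparator matrix is whatever the analyst supplies (e.g. a phylogenetic
distance matrix); the package imposes no tree model.

## IR detection and junction accounting

`detect_inverted_repeats()` finds the longest pair of disjoint exact
reverse-complement substrings of at least `min_ir_length` bp (default
1,000 — comfortably above the incidental inverted repeats of single-copy
regions, far below real plastome IRs of ~25 kb). Matching is exact by
design: IR copies within a genome are typically identical or nearly so,
and for a near-identical pair the detector reports the longest exact
core, available directly from `find_longest_inverted_repeat()`. When the
mismatch-split flanks no longer tile a quadripartite frame from position
1 the partition constructor refuses rather than silently mislabelling
regions. If the two single-copy stretches tie in length, the stretch
containing position 1 is labelled LSC, with a warning.

The search seeds 32-mers at a stride that guarantees at least one seed
inside any qualifying repeat, matches them against the reverse
complement, and extends every exact run on each candidate antidiagonal —
so one internal mismatch yields both flanks as candidates, and the
longest wins.

Junction structure is quantified two ways: `junction_spans()` reports
how many bp of each boundary-crossing gene lie on either side of its
junction (a gene crossing two or more junctions is treated as an
annotation error), and `junction_shift_table()` reports, per region
class, the across-species range (max − min) of region lengths — the only
definition that yields one shift number per region class, with the IR
shift computed on the shared IR length.

## Nucleotide diversity

`nucleotide_diversity()` computes Pi as the mean pairwise difference
proportion over all sequence pairs. Gap handling defaults to **complete
deletion** — a column containing any gap or N is dropped for all pairs —
which is the convention of standard sliding-window diversity tools and
keeps every pair compared over the same sites; pairwise deletion is
available as an option. Sliding windows (`sliding_pi()`) default to
600 bp windows at 200 bp steps, tile from column 1, and drop trailing
partial windows: a partial window changes the variance of Pi and the
published window convention does not state an edge rule, so the
conservative choice is to omit it. Window midpoints are reported for
plotting (`autoplot()`).

Genes are classified into four conservation categories with half-open
cuts at Pi = 0.012, 0.024 and 0.038. Published category tables leave the
interval boundary between "variable" and "highly variable" ambiguous at
the third decimal; the half-open scheme `[0.024, 0.038)` → variable,
`[0.038, ∞)` → highly variable is the one consistent with both printed
range labels. The headline "share of genes with Pi ≥ 0.024" is reported
overall and per region at one decimal. Per-gene Pi is computed over a
user-supplied gene-to-column map; the package never re-aligns.

## SNP and indel typing

`call_snps()` reports every alignment column with two or more distinct
non-gap bases, polarised by an explicit reference taxon (polarity
determines "gains" vs "loses" labels, so it is never implicit).
Biallelic columns are typed as transition (purine↔purine or
pyrimidine↔pyrimidine) or transversion and labelled with their A/T
gain–loss effect; columns with three or more bases, or where the
reference is gapped, are retained as `multiallelic` but excluded from
Ts/Tv and effect summaries. Indels are maximal runs of contiguous
columns sharing an identical gapped-taxon set; pairwise identity is
computed over columns where neither row is gapped, which is why a
426-column alignment with a 3-bp indel yields 423 compared columns.

Diagnostic sites require gap-free columns where the whole group carries
one base and all non-members a single different base; private alleles
are gap-free columns where exactly one taxon differs from the rest.

The built-in `rpl22_alignment()` fixture reconstructs the four-taxon
marker-gene alignment from its published diagnostic alleles. One
documented wrinkle: the trinucleotide deletion is described at positions
395–397 in the ungapped gene frame while substitutions are listed at
396/397 in alignment coordinates; one alignment cannot host both at the
same columns, so the fixture keeps the ten printed substitution columns
literal and realises the deletion in a neutral block at columns 150–152.

## The synthetic-data generators

`synth_plastome()` and `synth_alignment()` are pure functions of a
specification and a seed: repeated calls are byte-identical, and they
restore the caller's RNG state. They generate the study conditions the
detectors are validated under:

* a quadripartite genome with exact IRa = revcomp(IRb), planted SSRs at
  recorded coordinates (an IRb plant is mirrored into IRa and the mirror
  enters the truth set), and genes planted across junctions with
  declared upstream/downstream spans;
* alignments with planted biallelic SNPs (declared ref/alt/carriers),
  planted gap blocks, and i.i.d. background substitutions at per-site
  rate θ (each taxon independently mutates to a uniform different base,
  so two taxa differ at a background site with probability
  `2θ(1−θ) + (2/3)θ²` — the moment the recovery tests check against).

Background sequence is sampled i.i.d. at the specified GC (default
0.35, typical of plastomes) with a bounded rejection loop that resamples
any window creating an unplanned threshold-qualifying SSR and any base
that would extend the planted IR pair by chance — so truth sets are
exhaustive and boundary recovery is exact, which the tests verify with
the brute-force oracle rather than the package's own scanner.

Defaults for the synthetic frame are 10 kb / 3 kb / 2 kb
(LSC / IR / SSC): a compact genome preserving the real ordering of
region sizes while keeping the rejection loop and the 100-seed recovery
tests fast. What the generators deliberately do **not** emulate:
phylogenetically structured substitution (no tree; background noise is
star-like), indel length distributions beyond the planted events,
tandem-repeat length polymorphism, and base composition heterogeneity
along the genome. Passing the planted-truth tests therefore shows the
detectors are exact on clean signal in realistic composition — not that
they resolve the alignment or assembly artefacts of real data, which
enter upstream of this package.

Test problem sizes are the package's validation choices: oracle
equivalence on 200 random sequences up to 5 kb; IR/SSR/SNP/indel
recovery over 100 seeds each; Mantel null uniformity over 500 replicates
of 999 permutations; Pi recovery over 500 replicates of 4-taxon, 500-bp
alignments against the θ moment within three standard errors.

## Known limitations

* Exact-match IR detection: heavily diverged IR pairs (many internal
  mismatches) fragment into short exact cores and may fall below
  `min_ir_length`; plastomes that have lost one IR copy are out of
  scope.
* No circular-rotation search: genomes must be linearised at the LSC
  start.
* SNP positions are alignment-frame coordinates of the supplied
  alignment; the package does not map them back through gaps to
  ungapped gene coordinates.
* The Mantel comparator matrix and the gene-to-column diversity map are
  caller-supplied; the package validates their shape, not their
  provenance.
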