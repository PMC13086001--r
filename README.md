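# plastomics

A tidy R toolkit for comparative chloroplast-genome (plastome) analysis,
built around the questions a plastome study of a plant genus asks:

* **Where are the microsatellites?** Perfect simple sequence repeats
  (cpSSRs) are detected with MISA-style unit-size thresholds (10, 6, 4,
  4, 3, 3 repeats for motifs of 1–6 bp) and summarised over the
  quadripartite LSC → IRb → SSC → IRa frame: counts by unit size and
  region, densities per kb / per 100 kb, homopolymer composition and the
  T/A ratio used as a compositional gradient statistic across species.
* **Do motif repertoires carry taxonomic signal?** Species-by-motif
  presence/absence matrices, a motif informativeness ("balance") index
  `min(n_present, n_absent) / n_species`, Sørensen dissimilarity
  `d(i,j) = 1 − 2|P_i ∩ P_j| / (|P_i| + |P_j|)`, Ward.D2 hierarchical
  clustering with Newick export, seeded Mantel permutation tests, and the
  count–density correlation.
* **Where do the inverted repeats sit?** An exact-match IR detector finds
  the longest disjoint reverse-complement pair from sequence alone and
  returns the quadripartite partition; gene spans across the four IR/SC
  junctions and across-species junction shifts quantify boundary
  movement.
* **Which regions and genes are variable?** Nucleotide diversity
  (Pi, the mean pairwise difference proportion) per alignment, per
  sliding window (600 bp / 200 bp defaults) and per gene, with the
  four-class conservation scheme (cuts at Pi = 0.012, 0.024, 0.038) and
  regional variability summaries.
* **Which sites diagnose groups?** SNP calling from marker-gene
  alignments with transition/transversion typing and A/T gain–loss
  ("T/A effect") labels, indel detection, shared-diagnostic and
  private-allele sites, and pairwise identity matrices.

Seeded synthetic-data generators (`synth_plastome()`,
`synth_alignment()`) produce quadripartite genomes with exact IR
reverse-complement identity, planted SSRs, junction-spanning genes, and
alignments with planted SNPs/indels — each with a machine-readable truth
set, so every detector is validated against known ground truth.

All user-facing functions take data frames first and return tibbles;
results chain with the pipe, plot via `autoplot()`, and tidy via
`tidy()`/`glance()`.

## Worked example: typing the *rpl22* marker

The package ships a 4-taxon, 426-column alignment of the *rpl22*
ribosomal-protein gene for one pachycaul (*Euphorbia drupifera*) and
three cactiform (*E. resinifera*, *E. ampliphylla*, *E. royleana*)
species, reconstructed from the published diagnostic alleles:

```r
library(plastomics)

fx <- rpl22_alignment()
snps <- call_snps(fx$alignment, reference = "E_drupifera")
snps[, c("position", "change_type", "change", "ta_effect")]
#>    position  change_type change       ta_effect
#> 1       223   transition    A>G         loses_A
#> 2       385   transition    A>G         loses_A
#> 3       390   transition    A>G         loses_A
#> 4       391   transition    T>C         loses_T
#> 5       392 transversion    A>T loses_A,gains_T
#> 6       394 transversion    G>T         gains_T
#> 7       396 transversion    A>T loses_A,gains_T
#> 8       397   transition    G>A         gains_A
#> 9       405 transversion    T>G         loses_T
#> 10      409 transversion    C>A         gains_A
```

Ten variable columns, five transitions and five transversions. Nine
sites are shared by the cactiform trio against *E. drupifera*; position
405 is private to the Asian *E. royleana* — a biogeographic marker:

```r
cactiform <- fx$groups$taxon[fx$groups$group == "cactiform"]
diagnostic_sites(fx$alignment, cactiform)$shared_diagnostic
#> [1] 223 385 390 391 392 394 396 397 409
```

Pairwise identity excludes the 3-bp indel block (the `AGC` retained only
by *E. drupifera*), so the cactiform pairs are compared over 423
columns:

```r
identity_matrix(fx$alignment)
#> Pairwise identity (%):
#>               E_drupifera E_resinifera E_ampliphylla E_royleana
#> E_drupifera        100.00        97.87         97.87      97.64
#> E_resinifera        97.87       100.00        100.00      99.76
#> E_ampliphylla      97.87       100.00        100.00      99.76
#> E_royleana         97.64        99.76         99.76     100.00
```

`99.76` is one mismatch in 423 compared columns — the single SNP that
separates *E. royleana* from *E. resinifera*/*E. ampliphylla*.

A junction example: in a 163,065 bp plastome partitioned
91,462 / 26,659 / 18,285 / 26,659 bp, a 423 bp *rpl22* copy ending 66 bp
past the LSC/IRb boundary splits as

```r
p <- build_partition(91462, 26659, 18285, 26659)
g <- tibble::tibble(gene_id = "rpl22", start = 91106, end = 91528)
junction_spans(g, p)
#> # A tibble: 1 × 6
#>   gene_id junction region_upstream region_downstream span_upstream span_downstream
#>   <chr>   <chr>    <chr>           <chr>                     <int>           <int>
#> 1 rpl22   LSC/IRb  LSC             IRb                         357              66
```

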