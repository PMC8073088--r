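---
title: "Pooled TILLING screens: model, thresholds, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled TILLING screens: model, thresholds, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tillseq)
```

## The screen in one paragraph

A chemically mutagenized M2 population is arrayed on 96-well plates and each
line's DNA enters exactly two sequencing pools: a *vertical* pool (its plate
row, across a pair of plates) and a *horizontal* pool (its plate column,
across a group of six plates). Pools are capture-sequenced over a panel of
target genes; a true induced mutation shows up as a low-frequency alternate
allele in exactly one pool of each axis, and intersecting those two pools
names two candidate wells, of which Sanger sequencing confirms one. This
package simulates that entire screen with known ground truth and implements
the decoding, calling, filtering, deconvolution and reporting around it.

## Pooling geometry

`build_scheme(n_plates = 42, n_rows = 8, n_cols = 12, pair_size = 2,
group_size = 6)` fixes the geometry that is consistent with all the design's
printed counts: a vertical pool is one plate row across a `pair_size`-plate
span (2 x 12 = 24 samples, 21 pairs x 8 rows = 168 pools) and a horizontal
pool is one plate column across a `group_size`-plate span (6 x 8 = 48
samples, 7 groups x 12 columns = 84 pools). The row/column roles are
configurable; the verbal description of such designs is ambiguous for
non-square plates, and this is the assignment under which every compatible
pool pair intersects in exactly `pair_size = 2` wells. How the 168 vertical
pools are laid out on physical pooling plates is a manifest convention
(lexicographic by plate-pair then row); it does not affect decoding.
Internally all plate/row/column/pool indices are 0-based; manifests, VCF and
labels (`"V001"`, well `"A01"`) are 1-based at I/O boundaries.

## The mutagenesis model

EMS alkylates guanine, so induced lesions are overwhelmingly G:C -> A:T
transitions and essentially never indels; the simulator therefore plants
point mutations only. The defaults are the study conditions throughout:

| parameter | default | meaning |
|---|---|---|
| `n_lines` | 4032 | M2 families (42 full plates) |
| `density` | 1/212,000 per bp per line | induced mutations per screened base |
| `spectrum` | 42.4% G>A, 40.1% C>T, 17.5% split over the 10 other types | substitution-type distribution |
| `het_fraction` | 1 | M2 mutations still heterozygous |

Per line and gene the mutation count is Poisson(`density` x `amplicon_bp`).
Each mutation's (position, type) pair is sampled *jointly*: position uniform
over the CDS and type from the spectrum, rejecting incompatible pairs.
Equivalently the type is drawn with weight `spectrum[type] x (count of its
reference base in the CDS)` and the position uniformly within that base
class. On base-balanced sequence this leaves the marginal type frequencies
at the spectrum and concentrates lesions at G/C sites, as the chemistry
does. (The tempting alternative — drawing the position first and
renormalizing the spectrum over that base — inflates mutations at A/T sites
roughly fivefold relative to the spectrum's 17.5% tail and is *not* what is
implemented.) Positions are unique per line and gene; clashes are redrawn
within the same base class, and in the pathological case of a saturated
base class surplus draws are dropped.

Selfing to M3 (`self_to_m3()`) treats loci independently: heterozygous
mutations produce progeny genotypes i.i.d. (WT 1/4, het 1/2, hom 1/4) and
homozygous mutations breed true.

### The synthetic gene panel

The six-gene fatty-acid desaturase panel (`synthetic_gene_panel()`) carries
the real screened amplicon sizes (1800, 1920, 3320, 2480, 2480, 2440 bp;
14,440 bp total) but *synthetic* CDS sequences of random sense codons: the
cultivar's own CDS sequences are not public. Consequences worth keeping in
mind: real codon usage, GC heterogeneity, and exon structure are not
emulated, and effect-class proportions observed on the synthetic panel are
those of random sequence, not of the real genes. The screened-amplicon size
is used for the mutation opportunity while positions fall in the CDS (whose
length is the amplicon rounded down to a codon multiple) — the simulator
treats the screened region and the CDS as coextensive.

## The sequencing and calling model

Sequencing is simulated at the allele-count level — counts are the
sufficient statistic for pooled SNV detection, and alignment-level
artifacts are deliberately out of scope. For a pool of *n* lines the depth
at a site is Poisson(2*n* x `depth_per_haploid`), default 10 reads per
haploid genome (480x for a 24-line pool, 960x for 48); each read reports
its sampled allele with probability `1 - error_rate` (default miscall rate
0.001), otherwise a uniform other base, giving the closed-form expected
observed alt fraction `f (1 - e) + (1 - f) e / 3`.

`call_pool()` emits, for each non-reference base with at least
`min_alt_reads = 3` reads (singleton and doubleton error reads are noise by
construction), a Phred-scaled confidence against the error-only null:

```
QUAL = -10 log10 P(X >= k),  X ~ Binomial(depth, error_rate / 3)
```

capped at 3000 (the cap absorbs tail probabilities below double-precision
underflow). Ties at one site with different alternate bases are independent
records; zero-depth sites are skipped with a warning.

### Threshold calibration

`integrate_and_filter()` groups calls by variant key. Supporting calls are
those meeting the per-pool threshold `qual_min`; each supporting pool
contributes two estimated alternate allele copies (`AC = 2 x pools`,
because one heterozygous carrier surfaces once per axis), the variant QUAL
is the minimum over supporting calls, and passing requires `AC >= ac_min`
(default 4 — detection on both axes for a singleton).

Two calibration points deserve explanation:

* **`qual_min = 40`.** Production pool-callers print QUAL on their own
  joint-likelihood scale, on which a conservative threshold in the hundreds
  is natural. On this package's single-pool binomial-tail scale, a true
  heterozygous singleton at the design depth yields about 10 alternate
  reads and a QUAL around 110–150, so thresholds in the hundreds are
  unreachable by construction. `qual_min = 40` is the error-null p <= 1e-4
  point: at 480x/960x it admits carriers from ~4–5 alternate reads upward
  while a coincidental error call that strong arises at ~3 x 1e-5 per
  pool-site-base, and the `AC >= 4` two-pool requirement then squares that
  rarity. This value was derived from the null model, not tuned on
  simulation outcomes.
* **Gating support at `qual_min` before aggregation.** With ~3.6M pool-sites
  per run, a true variant's key collects on average a fraction of a stray
  3-read error call from an unrelated pool. Taking the variant QUAL as the
  minimum over *all* co-located calls would let that stray call veto the
  variant; gating first (the count-level equivalent of filtering a VCF's
  per-pool records before integration) keeps the minimum-over-support
  semantics without the veto. Raising either threshold still never adds a
  variant.

## Deconvolution

`demultiplex()` maps each passing variant to candidate wells by decoding
every supporting (V, H) pool pair and taking the union of decodes (never
the cross-product of addresses — decodes are the only wells consistent with
both memberships). Variants with one-axis support are flagged
`unresolvable`, pool combinations with empty intersection `discordant`;
nothing is silently dropped. `sanger_resolve()` is an error-free truth
lookup by default, with a per-lookup miss probability (`sanger_error`) as a
configuration hook. Zero carriers among candidates marks a
`false_positive`; two or more, a `collision` (both recorded). The
`recovery_rate()` metric is the fraction of *planted* mutations resolved to
their true line — mutations lost at any stage count against it.

## Annotation and characterization

Effect annotation works purely in CDS coordinates under the standard
genetic code (`Biostrings::GENETIC_CODE`): residue index
`floor((pos - 1)/3) + 1`, classes `missense`/`silent`/`nonsense`/
`stop_loss` (the last absent from typical EMS tables but included for the
partition to be total). Splice, UTR and genomic-coordinate effects are out
of scope. Because the reference CDS behind a published mutant table is
often unavailable, `check_table2_consistency()` verifies each printed
nucleotide-change/substitution pair by (a) the residue-index arithmetic and
(b) existence of a sense codon compatible with both the base change and the
amino-acid change — the strongest check possible without the sequence; all
24 packaged mutant records pass it.

Summaries follow the conventions of such screens: EMS-type fraction
`(G>A + C>T)/total` in percent rounded half-up to one decimal; mutation
density `screened bp x lines / mutations`, rendered `1/<kb> kb` with the
kb figure rounded half-up (the only denominator convention under which the
packaged six-gene table's 274 mutations over 14,440 bp x 4032 lines give
1/212 kb). The packaged summary covers the six-gene desaturase panel; an
aggregate density over a whole 138-gene panel is not recomputable from the
packaged data (the full screened footprint is not published) and is not
attempted. Duplication dating is the molecular-clock identity
`T = Ks/(2 lambda) x 1e-6` Mya with `lambda = 6.1e-9`
substitutions/site/year; `Ka/Ks` is flagged undefined at `Ks = 0`.

## Reproducibility and problem sizes

Every simulating function takes a single integer seed and restores the
caller's RNG state; the pipeline derives stage seeds deterministically from
`run_config(seed)`, so a fixed seed reproduces every artifact byte for
byte. The test suite exercises the full-scale design (4032 lines, 3.6M
pool-sites, a few seconds per run) for the end-to-end recovery and
specificity checks, a ~1e5-pool-site carrier-free control for the
zero-false-pass property, and 40,000 progeny for segregation fractions;
property checks on the samplers use populations of 1e4+ mutations.

## Known limitations

* Counts, not reads: capture bias, mapping error, strand artifacts and
  index hopping are not modeled; the miscall model is a single symmetric
  per-base rate.
* The two-pool AC convention makes a variant's AC even by construction;
  published AC values from joint pool-callers need not follow it.
* Collisions (two carriers of the same variant in intersecting pools) are
  detected but not disambiguated — both lines are reported for follow-up.
* The synthetic panel supports method-level conclusions (recovery rates,
  spectrum retrieval, threshold behavior), not sequence-level ones about
  the real genes; passing tests say nothing about alignment-stage failure
  modes in real data.
* Phenotypes are fixtures: the package tabulates the packaged fatty-acid
  table but simulates no genotype-phenotype link.
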