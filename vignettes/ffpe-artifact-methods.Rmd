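---
title: "Models and methods: degradation metrics, artifact rates, and call concordance for FFPE exomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: degradation metrics, artifact rates, and call concordance for FFPE exomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffpeqc)
```

## The problem

Formalin fixation with paraffin embedding (FFPE) preserves tissue morphology
but damages DNA in two characteristic ways. First, it fragments the template:
FFPE exome libraries show median insert sizes around 100 bp where matched
fresh-frozen libraries sit around 150-200 bp. With 2x100-bp paired-end
sequencing, a 100-bp insert is read completely by *both* mates, so every
template base is sequenced twice; this mate overlap silently doubles the
apparent read evidence at those positions, and degraded fragments also ligate
non-specifically, producing reads whose ends do not match the locus they map
to and are soft-clipped by the aligner. Second, formalin cross-links
cytosines; during PCR the polymerase reads through the lesion and incorporates
adenine opposite it, so the library carries artifactual C>T alterations (seen
as G>A when the lesioned strand is the reverse strand in reference
orientation). These artifacts sit on top of the ordinary sequencing-error
background and can masquerade as low-allele-fraction somatic variants.

`ffpeqc` packages three things: a simulator that injects each artifact at a
configurable, recorded rate into matched blood / frozen / FFPE libraries; the
degradation metrics that quantify the artifacts from alignments; and the
two-pass homozygous-site estimator that separates FFPE-induced alteration
rates from the sequencing-error background, plus a LOD-threshold concordance
analysis of somatic call sets.

## The two-pass artifact-rate estimator

The core statistic works on two matched samples at a time and runs each
direction of a cross-design once:

1. **Site definition (lenient pass).** In sample A, build a pileup with
   mapping and base quality >= 20 and keep sites with depth >= 50 that show
   *exactly one* allele. The lenient filter is deliberate: filtering harder
   here would hide rare true second alleles and mislabel heterozygous or
   mosaic sites as homozygous. Any second allele, however rare, excludes the
   site.
2. **Discrepancy counting (stringent pass).** In the matched sample B, count
   every base at those sites that passes mapping quality >= 60 (the unique
   alignment cap of common aligners) and base quality >= 30. Bases equal to
   the site allele increment the denominator; bases different from it
   increment one of the 12 ordered substitution classes X>Y.

Counting discrepancies in the *control* (blood) at sites defined in the
tumor/FFPE sample estimates the **background** rate: control DNA is assumed
intact, so its discrepancies are sequencing error plus background damage.
Swapping the direction — sites from blood, discrepancies counted in the
frozen or FFPE sample — estimates the **overall** alteration rate, and the
**FFPE-induced** rate is the per-class difference, floored at zero (a rate is
non-negative by definition; the signed difference is kept for diagnostics).

Two choices here are genuinely open and are implemented as options:

* **Denominator.** Rates are normalized per class source by default: the C>T
  rate divides C>T discrepancies by all passing bases at homozygous-C sites,
  making each rate a per-opportunity probability. The aggregate variant
  (every class divided by all passing bases at all sites) is available via
  `denominator = "aggregate"` for sensitivity analysis; with an
  approximately uniform base composition the two differ by roughly a factor
  of four in scale but not in pattern.
* **Filter on the denominator.** Both numerator and denominator are
  restricted to bases passing the stringent filter, keeping the ratio a
  proper rate.

Sites where the counting sample's own consensus contradicts the defining
allele (germline mismatch, e.g. loss of heterozygosity in a tumor) are
excluded from counting entirely rather than counted as massive discrepancy.

## What the simulator emulates

`sim_config()` fixes the study conditions; the defaults are the conditions
the package's tests and acceptance checks run under.

* **Reference and variants.** Uniform-composition contigs (GC 0.45 by
  default; 300 kb at ~100x in the full-scale checks, smaller in unit tests).
  Heterozygous germline SNVs at 1e-3 per base are planted on one of two
  haplotypes shared by all three libraries; somatic SNVs (5e-5 per base by
  default) exist only in tumor libraries, carried by a fragment with
  probability `somatic_vaf * tumor_purity`.
* **Fragments.** Lengths are log-normal — matching the right skew of real
  insert distributions — with median `insert_median` (200 blood / 185
  frozen / 100 ffpe) and log-sd 0.55, then *clamped* to
  `[read_length/2, 10 * insert_median]`. Clamping rather than rejection is
  deliberate: it leaves every quantile above the lower bound untouched, so
  the sample median equals `insert_median` exactly, which keeps the
  insert-median parameter directly interpretable. Fragment counts are
  calibrated from a pilot draw so that expected sequenced-base depth matches
  `mean_depth`.
* **Deamination.** Modeled duplex-symmetrically at the template level: every
  reference-orientation C on an FFPE fragment flips to T with probability
  `deamination_rate`, and every G flips to A with the same probability, as
  if both strands carried lesions at the same per-cytosine rate. Both mates
  of an overlapping pair therefore read the flipped base identically —
  the property that makes mate-overlap double-counting inflate artifact
  evidence, and the one the `fragment` pileup mode exists to quantify. This
  parameterization makes the observed per-class alteration rate equal the
  configured probability (1e-3 per fragment base gives 1000 per Mb), with
  C>T and G>A at equal expected heights. The alternative — choosing one
  template strand per fragment — would halve the observed per-class rate
  relative to the parameter, which is why it was not used.
* **Sequencing.** Mate 1 reads the 5' end, mate 2 the 3' end, each
  `min(read_length, insert)` bases; base qualities come from a two-point
  profile (Q35 with a 2% tail at Q11, heavier on unmapped reads if
  configured); miscalls are injected per sequenced base at `miscall_rate`
  (6e-4 by default), uniformly over the three alternative bases and
  independently between mates — unlike deamination, so overlap-consistency
  separates the two artifact kinds.
* **Soft clips.** With probability 0.6 per FFPE read, one end (fair coin) is
  replaced by random sequence of truncated-geometric length. The geometric
  rate is solved numerically so the *truncated* mean (cap
  `read_length - 20`) equals `clip_length_mean`; a plain geometric with mean
  50 capped at 80 would have mean ~40 and the realized clipped-base fraction
  would undershoot `clip_probability * clip_length_mean / read_length`. At
  least 20 aligned bases always remain.
* **Mapping fates.** A configured fraction of pairs is emitted unmapped and
  another fraction mapped but not properly paired. Mapped reads carry MAPQ
  60 (so the stringent filter's MAPQ >= 60 passes them; per-read degradation
  is available for filter testing). TLEN always records the true template
  length; a leading soft clip shifts POS and shrinks the CIGAR `M` span but
  does not alter TLEN, since the simulator knows the template exactly.

Everything derives deterministically from the config seed, with separate
streams per stage and per sample type, so an identical config reproduces a
library byte for byte while matched libraries stay statistically independent.

What the simulator does **not** emulate: base-composition structure and
mappability variation of a real genome, capture-probe affinity bias, PCR
duplicates, indel artifacts, quality-score correlation along the read, and
aligner behavior (reads are emitted pre-aligned with truth coordinates, which
is what makes clip positions and artifact counts exact rather than inferred).
Passing tests therefore demonstrate that the estimators recover known rates
under a clean generative model — not that every real-data complication is
handled.

## Degradation metrics

* **Insert sizes** use `|TLEN|` of properly paired reads, one contribution
  per pair.
* **Double-sequenced bases**: per proper pair, the intersection of the two
  mates' aligned (`M`) reference spans, accumulated once per pair and divided
  by all sequenced bases of those pairs. Counting the redundant copy once
  keeps the fraction interpretable as "fraction of data that is redundant"
  and caps it at 0.5 (reached exactly when every insert fits inside one
  read); the both-copies variant is available via `denominator = "both"`.
  Soft clips shrink the spans — clipped bases are not sequenced template
  positions.
* **Soft-clip fraction**: CIGAR `S` bases over all bases of mapped reads.
* **Target coverage**: depth from `M` spans; flanks are the 100 bp each side
  of the merged targets, target-excluded; off-target bases are aligned bases
  in neither. The flank-exclusive definition is one consistent reading of
  "off-target" and is documented rather than asserted as canonical; under
  it, long frozen-library templates that extend past probes land in flanks
  and beyond, raising the frozen off-target fraction relative to FFPE.
* **Quality by mapping status**: normalized Phred histograms for mapped and
  unmapped reads with the Q >= 30 and Q <= 20 fractions, the contrast that
  distinguishes quality-driven mapping failure (blood/frozen) from
  alteration-driven mapping failure (FFPE).

## Pileup semantics and numerical choices

Coordinates are 0-based half-open internally; SAM's 1-based positions and
BED's 0-based intervals are converted at I/O boundaries only. CIGARs are
restricted to `M` and `S` (the analyses are SNV-only); anything else is
rejected loudly by operation name rather than skipped. Consensus ties yield
`NA` — a tied site can never be "single allele". Overlapping mates both
count by default (the naive regime whose inflation is the point of the
double-sequencing analysis); `mode = "fragment"` keeps a random mate's base
per template position, and under template-level deamination it yields
induced-rate estimates at or below the default mode. Columns below the depth
threshold are emitted but flagged, never silently dropped. Zero denominators
make a class `undefined`, never zero. Subtraction floors at zero with the
signed difference preserved.

The minimal somatic caller scores each candidate with a two-binomial
likelihood ratio (`LOD_T`, log10), using the configured per-base error rate
`e`: alt reads arise with probability `f(1-e) + (1-f)e/3` under allele
fraction `f` and `e/3` under the null, and the matched normal must be
consistent with allele absence (one-sided binomial test at level 0.01). It is
plumbing for concordance sweeps, not a production caller: external VCFs with
a LOD INFO field are first-class input via `read_calls_vcf()`. In the sweep,
overlap is keyed on `(contig, pos, ref, alt)` — the stricter reading — and
the strict curve's denominator is the frozen call set while the rescue
curve's is the FFPE call set, each recorded in the output attributes.

## Problem sizes and reproducibility

The full-scale checks in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R` use 300-kb references at ~100x (about 180,000 read
pairs per library, ~6 x 10^6 stringent-filter bases per substitution-class
denominator), which puts the 3-SD band on an induced rate of 1000 per Mb at
roughly +-40 per Mb; unit tests use 20-100 kb at 15-60x. The acceptance
script averages the rate targets over three derived seeds. All randomness
flows from the single `--seed` argument.

## Known limitations

* Rates are SNV-only; indel artifacts and OxoG-type (G>T, orientation-biased)
  damage are out of scope, as is F1R2/F2R1 strand decomposition — the natural
  extension for separating deamination from other damage on real data.
* The background estimate folds true background DNA damage into "sequencing
  error"; the design cannot separate them, only their sum, which is what gets
  subtracted.
* `read_alignments()` ingests plain-text SAM (the simulator's output format);
  BAM users should convert first (e.g. `samtools view -h`).
* The homozygous-site design assumes the two samples share germline genotype;
  sites where consensus disagrees are dropped, which also drops real LOH
  regions from the denominator.
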