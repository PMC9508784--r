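---
title: "Mapping a recessive locus with bulked segregant sequencing: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a recessive locus with bulked segregant sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`bsascan` maps a single-gene recessive trait from pooled sequencing of two
phenotype-selected bulks drawn from an F2 population. This vignette is the
package's account of the underlying models, the parameters that matter, and
the places where the design was genuinely open and a choice had to be made.

## The genetic model

The cross is an F1 self: the F1 parent is heterozygous (*Aa*) at the causal
locus and, for the simulator, at every segregating marker, with the mutant
allele riding one parental haplotype. F2 genotypes therefore segregate
1:2:1 and the recessive phenotype 1:3 (`chi_square_ratio()` tests observed
counts against that ratio with the plain Pearson statistic, df = 1; the
Yates correction is off by default because the uncorrected statistic is the
one conventionally quoted for Mendelian ratio tests — for example 56:210
against 1:3 gives χ² = 2.21 uncorrected, ≈ 1.99 corrected — and a
`correct` flag restores it for those who want it).

Selecting bulks on phenotype fixes the causal-locus composition of each
bulk: the mutant (weeping) bulk is all *aa*, the wild-type (standard) bulk
is *AA*:*Aa* = 1:2. Counting mutant alleles gives the expected SNP-indices
at the causal site,

* mutant bulk: 1,
* wild-type bulk: (0·1 + 1·2)/(2·3) = 1/3,
* Δ(SNP-index) = 1 − 1/3 = 2/3 ≈ 0.667,

returned by `expected_indices("f2_recessive")`. At unlinked sites both
pools have expected index 1/2 and Δ has expectation 0. These three numbers
anchor most of the package's tests.

## The simulator: what it emulates and what it does not

`simulate_f2_population()` produces each individual as the fusion of two
independent gametes; each gamete is a Markov walk along a chromosome's
markers whose phase switches between adjacent markers with the Haldane
recombination fraction r = ½(1 − e^(−2d/100)), d the inter-marker distance
in cM. Haldane's map (no crossover interference) is the simplest model
consistent with single-crossover fine mapping; interference is out of
scope. Physical distance converts to genetic distance by a single uniform
`cm_per_mb` rate.

`simulate_pool_reads()` models pooled sequencing as: total depth per site ~
Poisson(depth_mean); mutant-read count ~ Binomial(depth, f′) with
f′ = f(1 − e) + (1 − f)e, f the pool's true mutant-allele frequency and e a
symmetric per-read allele-flip error. `embed_diagnostic_indel()` adds one
indel whose alleles co-segregate perfectly with the causal haplotypes; by
default a 35 bp segment is deleted on the *standard* haplotype, so mutant
individuals are homozygous for the full-length allele.

Default study conditions (chosen once, as the conditions the analysis is
meant for): an F2 of 395; bulks of 15; mean pooled depth 100×
(`depth_mean`); sequencing error 0.001; error-free phenotyping (a
`pheno_error` rate exists for robustness experiments). The default genome —
two 25 Mb chromosomes, a marker every 10 kb, 4 cM/Mb — is deliberately
desk-scale: small enough that a full pipeline run takes seconds, large
enough that 1 Mb windows, threshold lookup and region merging are all
exercised; genome-scale coordinates are reachable through
`genome_model()`. One bulk-size note: the source protocols state both
15-plant and 20-sample pools at different stages; the package defaults to
15 (the pool size of the sequencing design) and leaves it configurable.

Deliberate omissions: no read-level FASTQ or alignment simulation, no base
qualities, no multi-allelic sites, no polygenic or epistatic trait models,
no phenotype-dependent depth. Passing tests on this generator therefore
demonstrate correctness of the *analysis logic* under the stated
statistical model — binomial read sampling around truth — not robustness
to alignment artefacts, reference bias or structural variation in real
data.

Reproducibility: every stochastic operation takes (or derives) a seed,
`withr::with_seed()` isolates it from the session RNG, and the seed is
recorded in output headers and the run manifest; identical seeds give
byte-identical outputs.

## SNP-index computation and filters

Because the F1 parent is heterozygous, its phase is unobservable from a
single sample, so the mutant allele cannot be defined "relative to the
parent" site by site. `orient_mutant_allele()` instead defines it as the
allele enriched in the mutant bulk relative to the wild-type bulk (ties go
to the alt allele, deterministically); the parent sample serves only as a
heterozygosity filter (index within 0.3–0.7) that removes miscalled or
non-segregating sites. A pool with zero or missing depth yields a missing
index, never index 0 — absence of reads is not evidence of absence.

`apply_site_filters()` implements the conventional criteria, each
configurable via `filter_config()`:

* `min_depth` (default 7): both pools must reach 7× at the site;
* one-pool-missing: sites observed in only one pool are dropped;
* `min_index` (default 0.3): the low-index discard is applied only when
  **both** pools fall below the cutoff. This is the deliberate resolution
  of an ambiguity: truly linked sites are *expected* to have wild-type-bulk
  index 1/3, a hair above 0.3, so discarding on either pool would erase the
  signal the scan exists to find. The literal either-pool reading is
  available as `index_filter_mode = "either"`.

Each failing record carries one reason under the fixed precedence
`low_depth > one_pool_missing > parent_not_het > low_index`, so the report
counts partition the discarded records.

## The windowed scan and its null thresholds

`sliding_windows()` uses the large-window/small-step convention — 1 Mb
windows advanced 1 kb — reading "1 Mb intervals and a 1 kb sliding window"
the way QTL-seq scans are conventionally drawn. A window's statistic is the
unweighted mean of per-site Δ; its depth is the mean per-site
min(depth of the two pools), a conservative summary for threshold lookup.
Windows with no passing site are omitted rather than imputed.

`simulate_null_thresholds()` builds the confidence curve: for each depth d,
draw each pool's allele frequency from the null F2 composition — under no
linkage, phenotype selection does not constrain a site, so both pools'
mutant-allele counts are Binomial(2·bulk_size, ½) — then draw
Binomial(d, f) reads per pool, 1,000 replicates by default, and record the
2.5% and 97.5% empirical quantiles of Δ at 95% confidence. A
label-permutation test is not meaningful here (each pool contributes one
observation per site), which is why the "permutation" is implemented as
this parametric null simulation of bulk composition plus read sampling.
Region calling is one-sided on the upper tail — the design makes Δ positive
at linked sites — while the lower quantile is still reported. Threshold
lookup uses the nearest depth in the grid; the pipeline's default grid is
the deciles of the observed window depths.

`call_candidate_regions()` merges maximal runs of consecutive significant
windows; a run may bridge up to `max_gap` (default 1) *omitted* steps but
never an emitted non-significant window. One post-processing rule is the
package's own: two runs separated by a significance gap shorter than the
window size have overlapping genomic extents, describe the same candidate
at the scan's resolution, and are coalesced into one region. Regions are
ranked by peak window Δ, and `interval_length_kb()` reports lengths
rounded to the nearest kb (the fine-mapping flank positions 20,839,173 and
20,998,220 span 159 kb).

### Calibration and the false-positive behaviour of the scan

Per-site orientation by bulk contrast folds the null distribution of Δ:
after orientation the per-site statistic is |Δ|, and the upper threshold
(the 97.5% quantile of signed Δ, equal by symmetry to the 95% quantile of
|Δ|) tests each window at close to the nominal 5% level. The tests verify
this directly: fresh null draws exceed the upper threshold at ≈ 2.5%
(signed) and the fraction of significant windows in null-cross scans stays
within twice the nominal rate.

Genome-*wide*, however, the windowed null field is dominated by bulk
composition, which windowing does not average away, and decorrelates only
over ~12.5 Mb at 4 cM/Mb. The maximum of that smooth field over a
two-chromosome genome lands essentially at the per-site 95% threshold, so
roughly half of null-cross runs show at least one borderline significant
window somewhere. This is a property of the per-site-threshold construction
itself (visible in published QTL-seq scans as isolated windows poking above
the confidence line away from any QTL), not of this implementation; users
should judge candidates by peak Δ and region extent, not by bare
significance of a single window. Under the true cross the causal region's
peak (~0.5–0.67) is far above threshold and the top-ranked region contains
the causal locus in well over 90% of simulated experiments.

## Fine mapping and the diagnostic marker

`count_recombinants()` applies the recessive rule: an individual is
recombinant at a marker iff it is phenotypically mutant without being
homozygous mutant (code B) there, or wild type while homozygous mutant;
missing genotypes are uninformative. `localize_interval()` takes the block
of zero-recombinant markers and extends to the nearest recombinant-bearing
marker on each side; the interval is *closed at those flanking markers*,
matching how fine-mapped intervals are conventionally reported by naming
their recombinant flanks. Sides without such a flank are open and flagged.
Dominant or codominant marker designs are out of scope. The pipeline's
marker selection mimics the practical two-round screen: a coarse set across
the scan's top region, then every available marker within one coarse
spacing of the best coarse marker.

`find_diagnostic_indels()` screens a region for indels whose bulks are
near-fixed for opposite alleles: mutant-bulk index ≥ 0.95 and
wild-type-bulk index inside 0.15–0.55 — a band centred on the expected 1/3
of an *AA*:*Aa* = 1:2 pool, widened for binomial sampling at ~100×. Both
cutoffs are arguments. `co_segregation_accuracy()` scores a marker as a
phenotype predictor (mutant iff homozygous for the mutant-linked allele)
and reports percent concordance over informative individuals; the embedded
fully linked indel scores 100% on error-free panels by construction, and
each injected discordance lowers the concordant count by exactly one.

## Numerical and interface conventions

* Coordinates: sites are 1-based inclusive (VCF convention); intervals are
  0-based half-open (BED convention); `interval_from_1based()` /
  `interval_to_1based()` convert and compose to the identity.
* Quantiles use R's default type-7 estimator; at confidence 0 both bounds
  collapse to the null median.
* Genotype codes are the mapping-population alphabet A/H/B/− ; marker
  positions may be parsed from `NAME-<pos>` marker names when no explicit
  position column exists, because that is how such markers are usually
  named.
* Multi-allelic VCF records are skipped with a message; unsorted inputs are
  sorted with a warning; malformed records fail with the offending line.
* Orientation ties, region ranking ties and nearest-depth ties resolve
  deterministically (alt allele; input order; first grid point), so equal
  seeds give equal outputs.

## Problem sizes used by the test-suite

Unit tests run on toy genomes (1–2 chromosomes of 1–20 Mb, markers every
20 kb–1 Mb) where brute-force oracles are exact and fast. The
experiment-level checks use the default study conditions — 50 simulated
crosses (n = 395, bulks of 15, 100×, 1 Mb/1 kb windows, 1,000 null
replicates, 95% confidence) for causal-locus recovery and 50 null crosses
for false-positive behaviour — sizes chosen so the whole suite completes in
a few minutes on one core while leaving Monte-Carlo margins well clear of
the asserted bounds.

## Known limitations

* The recombination map is uniform and interference-free; real chromosomes
  have hot and cold spots, so simulated fine-mapping resolution is
  optimistic for a given population size.
* The null threshold simulation ignores the sequencing error rate
  (negligible at e ≈ 0.001 against binomial sampling noise) and assumes
  equal depth in both pools at a site.
* Per-site orientation by bulk contrast makes the genome-wide
  false-positive rate of *single borderline windows* appreciable, as
  discussed above.
* Only biallelic sites and the two-class (df = 1) segregation test are
  supported; multi-parent designs, dominant markers and G′-style smoothed
  statistics are intentionally absent.
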