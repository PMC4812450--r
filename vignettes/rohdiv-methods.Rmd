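---
title: "Methods: ROH detection, diversity, and shared variation in small cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROH detection, diversity, and shared variation in small cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Captive breeding programmes for critically endangered species — here the
Visayan warty pig (*Sus cebifrons*), surviving on the Philippine islands of
Negros and Panay — are managed from studbook pedigrees under the assumption
that founders are unrelated and non-inbred. Whole-genome resequencing of
even a handful of individuals can test that assumption directly: runs of
homozygosity (ROHs) reveal autozygosity the pedigree cannot see, nucleotide
diversity outside ROHs measures what variation remains, and the partition
of cohort variants into island-shared and island-private classes quantifies
how differentiated the two source populations really are. `rohdiv`
implements that analysis chain for small cohorts, together with a
synthetic-data generator that gives every stage an exact or statistical
recovery test.

## The ROH model

Each genome is tiled with adjacent, non-overlapping 10-kb bins
(`bin_genome()`). Heterozygous SNPs are counted per bin; a 1-based site at
position $p$ falls in bin $\lfloor (p-1)/10^4 \rfloor$. Because not every
position is callable, observed counts are extrapolated from the covered
fraction of the bin to its full length (`scale_bins()`):

$$s_b = r_b \cdot \frac{10{,}000}{c_b},$$

with $r_b$ the raw SNP count and $c_b$ the number of covered sites — those
whose read depth lies in the sample's depth window. Bins with $c_b < 1{,}000$
(under 10% covered) carry too little information and are excluded, as are
sex chromosomes, whose recombination landscape differs from the autosomes
(`filter_bins()`).

A ROH is a maximal run of at least 20 consecutive retained bins with
$s_b < 0.33\,\bar{s}$, where $\bar{s}$ is the genome-wide mean of $s_b$ over
retained bins (`call_rohs()`). Two conventions deserve emphasis:

* the inequality is strict — with $\bar{s} = 12$ the cutoff is $3.96$, and a
  bin at exactly $3.96$ does not qualify;
* $\bar{s}$ is computed over *all* retained bins, ROH bins included: the
  average is defined before any ROH exists, so excluding them would be
  circular.

"Consecutive" is taken literally: a non-retained bin terminates a run, and
the default gap tolerance is zero (`max_gap_bins = 0`, configurable).
"Sliding window" is implemented as step = width; only then does
`length = n_bins × 10 kb` hold, consistent with reporting ROH length as a
bin multiple. The genomic average is genome-wide per individual, not per
chromosome — with ~3,000 bins per chromosome the difference is small, and a
single reference keeps the cutoff interpretable.

Nucleotide diversity $\pi$ is the mean $s_b$ over retained bins outside
every ROH (`diversity_outside()`), in units of heterozygous SNPs per 10-kb
bin. ROH lengths are classified into half-open categories with default
edges 0.2, 0.5, 1, 2, 5 Mb: a 0.5-Mb ROH belongs to 0.5–1 Mb. The bottom
edge (0.2 Mb) equals the minimum ROH length of 20 bins, so the
shorter-than-smallest-edge error cannot occur with default parameters.
Cohort summaries report group means and sample SDs; where they are printed
as integers they are rounded half away from zero (`round_half_away()`),
which reproduces the published integer summaries (e.g. a Negros mean ROH
count of 54.5 reported as 55).

## Depth filtering

Variants are filtered per sample against the sample's own mean depth
$\bar{d}$: a genotype is kept iff $0.5\,\bar{d} \le d \le 2\,\bar{d}$,
bounds inclusive (at 10x, depths 5 and 20 both pass). Low depth means
unreliable calls; high depth suggests collapsed repeats or copy-number
variants. Filtering masks the individual genotype rather than dropping the
record, because each genome is judged against its own average; the mean is
taken over non-missing DP values only. The same window defines a "covered
site" for the binning stage — the one depth criterion in the method is
reused rather than inventing a second one.

The window reference can be supplied explicitly (`filter_depth(means=)`).
This matters at integer knife-edges: when the true mean is exactly 10, an
estimated mean of 10.002 silently excludes all depth-5 sites (3.8% of a
Poisson(10) mass) while the coverage track, defined with the true window,
still counts those positions as covered — biasing $\pi$ downward by up to
~4%. Analyses on simulated data therefore pass the generator's known mean;
on real data, where the coverage track and the variant filter are derived
from the same estimate, the two stay consistent automatically.

## Variant partitioning

For the shared/private analysis, sites where every called genotype is
homozygous-alternate are removed first: they are fixed differences against
the reference assembly (standing proxy for the reference species) and carry
no within-species information. Sites with minor allele count below 2 —
counted over haplotypes, het = 1, hom = 2, across all called genotypes —
are removed as likely call errors. The minor allele is determined per site
from cohort haplotype counts; a 7:7 tie treats the alternate allele as
minor. A site is island-private iff its minor-allele carriers all come from
one island; missing genotypes contribute nothing and cannot make a site
private on their own. The two filters commute, and the three categories sum
to the class total by construction — both properties are tested.

Consequence classes come from a precomputed annotation table (running
VEP/SIFT is upstream and database-version-dependent). Nonsynonymous
variants with SIFT score strictly below 0.05 (the conventional threshold;
configurable) are "not tolerated"; a score of exactly 0.05 is tolerated.
The heterozygous/homozygous genotype ratio per class is reported as a
purging diagnostic, with the zero-homozygote case flagged rather than
returned as infinity.

## Distances and the tree

The original analysis computed pairwise distances with an unstated PLINK
option; this package fixes the metric to the allele-sharing distance
$d = 1 - \mathrm{IBS}$, the conventional genotype distance: per site both
samples called, shared alleles are $2 - |g_a - g_b|$ under 0/1/2 coding.
This is a deliberate, documented deviation in favour of a reproducible
definition. Neighbour joining is implemented with two determinism rules:
Q-matrix ties break to the lexicographically lowest (row, column) pair, and
negative branch estimates are clamped to zero with the deficit absorbed by
the sibling branch (preserving the pair's summed length). Midpoint rooting
examines all leaf pairs (ties break by label order) and roots at the exact
midpoint of the diameter path, which may fall on an internal node. On
additive matrices the NJ tree reproduces the input distances exactly; tests
verify this against matrices built from random reference trees, and
cross-check the implementation against `ape::nj` and `phangorn::midpoint`.

## Pedigree inbreeding

Studbooks mark wild-caught founders with parent "WILD"; unknown and
unlisted parents are normalised to the same value. Kinship is computed by
the tabular method over a parents-before-offspring ordering (a failure to
find such an ordering reports the cycle), with founders assumed unrelated
and non-inbred — exactly the optimistic assumption whose violation the
genomic ROH evidence is meant to expose, and the reason the package reports
both. $F$ of an individual is the kinship of its parents. Tests verify the
tabular method against an independent Wright path-counting oracle on
textbook schemes (full-sib 1/4, half-sib 1/8, first-cousin 1/16) and on
random pedigrees. Generation time is the mean parental age at offspring
birth over all datable parent–offspring pairs; year-only dates use a
mid-year convention.

## The synthetic-data generator

`simulate_individual()` places heterozygous sites by a Poisson process at
rate $\lambda$ per 10-kb bin (default 12, the diversity level observed in
the study system) outside planted autozygous tracts and $\varepsilon
\lambda$ inside them ($\varepsilon$ defaults to 0; recovery analyses use
0.02 — real autozygous tracts retain residual heterozygosity from
genotyping error and recent mutation). Tract positions are user-specified
rather than drawn from a recombination model: exact truth makes boundary
tests exact. Mean depth defaults to 10x, matching the 5x–20x window gloss.

Coverage is modelled at bin resolution: covered sites per bin are drawn as
$\mathrm{Binomial}(10^4, p)$ with $p$ the probability that a
$\mathrm{Poisson}(\mu)$ depth lands inside the depth window — the same
retention probability applied to the variants, whose DP is drawn per site.
This is statistically equivalent at the bin level to materialising 30
million per-base depths and keeps multi-replicate suites fast. Dropout bins
get zero coverage and zero-depth variants. The choice $\varepsilon = 0.02$
for recovery tests is analytic, not tuned: the run-breaking probability per
interior tract bin is $P(\mathrm{Poisson}(\varepsilon\lambda) \ge 4)$,
about $10^{-4}$ at $\varepsilon\lambda = 0.24$, so the expected number of
broken tracts across a 20-replicate suite is far below one, whereas at
$\varepsilon = 0.05$ it would approach two — the recovery property would
then fail for reasons unrelated to the caller.

`simulate_cohort()` builds a two-island cohort with exact category truth.
Shared sites get island-specific carrier probabilities drawn uniformly from
0.2–0.8 per site (emulating drift since the split), redrawn until each
island has a carrier; private sites are island-diagnostic (every island
member heterozygous; a lone member homozygous so the minor allele count
still reaches 2). Every emitted site passes MAC ≥ 2 by construction, so
`partition_by_island()` recovers the planted counts exactly. The default
analysis cohort — 5 + 2 samples, 1,000 shared and 115 + 63 private sites —
mirrors the study's sample configuration and ~15% island-specific fraction.

What the generator does *not* emulate: linkage disequilibrium, allele
frequency spectra from a coalescent, sequencing error in genotypes,
reference bias, or recombination-driven tract length distributions. Passing
recovery tests therefore demonstrates that the estimators are correct under
their stated model, not that they are robust to every artefact of real
resequencing data. Two consequences worth noting: with only two samples on
one island, forcing every shared site to have a carrier on each island
inflates within-island mismatch, so island clade recovery on simulated
cohorts is high but not guaranteed for every random cohort; and the
published per-individual genomic values themselves derive from ~7 whole
genomes and are not recomputable at desk scale — the package recomputes the
cohort-level summaries and accounting identities from the published
per-individual table (`sus_roh_summary()`, `sus_variant_partition()`), and
validates the genome-scale machinery on simulation instead.

## Problem sizes and determinism

The test and acceptance suites use single 30-Mb chromosomes (3,000 bins,
~36,000 heterozygous sites at $\lambda = 12$) with 10–20 seeded replicates
per property, cohorts of ~1,200 sites, and random trees of up to 8 leaves —
sizes at which every property is checked in seconds while the statistical
tolerances (5% for $\pi$ recovery, one bin per ROH edge) remain meaningful.
All randomness flows through explicit integer seeds; identical
configuration and seed give byte-identical outputs, including the pipeline
driver `run_pipeline()`, which logs every effective parameter.

## Known limitations

* The fixed-difference filter uses the reference-assembly allele as a proxy
  for the reference species; a true outgroup comparison would need that
  genome.
* The allele-sharing distance treats all sites equally; no allele-frequency
  weighting or LD pruning is applied before tree building.
* Pedigree $F$ inherits the founder-unrelatedness assumption; it is a lower
  bound when founders are related, which is precisely what the genomic
  comparison is for.
* `bin_genome()` consumes per-bin coverage; per-base BED-graphs must be
  reduced to bins upstream (the depth window defines "covered").
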