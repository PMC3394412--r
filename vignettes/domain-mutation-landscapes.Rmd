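---
title: "Domain-centric mutational landscapes: model, assumptions, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain-centric mutational landscapes: model, assumptions, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(domainscape)
library(dplyr)
```

## The problem and the model

Tumor sequencing studies try to separate *driver* mutations — somatic
changes under positive selection in the tumor — from the far more numerous
*passengers*. Gene-centric analyses rank genes by how often they are mutated
across patients, which misses two things: where in the protein a mutation
falls, and signal that is rare in any one gene but concentrates in a protein
domain shared by many genes. domainscape implements a domain-centric
analysis: every somatic coding mutation is mapped both to its gene and to
the individual domain instance (an interval on a specific protein) that
contains it, and mutation burden is tested at both levels.

The statistical model is deliberately simple. Under the null, passengers are
uniformly distributed over coding sequence, so for a region of length $L$
amino acids observed across $n$ patients the per-residue occurrence count is
binomial with a common success probability. Writing $k$ for the
occurrence-weighted mutation count of a region (each patient carrying a
variant contributes one occurrence) and $\hat p = k/L$ for its
length-normalized frequency, we standardize against the pooled background
rate $p_0 = \sum k \,/\, \sum L$ taken over all regions being tested:

$$ z = \frac{\hat p - p_0}{\sqrt{p_0 (1 - p_0) / L}} . $$

This is the Bernoulli signal-to-noise standardization of $\hat p$: under the
uniform-passenger null it is approximately $N(0,1)$, which is exactly what
the downstream local-fdr machinery expects, and it is strictly increasing in
$k$ at fixed $L$. A literal signal-to-noise transform
$z = \sqrt{\hat p / (1-\hat p)}$ is available behind `z_form = "snr"` for
users who want the untranslated form; it is monotone in $\hat p$ but not
centered, so the default is the standardized form. Genes and domains are
always fitted as *separate* landscapes — separate universes, separate
$p_0$, separate null fits — because their length distributions and count
processes differ.

Normalizing lengths are: for a gene, the length of its *representative
protein* (the longest isoform, ties broken by smallest accession, so the
choice is reproducible); for a domain, the *cumulative* length of all of its
placements across representative proteins — a domain repeated seven times in
one protein contributes all seven copies, which both controls for the extra
target size and keeps the domain landscape from being biased toward
frequently occurring domains.

## Local false discovery rate

Significance is assessed with a local false discovery rate over the ensemble
of region scores, following Efron's empirical-null recipe:

* the marginal density $f(z)$ is a Poisson regression of histogram counts
  (120 equal-width bins spanning the score range) on a degree-7 orthogonal
  polynomial of the bin centers;
* the null $f_0 = N(\delta, \sigma^2)$ and the null proportion $\pi_0$
  (capped at 1) are estimated by truncated-normal maximum likelihood on the
  central 50% of scores, where passengers dominate;
* $\mathrm{lfdr}(z) = \min\!\big(1,\ \pi_0 f_0(z) / f(z)\big)$.

A region is a **peak** when its lfdr is strictly below 0.1 *and* its
frequency is elevated ($z > 0$): the lfdr is small in both tails, and
without the sign condition a strongly depleted region would be called a
"peak". Two further guards apply. Regions shorter than 150 aa are excluded *before* fitting (flagged
`excluded_short`): on very short regions $\hat p$ is dominated by integer
jitter in $k$, and a single mutation can look like a large rate. And the
empirical null needs a reasonably large ensemble — with fewer than 200
regions the package falls back to the theoretical $N(0,1)$ null with
$\pi_0 = 1$ (with a warning), because location/scale estimation on a small
central band is unstable. Zero-count regions stay in the fit (they carry
information about the background) but are never called significant. The
pooled rate $p_0$ is computed over the regions actually entering the test,
i.e. after the length exclusion, so the background and the ensemble describe
the same universe.

```{r lfdr}
sim <- suppressWarnings(simulate_cohort(
  seed = 42,
  drivers = tibble::tibble(region_kind = c("gene", "domain"),
                           region_id = c("G005", "DM0002"),
                           multiplier = 10)))
gl <- gene_landscape(sim$cohort)
dl <- suppressWarnings(domain_landscape(sim$cohort))
glance(gl)
significant_regions(dl)
```

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `evalue_cutoff` | 0.001 | E-value | conventional threshold for trusting a complete-domain placement |
| `lfdr_threshold` | 0.1 | posterior prob. | a called peak is at least 90% likely to be non-null |
| `min_length` | 150 | aa | heuristic guard against unstable frequencies on short regions |
| `min_regions` | 200 | regions | minimum ensemble size for the empirical null |
| `prevalence_threshold` | 0.04 | mutations/patient | inclusive cutoff for the "high prevalence" flag |
| `z_form` | `"binomial"` | — | standardized score (approx. N(0,1) null); `"snr"` is the literal transform |

## From mutations to cohorts

The readers consume protein-space inputs: an annotation step (ANNOVAR-style)
is assumed to have already translated genomic variants into protein
coordinates and consequence classes, and a domain search (HMMER-style,
`--domtblout` supported directly) to have placed domain models on proteins.
All coordinates are 1-based inclusive residue indices; indels are located by
their start residue, so a deletion beginning inside an instance belongs to
it even if it runs past the instance end. Four filters define the analyzable
set: somatic only, QC-passed only, no known polymorphisms (a user-supplied
dbSNP-style exclusion list), no synonymous SNVs. Retention is a conjunction,
so filter order cannot matter; duplicate (sample, variant) rows — e.g. the
same call from two sequencing centers — count once, but the same variant in
$m$ patients counts $m$ times. A mutation covered by overlapping instances
of *different* domains is assigned to each (dropping either would silently
lose signal, and multi-assignments are visible in the report); covered by
several instances of the *same* domain, it counts once for that domain.

## Peak anatomy and cross-cohort comparison

Two analyses relate the domain landscape back to the gene landscape. Peak
*origin* classifies each significant domain by its contributing genes: all
significant (`from_gene_peaks`), none significant (`aggregated` — the
interesting case, where signal exists only after pooling across genes), or
`mixed`. The `mixed` class is not one of the two poles usually discussed,
but real breakdowns need it: a domain can draw 27 of 28 mutations from one
significant gene and one more from a non-significant paralog. Peak
*retention* removes every mutation of every significant gene (whole-gene
node removal, not just in-domain mutations) and recomputes the domain
landscape from scratch — counts, $p_0$, scores, and a fresh lfdr fit, since
removal changes the ensemble the null is estimated from. Domains still
significant afterwards carry signal that does not piggyback on a single
dominant gene. Landscape comparisons across cohorts are raw set overlaps of
significant ids with percentages to one decimal; no overlap test is
attached, because proportions are what the analysis reports.

## GO enrichment

Entities (genes or domains) are annotated with GO terms, closed under
ancestors along every path (`is_a` and `part_of` edges both count; the
namespace roots are excluded), and tested term by term with a right-tail
Fisher exact p-value on the 2×2 table of significant × annotated over the
background of entities carrying at least one mutation. Biological-process
and molecular-function terms are tested; cellular component is excluded.
Rankings are on raw p-values; a Benjamini–Hochberg column is emitted for
convenience but not used to truncate anything. One property worth knowing:
with the annotated margin fixed, growing the background with unannotated
entities makes an observed overlap *more* surprising, so p-values shrink —
enrichment against a background restricted to mutated entities is therefore
deliberately conservative compared to testing against the whole proteome.

## The synthetic generator

`generate_proteome()` + `generate_cohort()` emulate the structure the method
depends on: multi-isoform genes (exercising representative selection), a
tandem-repeat domain (several copies in one protein, so cumulative length
sums over copies), a domain shared across many genes (the substrate for
aggregated peaks), and per-patient, per-residue Bernoulli mutations at a
uniform background rate with planted driver regions at an elevated rate
(gene-scoped: the whole protein; domain-scoped: every instance; overlaps
take the maximum multiplier). A per-residue Bernoulli model is the simplest
process consistent with the uniform-passenger null, and makes counts
occurrence-weighted by construction. Decoy records — synonymous SNVs,
dbSNP-flagged variants, germline calls, QC failures — are planted at
configurable fractions so the filters have real work to do.

Default study conditions: 200 genes, 40 domains, 100 patients, background
rate $r = 5\times10^{-5}$ per residue per patient (so a 500-aa protein
expects $r L n = 2.5$ occurrences per cohort), log-normal protein lengths
around 500 aa, variant classes drawn in colon-exome-like proportions
(~80% nonsynonymous SNVs, ~12% frameshift insertions, ~7% stop-gains).
These sizes complete a full pipeline run in about a second, which is what
makes the 20-replicate calibration and power suites practical; all are
overridable. The property suites assert, at these fixed conditions: at most
2% of tested regions called significant on pure-null cohorts, and at least
90% recovery of planted drivers with multiplier 10 on tested-length regions
(20 seeds each).

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: trinucleotide mutational signatures and other
sequence-context rate variation, covariate structure in the background rate
(expression, replication timing, chromatin), hypermutator patients (real
cohorts have per-patient burdens spanning two orders of magnitude),
recurrent hotspot positions within domains, and realistic gene/domain
identifier structure. The calibration results say the statistics behave
under the model's own null, not that the uniform null is adequate for any
particular tumor cohort.

## Numerical choices and degenerate inputs

* Histogram bins span exactly the observed score range; a constant score
  ensemble (or a single tested region) cannot be fitted — `fit_local_fdr()`
  refuses, and `call_peaks()` degrades to "no lfdr, nothing significant"
  with a warning rather than failing a whole pipeline run on a toy input.
* The truncated-normal likelihood is optimized by Nelder–Mead from the
  central band's moments; on failure (non-convergence, degenerate band) the
  theoretical null is used, with a warning.
* $f(z)$ is floored at the smallest positive double before the ratio, and
  lfdr values are clipped to $[0,1]$.
* Ties in representative-isoform length break by accession; output tables
  sort by descending $\hat p$ with ties by region id; the landscape-map
  layout shuffles grid cells with a caller-supplied seed — all so that a
  fixed configuration reproduces byte-identical outputs.
* `background_rate()` errors on an all-empty universe ($\sum L = 0$), and
  `bernoulli_z()` requires $0 < p_0 < 1$: an all-zero-count landscape has no
  testable signal and is reported as an error rather than a full set of
  z = 0 regions.

## Known limitations

The background model is a single pooled rate: regions whose true passenger
rate is elevated for non-selective reasons will inflate z. Domain-level
aggregation is restricted to annotated domain regions — mutations in linkers
and unannotated regions are visible to the gene landscape only. The lfdr
fit inherits Efron's assumptions (a dominant null component and a smooth
marginal); landscapes with a large fraction of true peaks will see $\pi_0$
and the central-band fit degrade. And the per-gene breakdown attributes a
mutation to every domain covering it, so overlapping-domain architectures
double-attribute at the breakdown level even though each domain's own count
is correct.
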