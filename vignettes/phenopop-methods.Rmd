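---
title: "Methods: temporal isolation, hybrid classification and divergence scans"
author: "phenopop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal isolation, hybrid classification and divergence scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenopop)
```

## The problem

Closely related insect taxa that look alike can only be told apart
genetically, which makes it hard to know whether they are reproductively
isolated by *timing*: if two taxa fly (and mate) in different weeks, or in
different years, gene flow is limited even without intrinsic barriers.  The
canonical case handled here is a two-taxon spruce budworm system in western
Canada: one taxon univoltine and earlier-flying, the other largely biennial
(adults abundant only in alternating "parity" years) and later-flying, with
rare F1 hybrids.  `phenopop` packages the full analysis chain for such a
study — interval pheromone trapping over two seasons at ~10 locations,
SNP genotyping of subsamples, genotype-based taxon assignment, flight-period
overlap quantification at two spatial grains, degree-day phenology, and
genome scans for divergent selection — together with a synthetic-data
generator so that every stage is testable end to end without any external
download.

## Genotype container and SNP filters

Genotypes are biallelic alternate-allele dosages (0/1/2, NA missing) in a
`GenotypeMatrix`, a `RangedSummarizedExperiment` whose rows carry scaffold
coordinates.  `filterVariants()` applies the three locus filters in a fixed
order:

1. call rate ≥ 0.95 (i.e. ≤ 5% missing per SNP, the VCFtools convention for
   a "95% missing data threshold");
2. minor-allele frequency ≥ 0.10, computed over all individuals pooled
   (filtering precedes clustering; per-group refiltering is applied again
   inside `substructure()` and `groupedScans()`);
3. distance thinning: within each scaffold, loci are scanned in position
   order and any locus closer than 10 kb to the last retained locus is
   dropped.  Keeping the *first* locus of each window makes the result
   deterministic and independent of input row order.

Whether MAF filtering precedes or follows thinning is not observable from a
filter-count report alone; the order above is fixed and reported in the
`FilterReport`, whose counts always satisfy input = output + removed.

## Ancestry: PCA, EM admixture, number of clusters

`genoPca()` mean-imputes missing dosages per locus, centers, and takes a
truncated SVD — scores are deterministic up to sign.

`fitAdmixture()` is a maximum-likelihood admixture model: each of an
individual's two allele copies derives from cluster *k* with probability
`Q[i,k]` and is then the alternate allele with probability `P[k,l]`, so
dosages are Binomial(2, QP).  It is maximized by expectation–maximization
(the classic frequency-estimation updates), which guarantees a monotone
log-likelihood; iteration stops when the change drops below `tol` (1e-6)
or at `maxIter` (500).  Missing genotypes contribute nothing to the
likelihood.  This deterministic, desk-scale model replaces the Bayesian
MCMC clustering used interactively in field studies; it shares the Q/P
parameterization but has no location-prior feature.  Replicate runs from
different seeds are aligned by greedy cluster matching on the correlation
of allele-frequency rows (a stand-in for post-hoc replicate alignment
tools) and averaged.

`selectK()` reports both standard criteria: mean log-likelihood per *k*
("LnP(k)") and the second-order Evanno-style statistic
Δk = mean(|L(k+1) − 2L(k) + L(k−1)|) / sd(L(k)), defined only for interior
*k* and flagged undefined when the replicate sd is zero.  The chosen *k* is
the Δk argmax, with an LnP(k) fallback when no Δk is defined; a flat
surface is flagged ambiguous rather than resolved silently.

`assignSpecies()` applies a strict > 0.90 membership rule: an individual at
exactly 0.90 is *ambiguous* (forwarded to the hybrid classifier); ties at
the threshold are never resolved in favour of a species.  Cluster-to-species
naming is by
anchor individuals supplied by the user — the geographic reasoning that
names clusters in a real study is not something the model can infer.

## Hybrid categories

`buildHybridModel()` estimates per-locus parental allele frequencies from
reference panels (in practice, individuals with > 0.99 admixture
membership) with additive smoothing 0.5 (Jeffreys-style), which keeps
frequencies strictly inside (0,1) so fixed differences cannot produce
zero likelihoods.  Each of the six classes — P1, P2, F1, F2, BC1, BC2 —
has Mendelian mixing proportions (π0, π1, π2) over the number of
parental-1-origin allele copies; per locus,

P(g | class) = π2·HW(g; p1) + π0·HW(g; p2) + π1·M(g; p1, p2),

where M is the genotype distribution of one allele drawn from each
parental pool.  Log-likelihoods are summed over non-missing loci and
combined with a uniform prior over the six classes (configurable).  Fixing
the parental frequencies from panels is a deterministic approximation of
the joint MCMC used by the standard hybrid-category tool; with hundreds of
ancestry-informative SNPs the parental frequencies are essentially known,
and the approximation is exercised in the tests (simulated F1s at
study-scale divergence receive F1 posteriors above 0.99).

`hybridizationRate()` is n(F1) / (n(F1) + n(P1) + n(P2)); F2 and
backcross individuals are reported but excluded from the denominator, and
the formatted output follows the "x% (a of b)" convention, with the F1s
included in the denominator (so 5 F1 among 169 parentals prints as
"2.9% (5 of 174)").

## Flight-period overlap at two grains

`presenceIndex()` is (collection periods with both taxa) / (periods with
either taxon).  At the by-location grain it is computed per sympatric
location and *unweighted*-averaged ("averaged across these locations");
a weighted option exists.  At the pooled grain, presence is unioned across
locations per (year, interval) first.  Years are never merged: a 2017
interval is never pooled with a 2018 interval.  `abundanceIndex()`
replaces presence by individual counts: the numerator counts *both* taxa's
individuals in co-occurrence intervals (the conjunctive reading of "the
total number of individuals of both species collected in the same
interval"); a minority-only numerator is available behind a flag.  F1
hybrids count toward neither taxon.  An individual's collection date is
its interval's trap-emptying date — the only date a trap study records.

The two grains answer different questions: pooling asks whether the taxa
fly at the same *time of year* anywhere in the region; the by-location
grain asks whether they actually meet.  On synthetic data with staggered
local phenologies the pooled index is several times the by-location index,
which is the qualitative pattern that motivates computing both.

`flightSummary()` compares flight timing (dates or accumulated
degree-days) with a Wilcoxon–Mann–Whitney test: U from midranks (both
orientations U1 and U2 are reported, since published U values rarely say
which), a tie-corrected normal-approximation p, and the effect size r
under both conventions — rank-biserial |1 − 2U/(n1·n2)| and |Z|/√N —
labelled, because printed r values are usually not attributable to one
convention.

## Degree-days

`singleTriangulation()` approximates the diurnal temperature curve as a
triangle from tmin up to tmax and back, and accumulates the area above the
lower developmental threshold T_L = 5.5 °C:

* tmax ≤ T_L → 0;
* tmin ≥ T_L → (tmax + tmin)/2 − T_L;
* otherwise → (tmax − T_L)² / (2 (tmax − tmin)).

The two regimes meet continuously at tmin = T_L (both give
(tmax − T_L)/2).  An upper threshold (38 °C for the univoltine taxon) is
implemented by subtracting the apex triangle but is off by default —
summer temperatures at boreal trap sites essentially never reach it.
`calibrateTemperature()` aligns weather-station series to on-site loggers
by the median logger-minus-station difference over paired days, computed
separately for daily highs and lows (one shared correction is a flag
away), applied from 1 January.  The logger-vs-station comparison test is
the unpaired rank-sum test by default, as such comparisons are usually
printed, with the paired signed-rank variant behind a flag.
`ddAtCollection()` joins cumulative degree-days to individuals by
(location, collection date), inclusive of the collection day (documented,
configurable).

## Divergence scans

`wcFst()` computes the Weir–Cockerham (1984) variance components a, b, c
per locus and the genome-wide ratio-of-sums Σa / Σ(a+b+c).  Loci where a
group has no called genotypes are undefined and excluded from the sums.
Note that published scan tools report their own model-based F_ST
estimates, so small discrepancies from the Weir–Cockerham values are
expected.

`bayescanScan()` reimplements the standard Bayesian outlier model for
biallelic counts: group allele frequencies follow a beta distribution
around a locus ancestral frequency π_i with precision
θ_ij = (1 − F_ij)/F_ij and logit(F_ij) = α_i + β_j.  A reversible-jump
MCMC toggles the locus selection term α_i with prior odds 10 for
neutrality; birth proposals draw α from its N(0,1) prior, so the prior
density cancels and the acceptance ratio is the likelihood ratio divided
by the prior odds.  β_j has a N(−1,1) prior; π_i is uniform, updated on
the logit scale with the Jacobian term.  Pilot runs adapt all random-walk
proposal SDs toward 25–45% acceptance.  Default chain settings are prior
odds 10, thinning 10, 20 pilot runs of 5000, burn-in 50 000, 10 000 output
iterations; a `"reduced"` preset (5 pilots of 500, burn-in 5000, 2000 kept
samples) is used for routine runs and testing.  Posterior inclusion
probabilities are converted to q-values by the posterior-odds FDR
convention — rank loci by inclusion probability and take the cumulative
mean of (1 − PIP) — with decisions at q ≤ 0.05.  A chain whose
ancestral-frequency acceptance falls below 5% is flagged as non-mixing in
the diagnostics.  `unionOutliers()` merges the outlier lists of replicate
runs, keeping per-run provenance.

## Genotype–environment associations

`geaScan()` follows the latent-factor regression idea: confounding
population structure is captured by the top-K left singular vectors of the
centered genotype matrix; each locus is regressed on each standardized
environmental variable plus the factors; the environment coefficient's
z-score is recalibrated by the genomic-inflation factor
λ = median(z²)/0.456 before p-values and per-variable Benjamini–Hochberg
q-values.  The closed-form SVD-factor regression replaces the exact
ridge-penalized estimator of the cited latent-factor method; it shares the
same confounder-adjustment structure and is exact at K = 0.  K is taken
from the admixture K-selection for the group being scanned.
`strongestVariable()` resolves loci significant for several (spatially
correlated) variables by the largest median |z| across replicate scans —
medians are taken across replicates per variable, then the argmax across
variables — with lexicographic, flagged tie-breaks.  Groups whose
individuals span fewer than three distinct-environment locations are
refused as rank-deficient.

## The synthetic-data generator

`simulateStudy()` emulates the study design so the whole chain can be
validated against known truth:

* **Genotypes.** Balding–Nichols divergence: ancestral frequencies uniform
  on [0.1, 0.5]; each taxon's frequency Beta-distributed around the
  ancestral value with variance parameter F = 0.34, the observed
  between-taxon divergence (the single-parameter model matching an F_ST
  summary).  2831 loci on 400 synthetic scaffolds at uniform random
  positions (so 10-kb thinning is exercised), 2.79% missing calls.
  Class composition defaults to the study's: 102 + 153 parentals and 5 F1;
  F2 and backcrosses default to zero but are fully supported (F1 = one
  gamete from each parental pool, F2 = two F1 gametes, BC = F1 gamete +
  parental gamete).
* **Temperatures.** An annual sinusoid (mean 2 °C, amplitude 16 °C, peak
  mid-July) shifted per location, with AR(1) daily anomalies; loggers =
  station + fixed per-location offset + observation noise, tmax clamped
  ≥ tmin.
* **Phenology.** An individual emerges on the first day its location's
  cumulative degree-days (5.5 °C threshold, from 1 January) reach its
  taxon threshold plus N(0, ddNoiseSd) noise: defaults 600 °C·day for the
  earlier taxon and 830 for the later — roughly a three-week flight
  offset under the default climate.  Hybrids use the parental midpoint,
  reflecting the hypothesis of intermediate developmental rates
  (configurable).  The biennial taxon flies only in its parity year except
  a 5% off-year fraction ("a year of very few adults").
* **Trapping.** Emergence dates are binned into 10-day intervals over a
  1 June – 3 September season; per location-interval, min(available, 10)
  individuals are genotyped, and the earliest and latest emergers of each
  location-season are always kept.  Out-of-season emergers are excluded
  and counted.

Two generator parameters are genuinely free (no published value) and were
fixed once on field realism: the within-season emergence spread
`ddNoiseSd = 60` °C·day (≈ 5 days, so each location's flight period spans
2–3 collection intervals, as trap histograms typically do) and the
between-location climate offsets, spanning +4 to −4 °C across the ten
default locations (sites in such studies span several degrees of latitude
and hundreds of meters of elevation).  The offsets stagger local
phenologies in calendar time, which is what makes the pooled and
by-location overlap grains diverge.

What the generator does **not** emulate: linkage (loci are independent, so
thinning's effect on downstream statistics is structural only), dispersal
between locations, host-plant bud-flush timing, read-level sequencing
error, and any geographic cline within taxa.  Passing tests therefore
validate the statistical machinery, not these field phenomena.

## Problem sizes and numerical choices in the test-suite

The tests run the generator at reduced sizes chosen to keep the suite
brisk while preserving the regimes of interest: 400-locus panels for
classifier and admixture recovery (the size used for hybrid classification
in practice), 500-locus scans with 30 + 30 individuals for outlier
calibration and power (reduced chains), 2000 loci for realized-F_ST
checks, and 50-locus studies where only phenology matters.  Oracles are
kept independent of the implementation: triangle areas come from a
segment-clipping geometric computation, Mann–Whitney U from exhaustive
pair counting, Weir–Cockerham components from a direct scalar evaluation
of the published formulas, BH discoveries from a step-up re-implementation,
and EM log-likelihoods are benchmarked against a grid search over
memberships at fixed true frequencies.

## Known limitations

* The admixture model ignores linkage and inbreeding; memberships are
  maximum-likelihood point estimates without credible intervals.
* Fixed-parental-frequency hybrid classification slightly understates
  uncertainty when panels are small; the smoothing constant matters below
  ~10 panel individuals.
* The reversible-jump scan's prior-as-proposal birth move mixes slowly for
  weak outliers; the pilot adaptation targets the random-walk moves only.
  Posterior inclusion probabilities for borderline loci are therefore
  conservative at reduced chain lengths.
* The genomic-inflation recalibration assumes most loci are null; scans of
  very small SNP panels with pervasive signal would be over-corrected.
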