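---
title: "Models and methods behind polysomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind polysomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polysomics)
library(dplyr)
```

`polysomics` analyses label-free (LFQ) polysome profiling proteomics: MS
quantification of proteins across sucrose-gradient fractions — monosomes
(F1) through heavy polysomes (F5) — and matched total lysates (T), under
unstressed, oxidative-stress (H₂O₂) and histidine-starvation (3-AT)
conditions. This vignette describes the statistical models the package
implements, the choices made where the design was genuinely open, and what
the synthetic-data generator does and does not emulate.

## The data model

All stages consume a *long* intensity tibble: one row per
(protein, condition, fraction, replicate) with a non-negative LFQ
intensity. A value of 0 always means "not quantified" (the MaxQuant LFQ
convention), never a measured zero; every estimator in the package
therefore works on the strictly positive replicate values and records how
much signal was available. Readers for the MaxQuant `proteinGroups` /
`peptides` dialects remove contaminant, reverse-decoy and
identified-by-site rows at load time.

## Ribosome association

For protein $p$ in condition $c$ the fraction sum is
$$\mathrm{FS}(p,c) = \sum_{f \in F1..F5} \overline{\mathrm{LFQ}}(p,c,f),$$
the sum over ribosomal fractions of the mean across strictly positive
replicates (a fraction with no signal contributes 0). Association is
$\log_2(\mathrm{FS}/T)$ with $T$ the replicate-mean total intensity, and
the estimated ribosome-associated proportion is
$$\%\,\text{ribosomal} = 100 \cdot \frac{\mathrm{FS}/T}{L},$$
with loading factor $L = 30$ by default. $L$ encodes how much more
fraction material than total material was analysed at the bench; it is a
configuration parameter, not a universal constant. Estimates above 100%
are reported uncapped with a flag, since capping would hide calibration
problems.

Replicates are averaged on the raw intensity scale *before* the ratio, so
FS stays in intensity units and all replicates enter symmetrically; the
alternative (per-replicate ratios averaged afterwards) differs only at
second order in the noise but is undefined whenever a single replicate
lacks a total.

## The ribosomal-protein null for stress effects

The stress effect per protein is
$\Delta \mathrm{FS}/T = \log_2(\mathrm{FS}/T)_{stress} -
\log_2(\mathrm{FS}/T)_{unstressed}$. Under stress, ribosomes run off
polysomes into monosomes, so core ribosomal proteins redistribute across
fractions — but their *summed* fraction signal barely changes. Their
$\Delta$ values therefore estimate the spread of non-changing proteins,
and the package fits a normal null
$\mathcal N(\mu_{RP}, \sigma_{RP}^2)$ per stress condition (sample mean
and n−1 standard deviation over all annotated RPs with defined deltas; no
outlier trimming) and reports two-sided p-values
$2\Phi(-|\Delta - \mu_{RP}|/\sigma_{RP})$, the direction of change, and a
Benjamini–Hochberg column for reference (headline significance uses the
raw p at $\alpha = 0.05$, both directions flagged).

**What calibration means here, and its limits.** The single-sigma null
assumes protein-exchangeable noise. Two realistic features of the data
violate it mildly, and deliberately remain in the generator's defaults:

* *intensity-dependent dropout* leaves low-abundance proteins with fewer
  positive replicates, hence noisier deltas than the RP-dominated fit —
  at the default 15% missingness the type-I error at $\alpha = 0.05$
  stays within sampling error of nominal, but the p-value distribution is
  detectably non-uniform at $n = 10^4$;
* *stress run-off* concentrates RP fraction weight into F1, inflating RP
  delta variance by a few percent relative to non-shifting proteins
  (conservative for the latter).

The package's calibration checks therefore run on the *fully null*
configuration (no engagement change, no redistribution, no dropout),
where p-values are uniform. Even there, a subtlety matters at scale:
because $\mu_{RP}, \sigma_{RP}$ are estimated from a finite RP set and
shared by every p-value, a naive KS test of $2\times10^4$ pooled p-values
against the uniform rejects far more often than its nominal level — the
classic composite-null (Lilliefors) effect. The acceptance checks refer
the observed KS statistic to its Monte-Carlo distribution under the
fitted-null procedure, which is the correct reference.

## Enrichment profiles and clustering

A profile cell is the mean of $\log_2$ intensities across positive
replicates (a geometric mean on the raw scale, matching the log-scale
definition of the profiles), for each (condition, fraction) column over
T and F1–F4 by default. Each protein is centred by its own mean across
the *unstressed reference fractions* — F1–F4 by default, with an F1–F5
option; both conventions appear in the field and the package supports
either, defaulting to the fractions actually present in the clustered
matrix. Proteins missing any required cell are excluded, never imputed:
imputation would manufacture profile shape exactly where the data are
least trustworthy.

Clustering is agglomerative with Euclidean distance and complete linkage.
The package implements the agglomeration itself rather than calling
`stats::hclust`, for one reason: reproducibility under ties. Centred
log-ratio profiles frequently contain exactly duplicated rows (e.g.
noiseless or archetypal data), and `hclust`'s merge order for tied
distances depends on input order. Here, tied merges are resolved by the
lexicographically smallest pair of minimum member labels, making the
merge sequence — and hence cluster labels — invariant to row order.
`stats::hclust` remains the independent reference: on tie-free instances
the two produce identical heights and cophenetic matrices (verified
exhaustively in the tests), and an $O(n^3)$ from-scratch oracle checks
the linkage recurrence independently. Complete-linkage reducibility
guarantees non-decreasing merge heights, which the constructor asserts.

The tree is cut to exactly $k$ clusters ($k = 14$ by default; a count cut
is deterministic where a height cut would not be). Labels are renumbered
along the ribosome-association gradient — cluster 1 least associated,
cluster $k$ most — matching the published low-to-high ordering of this
analysis style; without an association table the mean profile value over
fraction columns serves as the proxy. Each cluster is classified from its
mean stress-condition profile: `Mono` if F1 exceeds the F2–F4 mean by
more than $\tau = 0.5$ log2 units, `Poly` if it falls below by more than
$\tau$, else `Even`. $\tau$ is configurable; 0.5 (a 1.4-fold contrast) is
half the spacing that visually separates the published cluster classes.

Whether total-lysate columns belong in the distance computation is an
open design point: they carry each protein's overall association (a
continuous quantity) rather than its profile *shape*. The package
includes them by default, with `include_totals = FALSE` to cluster on
shape alone — the setting used for planted-partition recovery tests,
where the planted truth is the shape archetype.

Marker-relative profiles (`rp_relative_profile()`) normalise each protein
to the designated reference RP group (Rps3/uS3 in the original design) on
a fraction-by-fraction basis and then to the protein's own unstressed-F1
value, so the marker itself maps to 1 everywhere.

## Peptide positional-bias control

If nascent chains contributed to the gradient signal, peptides near the
N-terminus would be over-represented in fraction samples relative to
totals (partially synthesised chains have their C-termini missing). The
control statistic builds, per protein and sample, the cumulative N→C
intensity curve: peptide intensity spread uniformly over the peptide's
inclusive residue span, summed per residue, cumulated, and normalised.
Uniform spreading preserves the residue axis without inventing a
point-mass convention; assignment to the start residue is available as an
option. Curves from each gradient fraction (or the pooled fractions) are
compared with the totals curve by $D = \max_r |F_{frac}(r) - F_{tot}(r)|$
with the sign at the maximising residue reported (positive = N-bias in
the fraction).

Only proteins exceeding *both* dataset medians — distinct peptide count
and sequence coverage (union of inclusive spans over protein length),
strict inequality, ties excluded — are tested; below that the curves are
too coarse to be meaningful.

The asymptotic p-value treats the curves as two-sample empirical CDFs
with the peptide counts as effective sample sizes. This is an
approximation: intensity weighting means a curve carries less information
than its peptide count when a few peptides dominate, making the
asymptotic p anti-conservative in that regime. The package therefore also
offers a permutation p-value (pooled relabelling of peptide observations
preserving group sizes, seeded, $(1+\#\{D^* \ge D\})/(B+1)$). On dense
tilings with comparable peptide intensities and moderate $D$, the two
agree within a factor of ~1.5; under strong N-ramps the permutation null
conditions on the H1-dispersed weights and is the one to trust. Raw
p-values are Bonferroni-corrected by the number of comparisons actually
performed (per-protein × per-fraction-sample by default).

## The synthetic-data generator

`simulate_experiment()` draws, per protein: a total abundance
$A = 2^{N(20, 2^2)}$ (spanning the ~6 orders of magnitude typical of
LFQ); an engaged fraction $\pi \in [0.05, 0.95]$ (0.02–0.10 for the
low-association archetype); and fraction weights $w(F1..F5)$ from one of
five archetypes (RP-like and monosome-shifted profiles move
`stress_runoff = 0.5` of their polysomal weight into F1 under stress;
polysome-retained and even profiles do not). Expected signals are
$T = A/L$ and $F_f = A \pi w_f$; observations multiply in log-normal
noise with CV 0.2 and are zeroed with probability
$\mathrm{logit}^{-1}(s(m - \log_2 x))$, midpoint $m = 12.6$ and slope
$s = 1$, chosen once to give ~15% marginal missingness under the default
abundance model — left-censored-like missingness, not MCAR, because
detection failures concentrate at low signal. Defaults follow the real
design: 3 conditions × 6 samples × 4 replicates, $L = 30$. Neither the
replicate CV nor the dropout rate of the real experiment is published;
0.2 and 15% are generator conventions consistent with replicate
correlations $r^2 > 0.9$ and the sparser detection of weak stressed
fractions. Planted stress effects (`frac_pi_change`, `pi_change_fold`)
are drawn among non-RP proteins only, because RPs are by construction the
non-changing anchor that defines the null.

`simulate_peptides()` tiles 7–25-residue peptides at random positions
(counts Poisson, proportional to protein length, so the median-based
eligibility filter has a spread to work on), with a per-peptide base
intensity shared across samples by default (peptide "flyability" is a
property of the peptide) and an optional exponential N-terminal ramp
$e^{-b \cdot \mathrm{pos}/L}$ applied to fraction samples only.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: protein-specific noise variances, correlated
missingness across fractions, ratio compression from co-eluting peptides,
shared peptides between protein groups, batch effects between conditions,
and any disagreement between bench loading and the nominal factor $L$.
Recovery of $\pi$ to machine precision on noiseless data validates the
estimator algebra, not the bench calibration.

## Numerical conventions

* Replicate means use only strictly positive values; all-zero cells are
  flagged (`no_total`, `no_fraction_signal`) rather than silently
  dropped, and never imputed.
* Reference-condition deltas are exactly 0 by construction (not a
  subtraction of two equal floats).
* The RP null refuses to fit with fewer than 3 RPs or zero variance.
* Merge ties in clustering break lexicographically (see above); merge
  heights are asserted non-decreasing.
* All simulation and permutation randomness flows from explicit integer
  seeds; `run_pipeline()` fans a single seed out to fixed per-stage child
  seeds so partial re-runs reproduce.
* Result TSVs serialise doubles with `%.17g` (round-trip exact), and the
  JSON manifest excludes filesystem paths so identical analyses produce
  byte-identical bundles.

## Problem sizes used by the checks

The packaged checks run at desk scale, chosen to make each property
measurable with comfortable margins: 300 proteins for exact noiseless
recovery (tolerance $10^{-9}$); $10^4$ proteins for null calibration
(type-I within 3 binomial SEs, KS against the Monte-Carlo fitted-null
reference at $\alpha = 0.01$); 2000 proteins with a planted 2-fold
engagement drop on 10% (power ≥ 90%, false flags ≤ 7%); 100 random
instances of up to 20 profiles against the reference linkage; 300
proteins across 3 archetypes for partition recovery (ARI 1 at low noise,
≥ 0.8 at CV 0.3); 20 independent 200-protein unbiased datasets for the
peptide-test size (zero Bonferroni hits in ≥ 95% of runs) plus a
40-peptide, ramp-8 power fixture and an 80-peptide moderate-ramp fixture
for permutation agreement.

## Known limitations

* The percent-ribosomal scale inherits any error in the loading factor
  wholesale; FS/T comparisons between conditions are unaffected.
* The RP null is a single-variance model; under heavy dropout or strong
  redistribution its p-values are approximate (see above). A
  protein-specific variance model would need replicate-level modelling
  the published analysis does not attempt.
* The asymptotic KS p-value for weighted curves is approximate; use the
  permutation p-value when a few peptides dominate a curve.
* Pure-R agglomeration is comfortable to a few thousand profiles;
  beyond that the $O(n^2)$ memory of the distance matrix dominates.
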