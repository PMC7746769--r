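---
title: "Methods: benchmark matching and model-based clustering of protein digests"
author: "pepdigest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmark matching and model-based clustering of protein digests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepdigest)
```

## Scope and data model

`pepdigest` evaluates in vitro dietary protein digests against a benchmark
protein (typically whey protein concentrate, WPC) from LC-MS peptide
ion-peak tables, and clusters the resulting digest characteristics together
with biological read-outs from an intestinal assay panel. The unit of data
is the *peptide ion*: one detected LC-MS feature with mass-to-charge ratio
(Thomson), integer charge state, retention time (minutes) and raw abundance
(arbitrary units). A per-replicate collection of ions forms an `ion_table`;
seven assay variables per source and replicate form a `bio_readout_table`.
Retention time is minutes everywhere — inputs recorded in seconds are
converted at read time — because the matching tolerance is stated in
minutes.

## Ion-peak processing

Processing follows a fixed order, with an ion-count audit after every step
so that `n_observed = n_abundance_excluded + n_blank_excluded + n_retained`
holds for every table (the constructor of the audit object enforces the
identity):

1. **Abundance filter.** Ions with raw abundance strictly below the
   threshold (default `1e5`) are excluded; an ion exactly at the threshold
   is retained. The boundary convention comes from the exclusion being
   stated as "< 1e5".
2. **Blank subtraction.** Every ion for which at least one enzyme-blank ion
   passes the tolerance predicate is removed. Exclusion needs no ranking,
   so only the predicate is applied, which also makes the operation
   idempotent. The benchmark itself is blank-corrected before serving as
   reference (switchable), for consistency with the digests.
3. **Benchmark matching.** Two ions are candidate matches iff their charges
   are exactly equal and both |Δm/z| ≤ 0.003 Th and |ΔRT| ≤ 0.5 min,
   inclusive. Charge equality is exact because charge is an integer; the
   tolerance bounds are read inclusively from the "±" notation. Among
   candidates the nearest reference ion wins under the weighted Pythagorean
   distance
   $$ d = \sqrt{\left(\Delta m/z \cdot \tfrac{0.5}{0.003}\right)^2 + \Delta RT^2}, $$
   which makes one m/z tolerance equal one RT tolerance (0.003 Th ≡ 0.5
   min), expressed in retention-time-equivalent minutes.

Ties in the distance are broken deterministically: smaller |Δm/z| first,
then smaller reference ion identifier. The source is silent on ties; a
deterministic rule is required for reproducibility, and the specific choice
is immaterial at real data densities (exact ties need exactly equal
floating-point distances). Matching is directional — each digest is matched
to the benchmark independently, each query ion is assigned to at most one
reference ion, and several query ions may share a reference ion, in which
case their abundances are summed in the per-reference aggregate.

The implementation sorts reference ions by m/z within each charge stratum
and scans a tolerance window per query ion; a property test verifies that
its output is pairwise identical to an exhaustive O(n²) oracle on random
tables across 50 seeds.

## Digest characteristics

Per digest replicate, five characteristics are derived from the retained
(filtered, blank-corrected) table and its benchmark match:

* `frac_ditri`, `frac_oligo`: abundance-weighted fractions of ions whose
  *neutral mass* `(m/z − 1.007276) × z` is at most / above the size cutoff.
  The size mechanism is not specified upstream, so the package classifies
  by neutral mass with an inclusive cutoff of 425 Da by default (the upper
  range of common tripeptides), configurable. Absolute fraction values
  depend on this choice; comparisons between digests are stable under it.
* `total_abundance`: summed retained abundance.
* `n_unique`: retained ions with no benchmark match.
* `pct_overlap`: matched ions as % of retained ions.
* `pct_abundance_overlap`: matched-ion abundance as % of retained abundance.

An empty digest yields zeros with a warning rather than NaN, keeping the
feature matrix total. The two fractions sum to one by construction; overlap
percentages are invariant under uniform abundance rescaling while
`total_abundance` scales linearly — both properties are tested.

**Feature list for clustering.** The two size fractions are complementary,
so after column standardization they are *exactly* collinear
(z(frac_oligo) = −z(frac_ditri)). A matrix containing both has rank
deficiency that makes every full-covariance mixture family singular,
leaving only diagonal families in the sweep — an avoidable distortion of
model selection. The default `feature_preset("proteomic")` therefore keeps
`frac_ditri` only (five columns); both fractions remain in the exported
feature records, and the feature list is an explicit argument throughout.
The combined analysis uses the four columns
`total_abundance, n_unique, pct_overlap, pct_abundance_overlap` next to the
seven biological read-outs, giving the 11-column joined matrix with
biological variables outnumbering proteomic ones 7:4.

## Biological statistics

Replicate groups are screened with a two-sided single-outlier Grubbs test
at α = 0.05: `G = max|x − mean|/sd` against
`G_crit = ((n−1)/√n) · sqrt(t²/(n−2+t²))`, `t` the upper `α/(2n)` t-quantile
on n−2 degrees of freedom. A single pass removes at most one value per
group (an iterative mode is available but off by default — single-pass is
the conservative reading of a bare "Grubbs test"). A constant group has
G = 0 and no outlier.

Two power facts worth knowing: the statistic is bounded above by
`(n−1)/√n`, which at n = 3–4 sits barely above the critical value, so even
gross (8 SD) outliers are detected with under 50% probability in triplicate
groups; from n ≈ 5–6 upward detection of gross outliers is reliable. The
package's detection tests therefore use 6-replicate groups, while the null
calibration (empirical flag rate ≤ α + 3 Monte-Carlo SE over 10,000
simulations) holds at every n from 3 to 10.

Benchmark comparisons are two-sample t-tests per (source, variable) plus a
one-way ANOVA across sources per variable. The t-test is Welch by default —
the upstream description does not state the variant — with pooled variance
available via `var_equal = TRUE` (under which ANOVA with two groups
reproduces F = t², a tested identity). No multiple-testing correction is
applied by default, matching the stated "P < 0.05" rule; a
Benjamini–Hochberg option exists but is off.

## The mixture engine

Clustering operates on the sources × features matrix of replicate means,
column-standardized to mean zero and sample standard deviation one
(n−1 convention; standardization is idempotent and zero-variance columns
are an error naming the column).

Component covariances are parameterized by the eigen-decomposition
Σₖ = λₖ Dₖ Aₖ Dₖᵀ — volume λₖ > 0, diagonal shape Aₖ with det 1,
orthonormal orientation Dₖ — and the fourteen families EII … VVV constrain
each factor to be Equal across components, Variable, or the Identity.
Fitting is EM with family-constrained M-steps:

* Closed forms for EII, VII, EEI, EVI, VVI, EEE, EVV, EEV, VVV (the last
  two via per-component eigendecomposition of the scatter matrices, with
  eigenvalues aligned in decreasing order).
* Fixed-point iterations alternating volume and shape for VEI, VEV, VEE.
* For the shared-orientation families EVE and VVE, the orientation update
  minimizes `Σₖ tr(Dᵀ Wₖ D Bₖ)` over orthogonal D by
  majorization–minimization: each term is majorized at the current D using
  the largest eigenvalue ωₖ of Wₖ (so that ωₖI − Wₖ ⪰ 0) and the linear
  surrogate is minimized by the polar factor of `Σₖ (ωₖI − Wₖ) D Bₖ`.

All iterative M-steps warm-start from the previous EM iteration's
parameters and perform a small fixed number of block-descent rounds (four;
each round is itself monotone), so each M-step cannot increase the
objective — a generalized EM — and the observed log-likelihood is
non-decreasing at every iteration for every family — a
property asserted across seeds in the tests, alongside exact satisfaction
of each family's equality constraints by the realized covariances. In one
dimension only the volume letter is meaningful and families collapse to
equal or per-component variance.

Numerical choices: the E-step uses Cholesky factorization and log-sum-exp;
convergence is a relative log-likelihood change below 1e-8 or 500
iterations (both configurable); responsibilities' argmax ties break toward
the lower component index; an emptied component or a covariance singular
within machine tolerance marks the fit *degenerate* — reported as
non-converged with diagnostics rather than an error, and excluded from
model selection. Degeneracy is common by design when sweeping k up to 6
over 19 rows in 11 dimensions; the sweep table records it per (family, k).

Initialization is seeded k-means++ assignments (softened to
responsibilities), with `n_restarts` (default 10) independent seeded starts
keeping the best final log-likelihood per (family, k). The original
model-based hierarchical agglomeration initializer is deliberately not
reproduced: it is under-documented for reimplementation, and the selection
procedure — not the initializer — is the scientifically specified part.
Everything downstream of a seed is deterministic, and
`select_model(x, seed = s)` is bitwise reproducible.

Model selection maximizes BIC = 2·loglik − m·log n, with m the standard
parameter count (k·d means, k−1 weights, family-specific covariance count;
unit-tested against hand computation for d ≤ 3, k ≤ 3). Free-parameter
counts and the BIC sign convention follow the established convention in
which the best model is the BIC maximum, so "best = highest BIC" reads as
in the source literature. On data simulated from a 3-component
variable-orientation mixture at 4-SD separation (n = 500), the sweep
recovers k = 3 in at least 80% of 25 seeds; an independent mixture package
agrees on such data, and an independently coded spherical EM reproduces the
EII log-likelihood to 1e-6 from a shared start. The biological model being
reported once as diagonal (EEI) and once as full (EEE) upstream is an
internal contradiction of the source; both are runnable here and neither is
asserted as ground truth.

## Synthetic data: what it does and does not emulate

The generators stand in for raw data that cannot be regenerated without
proprietary peak detection. They are seeded and bitwise reproducible.

* `simulate_benchmark` places ions uniformly over the instrument windows
  (m/z 70–1200 Th, RT 0–40 min), charges 1–3, with all same-charge pairs
  separated by more than twice the tolerance radius in the weighted metric.
  The separation makes nearest-match ground truth unambiguous: a
  sub-tolerance jittered copy is strictly nearest to its parent and outside
  every other ion's tolerance box. Ambiguous near-duplicates — present in
  real data — are exercised separately by adversarial tie-break fixtures.
* `simulate_digest` builds `round(overlap_fraction × n_digest_ions)`
  jittered benchmark copies (jitter SDs 0.0008 Th and 0.1 min, i.e. 3.75 σ
  and 5 σ inside the tolerances, keeping > 99% of planted overlaps
  matchable), unique ions placed outside tolerance of benchmark and blank,
  and blank-contamination copies. The configuration exposes
  `n_digest_ions` as the size knob; the unique-ion count is the derived
  remainder (reported in the ground truth), since fixing both the overlap
  fraction and the unique count would over-determine the table size.
* Abundances are log-normal with ~25% of mass below the 1e5 threshold
  (meanlog = log(1e5) + 0.6745·1.2, sdlog = 1.2), so the abundance filter
  is always exercised.
* `simulate_bio_readouts` draws replicate values from planted per-cluster
  Gaussians over the seven assay variables, with optional injected
  outliers of at least 5 within-group SDs.

With zero jitter and threshold zero the full pipeline recovers the planted
overlap, unique and blank-contamination counts exactly; under default
jitter the measured overlap percentage is within one point of the planted
fraction at 2000 ions. Two caveats about interpreting such runs: the
generators produce no retention-time drift between runs, no isotope
envelopes or adducts, and no correlated abundance structure, so passing
tests demonstrate correctness of the *computational* pipeline, not
robustness to those instrumental effects (retention-time alignment is
explicitly out of scope). And when the benchmark itself is
abundance-filtered before matching — as the full pipeline does — jittered
copies of filtered-out benchmark ions can no longer match, so the
pipeline's measured overlap sits below the planted fraction by the
benchmark retention rate; planted-fraction recovery checks therefore match
against the unfiltered benchmark.

## Problem sizes in the validation suite

The test suite and the reference computations use deliberately moderate
sizes chosen to exercise every code path with comfortable statistical
margins: ion tables of a few hundred to 2500 ions, 18–19 sources with 2–3
replicates, mixture recovery at n = 500 in 3 dimensions over the full
14-family sweep with k ≤ 5 and 2 restarts, 25-seed selection replicates,
and 10,000-sample Grubbs null calibration per group size. The analysis
drivers under `analysis/` run an 18-digest synthetic study in triplicate at
comparable scale.

## Known limitations

* Size-class fractions depend on the neutral-mass cutoff; only relative
  comparisons between digests are cutoff-stable.
* The EM engine fits at most one component per distinct data mode it is
  seeded near; with 18–19 rows, BIC model selection is honest but
  high-variance, and degenerate (excluded) fits are expected for the
  richer families at larger k.
* Grubbs screening in triplicate groups has very low power (see above);
  this is a property of the test itself, not of the implementation.
* No retention-time warping, isotope/adduct collapsing, or peptide
  sequence identification: the pipeline starts from exported ion tables
  and ends at clustered characteristics.
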