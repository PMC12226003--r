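---
title: "Methods: phn cluster screening and oxic methane quantitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phn cluster screening and oxic methane quantitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phnomp)
```

# Scope

`phnomp` implements two computational arms used in studies of aerobic
("oxic") methane production from methylphosphonate (MPn) degradation by
heterotrophic bacteria:

1. **Survey arm** — detection of intact carbon–phosphorus (C–P) lyase gene
   clusters (`phnC`–`phnP`) in prokaryotic genomes from profile-HMM hits,
   with prevalence rollups by habitat and taxonomy.
2. **Incubation arm** — the quantitation chain from gas-chromatography (GC)
   headspace measurements to dissolved and total CH₄, volumetric
   production rates, CH₄/DOP consumption stoichiometry, and phosphate
   repression statistics.

A synthetic-data module plants clusters, decoys and incubation kinetics so
that every stage is testable without external genome databases or
instrument files.

# Survey arm

## The cluster-calling rule

Fourteen phn families are screened: the phosphonate ABC transporter
(`phnC`–`phnE`), the transcriptional regulator (`phnF`), the multi-subunit
C–P lyase core (`phnG`–`phnM`) and accessory genes (`phnN`–`phnP`). A
candidate cluster is **valid** when three conditions hold simultaneously
on a single contig:

* at least `k = 5` *distinct* phn families are present,
* their joint span — leftmost gene start to rightmost gene end, 1-based
  inclusive — is at most `W = 16000` nucleotides,
* the core families `phnK`, `phnL`, `phnM` are all present.

All three parameters (`W`, `k`, `core`) are arguments of `scan_contig()`
and `run_survey_pipeline()`. Several readings of this rule were genuinely
open, and the package fixes them as follows:

* **Distinct families, not hits.** Five tandem paralogs of one family do
  not make a cluster; duplicate copies count once toward `k`. This
  prevents tandem duplications from faking co-localization.
* **Core = all of phnK, phnL and phnM.** These encode essential C–P lyase
  subunits; a cluster missing any of them cannot catabolize phosphonates
  via this pathway. The core set is configurable for users who prefer an
  "any missing core gene disqualifies" reading with a different set.
* **Window metric = joint span of member genes.** The most literal
  "within a window" reading; the exhaustive test oracle uses the same
  metric, so the choice is self-consistent.
* **All 14 families count toward `k`**, including the regulator and
  accessories, because all 14 are screened.
* **Strand is ignored**; operonic phn clusters are typically co-oriented,
  but the rule imposes no strand condition and neither do we.

## Scanner and oracle

`scan_contig()` anchors a window at each phn gene's start and collects
every phn gene fully contained in `[start, start + W − 1]`. Because adding
a gene that fits inside a window can only add families, any valid gene
subset is contained in at least one anchored window's member set; anchored
windows therefore decide validity exactly. Non-maximal member sets are
dropped and overlapping calls are merged when the merged span still fits
`W`; otherwise overlapping windows are reported separately, and invalid
candidates are retained for audit.

`brute_force_scan()` is an independent oracle written in C++: it
enumerates *every* subset of phn-assigned genes by bitmask dynamic
programming, keeps those satisfying the three conditions, and returns the
maximal ones. It is exponential by construction (guarded at 25 genes) and
exists so that the production scanner can be checked against a
definitional implementation on hundreds of random contigs; the test suite
does exactly that on 500 seeded contigs.

## Trusted cutoffs and family assignment

`assign_families()` discards hits scoring below their family's trusted
cutoff (a per-model bit-score threshold above which hits are accepted
without further filtering) and keeps the single best surviving hit per
gene, breaking score ties by the lexicographically smallest family name so
results are order-independent. The package ships a table of *synthetic
default* cutoffs used by the simulator and tests
(`inst/extdata/phn_trusted_cutoffs.tsv`); real screens must supply the
trusted cutoffs of their own curated HMM models via `read_cutoffs()`.

## Prevalence reporting

`summarize_survey()` counts positives overall, per habitat (closed
vocabulary: freshwater, aquatic, soil, sediment, unknown) and per GTDB
phylum/order. Percentages are rounded half-up to one decimal place —
1445/16671 reports as 8.7%, 127/1153 as 11.0% — and
`format_approx_pct()` renders the whole-number form ("≈9%") used in
running text. `collapse_rare()` merges groups below 1% of positives into
"other" for display only; counts are never collapsed.

# Incubation arm

## From peak area to bottle inventory

GC peak areas are converted to headspace mixing ratios through an
ordinary least-squares calibration line over the standards (default
2.02, 4.99, 10.1, 100, 1000 ppm); the intercept is estimated by default
and can be forced through zero. `headspace_partition()` then reconstructs
the bottle inventory assuming full liquid–headspace equilibrium (bottles
are shaken continuously, so no kinetic transfer model is used):

* headspace amount from the ideal gas law,
  `n = x·P·V_head / (R·T)` with `R = 0.082057` L atm mol⁻¹ K⁻¹;
* dissolved concentration from the Bunsen coefficient,
  `C = β(T, S)·x·P / 22.414` mol L⁻¹, where β is evaluated from the CH₄
  polynomial of Wiesenburg & Guinasso (1979), with coefficients stored in
  `inst/extdata/ch4_bunsen_coefficients.yaml` so their provenance is
  auditable, valid over 273–313 K and 0–40 ‰ salinity.

Default geometry is a 125 mL serum bottle with 20 mL medium and 105 mL
headspace at 303.15 K, 1 atm and zero salinity; headspace pressure stays
at 1 atm unless configured, since biogenic overpressure at micromolar CH₄
is negligible. Reported concentrations are **totals (headspace +
dissolved) normalized to liquid volume**, which makes production rates
(nmol L⁻¹ h⁻¹) and the mass balance (µM) commensurable. A flag-level
alternative — dissolved-only reporting — is available by using the
`dissolved_umol_L` column directly. The partition is linear in the mixing
ratio, so `mixing_ratio_from_total()` inverts it exactly; this round-trip
is held to 10⁻⁹ relative error in the tests.

## Rates, stoichiometry, regulation

`production_rate()` defaults to a pooled least-squares slope of
concentration against time inside a window (replicates pooled into one
regression), with an endpoint `(ΔC/Δt)` method retained for comparison;
regression is the default because it is robust to single-timepoint noise.
Which estimator the headline rates of such experiments use is typically
unstated, so both are exposed.

`stoichiometric_series()` computes DOP pointwise as TDP − DIP, net
changes relative to the first timepoint, and the trajectory of
ΔCH₄/ΔDOP. Ratios are undefined (NA, never an error) where |ΔDOP| falls
below a floor, default 0.05 µmol L⁻¹ — roughly the precision of
colorimetric phosphorus determination, and small enough that the
lag-phase drawdown (≈0.24 µM at the default planted kinetics) remains
observable. Negative DOP values (TDP < DIP) are flagged and propagated,
never clamped.

`dose_response_trend()` summarizes a Pi-amendment series by the Spearman
rank correlation of mean final CH₄ against the initial Pi level, plus a
monotone-decrease verdict allowing a small upward wobble (default 5% of
the mean range) between consecutive levels.

`repression_test()` compares production rates before and after phosphate
addition with a two-sample t-test. The **pooled (Student) form is the
default**: at triplicate bottle sizes the Welch approximation is markedly
conservative (its empirical size at n = 3 + 3 is ≈0.035 at a nominal
0.05), whereas the pooled test is exact under the homoscedastic null that
identical replicate bottles represent — and with n = 3 per group there is
no practical power to detect variance inequality anyway. Welch remains
available via `var_equal = FALSE`. Both-groups-constant input returns
p = 1 (equal means) or p = 0 (different means) without division errors.

# The synthetic-data module

## What the survey generator emulates

`simulate_survey()` plants, per positive genome, a full 14-family operon
with gene lengths of 600–900 nt and intergenic gaps of 50–250 nt — a
compact architecture whose worst-case span (15 850 nt) is verified at
spec-construction time to fit the 16 kb window, so planted positives are
valid *by construction*. Each negative genome carries either background
genes only or exactly one decoy violating a single screening rule:
four-gene clusters (below `k`), core-less clusters (no phnK/L/M),
overspread clusters (gaps of 4.5–5 kb, so no window holds five genes),
clusters split across contigs with neither part valid, and intact
architectures whose bit scores sit below the trusted cutoffs. This gives
every filter a dedicated negative control. The planted positive count is
deterministic (`round(n × prevalence)`).

Habitat proportions default to freshwater 0.07 (matching the roughly 7%
freshwater share of large habitat-annotated genome collections), aquatic
0.35, soil 0.40, sediment 0.18; positives draw their lineages mostly from
Pseudomonadota, echoing the taxonomic skew such surveys observe. The
generator emits no nucleotide sequence — only coordinates, scores and
metadata — so screening sensitivity/specificity results say nothing about
HMM search quality on real sequence, only about the co-localization logic
downstream of the hit table.

## What the incubation generator emulates

`simulate_incubation()` plants a piecewise-linear CH₄ trajectory: a lag
phase (default 24 h) at `lag_rate` (default 4.0 nmol L⁻¹ h⁻¹) followed by
a production phase at `planted_rate` (default 92 nmol L⁻¹ h⁻¹). The
stoichiometric ratio trajectory is planted directly — `lag_ratio`
(default 0.4) through the lag, a linear ramp, then `asymptotic_ratio`
(default 1.0, complete dealkylation) from `ramp_end` (default 240 h)
onward — and DOP is derived as `dop0 − CH₄(t)/ratio(t)`. The lag-phase
rate and the lag-phase ratio are deliberately *independent* planted
parameters: they are distinct observables (4.0/92 ≈ 0.04 is not 0.4), and
the recovery tests require both. The coupling is planted through the
ratio rather than a mechanistic uptake model because the reported
statistic is the ratio; the generator's job is to make it recoverable,
nothing more.

Sampling follows the bottle-sacrifice schedule of a 12-day incubation:
every 6 h for the first 24 h, then every 48 h. Pi treatments (default
0–40 µM) scale both rates by a hyperbolic inhibition factor
`1/(1 + Pi/K)` with half-inhibition `K = 10` µM, a monotone-decreasing
choice consistent with reports of near-complete suppression above
~30 µM Pi. Headspace ppm values are back-computed through the same
partition model the quantitation chain inverts, so noise-free tables
round-trip to machine precision.

Measurement noise is Gaussian per observable: mixing ratios get
FID-style proportional noise (2% relative) plus a 0.05 ppm floor;
phosphorus pools get 0.3 µM absolute; cell counts 5×10⁴ mL⁻¹. Draws that
would go negative are resampled and counted (attribute `n_resampled`),
never silently clamped. The generator does not emulate instrument drift,
autocorrelated noise, replicate-bottle heterogeneity, or evaporative
losses — parameter-recovery results should be read with that in mind.

# Numerical choices and problem sizes

* Percentages round half-up (not banker's) to one decimal; the
  whole-number "≈" rendering rounds half-up to integers.
* Family-assignment ties break lexicographically; cluster calls are
  sorted by family count, span and membership, making all outputs
  order-independent and reproducible.
* All simulations take explicit integer seeds and restore the caller's
  RNG state.
* The test suite exercises the scanner–oracle agreement on 500 random
  contigs of up to 20 phn genes, planted-truth screening on 200 genomes
  at 10% prevalence, stochastic recovery on 100 noisy incubations, and
  the t-test's size on a 10 000-replicate null — sizes chosen to give
  stable Monte-Carlo estimates at interactive runtimes.

# Known limitations

* The survey arm consumes hit tables; it does not run HMM searches, so
  end-to-end sensitivity on real genomes also depends on profile and
  cutoff quality outside this package's scope.
* Habitat vocabulary is closed; metadata with richer biome labels must be
  mapped before use (unmapped labels become "unknown" and stay in the
  denominators).
* The equilibrium-headspace assumption breaks for unshaken bottles or
  very short equilibration times.
* `sequence_stats()` excludes ambiguity codes from the G+C denominator;
  published G+C figures computed with other conventions can differ in the
  last decimal.
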