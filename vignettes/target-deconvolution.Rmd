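---
title: "Target deconvolution from differential precipitation proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Target deconvolution from differential precipitation proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffpop)
library(dplyr)
```

## The problem

A small molecule that binds a protein usually stabilizes its folded
state. In differential precipitation profiling (DiffPOP), a lysate is
exposed to a ladder of increasing acidified-methanol concentrations and
the protein pelleted after each addition is quantified, giving each
protein a per-fraction precipitation profile. A ligand-bound target
resists solvent denaturation and precipitates later: its profile shifts
toward higher solvent concentrations relative to vehicle. Detecting
such shifts proteome-wide nominates the compound's direct targets
without any chemical modification of the molecule — valuable for
natural products that are scarce and hard to derivatize.

This package implements the downstream analysis of that experiment,
starting from protein-level intensity tables, together with the three
companion analyses such a target-deconvolution study leans on:
differential proteomics (TMT 6-plex and DIA) with a multi-cell-line
intersection, four-parameter logistic dose-response (IC50) fitting with
a selectivity index, and noncompartmental pharmacokinetics.

## The shift statistic and the candidate rule

For one protein, each replicate profile is normalized to per-fraction
shares (so total abundance cancels) and averaged within condition. With
$a_j$ and $b_j$ the mean vehicle and compound shares in fraction $j$,
the shift statistic is the Kolmogorov–Smirnov distance between the
cumulative profiles,

$$D = \max_j \left| \sum_{i \le j} a_i - \sum_{i \le j} b_i \right|
\in [0, 1],$$

zero when the cumulative profiles coincide and 1 for fully separated
profiles. With only nine fractions the asymptotic KS null distribution
is meaningless, so significance is a fixed quantile rule: the top 3% of
$D$ scores among scored proteins pass the rank cut
(`ceiling(0.03 * N)` proteins, exactly). Direction is summarized by the
intensity-weighted centroid in solvent percent; candidates must be
*stabilized* (positive centroid shift, precipitation delayed). The
default 9-step ladder is 2.62, 6.45, 11.98, 19.80, 30.53, 44.53, 61.38,
79.03, 87.50 % (v/v).

Before any protein is ranked it must pass a reproducibility gate: the
minimum pairwise Spearman correlation of its raw replicate profiles
must exceed 0.7 in both conditions. A replicate with zero variance
makes the correlation undefined and fails the gate. Proteins failing
the gate are reported with a reason but excluded from ranking, so they
cannot dilute the quantile cut.

Three design points were genuinely open and decided here:

* **Replicate combination.** Replicates are averaged *after*
  normalization, giving one $D$ per protein (lower variance, one
  ranking). Per-replicate-pair $D$ values are available as diagnostics
  (`score_shifts(replicate_ds = TRUE)`).
* **Direction metric.** The centroid uses the real ladder spacing in
  solvent percent rather than fraction indices, so a shift across the
  widely spaced upper steps counts for more than one across the dense
  lower steps. The argmax peak fraction (ties to the lowest index,
  1-based) is reported alongside for comparability with profile plots.
* **Significance.** The quantile rule is operative. A permutation
  p-value (condition-label shuffles within protein,
  `ks_permutation_pvalue()`) is provided as a diagnostic but is not
  part of the default candidate call: with 3 + 3 replicates only 20
  relabelings exist, so its resolution is coarse.

Missing fraction intensities are treated as zero after an
eligibility check (an absent pellet value means nothing precipitated at
that step); profiles with no positive value at all are unscorable and
reported as such. Ties in $D$ are broken by larger centroid shift, then
protein ID, making the output fully deterministic.

```{r diffpop-run}
sim <- simulate_diffpop(n_proteins = 300, n_targets = 5,
                        shift_delta = 25, noise_cv = 0.1, seed = 42)
res <- score_shifts(sim$data)
call_targets(res) |>
  select(protein_id, ks_stat, centroid_shift, peak_vehicle,
         peak_compound, quantile_rank)
sort(sim$truth$protein_id[sim$truth$is_target])
```

## What the simulator emulates — and what it does not

The generator is first-class, tested code: it defines the conditions
under which the pipeline's statistical behavior is verified.

Cumulative precipitation is modelled as a logistic function of solvent
concentration — the simplest monotone saturating curve consistent with
delayed precipitation under stabilization. Fraction $j$ receives
$A\,[F(c_j) - F(c_{j-1})]$ with $F$ centred at the protein's midpoint
(displaced by `shift_delta` under compound for planted targets) and
$F(c_0)$ evaluated at a notional 0% baseline rather than forced to
zero, avoiding a discontinuity for low-midpoint proteins. Noise is
multiplicative lognormal (mean-one), matching the positive,
heteroscedastic character of MS intensities; missingness is a hard
intensity threshold, the simplest mechanism reproducing low-abundance
dropout. Defaults mirror the motivating study's geometry: triplicates
per condition, the nine-step methanol ladder, 300-protein panels for
recovery experiments. No published effect-size scale exists for real
stabilization shifts, so the default `shift_delta` (15 solvent points;
25 in the noise-free recovery runs, at least two ladder steps in the
mid-range) is chosen for testability, not realism.

The simulator works at the protein level only. It does not emulate
peptides, spectra, retention-time alignment, search-engine scoring, or
correlated (structured) missingness, and planted shifts are pure
location displacements of an otherwise identical curve. Passing tests
therefore demonstrate that the *analysis* behaves as specified under
its own assumptions — exact selection counts, calibrated null rates,
monotone response to effect size — not that real lysate data meet those
assumptions.

Condition labels are fixed strings `"vehicle"` and `"compound"`;
mapping them to a study's DMSO/compound naming is the reader's concern.

## Differential proteomics

**TMT 6-plex** (3 vehicle + 3 compound biological replicates, channels
alternating as in the motivating design): missing reporter values are
imputed with the protein's lowest observed intensity across its six
channels; matrices are log2-transformed, median-centred and scaled to
unit SD per channel (MAD scaling behind a switch); the per-protein test
is an equal-variance two-sample t on log2 values (the balanced-design
choice), with raw p-values — no multiplicity adjustment, by design.
Volcano calls use p < 0.05 (strict) and |log2FC| ≥ 0.38 (inclusive);
0.38 on the log2 scale is about a 30% abundance change. On noise-free
data the test's zero-spread corner cases are defined explicitly: equal
means give p = 1, unequal means give the limiting value p = 0 with a
`degenerate` flag.

**DIA panels**: proteins must be quantified in at least 2 of 6
injections per condition to be testable; all six injections (3
biological × 2 technical) are then pooled as observations in a Welch
t-test on log2 intensities. Pooling technical with biological
injections is pseudo-replication; it is reproduced deliberately because
it is how the merged per-condition statistics are computed in this
design, and it is flagged here rather than silently corrected. The
four-cell-line intersection takes the per-line significant sets (up and
down calls; an up-only mode covers the stricter variant) and returns
the exact intersection plus every exclusive Venn region.

## Dose-response and selectivity

`fit_four_pl()` fits
$y = \text{bottom} + (\text{top} - \text{bottom}) /
(1 + (d/\text{IC}_{50})^{h})$ by unweighted least squares with the dose
on the log10 scale internally, the "log(inhibitor) vs response —
variable slope" convention. The fit is unconstrained (no asymptote
clamping) and deterministic: starting values come from the extreme-dose
response means, a log-dose interpolation to the half-response, and the
trend sign — no random restarts. If the initial Jacobian is singular
(which can happen when the IC50 start lands exactly on a design dose of
noise-free data) the start is nudged by fixed offsets and retried, still
deterministically. The selectivity index is the plain IC50 ratio of the
reference (non-tumorigenic) line over the test line, reported to one
decimal in summaries but returned at full precision so the reciprocal
identity holds exactly.

## Noncompartmental pharmacokinetics

AUC uses the linear trapezoidal rule throughout (determinism and exact
additivity over sub-intervals; a log-down variant is a possible future
switch). The terminal slope $\lambda_z$ is the best-adjusted-$R^2$
log-linear regression over candidate windows — every suffix of at least
3 points strictly after C~max~ — with ties to the longer window; this
is the standard convention that commercial NCA tools apply. Below-LLOQ
points are excluded entirely (no zero substitution), matching how
sub-quantification values are handled in the motivating study (LLOQ
23.2 nM there). For IV bolus data, C~0~ is back-extrapolated
log-linearly from the first two points and prepended for integration;
$\text{AUC}_\infty = \text{AUC}_\text{last} + C_\text{last}/\lambda_z$,
$\text{CL} = \text{dose}/\text{AUC}_\infty$, and
$V_{ss} = \text{CL} \cdot \text{AUMC}_\infty / \text{AUC}_\infty$.
Time above a therapeutic threshold locates crossings by log-linear
interpolation (linear fallback for non-positive brackets). Units
follow the inputs; dose is per kg while thresholds are typically molar,
so mixing mass and molar unit systems requires the compound's molecular
weight as an explicit conversion the caller performs.

```{r nca}
prof <- simulate_pk_profile(dose = 1, volume = 0.1,
                            elimination_rate = log(2))
glance(nca(prof, dose = 1, route = "iv", threshold = 1))
```

## Numerical choices and problem sizes

Normalized shares must sum to 1 within 1e-8 before the KS statistic is
computed; the statistic itself is validated against a brute-force
prefix-sum oracle to 1e-12. Channel normalization post-conditions
(median 0, SD 1) hold to 1e-9. The recovery and calibration experiments
in the test suite use 300-protein DiffPOP panels, 50–200-protein TMT
matrices over 200 seeds, 300-protein four-line DIA panels, and
400-point PK profiles — sizes chosen so every property is measured with
comfortable Monte-Carlo margins while the whole suite stays quick to
run.

## Known limitations

* Candidate counts from real deposited data (e.g. how many proteins a
  3% rule flags in a specific lysate) depend on upstream search and
  quantification software and are out of scope; the pipeline starts at
  protein-level tables.
* The Spearman gate is a hard threshold; proteins near 0.7 flip in and
  out under resampling.
* The quantile rule guarantees its own false-positive budget by
  construction but has no per-protein error rate; the permutation
  p-value is coarse with triplicates.
* DIA pooling of technical injections understates within-condition
  correlation (see above); a hierarchical variant is deliberately not
  provided.
* The NCA half-life/clearance/volume triplet is internally consistent
  under this package's conventions; values from commercial tools can
  differ slightly in window selection and back-extrapolation rules.
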