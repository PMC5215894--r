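---
title: "Inferring central-metabolic fluxes from targeted metabolomics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring central-metabolic fluxes from targeted metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxmet)
```

## The problem

Targeted LC-MS metabolomics measures the abundance of a few dozen central
energy metabolites in replicate samples at a handful of time points. fluxmet
turns such replicate intensity tables into estimates of the *average reaction
fluxes* of central energy metabolism over each time interval — which pathways
sped up, which reversed — without any kinetic parameters. The only biological
input is the stoichiometry of the network.

The pipeline has four stages:

1. **Accumulation**: for each metabolite, the rate of change of its abundance
   over an interval, with a variance and an inverse-variance weight.
2. **Flux fit**: a weighted bounded-variable least-squares (BVLS) problem over
   the stoichiometric matrix; bounds encode irreversibility.
3. **Exemplars**: linear-programming flux profiles that maximize a synthesis
   reaction, used as hypothesis references ("what would metabolism look like
   if it were optimized for collagen production?").
4. **Robustness**: randomization of the input table, correlation of the
   re-estimated fluxes with the originals, flux-accumulation correlation, and
   correlation-distance clustering of samples.

## Accumulation rates and weights

For metabolite $i$ with replicate abundances $a_0$ at time $t_0$ and $a_1$ at
$t_1$, the accumulation rate is

$$\Delta_i = \frac{\mathrm{center}(a_1) - \mathrm{center}(a_0)}{t_1 - t_0}.$$

The center is the median by default: with $n = 4$–$5$ replicates a single
outlier moves the mean substantially but leaves the median untouched
(`estimate_accumulation()` exposes `center = "mean"` as well). The variance
attached to $\Delta_i$ is the Welch variance of a difference of two means
with unequal variances, $s_1^2/n_1 + s_2^2/n_2$. Two notes on this pairing:

* The Welch formula is the variance of a difference of *means*; we keep the
  conventional pairing with median centers rather than switching to a
  median-specific estimator, because only the *relative* weights across
  metabolites reach the solver.
* Because $\Delta_i$ divides by $(t_1 - t_0)$, the variance carried forward is
  $(s_1^2/n_1 + s_2^2/n_2)/(t_1 - t_0)^2$, keeping the weight dimensionally
  consistent with the rate. For a single common interval this changes all
  weights by a constant factor, and the flux fit is invariant to a constant
  rescaling of the weights (this is asserted in the test-suite).

The weight is $w_i = \sigma_i^{-2}$. Metabolites with zero sample variance
would get infinite weight; the default policy caps their weight at the
largest finite weight (preserving the "most reliable" ranking), with an
epsilon-floor variance as an alternative. If *all* variances are zero the
data are degenerate and weighting errors out (an unweighted fit is still
available via `weights = "unit"`).

An ANOVA screen (`anova_screen()`) flags metabolites whose intensity changes
with time at a deliberately lenient $p \le 0.15$ — this is a screen to choose
metabolites for sample clustering, not a discovery threshold. Flat
(zero-variance) metabolites receive $p = 1$ by convention and are never
flagged. Both a one-factor (time) and a two-factor (time × group, with
interaction) variant are provided; the screening default is the one-factor
form.

An optional limit-of-detection floor (`lod`) can drop sub-threshold
intensities before any computation; it is off by default because the
threshold is instrument-specific.

## The stoichiometric model

The packaged network covers glycolysis (G1–G10), pyruvate processing into
acetyl-CoA (PYP), the TCA cycle (TCA1–TCA10), the pentose phosphate pathway
(PPP1–PPP8), the electron transport chain (ETC1–ETC3), anaplerotic reactions
(AP1–AP4), and the lactate and glutamate dehydrogenases: 52 metabolites by 38
reactions, transcribed from standard mammalian biochemistry. Conventions:

* consumed = negative coefficient, produced = positive; reversible reactions
  take the drawn direction as forward, and a negative fitted flux means a
  reversible reaction running backwards;
* the TCA cycle is numbered from citrate synthase (TCA1); succinate
  dehydrogenase is split into FAD reduction (TCA7) and ubiquinone transfer
  (TCA8), which also gives the ETC its entry point;
* lactate dehydrogenase is encoded irreversible toward lactate. Lactate is an
  unconstrained external pool (it is secreted into the medium); were LDH
  reversible, the exemplar LP below could import lactate carbon for free and
  bypass glycolysis entirely, which is not a biologically meaningful optimum
  for cells grown in high-glucose medium.

`reduce_to_measured()` adapts the network to what the instrument sees.
Unmeasurable *external* metabolites (glucose — swamped by the medium; O2,
H2O, CO2 — invisible to positive-mode LC-MS) cannot be constrained and their
rows are dropped. Unmeasurable *internal* metabolites are kept with their
accumulation pinned to zero so pathways stay connected. The only such
metabolites in the packaged network are the electron-transport carriers
(oxidized/reduced ubiquinone and the gradient protons): the cell tolerates
very little change in these pools, so zero accumulation is the right
constraint, but since it is an assumption rather than a measurement those
rows also receive the *lowest* weight among the measured ones. After adding
one synthesis column the reduced system is 48 rows × 39 columns with full
column rank 39, so the weighted BVLS fit has a unique solution.

### Synthesis reactions

Biosynthetic demand enters as one extra irreversible column that consumes
precursor metabolites (negative coefficients) and produces nothing inside
the network. For proteins the tracked precursors are 3-phosphoglycerate,
pyruvate, α-ketoglutarate and oxaloacetate; for lipid, acetyl-CoA.
`synthesis_from_sequence()` tallies an amino-acid sequence into precursor
demand with a fixed residue-to-family mapping (Ser/Gly/Cys → 3PG; Ala/Val/Leu
→ PYR; Glu/Gln/Pro/Arg → AKG; Asp/Asn/Thr/Met/Lys → OAA; Ile split 50/50
between PYR and OAA). Aromatic residues and histidine draw on precursors the
network does not track (erythrose-4-phosphate/PEP via shikimate only in
plants and microbes; His from PRPP) and are skipped with a logged count —
this is a documented choice, and the mapping is a plain replaceable table.
Coefficients are normalized to sum to 1 by default ("ratiometric" shares):
only the proportions shape a flux profile, and the unit scale keeps the
exemplar flux cap meaningful. A per-molecule (raw count) normalization is
available.

The packaged FASTA contains *synthetic, composition-based surrogate*
sequences for type II/VI collagen, aggrecan and albumin — sequences generated
to match the published amino-acid compositions, not the real proteins. Since
the synthesis column depends on the sequence only through its composition,
the surrogates give the same coefficients a real sequence of identical
composition would.

## The flux fit

With $S$ the reduced stoichiometric matrix and $\Delta$ the accumulation
vector, the fit solves

$$\min_v \lVert S_w v - \Delta_w \rVert_2 \quad \text{s.t.} \quad v_i \ge 0
\text{ for irreversible } i,$$

where row $i$ of $S$ and $\Delta_i$ are both multiplied by $w_i$. (Note this
row-multiplier convention means the implied generalized-least-squares weight
is $w_i^2 = \sigma_i^{-4}$; it is kept because it is the procedure this
pipeline reproduces.) The solver is a hand-written active-set BVLS
(`bvls_fit()`): optimize the free set by unconstrained least squares, clip
the step at the first bound crossing, release the bound variable whose
gradient most violates the KKT conditions, repeat. Subproblems are solved by
SVD, so a rank-deficient problem returns the minimum-norm minimizer with an
explicit warning rather than an arbitrary one. Convergence is certified by
the KKT conditions at tolerance `tol` (default 1e-10, relative to
$\lVert S_w^\top \Delta_w\rVert_\infty$), and the iteration cap is
$10 n^2$. The test-suite checks the solver against an exhaustive
active-set enumeration oracle and against an independent quadratic-programming
solver on random instances.

Zero-accumulation rows (the unmeasured internal metabolites) are weighted
rows with $\Delta = 0$ by default — the problem stays a pure BVLS. The
stricter reading, a hard equality, is exposed as `hard_zero = TRUE` and is
realized by weight escalation (1e8 × the largest weight) followed by a
feasibility check that errors if the hard rows' residuals exceed tolerance;
an exact equality-constrained implementation would require a general
linear-inequality least-squares solver and changes nothing at the tolerances
involved.

## Exemplar profiles

A hypothesis profile for "metabolism optimized toward product X" is the LP

$$\min_v c^\top v \quad \text{s.t.} \quad S_I v = 0,\; A v \ge 0,\; v \le 1,$$

with $c$ equal to $-1$ at the synthesis column and zero elsewhere, $S_I$ the
internal-metabolite rows (pathway intermediates balanced at steady state),
and $A$ selecting irreversible reactions. Two deliberate choices:

* **Boundedness.** The unit cap bounds every flux above but a reversible
  cycle can still run to $-\infty$; a symmetric lower cap of $-1$ on
  reversible reactions makes the program bounded in every direction. This is
  a well-posedness requirement, not a biological statement.
* **Degeneracy.** LP optima are typically non-unique. A secondary LP
  minimizes $\lVert v\rVert_1$ at the fixed optimal objective, so the
  reported profile is the sparsest optimal vertex and is deterministic
  across solvers and platforms.

The LP kernel is a small dense two-phase simplex with Bland's rule —
deterministic, immune to cycling, and adequate for a 39-variable program.
The exemplar tests include a brute-force vertex-enumeration oracle on a
branched toy network.

**Internal vs external classification.** The LP constrains only internal
rows. Media and secretion pools (glucose, glutamine, lactate, ammonium, O2,
H2O, CO2) are external: the network draws on or excretes into them freely.
The energy and phosphate currencies (ATP/ADP, GTP/GDP, Pi, NADP(H), free
CoA) are also classified external, i.e. buffered pools. This is a modeling
necessity as much as a convenience: the synthesis columns carry no ATP cost
(they consume carbon precursors only), so a network that must balance ATP
internally has no ATP sink at all and every synthesis LP collapses to zero
flux. Treating the currencies as buffered pools restores the biologically
intended optima. The redox carriers NAD(H), FAD(H2), ubiquinone and the
gradient protons stay internal — their balance is exactly what couples
glycolysis and the TCA cycle to the ETC.

With these choices the protein exemplar runs glycolysis with withdrawals at
3-phosphoglycerate and pyruvate (so the steps after each precursor carry
less flux than the step feeding it — the "protein-like" signature checked by
`profile_shape_features()`), supplies α-ketoglutarate by glutaminolysis and
oxaloacetate by pyruvate carboxylase, and the lipid exemplar maximizes
glycolysis into pyruvate processing. TCA-cycle flux is zero in both
exemplars of this transcription (anaplerotic supply of the precursors is
cheaper for the LP than running the cycle), so "evenness of the TCA
distribution" is not a usable discriminator here; pathway totals and the
precursor upstream/downstream comparison are. The four protein exemplars
differ only in precursor proportions and are mutually much closer (maximum
pairwise relative distance, $\lVert v_1 - v_2\rVert / \min(\lVert
v_1\rVert, \lVert v_2\rVert)$) than any of them is to the lipid exemplar;
this ordering is asserted in the tests. Because all proteins draw on the
same four precursors, exemplar profiles cannot identify *which* protein is
being made — only protein-like vs lipid-like metabolism.

The `upstream_mean`/`downstream_mean` feature compares the flux of the
step(s) *producing* a precursor with the mean flux of the pathway steps
after it. Comparing whole-segment means instead would be confounded by the
stoichiometric doubling at the triose-phosphate split (two C3 units per
glucose), which inflates the post-split segment irrespective of any
withdrawal.

## Randomization, correlation, clustering

`randomize_table()` perturbs the data within measurement uncertainty: for
each (group, time, metabolite) cell the replicate values are redrawn from a
normal centred on the cell mean, truncated to the 95% confidence interval
$m \pm 1.96\,\mathrm{SE}$. The "standard deviation of each sample for a given
time and metabolite" is read as the across-replicate SD of the cell — the
only self-consistent reading, since a single observation has no SD — and the
CI is on the mean (SE-based). Truncation is by rejection sampling; the
acceptance rate is ≈95%, and the draw stream is strictly sequential so a
single seed fixes the whole ensemble bit-for-bit (asserted in the tests).

`sensitivity_run()` re-runs accumulation → weights → BVLS per randomized set
and interval with identical settings and records the Pearson correlation of
each randomized flux vector with the original one, the fraction above 0.5,
and the full flux/accumulation ensembles. Solver failures on a randomized
set are counted and reported, never silently dropped. The default `n_sets`
in the pipeline is modest (100) so that interactive runs are quick; the
histogram stabilizes in the low thousands and the function takes any count.

`flux_metabolite_correlation()` correlates, across the ensemble, each
reaction's flux with each metabolite's accumulation, and clusters rows and
columns hierarchically on the Euclidean distance between correlation
vectors. Constant fluxes or accumulations have undefined correlations; these
entries are reported as 0 and flagged rather than dropped.

`cluster_samples()` standardizes each sample's intensities (z-score by
column) over a metabolite subset — typically the ANOVA-flagged set — and
clusters samples with the correlation distance $1 - r$. The linkage is
average by default (the original analysis does not state one) and
configurable.

## The synthetic-data generator

`generate_table()` emulates the study design: times 0/15/30 min, control and
compressed groups, 5 replicates per cell, per-metabolite baselines drawn
lognormal (meanlog $\log 10^4$, sdlog 1) to span the intensity decades of
real targeted LC-MS data, and multiplicative replicate noise
(`intensity = center × (1 + ε)`, $ε \sim N(0, \mathrm{cv})$) because LC-MS
intensity noise scales with signal — this also exercises the
inverse-variance weighting nontrivially. Cell centers move by
$(S v_\text{group})\,\Delta t$ per elapsed interval, so zero noise makes
`estimate_accumulation()` return $S v$ exactly and the BVLS fit recover $v$
to machine precision on the full-column-rank network (both asserted).

The default ground truth is the protein exemplar for the compressed group
and zero flux for the control. The truth is rescaled once so that the median
nonzero per-interval center shift is 20% of the affected metabolite's
baseline — a clearly detectable metabolomic shift — subject to a feasibility
guard that never depletes any pool below 20% of its baseline (intensities
are nonnegative; a flux scale that drives a center negative is physically
meaningless). `generate_true_flux()` also provides a lipid-like mode and a
`random` mode (uniform within bounds) for solver exercises.

**What the generator does not emulate**: chromatographic artifacts,
missingness, batch effects, heteroscedasticity beyond the multiplicative
model, and real biological covariance between metabolites. Passing tests on
synthetic data therefore demonstrate the *computational* correctness of the
pipeline (round trips, solver optimality, determinism), not that any
particular biological dataset meets the model's assumptions.

**A known limitation, quantified.** With an exemplar (steady-state) truth,
all internal measured metabolites have zero true accumulation; the signal
lives in a handful of external-pool rows, and with i.i.d. lognormal
baselines the attainable flux magnitude is capped by the depletion guard.
Under these conditions the noisy-recovery experiment in
`scripts/acceptance.R` reports a median truth-recovery correlation of about
0.5 at noise cv 0.05 (n = 5), reaching high correlation only at much lower
noise; the same script verifies that recovery degrades monotonically with
noise. Recovery of the *flux vector* from a single 15-minute interval at
realistic noise is therefore genuinely hard in this design — many reaction
combinations are only weakly constrained by 45 accumulation values — and
this is reported honestly rather than hidden by an unrealistically large
signal scale. The randomization-based sensitivity analysis, which perturbs
within the data's own confidence intervals, shows high self-consistency
(fraction of correlations above 0.5 near 1), matching the qualitative
robustness claim the pipeline is designed to check.

## Numerical choices, in one place

* BVLS: KKT tolerance 1e-10 (relative), iteration cap $10n^2$, SVD
  subproblems, minimum-norm + warning under rank deficiency.
* Simplex: Bland's rule (anti-cycling), pivot tolerance 1e-9, two-phase with
  artificial-variable cleanup; L1 tie-break for degenerate optima.
* Weights: reciprocal variance; zero-variance capped at the maximum finite
  weight; ETC rows at the minimum measured weight; other constrained rows at
  the median measured weight; `hard_zero` escalates by 1e8 and verifies.
* Serialization: 12 significant digits in all CSV writers; manifest JSON
  with md5 checksums; all randomness behind explicit integer seeds.
* Ties/degeneracies: flat ANOVA metabolites get $p = 1$; undefined
  correlations become 0 with a flag; zero-norm profiles refuse a relative
  distance.
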