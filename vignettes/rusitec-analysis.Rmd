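---
title: "Methods: Rusitec seaweed-supplementation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Rusitec seaweed-supplementation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rusitecr)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, the synthetic-data generator that stands in
for experimental downloads, and the numerical and design choices made
where the methodology left room.

## The experimental system

A Rusitec is a continuous-flow in vitro fermentation system: glass
fermenters hold rumen inoculum at 39 °C, artificial saliva (buffer) is
infused at 75% of the 950 mL fermenter capacity per day (0.7125 L/d),
feed is supplied in nylon bags that reside 48 h, and effluent and gas
are collected continuously. The design modeled here is 2 runs × 10
fermenters over days 0–13 (7 adaptation, 7 sampling), with 5 treatments
— a total mixed ration (TMR) alone or with *Ascophyllum nodosum* or
*Fucus vesiculosus* at 2.5% or 5% DM inclusion — replicated twice per
run. Five fermenters share one circulation thermostat, which acts as a
block; each treatment occurs exactly once per block
(`rusitec_design()`, `design_summary()`).

## Diet formulation

`mix_composition()` treats every nutrient fraction, DM included, as a
linear DM-basis mixture of the analyzed ingredient assays. Internal
values are never rounded; report output uses half-away-from-zero
rounding to one decimal (`round_half_up()`), the convention of
composition tables. Published composition tables are typically mixed
from *unrounded* assays, so a mixture recomputed from printed
(1-decimal) ingredient rows can land half a rounding unit away from a
printed diet cell. The tests therefore pin only rounding-robust cells
exactly and hold all cells to ±0.1 percentage points. Trace
constituents (iodine, bromoform, phenolics) mix identically but
propagate as *unavailable*, not zero, when any component lacks the
assay.

## Fermentation mass balances

* **Degradation** is `100 × (input − output)/input` per nutrient, with
  feed bags pooled by fermenter over the degradation span before the
  quotient is formed. Bags are indexed by removal day; the default span
  is removal days 7–12. Negative degradation (residue gain, e.g.
  microbial colonization) is flagged with a warning, never clipped.
* **Averaging hierarchy** is day → fermenter → treatment everywhere:
  treatment means are means of per-fermenter means, matching pooling by
  the fermenter, and treatment-level dispersion is reported as the
  pooled SEM of the mixed model rather than raw SDs.
* **C2:C3** is the mean of daily acetate:propionate ratios. The ratio
  of mean productions is a different number whenever days vary
  (Jensen's inequality) and is deliberately not used; the unit tests
  demonstrate the difference on a two-day example.
* **Total VFA** is the fixed-order sum acetate → valerate, excluding
  ammonia-N. Totals re-derived from rounded printed component means can
  differ from a printed total by up to ~0.13 mmol/d, so the acceptance
  check uses ±0.15 as its tolerance.

## ¹⁵N isotope dilution and EMPS

Microbial N leaving the fermenter is partitioned into the
liquid-associated pool estimated from the tracer balance
(`n_lam_e()`) and the solid-associated pool estimated from feed-residue
enrichment (`n_sam()`); their sum times 6.25 gives microbial CP, and
EMPS is microbial CP per kg of truly degraded OM — feed OM degraded
plus the microbial OM returned in the residues (`om_sam()`,
`microbial_outputs()`).

Three points deserve comment:

* **The OM_SAM formula as printed in methodological sources is
  typographically ambiguous.** The implementation adopts the only
  unit-consistent reading: divide SAM N by the N fraction (N%/100) to
  get SAM dry matter, multiply by the OM fraction (100 − 12)/100 and by
  the DM proportion of the isolated SAM fraction, 0.93. All three
  constants are exposed as arguments (`ash_pct`, `dm_prop`,
  `n_pct_sam`); whether 0.93 should multiply or divide cannot be
  resolved from the printed text, so the choice is documented here and
  overridable.
* **The tracer balance is implemented literally by default** (total
  abundances, no background subtraction), because that is how the
  balance is stated. An excess-abundance mode
  (`n_lam_e(mode = "excess")`) subtracts the natural ¹⁵N carried by the
  bulk N flows and divides by the abundance excess; the two agree
  exactly whenever the feed and effluent backgrounds are identical and
  the bulk N balance closes with the microbial outflow, which the test
  suite verifies constructively.
* **Degraded OM feeding the EMPS denominator is bag-derived.** Reported
  methane-per-degraded-OM figures and reported degradation percentages
  applied to a 15 g daily feed bag are not exactly mutually consistent
  in this literature; the package does not attempt to reconcile them.
  The generator derives OM_deg from its own bag mass balance, and all
  percent-reduction summaries operate on treatment means taken as
  inputs, so nothing downstream depends on the discrepancy.

Constants: N→CP 6.25; natural ¹⁵N background 3.66303 µg/mg; buffer
NH₄Cl 0.0378 g/L at 104 mg ¹⁵N/g N; N mass fraction of NH₄Cl from
atomic masses (14.007/53.49). All are defaults of `rusitec_config()`
or function arguments, never hard-wired into callers.

## Treatment inference

`fit_treatment_model()` fits trait ~ treatment with random intercepts
for run, thermostat block, fermenter and day (lme4). Random factors
with a single level, or with as many levels as observations (where they
are confounded with the residual, e.g. fermenter for one-value-per-
fermenter traits), are dropped and noted in the result. Denominator
degrees of freedom use the **Satterthwaite** approximation (lmerTest,
emmeans): it is the established, well-tested choice in the R ecosystem
for this model class, and the package establishes the calibration of
the resulting F-test by simulation rather than by emulating any
particular software's containment rules — the acceptance study runs
1000 null experiments at the study design and checks the rejection rate
at α = 0.05.

Pairwise comparisons are unadjusted t-tests on estimated marginal means
(Fisher's LSD), *protected*: letters are only computed when the overall
F-test is significant, otherwise all treatments share one letter. The
compact letter display uses the insert-and-absorb algorithm; ties are
impossible by construction and the output is deterministic because
letter sets are ordered by their largest member mean. The defining
property — two treatments share a letter iff their pairwise P exceeds α
— is property-tested against random P patterns, and minimality against
brute-force enumeration.

Rank-based testing for compositional traits (`kruskal_dunn_bh()`) uses
mid-ranks with the tie-corrected H statistic, Dunn's z-tests with the
same tie correction, and Benjamini–Hochberg step-up adjustment within
the pairwise family. All-tied data return H = 0, P = 1 by convention.
Residuals and fitted values are returned for graphical normality and
homogeneity checks; no automatic gate acts on them.

## Community summaries

* Genus collapse labels unannotated features by the last available rank
  with the rank in parentheses (`"F082 (family)"`), or `"Unassigned"`
  when no rank exists; per-sample totals are conserved.
* The ≥1% abundance filter retains a genus that reaches the threshold
  in **at least one sample** (default); a mean-abundance variant is
  available via `mode = "mean"` since the per-sample-max reading is the
  more permissive and more common one but the convention is not
  universal.
* Shannon entropy is reported in **bits** (base 2) by default, with the
  base exposed, since reporting conventions differ.
* Rarefaction subsamples without replacement (vegan's `rrarefy`) to the
  configured depths (3580 archaea, 5856 bacteria); samples below depth
  are dropped with a warning naming them.
* Jaccard distances are computed on presence/absence after rarefaction;
  Bray–Curtis on counts. Both come from vegan's `vegdist`.
* PERMANOVA is implemented in-package for one-way designs so that the
  permutation stream is seedable and the P convention explicit:
  `P = (1 + #(F_perm ≥ F_obs)) / (1 + permutations)`, making 0.001 the
  floor at 999 permutations. The pseudo-F and R² are cross-checked
  against `vegan::adonis2` in the tests.
* Trait correlations are Spearman, retained only when |r| ≥ 0.3 and
  P ≤ 0.05, with constant series skipped (undefined, not zero).

## The synthetic-data generator

`simulation_config()` fixes the study conditions; the defaults *are*
the conditions the analysis targets:

* **Design**: 2 runs × 10 fermenters, 5 treatments, 2 blocks/run,
  days 0–13, giving n = 4 per treatment.
* **Setpoints**: treatment means of total gas (1386…1114 mL/d), CH₄
  concentration (16.9…15.4%), nutrient degradation, effluent
  productions and EMPS (120…100 g/kg) are taken from the reference
  study's reported means (`rusitec_reference_means()`), so simulated
  data are magnitude-realistic. `zero_effects = TRUE` collapses all
  treatments onto the control for null studies, and `effects` applies
  multiplicative deviations to single cells.
* **Noise**: multiplicative lognormal with mean 1 at four levels — run
  CV 3%, block CV 1.5%, fermenter CV 3%, day CV 5% — chosen once so the
  simulated pooled SEM of total gas (~36–40 mL/d at n = 4) matches the
  scale reported for such experiments, with an optional AR(1)
  day-to-day correlation (default independent days, since true
  autocorrelation is unknown). Isotope abundances get additive Gaussian
  noise (CV 2%) truncated at the natural background. Lognormal
  multiplicative noise preserves positivity of volumes and
  concentrations; nothing heavier-tailed is attempted because the
  emulated measurement chains report only SEMs.
* **Forward model**: isotope panels are built by running the dilution
  equations forward from the true microbial N flux, so the estimator
  inverts them *exactly* (to floating-point precision) in the
  noise-free case — this is the generator-inversion property the
  acceptance suite checks at 1e-9.
* **Community**: Dirichlet-multinomial counts around sample-type and
  day dependent genus profiles implementing the inoculum→Rusitec
  dominance shift (Methanobrevibacter declining, Methanomicrobium
  rising), with treatment fold-changes in fermenter-derived samples and
  lognormal sequencing depths that straddle the rarefaction thresholds.
* **Determinism**: one master seed feeds named substreams per stage
  (design, gas, bags, effluent, panels, community), so a stage is
  byte-reproducible even when other stages are skipped
  (`simulate_experiment(stages = ...)`).

What the generator does **not** emulate: read-level sequencing error,
chimeras and denoising artifacts; protozoal dynamics; fermentation
kinetics within a day; correlated multi-trait noise beyond the shared
unit multipliers; missing-data mechanisms. Passing tests therefore
demonstrate correctness of the estimators and calibration of the tests
under this generative model — not agreement with any real sequencing
dataset, which would require the original reads.

## Problem sizes and runtime choices

The simulation studies are sized to give tight Monte-Carlo error while
staying light enough for routine re-runs: 1000 null experiments for the
type-I calibration (binomial SE ≈ 0.007 at α = 0.05), 500 panel
replicates for the EMPS bias bound, 100 experiments for the EMPS power
estimate, and 200 replicates × 999 permutations for the PERMANOVA null.
These sizes are the package's own choices and are encoded in the
acceptance script and tests.

## Degenerate inputs and tie-breaks

Zero inputs raise errors where a quantity is undefined (degradation
with zero input, EMPS with non-positive degraded OM, Shannon with empty
samples, distances between two empty samples) and return exact zeros
where that is the correct value (zero microbial N → EMPS 0). Negative
tracer balances and negative degradations are returned *flagged with
warnings* rather than suppressed, because they are diagnostically
meaningful. Validation of experiment tables is total: every record is
either accepted or produces a diagnostic naming the file and record.

## Known limitations

* The mixed model supports the stated one-way design with crossed
  random intercepts only; repeated-measures covariance structures and
  treatment × day interactions are out of scope.
* PERMANOVA is one-way; multi-factor partitions should go to
  `vegan::adonis2` directly.
* The missing-data policy (available-case means after an explicit
  flag) is a package choice; the emulated workflow does not document
  one.
* Tree-dependent diversity (Faith's PD), ordination plotting,
  compositional differential abundance and co-occurrence networks are
  intentionally not reimplemented; established tools exist and the
  package's scope ends at the statistics it can validate against its
  own generator.
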