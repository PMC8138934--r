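---
title: "Dissecting CAF heterogeneity by Boolean gating: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting CAF heterogeneity by Boolean gating: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cafcyto)
```

## The problem

Cancer-associated fibroblasts (CAFs) are not one cell type. In murine
triple-negative breast tumours (the 4T1/4T07 sister models), six surface
and reporter markers — aSMA, FAPa, CD26/DPP4, PDGFRa, PDGFRb and PDPN — are
individually informative but overlap heavily, so the unit of analysis is
the *Boolean subset*: the combination of positive/negative calls across
all six markers. Six markers give $2^6 - 1 = 63$ non-empty combinations,
and the biological questions are compositional: which of the 63 subsets
exist, which dominate, and how the composition shifts with tumour type and
time (days 7/14/21 after implantation, against healthy mammary fat pad at
day 0).

`cafcyto` implements the full analysis chain for this design —
compensation, FMO-calibrated gating, Boolean composition, and the
statistical layer — together with a ground-truth-labelled synthetic
cytometry generator, so that every stage is verifiable without access to
the original tumour acquisitions (which were never deposited).

## The synthetic generator

The generator is first-class, tested code: it defines the study
conditions under which every downstream guarantee is checked.

**Signal model.** Each ground-truth population is a template: a 6-bit
marker profile, a lineage flag and a scatter position. A positive marker
emits a lognormal signal parameterised by its arithmetic mean and CV
(default 20,000 a.u., CV 0.5); negative markers emit nothing. Every
fluorescence channel additionally receives an autofluorescence baseline,
normal with mean 100 and SD 30 a.u. truncated at zero. The observed row
vector is

$$\mathbf{y} = \mathbf{g}_b \odot \big[(\mathbf{s} + \mathbf{a})\,S\big],$$

where $S$ is the spillover matrix (rows = source fluorophore, unit
diagonal), and $\mathbf{g}_b$ the batch's multiplicative per-channel gain.
With all noise scales at zero this identity holds to machine precision,
which is what the mixing-linearity tests assert.

**Artefacts.** A configurable fraction of events are doublets — the
channel-wise sum of two independently drawn cells, except that pulse
heights take the larger cell's value, so width roughly doubles while
height does not, exactly the geometry the singlet gate exploits. Dead
cells (a configurable fraction, default 10%) carry a bright lognormal
viability-dye signal. Lineage-positive contaminants (immune, endothelial,
epithelial) stain in the dump channel.

**Determinism.** All randomness flows from one scenario seed through a
31-bit string hash of (tumour type, day, batch, control kind), so any
sample can be regenerated in isolation and extending a design never
perturbs existing samples.

**The default scenario** encodes the study's qualitative biology, with
abundances chosen once to match the published percentages where stated:
healthy fat pads are PDGFRa-dominant (about 90% of CAF+ cells PDGFRa+);
tumours shift towards FAPa/CD26/PDGFRb-expressing subsets; CD26
single-positives are about 14% of CAF+ in 4T07 versus 6% in 4T1 at day 7;
PDGFRa single-positives persist in 4T07 (about 14% of CAF+) but nearly
vanish in 4T1 (1.5%) by day 21; CD26-expressing subsets rise with time in
4T1 and fall in 4T07 (a time-by-type interaction); half of all cells are
lineage-positive and 20–40% of Lin- cells are negative for all six
markers. Three batches carry gains 1.00/1.12/0.92.

**Between-sample variability** is controlled by `abundance_cv`: a
per-sample lognormal jitter on the abundance vector (renormalised). The
default is 0 — samples of a condition share the configured composition
exactly, so recovery checks compare the pipeline against a fixed truth
and the only noise is multinomial sampling and gating error. The power
and calibration studies in the test suite set `abundance_cv = 0.2`,
a realistic between-tumour spread, because there the between-sample
variance is itself the object of study.

What the generator does *not* emulate: debris and the FSC/SSC cell gate
(pass-through by default), time-resolved acquisition drift, and spectral
(non-linear) mixing. Stored values are linear-scale; display transforms
are a consumer concern. Passing tests therefore demonstrate correctness
of the analysis chain under lognormal, linearly-mixed signals — not
robustness to every artefact of real acquisitions.

## Compensation

Spillover is estimated from single-stain controls exactly as bead
controls are acquired: each control's events are split into
positive/negative on its primary channel by one-dimensional two-means
clustering (deterministic initialisation at the 10th/90th percentiles —
bead controls are bimodal and have no FMO), and the coefficient into each
other detector is the ratio of background-subtracted medians. Negative
estimates are physically impossible and are clipped to zero with a
warning; controls whose clusters have fewer than 50 events each, or no
median separation, raise an insufficient-separation error.
Compensation itself is the exact inverse, `observed %*% solve(S)`,
applied only to fluorescence channels; tables are flagged so a second
application errors. Cell-derived controls (the aSMA reporter and the
PDGFRb antibody that does not bind beads) need no special handling — the
estimator only assumes a bimodal primary channel.

## Gating

The tree is: cells (optional scatter rectangle) → singlets → live →
lineage-negative → six marker calls → CAF+ (at least one marker, Boolean
OR) / CAF- (none). Counts can only shrink down the tree, and CAF+/CAF-
partition Lin- exactly.

**The FMO rule.** Marker gates come from fluorescence-minus-one controls:
the gate is placed so that no more than 0.03% of the control's live
events fall inside it. We implement this as a tail-count rule: the cutoff
is the smallest observed value $v$ with
$\#\{x_i > v\}/n \le q$, $q = 3\times10^{-4}$ — not an interpolated
quantile — so the bound holds *exactly* on the calibration sample, ties
resolving conservatively upward. Positivity downstream is strict `>`. A
quantile-type rule on the linear scale is equivariant under monotone
transforms, so the unknown instrument display transform is immaterial.
At least $1/q$ live events are required for the rule to be meaningful
(the calibrator warns below that); the pipeline therefore acquires
simulated control tubes at $1.5/q$ events by default, covering losses to
the viability gate.

**Viability and lineage cutoffs** were set visually in the original
protocol; a reproducible rule is required here, so they are calibrated by
the same tail-count rule against an unstained control at a looser
$q = 0.5\%$. The FMO rule is applied to live-gated control events (the
published gates were drawn on live cells).

**Singlets.** An event is kept if its width/height ratio on *both*
scatter pairs is at most 1.5 times the sample median ratio. Under the
generator's doublet geometry the doublet ratio sits near twice the
singlet median, so the default limit separates cleanly; on null data the
gate removes well under 1%.

## Boolean composition

Subset `index` is the binary encoding of the six calls with bit 1 = aSMA
(the first marker of the gating order) and bit 6 = PDPN; index 0 is the
CAF- sentinel and is not one of the 63 subsets. Published SPICE figures
label subsets S1–S63 by an internal ordering that is not derivable from
the text (only S32 = CD26 single-positive and S63 = PDGFRa
single-positive are identified there); this package documents its own
mapping and always emits human-readable labels ("FAPa+CD26+") alongside
indices to avoid ambiguity.

A `composition_profile` holds the 63 subset fractions of CAF+ plus the
summary percentages (CAF+ of Lin-, Lin- of live, per-marker % of CAF+).
Two identities hold *exactly*, not to tolerance: the 63 subset counts
plus the CAF- count equal the Lin- count, and the per-marker fraction
equals the sum of the containing subsets' fractions (the latter is
computed from the subset fractions for this reason). Samples with no
CAF+ cells get `NA` fractions and are excluded from group summaries with
a warning, mirroring the paucity of cells in some real tumour samples.

Downstream views — abundance ranking with SEM and top-k cumulative
coverage (ties broken by subset index), the 63-by-samples heatmap matrix,
and SPICE-style pie/arc data where each marker arc covers exactly the
slices containing it — are deterministic re-arrangements of the profiles
and are tested as such.

## Statistics

**Composition permutation test.** The published analysis delegates to
SPICE's built-in permutation test, whose statistic is unpublished. The
declared stand-in is the L1 distance between group mean composition
vectors, $T = \sum_{s=1}^{63} |\bar p_{A,s} - \bar p_{B,s}|$, with the
statistic pluggable. Labels are re-assigned to groups of the original
sizes; when the number of distinct splits is within the permutation
budget the null is enumerated exhaustively (exact p, observed split
included), otherwise sampling with the add-one convention prevents
$p = 0$. Note a granularity consequence: with equal group sizes,
complementary splits give identical statistics, so the smallest
attainable exhaustive p at 3-vs-3 is $2/20 = 0.1$; calibration studies at
$\alpha = 0.05$ therefore need groups of at least 5, and the test suite
uses 6-vs-6 (grain $2/924$).

**Welch t-tests with FDR.** Inter-tumour comparisons are unpaired,
two-tailed, unequal-variance t-tests with Welch–Satterthwaite degrees of
freedom. "The FDR approach with Q = 1%" is interpreted as the sharpened
two-stage step-up procedure (the default behind that phrase in the
software used); plain Benjamini–Hochberg is available. Two constant,
identical groups get $t = 0$, $p = 1$ by convention. Lowering Q never
adds discoveries.

**Two-way ANOVA + Tukey–Kramer.** `value ~ day * tumour_type` with
sum-to-zero contrasts and Type III sums of squares (the convention of the
commercial software used for the published analysis; whether it used
Type II or III is not stated — Type III was chosen as that software's
default), with Tukey–Kramer pairwise day contrasts within each tumour
type via `emmeans`, valid for unequal group sizes. Designs with zero
residual variance (possible with synthetic input) are handled by a
dedicated branch: zero-SS effects get $F = 0, p = 1$, nonzero ones
$F = \infty, p = 0$.

**Trend fits.** Per-group OLS of percentage on day, a slope-nonzero
t-test, 95% confidence bands from the fit covariance, and the
extra-sum-of-squares F test comparing one pooled line (2 parameters)
against per-group lines (4 parameters) — "does one line fit both tumour
types?". The pooled one-way ANOVA variant adds a linear-trend contrast
with centred day coefficients (proportional to $-1, 0, +1$ for days
7/14/21).

**Batch-effect check.** Within each repeat, each sample's marker
percentage is divided by that repeat's mean in a fixed reference group
(4T1 day 7); the two-way ANOVA + Tukey layer is re-run on the ratios and
each comparison's significance call (at $\alpha = 0.05$) is paired with
its raw counterpart; the concordance fraction summarises how much the
batch structure drives conclusions. With a single batch the
normalisation is a per-marker rescaling, so calls are unchanged — a
tested invariant. The calibration study in the test suite drives this
with a deliberately adversarial schedule (one tumour type's late
samples concentrated in a gain-carrying repeat) because with batches
balanced across design cells a multiplicative gain only inflates
variance, not false positives.

## Numerical choices and problem sizes

* FMO tail count uses `floor(q*n + 1e-9)`: the epsilon guards exact
  multiples of $1/q$ against binary rounding (e.g. $3\times10^{-4}
  \times 10^4$).
* Exhaustive permutation comparisons use a $10^{-12}$ slack on
  $T_{perm} \ge T_{obs}$ so re-computed observed statistics tie with
  themselves.
* Spillover matrices must have unit diagonal, off-diagonals in $[0,1)$;
  condition numbers above $10^6$ warn.
* Two-means bead splitting initialises at the 10th/90th percentiles and
  is fully deterministic.
* Test problem sizes are the package's own choices: recovery runs use
  50,000 events/sample (subset recovery within ±1 percentage point for
  subsets at 2% or more); doublet/viability rate checks use 20,000–50,000
  events; FMO contract checks 100,000; abundance convergence 200,000;
  permutation calibration 1,000 replicates of 6-vs-6; FDR calibration
  500 replicates of 36 comparisons; batch calibration 200 replicates;
  the end-to-end interaction power study 100 replicates at 2,000
  events/sample with `abundance_cv = 0.2`, 36 samples per replicate.

## Known limitations

* The fluorescence model is lognormal-plus-truncated-normal; real
  acquisitions have heavier tails, debris, and margin events.
* Compensation is median-ratio per control — deliberately simple; no
  OLS/AutoSpill-style refinement or spectral unmixing.
* The permutation statistic is a documented stand-in for an unpublished
  one; conclusions about *which* statistic SPICE used cannot be checked.
* Tumours are treated as independent samples (two tumours per mouse in
  the original design were likewise analysed as independent); no
  mixed-effects modelling of mouse pairing.
* The S1–S63 label ordering of published SPICE figures is not
  reproduced; only this package's binary indexing plus marker-name
  labels are used.
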