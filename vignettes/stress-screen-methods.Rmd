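---
title: "Methods: quantitative machinery of a stress-reporter genetic-interaction screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative machinery of a stress-reporter genetic-interaction screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressGI)
```

## The measurement problem

Yeast mounts a generic transcriptional stress program largely driven by the
partially redundant transcription factors Msn2 and Msn4. A sensitive way to
study how signalling genes shape this program is a reporter screen: strains
carrying knockouts (singles, doubles, and triples on an *msn2 msn4*
background) and a genomically integrated stress-reporter GFP fusion
(an Msn2/4 target such as HSP12) are grown robotically, exposed to growth
and stress conditions, and read out by high-throughput flow cytometry. The
quantitative questions are then: which knockouts change reporter output,
in which conditions; how much of each effect is routed through Msn2/4;
which pairs show masking epistasis; and what neutral model best predicts a
double knockout from its singles.

`stressGI` implements that entire quantitative chain, together with a
ground-truthed synthetic-data generator, so every stage can be validated
without instrument data.

## The generative model

`make_truth()` assigns each gene, per condition, a multiplicative
component $m$ (dimensionless), an additive component $a$ (GFP a.u.), and
an Msn2/4-dependent fraction $d$. With condition baseline $B$ (wild-type
reporter level), expected levels are:

* single knockout: $B\,m + a$;
* double knockout (neutral): $B\,m_X m_Y + a_X + a_Y$, plus any injected
  interaction term (`inject_interaction()`) used to plant known epistasis;
* *msn2 msn4* double: a residual baseline $B' = \rho B$, with
  $\rho = 0.2$ by default and $0.3$ for KCl-like (osmotic) conditions,
  reflecting the HOG-pathway route into the reporter that bypasses
  Msn2/4;
* triple (gene + *msn2 msn4*): $B' + (1-d)\,F$, where
  $F = a + B(m-1)$ is the gene's total wild-type-relative effect — only
  the Msn2/4-independent share of the effect survives loss of Msn2/4.

The model value can be negative for extreme double combinations; measured
fluorescence cannot, so the event simulator floors the expected level at
zero (a dark population) while the analytic model stays linear.

Default sampling ranges — $m \in [0.3, 3]$, $a \in [-0.3, 0.5]\,B$,
$d \in [-0.5, 1.5]$, $B \in [100, 1000]$ a.u. — span the regimes the
analysis must distinguish: strong activators and repressors, fully
dependent ($d = 1$), partially independent ($d \in [0,1)$), cooperative
($d > 1$) and negative ($d < 0$) knockouts. The between-replicate
coefficient of variation defaults to 5%; this is an assumption (typical
plate-to-plate reproducibility for robotic reporter screens), as no
measured value was available, and it is the noise level at which the
acceptance-grade recovery tests are run. Per-cell log-GFP spread defaults
to 0.3, giving the unimodal, roughly log-normal intensity histograms seen
in gated cytometry data; the per-event median is the autofluorescence
offset plus the strain's expected level by construction.

Scatter events mix a dense cell cloud — a correlated bivariate normal
(sd 1200 × 700 a.u. around 50,000 × 30,000, correlation 0.5) truncated at
its 99.5% Mahalanobis ellipse — with a configurable fraction (default
10%) of outliers drawn uniformly over a box of ±40 cloud standard
deviations, the analogue of debris scattered across the instrument's full
recorded range. Everything is a pure function of its arguments and a
seed.

What the generator does *not* emulate: spillover/compensation structure,
doublets, time drift within a well, cell-cycle–correlated scatter–GFP
dependence, or saturating growth. Passing tests therefore demonstrate the
correctness of the analysis pipeline under the stated statistical
assumptions, not robustness to every artefact of real cytometry.

## Stream processing

**Well demultiplexing.** An autosampler pushes wells sequentially into
one timed event stream; `partition_wells()` splits it into exactly
`n_wells` contiguous segments by maximizing the total inter-segment time
gap. Because each boundary contributes its own gap independently, the
optimal set of boundaries is exactly the `n_wells − 1` largest
inter-event spacings; the implementation selects them directly (ties
broken toward the earliest boundary), which is the closed-form solution
of the dynamic program over candidate boundaries. The assignment is
invariant to shifting or positively rescaling time. Exact recovery of the
true wells needs the inter-well gap to dominate the intra-well spacing;
the package's contract tests use gap/spacing ≥ 50, where recovery is
exact across 100 seeded streams.

**Density gating.** `gate_events()` histograms FSC × SSC on a
`resolution` × `resolution` grid (default 64) and retains events from the
densest bins, added in decreasing-density order, until the retained
fraction first reaches the target (default 90%). The realized fraction
can overshoot by at most one bin's mass. No connectivity of the retained
bins is enforced: with a unimodal cell cloud the retained set is a dense
area in practice. One structural note: when outliers make up 10% of
events and the gate is asked to keep 90%, the retained set must reach
90% of *all* events, so a handful of thin cloud-edge bins are necessarily
dropped — the gate removes essentially all outliers (recall ≈ 99% at
10,000 events under the default geometry) while sacrificing ≲1% of true
cells.

**Medians and correction.** Per well, the reporter median is the exact
order-statistic median of gated events; an empty well is flagged missing,
never zero. Autofluorescence is removed by subtracting the plate's
untagged-control median, clipping negative values to zero so downstream
ratios and log transforms stay defined. Replicates are averaged, and
reproducibility is reported as the Pearson correlation of log10 medians
between replicate pairs across strains, per condition (log scale because
strain medians span orders of magnitude).

## Growth planning

`plan_dilution()` implements the dilution-series optimization used to
land strains of unknown doubling time in a target OD window: growth is
exponential, $OD(t) = OD_0\,2^{t/\tau}$, with $\tau$ uniform over the
expected range (default 1.5–3.5 h — the prior is uniform because nothing
more is known); each strain is split into an $X:2X:4X:8X$ series and a
strain succeeds if at least one source ends inside the window after the
final growth period (default 10 h). The planner scans 200 log-spaced
candidates $X \in [2, 512]$ and maximizes the expected number of
successful strains; ties go to the smallest $X$. After the final OD read,
`select_sources()` keeps, per well, the in-range source closest to the
window midpoint ("best fit" is not otherwise defined; midpoint distance
is the package's choice). No lag phase or saturation is modelled.

## Effects and condition specificity

Effects are ratios to the same-condition wild type. A knockout has an
effect when the ratio is strictly above 1.1 or strictly below 0.8
(boundary values count as no effect); both thresholds are configurable.
Among the stress conditions, a knockout with effects in several
conditions is condition-specific when the spread (max − min) of its
effect magnitudes exceeds 0.3, in which case it is assigned to the
conditions above the mean magnitude (for increases) or below it (for
decreases); otherwise the effect is common. Strains with mixed directions
across conditions are handled per direction and the labels pooled; when
magnitudes of opposite directions must be compared on one scale (the
stress-general magnitude), distance from 1 is used. `summarize_specificity()`
assigns each effect-bearing strain to exactly one region of the
stress-condition Venn diagram, so region counts conserve the number of
effect-bearing strains.

## Msn2/4 dependence

For knockout $X$, with reporter levels of wild type, the single, the
*msn2 msn4* double and the triple:

$$D_X = \frac{GFP_{\Delta X} - GFP_{\Delta X \Delta msn2 \Delta msn4}}
             {GFP_{\Delta X} - GFP_{\Delta msn2 \Delta msn4}}.$$

This single ratio reproduces all four qualitative regimes: $D_X = 1$ when
the triple equals the *msn2 msn4* double (fully dependent); $0 \le D_X <
1$ when part of the effect bypasses Msn2/4 (exactly $D_X \cdot 100$
percent of the effect is Msn2/4-dependent); $D_X > 1$ when the triple
falls below the double (cooperativity); $D_X < 0$ when deleting Msn2/4 on
the knockout background *increases* the reporter relative to the single.
The computation is on linear GFP (the model formulas elsewhere use raw
GFP), and is invariant to rescaling the GFP unit and to a common offset.
Two numerical guards are additions of this implementation: the score is
flagged undefined when $|GFP_{\Delta X} - GFP_{\Delta msn2\Delta msn4}|$
falls below 2% of the wild-type level (the ratio is then noise-dominated),
and the "dependent" regime label covers $|D_X - 1| \le 0.05$.

## Epistasis

A pair is eligible for a masking call when its two single effects
(relative to wild type) differ by at least 20% of the larger effect
magnitude. For an eligible pair, $Y$ masks $X$ when the double resembles
the $Y$ single: $|GFP_{XY} - GFP_Y| \le \delta\,|GFP_X - GFP_Y|$, with
$\delta = 0.25$ by default; the symmetric rule gives the opposite
direction, and if both sides qualify the smaller normalized distance
wins. One normalized-distance rule is used for same-sign and
opposite-sign pairs alike — a deliberate simplification (the original
criteria distinguish cases, but a single rule reproduces the qualitative
call structure and keeps the threshold interpretable). A consensus
direction requires calls in at least two of the three stress conditions;
agreeing calls give that direction, conflicting calls are flagged as a
direction change.

## Interaction models

With $F_X = GFP_{\Delta X} - GFP_{WT}$ and $M_X = GFP_{\Delta X}/GFP_{WT}$,
the neutral expectations for a double are additive
($GFP_{WT} + F_X + F_Y$), multiplicative ($GFP_{WT}\,M_X M_Y$), or
combined:

$$E[XY] = GFP_{WT}\,m_X m_Y + a_X + a_Y,
\qquad a_X + GFP_{WT}(m_X - 1) = F_X \;\;\forall X,$$

the per-gene constraint ensuring the two components sum to the measured
total effect (the only reading under which both pure models are special
cases: $a = 0$ gives the multiplicative model, $m = 1$ the additive one).
The interaction score of a pair is observed − expected, optionally
normalized by the wild-type level.

**Fitting.** Substituting the constraint eliminates $a$ and leaves an
unconstrained bilinear least-squares problem in $u = m - 1$:

$$\min_u \sum_{XY} \big(d_{XY} - GFP_{WT}\,u_X u_Y\big)^2,$$

where $d_{XY}$ is the observed double minus its additive expectation.
This is solved by bounded Levenberg–Marquardt (`minpack.lm::nls.lm`,
analytic Jacobian, $m \in [0, 10]$) from three starts — additive
($u = 0$, a stationary point the optimizer keeps, so the combined fit can
never do worse than the additive model), multiplicative ($u = M - 1$),
and their midpoint — taking the lowest final SSE. The constraint
residual is zero by construction. Genes appearing in no double fall back
to the additive solution ($a = F$, $m = 1$) and are flagged. A useful
identity, verified in the tests for every fitted pair:
$E_{\text{combined}}[XY] = E_{\text{additive}}[XY] +
GFP_{WT}(m_X - 1)(m_Y - 1)$.

**Identifiability.** On a strictly bipartite query × target design the
objective only pins the *products* $u_X u_Y$, leaving a scale exchange
between the two sides free. The package's default screen therefore
includes the query genes in the target set, so the pair graph contains
triangles and the decomposition is unique; with that design the fit
recovers the generative $(m, a)$ to $10^{-6}$ relative on noiseless
data and correlates with the truth at $R > 0.99$ under 5% replicate
noise (30 query × 56 target screen).

**Dependence decomposition.** Each gene's effect splits into an
Msn2/4-dependent part $D_X F_X$ and an independent part $(1 - D_X) F_X$;
`component_dependence_correlation()` reports Pearson correlations (with
two-sided p-values) of the multiplicative component against the dependent
effect and of the additive component against the independent effect. The
dependent-*effect* (not the bare score) is used as the axis; the bare
$D_X$ can be substituted by passing a modified table.

## Localization dynamics

From per-cell nuclear and cytoplasmic intensities (image segmentation is
upstream of this package), `nc_ratio()` forms per-cell ratios (cells with
non-positive cytoplasmic signal are dropped and counted),
`timepoint_summary()` averages them per image — the mean by default, the
median by option, since both conventions are in use; they agree on
symmetric populations and the choice is recorded with the trace — and
`trace_auc()` integrates the summary ratio over time by the trapezoid
rule, the amount of time the factor spent in the nucleus. No baseline is
subtracted by default (an optional mode subtracts the first timepoint and
clips at zero). Final values average biological repeats, with a
repeat-vs-repeat scatter for reproducibility. The simulator's default
pulse shapes mirror the two canonical stress responses: a transient
osmotic-stress pulse peaking near 15 min and returning to baseline by
about 45–50 min (gamma-like shape of order 3), and a lower-amplitude
sustained oxidative-stress accumulation with no return within the ~2 h
movie; the default imaging grid is 7-min intervals over ~2 h.

## Orchestration and problem sizes

`run_screen()` chains all stages from one seeded config and writes every
result table (TSV/JSON) plus a deterministic manifest; identical config
and seed give byte-identical tables. The default desk-scale configuration
— 6 query × 14 target genes (queries included), five conditions, two
replicates, 300 events per well — runs in a few seconds; the package's
validation studies use a 30 × 56 screen (1,215 unordered pairs) for
parameter recovery and 10,000-event wells for gating, sizes chosen so the
full test suite completes in well under a minute while keeping
Monte-Carlo error far below the tolerances being checked.

## Known limitations

* The epistasis thresholds ($\delta$, eligibility fraction) are calibrated
  to reproduce qualitative masking structure; genome-scale call *counts*
  are sensitive to them and should be read comparatively, not absolutely.
* The dependence score is a ratio of differences and is deliberately
  suppressed (flagged undefined) near its singular denominator; strains
  whose single-knockout level sits close to the *msn2 msn4* level cannot
  be scored.
* The density gate assumes one dominant cell population; bimodal wells
  (e.g. severe aggregation) would be gated as if unimodal.
* The growth planner ignores lag phase and saturation; its success
  probabilities are exact only under clean exponential growth.
* FCS binary files are not parsed; event tables are consumed as CSV with
  standard channel aliases.
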