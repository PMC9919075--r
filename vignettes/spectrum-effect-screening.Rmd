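---
title: "Spectrum-effect relationship screening: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectrum-effect relationship screening: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speceffect)
```

## The problem

Herbal extracts are mixtures. A chromatographic fingerprint of an extract
panel (here: ten extracts of different polarity, twenty characteristic
peaks) quantifies the mixture's composition; a bioassay panel (inhibition
zones against a set of bacteria, IC50 values against digestive enzymes)
quantifies what each extract does. Spectrum-effect relationship analysis
asks which peaks co-vary with activity across the panel, and nominates
those peaks as the putative active constituents. This package implements
the full desk-side pipeline: peak-table alignment and normalization,
bioassay reduction, two complementary association methods (gray relational
analysis and PLS regression), a consensus screening rule, and the offline
graph statistics used when a nominated constituent is carried into
network-pharmacology follow-up.

The pipeline is correlational. With ten samples and twenty peaks it cannot
prove causation; it produces a short list for isolation and verification.

## Fingerprint processing

Peak tables arrive as per-sample lists of (retention time, area). Each
reference peak is assigned the nearest sample peak within a retention-time
window (default 0.2 min), greedily by ascending absolute deviation, each
sample peak used at most once; ties go to the earlier-eluting reference
peak. Reference peaks closer than twice the window trigger an ambiguity
warning rather than an error, because such chromatography is usable but
deserves inspection. When no authoritative reference run exists,
`refine_reference()` re-centres each reference time on the median matched
time across samples (one anchor pass, one re-match pass) — a robust
stand-in for vendor multipoint-calibration tools.

Undetected peaks are floored at 0.01 area units *before* normalization, so
every sample has a complete, strictly positive area vector; each row is
then divided by its total over the characteristic peaks. The denominator is
configurable (`supplied_total`) because fingerprints whose characteristic
peaks cover most but not all of the chromatogram can reasonably normalize
to either total; the characteristic-peak total is the default since it is
always available and makes rows exact compositions. Replicate precision is
summarized as the per-cell relative standard deviation (n−1 sd), with the
conventional 5% pass threshold applied per peak to the worst cell.

## Bioassay reduction

Enzyme inhibition is computed from absorbance quadruples as
$[1 - (A_{sa} - A_{sc})/(A_{ea} - A_{ec})] \times 100$. Negative rates are
retained — sugar-rich extracts genuinely interfere with the amylase
readout — but a dose-response fit is declared degenerate when fewer than
three rates exceed 10%, since such data carry no half-maximal point.

IC50 comes from a four-parameter logistic fit,
$y = b + (t - b)/(1 + (\mathrm{IC50}/c)^{h})$, by Levenberg-Marquardt
refinement of the best of a coarse multi-start grid (Hill slopes 0.5, 1, 2,
4 crossed with IC50 candidates at the concentration quantiles). The
reported IC50 is the curve-midpoint parameter, matching the common
"log(inhibitor) vs response" reduction; asymptotes are left free rather
than constrained to 0–100, trading a little variance for robustness to
incomplete plateaus. Replicates are fit separately and summarized as mean
± n−1 sd, mirroring how such panels are published; an endpoint with no
converged replicate is reported missing rather than guessed.

MIC is read from a dilution plate as the lowest concentration at or above
which no well grows, after control checks; off-scale plates are censored
(`>max`, or the series minimum flagged `<=min`) rather than extrapolated.
The shipped nine-step two-fold series (3.12 down to 0.0125 mg/mL) is a
named constant because its printed rounding cannot be recovered from a
rule.

## Gray relational analysis

Deng's relational degree compares the bioactivity sequence
$y_0$ against each peak's area sequence $x_i$ after per-sequence
normalization: with deviations $\Delta_i(k) = |y_0(k) - x_i(k)|$ and global
extremes $\Delta_{\min}, \Delta_{\max}$, the relational coefficient is

$$\xi_i(k) = \frac{\Delta_{\min} + \rho\,\Delta_{\max}}
                 {\Delta_i(k) + \rho\,\Delta_{\max}},$$

and the degree $r_i$ is its mean over samples. The resolution coefficient
$\rho$ defaults to the conventional 0.5 and is exposed as an argument; at
$\rho = 0.5$ with $\Delta_{\min} = 0$ the degrees live in $(1/3, 1]$.
Sequence normalization defaults to division by the sequence mean, which
makes degrees invariant to positive rescaling of any sequence; initial-value
normalization and no normalization are selectable. Zone endpoints enter
as-is; IC50 endpoints enter as reciprocals so that larger always means more
active. Samples missing an endpoint are deleted from that endpoint's
sequence rather than imputed, because $\Delta_{\min}$ and $\Delta_{\max}$
are global statistics and imputed values would distort them for every peak.
Ties in the degree ranking break by ascending peak index, so ranks are
deterministic.

## PLS regression, Q², and VIP

One single-response NIPALS model is fit per endpoint on the unit-variance
scaled peak matrix (unit-variance scaling is the standard chemometric
default; Pareto and centering-only are available). Endpoints where smaller
is better (IC50) are negated before fitting so that active constituents
always load positive and coefficient signs are comparable across
endpoints; the raw orientation is retained as an option. Weight-vector
signs are fixed by forcing each weight vector's largest-magnitude element
positive, so output is reproducible across platforms.

Model adequacy is judged by leave-one-out Q²: the scaling and the model are
re-estimated inside every fold, and $Q^2 = 1 - \mathrm{PRESS}/\sum (y -
\bar y)^2$. Leave-one-out is chosen over Monte-Carlo or 7-fold schemes for
determinism at n = 10. Component count can be fixed (default 2 for a 10 ×
20 problem), chosen by maximal Q², or by the conventional rule that adds a
component while the Q² gain exceeds 0.0975, with a floor of one component.
Variable importance in projection is
$\mathrm{VIP}_j = \sqrt{p \sum_a \mathrm{SSY}_a (w_{ja}/\lVert w_a
\rVert)^2 / \sum_a \mathrm{SSY}_a}$ with
$\mathrm{SSY}_a = q_a^2 t_a^\top t_a$; it satisfies $\sum_j
\mathrm{VIP}_j^2 = p$, making VIP > 1 the natural importance cut.

## The consensus screen

A peak is called active on an endpoint when three conditions hold at once:
high gray relational evidence (degree above 0.8 *or* rank within the top
six — both common readings of "highly correlated", OR-combined and both
configurable), VIP above 1, and a positive (activity-oriented) regression
coefficient. The consensus score counts such endpoints, and the active
call requires the score to reach `min_endpoints` (default: every endpoint
supplied, mirroring the practice of requiring agreement across a whole
activity class). Tightening any threshold can only shrink the active set.

## Network statistics

The network stage is deliberately offline: target predictions, disease
associations, interaction edges, and pathway membership are *inputs*
(delimited text exported from whatever databases the analyst uses), never
live queries, because versioned web resources are irreproducible. The
package computes exact set intersections with Venn counts, degree maps and
the average degree 2E/N, deterministic top-k degree ranking
(lexicographic ties), upper-tail hypergeometric enrichment with
Benjamini-Hochberg adjustment, and the tetrapartite
component-target-pathway-disease edge list (targets strictly above the
mean degree; top 20 pathways by ascending p). Significance filtering
defaults to adjusted p < alpha; the raw-p and reversed-inequality options
exist so that nonstandard published filter conditions can be reproduced and
audited rather than silently corrected.

## What the synthetic generators emulate

Every stage is testable without downloads because the `gen_*` family
generates inputs with known ground truth: a fingerprint truth (reference
times, true areas, planted active peaks with effect weights), jittered and
dropout-afflicted peak tables, activity endpoints linked to the latent
potency $u_s = \sum_{j \in \mathrm{active}} w_j x^{\mathrm{norm}}_{sj} +
\varepsilon$, 4PL dose-response records, MIC plates, and an annotation
universe with one planted enriched term. All generators are pure functions
of their parameters and a seed, drawing from per-generator substreams so
fixtures are reproducible piecewise.

The defaults encode a deliberately realistic regime, chosen once:

* **Ten extracts, twenty peaks, three planted actives.** The standard
  shape of an extract-panel screen.
* **Log-normal areas, common log-sd 0.25, medians spanning one order of
  magnitude.** Characteristic peaks are by construction all major
  constituents, and the resulting relative dispersion is commensurate with
  the spread seen in published endpoint panels — the regime in which a
  closeness-based gray relational ranking is informative at all.
* **Co-varying active congeners (log-area correlation 0.9).** The
  constituents such screens nominate are typically congeners of one
  biosynthetic family whose abundances rise and fall together across
  extraction polarities. This correlation is what lets a three-peak signal
  survive the √3 variance shrinkage of averaging and the assay baseline:
  with independent actives, no positive baseline admits a reference
  sequence as dispersed as its drivers, and closeness ranking degrades.
* **Equal-signal effect weights.** Weights are reciprocal dispersions of
  the normalized areas, rescaled to unit mean contribution, so every
  planted constituent is equally discoverable; recovery rates then measure
  the pipeline, not an accident of weight assignment.
* **Links.** Zones are `6 + 2u` mm (a 6 mm disk plus growth inhibition);
  IC50 is `300/(u + 0.5)` µg/mL so more potent extracts have smaller
  values, of order 100 µg/mL.
* **Noise.** Gaussian, on retention times (sd 0.02 min), on potency
  (stated as a fraction of the potency sd; validation uses 10%), and on
  dose-response rates (percent points).

What the generators do *not* emulate: chromatographic signal traces and
co-eluting peak overlap, heteroscedastic detector noise, systematic
retention drift within a run, plate-position effects, correlated
assay replicates, and annotation term overlap structure. Passing tests
therefore demonstrate correctness of the computations and sensible
behaviour in a realistic noise regime, not robustness to every artefact of
real instruments.

## Numerical choices and degenerate inputs

Matching uses a greedy nearest-assignment; on well-separated references it
coincides with the exhaustive minimal-total-deviation assignment (checked
against a brute-force oracle in the tests), and contended cases are flagged
by the 2-window ambiguity warning. Zero normalization denominators, zero
IC50s (no reciprocal), constant responses (no PLS), identical gray
sequences ($\Delta_{\max} = 0$, all degrees 1 with a warning), non-monotone
MIC plates, and failed controls all raise errors or flagged results rather
than silent numbers. The 4PL optimizer reports an honest `converged` flag;
cross-validation folds that fail fall back to the fold-training mean with a
warning rather than aborting the whole curve.

## Problem sizes used in validation

The shipped validation suite exercises the scales the pipeline targets:
100 random gray-relational instances (up to 12 samples × 25 peaks) against
a step-by-step oracle at 1e-12; 50 random 10 × 20 PLS instances against an
independent reference implementation at 1e-8; 50 pure-noise and 10
planted-signal Q² panels; 200 noisy dose-response simulations (2 percent
points of noise on a nine-concentration, triplicate design spanning two
decades around the expected IC50); MIC round trips over the full dilution
series plus 50 random plates; 100 end-to-end screening replicates at 10%
potency noise; and a complete enumeration sweep of every hypergeometric
configuration with universe size up to 20.

## Known limitations

* Ranks and calls from n = 10 panels are volatile under resampling; the
  consensus rule controls, but cannot eliminate, false nominations
  (the validation suite tracks the false-positive mean).
* Published gray relational tables are generally not exactly reproducible
  unless the original $\rho$, normalization, and missing-data handling are
  stated; this implementation makes all three explicit arguments instead.
* The PLS stage fits one endpoint at a time; multi-response (multi-Y)
  models, OPLS, and permutation validation are out of scope.
* The network stage trusts its input exports; it performs no identifier
  mapping, ontology propagation, or pathway topology analysis.
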