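---
title: "Methods: mesh-derived body measurements and the height-weight baseline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mesh-derived body measurements and the height-weight baseline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anthrofit)
```

## The problem

Many applications — virtual try-on, ergonomics, VR avatars — need a
person's body measurements (girths and lengths) without a measuring
tape, a scanner, or a photograph. Height and weight are the two numbers
almost everyone knows about themselves. anthrofit implements the
corresponding baseline: per-sex linear regressions that predict each of
15 standard body measurements from self-reported height and weight
alone, together with the machinery needed to *obtain* those
measurements from template body meshes in the first place, and to
evaluate any measurement-estimation method against expert accuracy
bounds.

## Measurement extraction from template meshes

The extraction protocol assumes a *template* topology: a fixed triangle
mesh (the SMPL body template, 6890 vertices) in which a given vertex
index always denotes the same anatomical location. Twenty landmarks are
therefore plain vertex indices (`smpl_landmark_table()`); the registry
treats the published indices as 0-based offsets into the vertex array,
the convention of the SMPL software ecosystem. For other topologies a
user-supplied registry with the same structure is accepted.

Each of the 18 measurement definitions is either

* a **length** — the Euclidean distance between its two landmark
  vertices, in mm; or
* a **circumference** — the mesh is cut by a plane through the landmark
  vertex, the triangle-plane intersection segments are chained into
  closed loops, and the perimeter of the loop nearest the landmark is
  returned.

Two choices here are ours and deliberately documented as such, because
the protocol's published description does not pin them down:

* **Plane orientations.** Girths of the head, neck, torso and legs (A,
  B, D, E, F, L, M, N) use horizontal planes (normal along the up
  axis); the arm girths (G, H, I) use vertical planes with the normal
  along the body's left-right axis, because in an A-pose the arms run
  roughly along that axis. Every orientation is overridable per
  measurement in the protocol config.
* **Multi-loop handling.** A waist plane in an A-pose also crosses both
  arms; a thigh plane crosses both legs. We keep the closed loop whose
  minimum distance to the anchoring landmark vertex is smallest. This
  anchor-nearest rule is an inference, not a published rule.

Raw segment sums are reported by default. A convex-hull ("tape
measure") variant is available per call (`convex = TRUE`) but off by
default, since the protocol sums the raw segments.

Numerical details: geometry is processed in metres (heights reported in
cm, measurements in mm, volume in litres, weight in kg). Segment
endpoints are matched with a 1e-9 m tolerance when chaining loops.
Triangle-plane classification uses a 1e-12 m band around the plane so
that planes passing exactly through a vertex ring — the common case,
since planes are anchored at vertices — produce the ring polygon
itself: on-plane edges are emitted by both adjacent faces and
deduplicated, coplanar faces are skipped, and single-point contacts are
dropped. An open chain after stitching (a non-watertight cut) is an
error, as is volume computation on any mesh where some edge is not
shared by exactly two consistently-wound faces.

## Weight from volume, and the self-report noise model

Template meshes carry no scale ambiguity, so body volume $V$ is exact
(signed-tetrahedron sum). Human body density is close to
$\rho = 1 \pm 0.005$ kg/L, which makes $w = V\rho$ a usable weight
estimate. Self-reported height and weight are noisy, and the model
makes that explicit with independent zero-mean Gaussian terms:

$$V' = V + N(0,\ \sigma_V = 5\ \mathrm{L}), \qquad
  h' = h + N(0,\ \sigma_h = 1\ \mathrm{cm}), \qquad
  w = V'\rho' + N(0,\ \sigma_w = 1.5\ \mathrm{kg})$$

with $\rho' \sim N(1, 0.005)$ kg/L. At $\rho = 1$ the volume term alone
propagates to a 5 kg standard deviation on weight. The density spread
is published as a range, not a distribution; we model it as Gaussian
for consistency with the other terms, and each of the four noise
sources is independently switchable so their contributions can be
isolated. Draws that would produce a non-positive height or weight are
rejected and redrawn; at these parameter values this is an
astronomically rare tail event and does not measurably distort the
distribution. The master seed defaults to 2021 and every draw comes
from one seeded stream in subject order, so cohorts are bit-for-bit
reproducible.

## The linear baseline

For each measurement $j$ and each sex separately,

$$y_j = \mathbf{x}^T \mathbf{a}_j + b_j$$

fitted in closed form over $N$ training subjects as $A_j = (X^TX)^{-1}
X^T Y_j$, where $X$ carries a leading column of ones. The implementation
solves the least-squares problem by QR factorisation rather than
forming $(X^TX)^{-1}$; the explicit pseudoinverse form is retained only
as an independent oracle in the test suite. Rank deficiency is a
reported error naming the collinear columns.

**Interaction terms.** The augmented baselines append derived
covariates: $I=2$ adds BMI ($w/h^2$) and $w/h$; $I=4$ also adds $w^2$
and $h^2$. Base height enters in cm and weight in kg; the interaction
terms use height in metres so the BMI column is conventional
kg/m$^2$ and the term magnitudes stay comparable. The published
description of these terms is typographically ambiguous; this reading
(ratios, then squares) follows the BMI gloss, and the term formulas are
isolated in `build_design_matrix()` should a different convention be
needed.

**Diagnostics.** Per coefficient: two-sided t-tests on $N-k$ degrees of
freedom ($k$ counts the intercept). Per measurement: adjusted
$R^2 = 1-(1-R^2)(N-1)/(N-k)$, MAE and RMSE of residuals in mm.
`residual_checks()` verifies the residual assumptions: a zero-mean
t-test; Anderson-Darling normality (chosen because cohort sizes exceed
the Shapiro-Wilk limit of 5000); and a Breusch-Pagan-style Lagrange
multiplier statistic for homoscedasticity, regressing squared residuals
on fitted values with $nR^2 \sim \chi^2_1$ under the null. All
covariates are retained regardless of significance — dropping, say, the
BMI term for shoulder breadth is left to the user. Exact fits report
p-values as undefined (`NA`), never 0.

**Train/test splits.** No canonical split proportion exists for this
baseline; the CLI defaults to 80/20 stratified by sex with a logged
seed (default 2021) and writes the training row indices next to the
model so any split is reproducible.

## Evaluation metrics

MAE ($\tfrac1N\sum|y_{est}-y_{gt}|$, mm), MRE
($\tfrac1N\sum|y_{est}-y_{gt}|/y_{gt}$, per-sample, reported as %), and
the expert ratio %<Expert — the percentage of subjects whose absolute
error is *strictly* below the expert inter-observer allowable error for
that measurement. The canonical allowable-error table covers 8 of the
15 codes (A 5, B 6, C 15, D 12, E 12, I 6, K 4, O 8 mm; unweighted mean
8.5 mm); metrics for unthresholded codes are omitted, not zeroed. Both
error metrics take absolute values: the defining formulas are sometimes
typeset with the bars lost, but "absolute"/"relative error" semantics
and the all-positive published values make the intent unambiguous. Note
that strict inequality means a zero error is within any positive
threshold, however small; ties at the threshold count as failures.

An adapter maps ANSUR-style tabular exports (a public anthropometric
survey of military personnel) onto the same codes: direct attribute
copies for the girths, and composite expressions for shoulder-to-crotch
($\mathrm{sittingheight}-(\mathrm{stature}-\mathrm{acromialheight})$),
arm length ($\mathrm{acromialheight}-\mathrm{wristheight}$) and
inside-leg length
($\mathrm{crotchheight}-\mathrm{lateralmalleolusheight}$). Attribute
names are matched case-insensitively after stripping non-alphanumerics
to tolerate export dialects. The adapter is exercised on synthetic
records only; evaluating on a real ANSUR export requires the external
download and is out of scope for the test suite.

## Synthetic fixtures: what they emulate and what they do not

**Humanoid meshes.** `make_fixture_body()` builds a body-shaped
disjoint union of capped prisms over regular 64-gons — two legs, torso,
neck, head, and two horizontal arms — with vertex rings placed at every
slicing height. Prisms (not smooth cylinders) are used so every ground
truth is an exact closed form: ring perimeter $2nr\sin(\pi/n)$,
cross-section area $\tfrac12 n r^2 \sin(2\pi/n)$, lengths from placed
landmark coordinates, volume as the sum of primitive volumes. The 20
landmark roles are mapped onto generated vertices, so the full protocol
runs unchanged. Statures other than the 1.75 m reference scale the body
uniformly. These fixtures validate the geometry and protocol machinery
exactly; they do *not* emulate realistic body shape, pose variation,
clothing or hair, so passing them says nothing about landmark
placement quality on real scans.

**Populations.** `make_population()` draws per-sex cohorts in which
every measurement is a known linear function of the design row plus
independent Gaussian noise — the regression model's own generative
form. Defaults, chosen once as plausible for an adult population and
not tuned: male height $N(175, 7^2)$ cm truncated to [145, 196],
female $N(162, 6.5^2)$ truncated to [135, 190] (windows echoing the
ranges reported for public mesh datasets); weight linear in height with
Gaussian residual (male $-100 + 1.0h \pm 8$ kg, female
$-90 + 0.9h \pm 7$ kg); generating coefficients of plausible
anthropometric magnitude for all 15 codes; 5 mm measurement noise.
Because the generator satisfies the model assumptions by construction,
recovery tests confirm the estimator, not the realism of linearity in
real populations.

## Problem sizes used in the shipped checks

Cohort-level checks run at $n = 2000$ per sex with 100 seeded
replicates for coefficient-recovery coverage (each true coefficient
within 3 standard errors; the expected two-sided coverage is 99.73%,
checked as at least 99% over all coefficient-replicate pairs), 500
refits at $n = 100$ for p-value calibration of a pure-noise covariate,
and $10^5$ Monte-Carlo draws for the noise-propagation SD. Held-out MAE
at 5 mm Gaussian noise is compared against the closed form
$\mathbb{E}|N(0,\sigma)| = \sigma\sqrt{2/\pi} \approx 3.99$ mm. These
sizes give comfortable statistical resolution for the stated
tolerances while keeping a full run to tens of seconds.

## Known limitations

* Landmark indices address one specific template topology; no landmark
  detection is attempted on arbitrary scans.
* Inputs are assumed near A-pose and watertight; there is no mesh
  repair, hole filling or pose normalisation.
* Plane orientations per girth and the multi-loop rule are documented
  inferences (above), configurable but not externally validated.
* Self-report bias (under/over-reporting correlated with body size) is
  deliberately not modelled; all noise is zero-mean and uncorrelated.
* The published ANSUR/mesh-benchmark error tables are not reproduced
  here — they require external datasets; only the metric machinery and
  the adapter are provided.
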