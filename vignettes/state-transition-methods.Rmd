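---
title: "State-transition modeling of leukemia development: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{State-transition modeling of leukemia development: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statetrans)
```

## The model

`statetrans` treats the transcriptome of a subject developing acute
myeloid leukemia (AML) as a particle moving on a one-dimensional disease
axis. Three critical points structure that axis: a stable state of
perturbed hematopoiesis $c_1$, an unstable transition point $c_2$ (the
"point of no return"), and a stable leukemic state $c_3$, ordered
$c_3 < c_2 < c_1$ so that disease lies at the negative end. The
quasi-potential is the quartic whose gradient has exactly these roots,

$$U(x) = \alpha \int (x - c_1)(x - c_2)(x - c_3)\,dx,$$

with scale $\alpha$ and integration constant fixed at 0. "Quasi" matters:
this is a model of stability relations between observable phenotypes, not
a physical energy. Individual trajectories follow the Langevin equation

$$dX_t = -U'(X_t)\,dt + \sqrt{2D}\,dB_t,$$

and the population density follows the matching Fokker–Planck (FP)
equation

$$\partial_t P = \partial_x\!\left(U'(x)\,P\right) + D\,\partial_x^2 P.$$

One parameter $D$ (state-units$^2$/month) plays both roles — Langevin
noise amplitude $\sqrt{2D}$ and FP diffusion coefficient — which makes
the simulator and the solver two faces of one stochastic process; the
package tests their agreement directly (`fp_vs_langevin_check()`). A
transport form with the opposite drift sign is occasionally written down
for this equation; its solutions do not match the Langevin ensemble, and
it is kept only behind `convention = "printed"` as a deliberate negative
control.

The probability of having transitioned by time $t$ is the density mass
past the unstable point,
$F(t) = \int_{-\infty}^{c_2} P(x, t)\,dx$, and $S(t) = 1 - F(t)$ is the
predicted survival curve.

## The state-space

The disease axis is built from data by singular value decomposition of
the centered, log-normalized count matrix, $X = U \Sigma V^*$, with
samples as rows and features (miRNAs) as columns. Principal components
are $U\Sigma$; rows of $V^*$ are feature loadings. The axis ("PC1" in
the package's vocabulary, whatever its rank in the SVD) is the component
most correlated with a disease-burden marker (Kit-like expression),
with genotype separation as tie-break, and is oriented so that leukemia
is negative — late CM samples sit below controls. Validation cohorts are
projected with the training loadings and training feature means only;
no refit.

Concretely, "log-normalized" means counts-per-million followed by
$\log_2(x + 1)$ and per-feature mean-centering (pseudocount and feature
means are stored so that new cohorts are transformed identically). The
default expression filter keeps features with at least 5 counts in at
least 3 samples. None of the downstream logic depends on these two
choices beyond their being applied consistently to training and
validation data.

## Estimating the model from data

**Critical points.** Exact 1-D $K$-means ($K = 3$, dynamic programming —
no random initialization, hence fully deterministic and
permutation-invariant) partitions the CM samples' axis coordinates into
clusters K1, K2, K3; $\hat c_1$ and $\hat c_3$ are the K1 and K3 means.
$\hat c_2$ maximizes the Boltzmann ratio
$\exp\{-(U(c_3) - U(c_1))/k_B\}$ over candidates drawn from K2, where
the candidate potential has roots $(\hat c_1, x, \hat c_3)$. The
objective is strictly monotone in the candidate
($d\Delta/dx = -\alpha\int_{c_3}^{c_1}(s-c_1)(s-c_3)\,ds \neq 0$), so
the estimate lands at the K1-side edge of K2 — the transition point is
identified near the K1/K2 boundary, which is also where simulation
says it is best estimated. Both $\alpha$ and $k_B$ apply monotone
transforms to the objective and cannot move the argmax; they are kept
as parameters for transparency, with $k_B$ defaulting to the estimated
diffusion (fluctuation scale as temperature).

**Diffusion.** $\hat D$ is half the slope of the mean squared
displacement of per-mouse axis trajectories against lag (default lags
1–3 months, all overlapping time origins), the Brownian identity
$\mathrm{MSD}(\tau) = 2D\tau$. On confined (in-well) trajectories the
MSD saturates and this estimator is biased low; on trajectories that
include a transition the large displacement inflates it. The package
does not correct either effect — the potential-scale calibration below
absorbs the residual scale error — but recovery is verified on free
Brownian cohorts, where the estimator is consistent.

**Potential scale.** The published description of the model never
states how $\alpha$ was fit. The package's choice is the minimal
calibration with an observable anchor: $\alpha$ is tuned by 1-D root
finding (on $\log\alpha$, coarse FP grid during the search) so that the
FP median transition time matches the training cohort's observed median
time-to-leukemia. Larger $\alpha$ deepens the barrier and slows
transition monotonically, so the root is unique.

**Initial condition.** The FP density starts as a Gaussian fitted to
the first post-induction (month-1) axis coordinates of the cohort being
predicted, with an SD floor of 0.1 state units. Samples already past
$c_2$ at month 1 are excluded: the time-to-transition question is posed
for subjects still at risk, and a baseline mixture containing
already-transitioned subjects is not a Gaussian around the
pre-transition state. For cohorts in which no subject has transitioned
by month 1 — the situation the protocol anticipates — the exclusion is
a no-op.

## The Fokker–Planck solver

The FP equation is discretized in conservative finite-volume form with
Scharfetter–Gummel (exponential-fitting) interface fluxes, no-flux
boundaries, and Crank–Nicolson time stepping (four backward-Euler start
steps damp the initial layer); the tridiagonal systems are solved by
the Thomas algorithm in compiled code. Two properties motivate this
scheme: total mass is conserved to solver precision (the generator's
columns sum to zero), and the discrete stationary solution is *exactly*
the Boltzmann density $Z^{-1} e^{-U/D}$ at the nodes. Defaults:
$n_x = 800$ nodes, internal step 0.01 month, domain padding
$\max(2.1,\ 0.35\,(c_1 - c_3))$ beyond the outer critical points. The
suite checks the heat-kernel limit ($\alpha = 0$, max error
$< 10^{-3}$), the stationary limit ($L_1 < 10^{-3}$), mass conservation
($< 10^{-6}$), Kramers' escape rate within 25% at $\Delta U / D > 5$,
grid-refinement stability, and agreement with a 5,000-path
Euler–Maruyama ensemble within three binomial standard errors plus
0.02 at every monthly time point.

Because mass can diffuse back across the unstable point, the reported
transition-probability curve applies a running-maximum envelope by
default; the raw integral is kept alongside and is the quantity
compared against the Langevin ensemble.

## Survival comparison

The predicted curve is compared to observed outcomes by the log-rank
test. A continuous model curve has no risk table, so the predicted arm
is instantiated as a pseudo-cohort by the inverse CDF of $F(t)$
restricted to the monthly evaluation grid. The quantiles are stratified,
$u_i = (i - \tfrac12)/n$, making the pseudo-cohort the deterministic
discrete representation of the curve — the test then measures
model-versus-data discrepancy, not Monte-Carlo noise; random draws
remain available. The pseudo-cohort defaults to three times the
observed cohort size, which reduces curve-discretization error while
the observed arm still dominates the variance. Subjects alive at the
study end enter as censored; the hazard ratio is the Mantel–Haenszel
observed/expected ratio with a log-scale normal interval.

## Critical-point-aligned differential expression and dynamics

Cluster membership (K1/K2/K3) acts as a pseudo-time alignment: mice
progress at different rates, but samples in the same cluster occupy the
same disease state. Each state's CM samples are compared against *all*
control samples (controls remain in their basin throughout; a
time-matched comparison is available behind a flag). The default engine
is limma's empirical-Bayes moderated t-statistic: the transition
cluster frequently holds only 2–7 samples, where per-feature Welch
tests have essentially no power while variance moderation across ~300
features retains it; Welch and Wilcoxon remain available. BH-adjusted
p < 0.05 declares a feature differentially expressed (DE).

Events are classified by set logic: early = DE only at $c_1$,
transition = only at $c_2$, late = only at $c_3$, persistent = DE at
all three; features DE at exactly two states are reported as
unassigned rather than forced into a class. Each class × direction gets
a contribution vector, the mean $(V_1^*, V_2^*)$ loading pair of its
members, and each member a leukemia-contribution score $-V_1^*$ if
up-regulated and $+V_1^*$ if down-regulated — positive scores move the
state toward the (negative) leukemic pole, so a feature with a large
positive loading whose expression falls contributes to disease just as
one with a negative loading whose expression rises.

Expression dynamics are explored by average-linkage hierarchical
clustering of feature–feature Pearson correlations (distance $1 - r$)
over CM samples, default four groups with a silhouette-based suggestion
printed but never auto-applied; group-mean expression is regressed on
the axis coordinate with a cubic polynomial (the lowest degree
admitting one interior extremum plus asymmetry; LOESS behind a flag)
and classified by the sign changes of the fitted derivative.
Group × event-class over-representation uses one-sided hypergeometric
tests with BH correction; empty classes give p = 1.

## The synthetic-cohort generator

`simulate_cohort()` emulates the designed study: a training cohort of 7
CM and 7 control mice sampled monthly from induction to 10 months, and
validation-style cohorts (9 CM, 7 control, 6 months) by changing the
size arguments. Its defaults *are* the study conditions under which the
acceptance properties are evaluated:

* **Geometry** $c = (2, 1, -4)$, $\alpha_{CM} = 0.55$, $D = 0.5$. The
  saddle sits close to $c_1$ and the leukemic well is deep and far:
  mice fluctuate tightly around perturbed hematopoiesis for months
  (well SD $\approx 0.39$), escape at a rate giving ~80% transition by
  10 months with median onset near 4 months (the model system's
  published median survival anchor), then descend rapidly and
  irreversibly. At fixed well spacing the escape rate
  $\propto \alpha e^{-\Delta U/D}$ is maximized near
  $\alpha_{CM} = 0.55$, which simultaneously keeps clusters tight,
  limits mid-descent samples, and leaves the barrier
  ($\Delta U/D \approx 1$) sensitive enough to diffusion mismatches for
  the negative-control check. A wider spacing with the saddle midway
  (e.g. $c_2 = 0$) cannot reach an 80% transition fraction at any
  $(\alpha, D)$ without noise levels that destroy the cluster
  structure; this is a scaling property of the cubic family, not a
  tuning accident.
* **Controls** evolve in the same cubic family at $\alpha_{ctrl} = 8$
  (escape probability $< 10^{-4}$ over the study), with their stable
  state offset $+0.75$ above $c_1$: normal and perturbed hematopoiesis
  are distinct states, so CM and control samples separate on the axis
  from the first post-induction month — and, crucially, features read
  out from the latent coordinate can be genuinely DE at $c_1$. With
  controls exactly at $c_1$, CM-at-K1 samples would be statistically
  identical to controls and no early or persistent events could exist.
  CM mice start at $c_1$ itself: the perturbed set point establishes
  within days of induction, far below the monthly sampling interval.
* **Observation and death.** All mice are sampled at integer months; a
  CM mouse whose position at an observation has fallen below
  $c_3 + 0.5$ (settled in the leukemic basin, i.e. moribund)
  contributes that terminal sample and exits; everyone else is
  censored at the study end. Ground truth records the first fine-grid
  crossing of $c_2$ as the onset time.
* **Count readout.** Expected $\log_2$ expression of feature $j$ is
  $b_j + f_j(x)$: linear in the latent coordinate for monotonic
  features ($\pm 0.5\ \log_2$/state-unit; "up in AML" means rising as
  $x$ decreases), a Gaussian bump of height 1 $\log_2$ unit and width
  1.3 state units centered at $c_2$ for peak/trough features (the
  "restoring force" picture: expression rises toward the point of no
  return and subsides once it is passed — an unbounded quadratic would
  instead put the dominant signal at $c_3$ and turn these features
  into late events), and 0 for null features. Counts are
  negative-binomial (dispersion 0.1) around compositional fractions
  scaled by a log-normal library (mean $10^6$). Disease-modulated
  features are drawn from the low/mid-abundance range
  ($b_j \sim U(4,7)$ vs $U(4,10)$ for nulls — the most abundant
  miRNAs are housekeeping-stable), which keeps their share of library
  mass small enough that counts-per-million normalization stays
  compositionally stable; without this, the large monotonic swings
  make most null features spuriously DE.
* **Marker.** $-x$ plus Gaussian noise (SD 1.0), so the Kit-like
  marker rises toward leukemia and the marker–axis $R^2$ falls in the
  0.6–0.8 range typical of the real measurement.
* **Integration.** Euler–Maruyama with a 0.005-month internal step and
  linear interpolation onto the observation grid; every random stage
  takes a seed and equal seeds give byte-identical cohorts.

### What the generator does and does not emulate

It reproduces the statistical structure the analysis assumes: a 1-D
latent disease process with bistable dynamics, a low-rank NB count
readout, monthly sampling with death-truncation, a noisy disease-burden
marker, and cohort sizes of the designed study. It does **not**
emulate batch effects, library-preparation artifacts, multi-lineage
cell-composition shifts in peripheral blood, feature–feature regulatory
correlation beyond the shared latent coordinate, or
genotype effects on expression that bypass the latent coordinate.
The last point matters for interpretation: in real data, "early
events" can be genuinely transient genotype effects (e.g. inflammatory
response after induction) that vanish later. Here every effect is a
function of latent position, so a feature peaked at $c_2$ is called
early-only exactly when the $c_2$ comparison is underpowered — which
happens in cohorts whose transition cluster is small. The early-event
enrichment of nonmonotonic features therefore holds as a per-replicate
majority, not in every cohort, and passing it should not be read as
evidence that the pipeline would find biologically transient early
events; that mechanism is outside the generator's scope.

## Numerical and degenerate-input policy

Zero-total-count samples, empty feature filters, constant markers,
rank-0 matrices, all-identical coordinates, empty candidate sets,
diverging trajectories, singleton state clusters and event-free
survival comparisons all fail with explicit messages rather than
propagating NaN. Constant features are excluded (with a warning) before
correlation; zero-variance features in DE are reported non-DE with
p = 1 and a degenerate flag. Exact ties in the Boltzmann objective
break toward the midpoint of $(c_3, c_1)$; ties in marker $R^2$ break
by genotype separation. State groups of two samples are allowed in the
moderated DE engine (variance is pooled across features); groups of one
are refused.

## Problem sizes

The test suite and the acceptance script use the designed cohort sizes
(7 + 7 training, 9 + 7 validation, 300 features) with 20-replicate
ensembles for recovery and survival properties, 5,000-path Langevin
ensembles, and 800-node FP grids; the full acceptance computation
completes in well under a minute on one core.

## Known limitations

* The MSD diffusion estimator is biased on confined trajectories (see
  above); only its Brownian-regime consistency is claimed.
* The $c_2$ estimator returns the K1-side edge of cluster K2 by
  construction; its uncertainty is bounded by the K2 range, not by a
  sampling distribution.
* The log-rank comparison of a model curve against nine mice has
  limited power; the quadrupled-diffusion negative control rejects in
  roughly 65–90% of replicate ensembles depending on the seed stream,
  because a fourfold diffusion change moves the escape rate only about
  twofold at this barrier height.
* With ~1.5% probability a default cohort yields a singleton
  transition cluster, in which case the $c_2$ differential-expression
  comparison is undefined and the package fails informatively.
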