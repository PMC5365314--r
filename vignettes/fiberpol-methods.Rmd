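---
title: "Models and methods behind fiberpol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fiberpol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiberpol)
```

# The scientific problem

Bifunctional rhodamine probes attached across two cysteines of a target
helix (the C or E helix of cardiac troponin C, or the B-C helices of the
myosin regulatory light chain) hold their fluorescence dipole rigidly along
that helix. In a permeabilized cardiac trabecula, the polarized fluorescence
from such probes reports the ensemble orientation of the labelled domain
relative to the fiber axis. The summary quantity is the second-rank order
parameter

$$\langle P_2\rangle = \left\langle \tfrac{3\cos^2\theta - 1}{2}
\right\rangle,$$

where $\theta$ is the dipole-to-axis angle: $+1$ if all dipoles are
parallel to the axis, $-0.5$ if all perpendicular, $0$ if isotropic. The
fourth-rank $\langle P_4\rangle$ carries complementary angular resolution.
Titrating the bathing calcium (expressed as pCa $= -\log_{10}[\mathrm{Ca^{2+}}]$)
and fitting force and $\langle P_2\rangle$ against pCa with the Hill
equation quantifies calcium sensitivity (pCa$_{50}$) and cooperativity
($n_H$); comparing these between sarcomere lengths of 1.9 and 2.3 µm, and
before/after the myosin inhibitor blebbistatin, dissects the cellular basis
of length-dependent activation. fiberpol implements that full quantitative
chain as reusable, tested code, driven by a synthetic-data generator so
every stage is verifiable without access to the original recordings.

# The optical model

## Forward model

We use the static uniaxial parallel-dipole model: excitation and emission
dipoles coincide, the dipole population is cylindrically symmetric about the
fiber axis, and the illumination/collection geometry resolves four intensity
components indexed by excitation and emission polarization
(parallel/perpendicular to the axis). With $m_2 = \langle\cos^2\theta\rangle$
and $m_4 = \langle\cos^4\theta\rangle$ and a brightness factor $S$:

$$I_{\parallel\parallel} = S\,m_4,\qquad
I_{\parallel\perp} = I_{\perp\parallel} = S\,\frac{m_2 - m_4}{2},\qquad
I_{\perp\perp} = S\,\frac{3}{8}\left(1 - 2m_2 + m_4\right).$$

These are the angular factors $\cos^4\theta$, $\tfrac12\cos^2\theta\sin^2\theta$
and $\tfrac38\sin^4\theta$ averaged over the distribution (the $\tfrac38$
arises from averaging the emission projection over the azimuth). The order
parameters follow linearly: $\langle P_2\rangle = (3m_2-1)/2$,
$\langle P_4\rangle = (35 m_4 - 30 m_2 + 3)/8$.

Two modelling choices deserve emphasis:

* **Fast wobble is metadata.** The sub-nanosecond wobble order parameter
  $\langle P_{2d}\rangle$ is, in the experimental literature, measured
  separately and folded into the intensity equations. Here it is carried as
  a supplied constant on the `order_params` object and may be applied as an
  extra attenuation factor in the generator, but it does not enter the
  absorption-emission correlation. The benefit is a model that is
  self-contained and exactly invertible; the cost is that our
  $\langle P_2\rangle$ is the time-averaged dipole order parameter, which
  differs from a full restricted-wobble treatment when wobble is large.
* **No numerical-aperture correction.** Collection-optics corrections are
  instrument-specific and are not modelled.

## Inversion, feasibility, projection

The three distinct components give an exact linear solve:
$S = I_{\parallel\parallel} + 4\bar I_\times + \tfrac83 I_{\perp\perp}$,
$m_4 = I_{\parallel\parallel}/S$, $m_2 = (I_{\parallel\parallel} + 2\bar
I_\times)/S$, where $\bar I_\times$ averages the two crossed components (the
static model predicts them equal; their measured discrepancy is returned as
a data-quality metric). A genuine moment pair must satisfy
$m_2^2 \le m_4 \le m_2 \le 1$. Noise can push the solved pair outside this
region; fiberpol then projects to the nearest feasible point (Euclidean
distance in the $(m_2, m_4)$ plane, solved as a 1-d clamped minimization)
and sets `feasibility_flag` — never a silent clip.

## Angle distributions

The generator's continuous family is a Gaussian on the sphere: density
$\propto \exp(-(\theta-\theta_0)^2/2\sigma^2)\,\sin\theta$ on $[0,\pi]$,
reflected at both boundaries. No parametric family is canonical here; this
one is smooth, has transparent parameters (mean angle, dispersion, both in
degrees at the interface), and tends to the isotropic distribution as
$\sigma \to \infty$, which the tests exploit. Moments are computed by
adaptive quadrature restricted to the mass-carrying interval (absolute
tolerance $10^{-12}$, verified against a dense-grid trapezoid oracle to
$10^{-8}$); delta distributions use the closed form and mixtures are
weight-averaged.

# Free-calcium solver

Activating solutions contain 10 mM EGTA, 5 mM MgATP, 1 mM free Mg²⁺ and
0-10 mM total calcium at pH 7.1, 20 °C, ionic strength 0.2 M. fiberpol
replaces the external MaxChelator-style program with a mass-balance solver
over the 1:1 species set {Ca·EGTA, Mg·EGTA, Ca·ATP, Mg·ATP}. Protonation
microstates are folded into *apparent* association constants at the stated
conditions, exactly as MaxChelator tabulations do; the shipped defaults
(`default_binding_constants()`, `inst/extdata/default_solution.yaml`) are
in the standard range for those conditions but are defaults, not
measurements — no quantitative claim in the test suite depends on their
exact values. Free Mg²⁺ is clamped (total Mg is an output), matching how
the solutions are specified. Because bound calcium is monotone in free
calcium, the calcium residual is strictly monotone and plain bisection
converges unconditionally; we run it to interval collapse (~1 ulp), leaving
conservation residuals near $10^{-19}$ M, far inside the $10^{-12}$ M
contract. The inverse problem (total calcium to hit a target pCa) is a
second bisection wrapped around the first.

# Hill fitting

The titration model is

$$Y(\mathrm{pCa}) = \text{baseline} + \text{amplitude} \cdot
\frac{1}{1 + 10^{\,n_H(\mathrm{pCa} - \mathrm{pCa}_{50})}},$$

four parameters for $\langle P_2\rangle$ curves (the relaxed-state
$\langle P_2\rangle$ is a real, probe-dependent baseline; amplitude is
signed, negative for the troponin probes) and three for force (baseline
fixed at 0, the package convention; `normalize = TRUE` reports responses as
fraction of the fitted maximum). The fitter is a small Levenberg-Marquardt
with the analytic Jacobian. We wrote it rather than use `nls()` because the
contract demands exact recovery (residual $<10^{-10}$) on noise-free
synthetic data, a regime where `nls()` aborts with its zero-residual error.
Standard errors come from the usual linearized covariance
$s^2 (J^\top J)^{-1}$. Initialization: plateau means of the two extreme pCa
points for baseline/amplitude, half-level crossing of the piecewise-linear
interpolation for pCa$_{50}$, $n_H = 3$. Bounds: $n_H \in [0.5, 10]$ and
pCa$_{50}$ within the data range ± 0.5, preventing divergence on noisy flat
curves (reported $n_H$ in this preparation is about 2.5-4.3). A fitted
amplitude indistinguishable from zero at $2\sigma$ flags the result
degenerate rather than raising.

The activation change $\Delta\langle P_2\rangle$ is the measured response
difference between pCa 4.5 and pCa 6, computed per preparation and averaged
afterwards — which is why a cohort's delta column can differ in the last
digit from the difference of the cohort means at the two anchor pCa values,
a discrepancy visible in published summary tables and reproduced by the
acceptance tests.

# Paired statistics

Every contrast is paired within a preparation (the same trabecula at both
sarcomere lengths, or before/after inhibitor), so the workhorse is the
classical two-tailed paired t-test on within-pair differences.
`build_summary_table()` assembles mean ± SEM grids in two layouts — the
sarcomere-length comparison (star = paired 1.9 vs 2.3 µm, p < 0.05) and the
inhibitor comparison (star = control vs inhibitor at 1.9 µm, hash = 1.9 vs
2.3 µm under inhibitor). Deliberate choices: no multiple-testing correction
(each flag is a single α = 0.05 test, noted in the rendered footer);
zero-variance difference vectors flag degenerate instead of raising
(identical pairs give no star); missing pairs empty the cell rather than
aborting the table.

# The synthetic world

The generator emulates the study design: per-trabecula Hill-shaped pCa
dependence of force and $\langle P_2\rangle$ on the grid
{9.0, 6.6, 6.0, 5.8, 5.6, 5.5, 5.4, 5.2, 5.0, 4.5}, two sarcomere lengths,
optional blebbistatin arm, and the probe-specific signs (troponin probes
lose order on activation, the light-chain probe gains it).

**Stated-world defaults.** The condition-effect table
(`condition_effects()`) uses the published-scale values observed at SL 1.9
control: C helix $\langle P_2\rangle$ 0.108 → 0.028 with pCa$_{50}$ 5.37 /
$n_H$ 3.28, force 22.7 kPa with 5.37 / 4.03; E helix 0.283 → 0.182, 5.34 /
3.59, force 23.2 kPa with 5.37 / 4.12. Effects: +0.11 pCa units on
$\langle P_2\rangle$ pCa$_{50}$ and +0.12 on force pCa$_{50}$ at SL 2.3,
×1.4 maximal force; blebbistatin shifts pCa$_{50}$ by −0.08, scales $n_H$
by 0.83 and leaves 1.5% of control force. The light-chain probe has no
published table; its defaults (0.040 → 0.100, pCa$_{50}$ 5.40, $n_H$ 3) were
chosen once as a plausible positive-going curve and are not revisited.

**Alignment attenuation.** Myofibrillar disorder multiplies order
parameters; stretched trabeculae are better aligned. Defaults:
$d_2 = 0.85$ at 1.9 µm and $0.93$ at 2.3 µm (their ratio, 1.094,
reproduces the observed rise of relaxed $\langle P_2\rangle$ with stretch,
e.g. 0.283 → 0.310 for the E helix), with $d_4 \approx d_2^2$. The
generator treats the SL 1.9 table values as *post*-attenuation, divides by
$d_2(1.9)$ to get the underlying dipole curve, forms the companion
$\langle P_4\rangle$ by the delta-function-at-mean-angle closure (the data
do not constrain it; the choice is recorded in the truth sidecar),
attenuates per sarcomere length, and runs the forward optical model. A
known, accepted consequence: multiplicative disorder scales
$\Delta\langle P_2\rangle$ by $d_2(2.3)/d_2(1.9)$ at the longer length
(−0.101 → about −0.110 for the E helix), whereas the published tables show
the delta unchanged by stretch; the mechanism preserves direction and
approximate magnitude of every contrast but not that exact invariance.

**Noise.** Multiplicative Gaussian noise on each intensity component
(CV 0.02) and on force (CV 0.03); per-trabecula random offsets on
pCa$_{50}$ (SD 0.05 pCa units) and on baseline $\langle P_2\rangle$
(SD 0.01), shared across a trabecula's conditions — this is what makes the
paired design informative. Magnitudes are calibrated so cohort SEMs at
n = 5-7 land within a factor of 2 of published-scale SEMs (a tested
invariant); real per-point scatter is not recoverable from printed tables,
so these are calibrated, not measured.

**What a green test does not establish.** The generator contains no
sarcomere shortening during activation (the end-compliance artifact that
biases fixed-end pCa$_{50}$ and $n_H$ downward — the fitter's response to a
simulated drift of that kind is tested qualitatively, but the generator
does not produce it), no photobleaching, no detector calibration drift, and
models blebbistatin purely through its effect table. Parameter recovery on
this synthetic world validates the pipeline's correctness, not the
biological conclusions.

# Numerical choices and degenerate inputs

* Bisection (never Newton) in the calcium solver: unconditional convergence
  on a monotone residual.
* Levenberg-Marquardt with bound clamping in the Hill fitter; convergence on
  relative step $<10^{-12}$ or SSR improvement $<10^{-15}$.
* Feasibility tolerances of $10^{-9}$ on the moment region: tighter than any
  physical signal, loose enough to absorb quadrature round-off.
* All-zero intensity vectors, negative intensities, mixture weights not
  summing to 1, fewer than 5 distinct pCa points, and unachievable pCa
  targets raise informative errors; flat titrations and zero-variance pairs
  flag instead of raising.
* Determinism: generators take explicit seeds, derive per-trabecula seeds
  reproducibly from the master seed, and restore the caller's RNG state.

# Known limitations

The optical model omits restricted-wobble coupling and numerical-aperture
effects; the calcium constants are defaults; the $\langle P_4\rangle$
closure is a one-parameter stand-in; the blebbistatin arm is
phenomenological; and the summary-table layout assumes probe groups are
independent cohorts. Each limitation is deliberate and localized so a user
with instrument-specific knowledge can replace the relevant defaults.
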