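# fiberpol

Quantitative analysis of polarized-fluorescence probe orientation and
calcium titrations in striated muscle.

Bifunctional rhodamine probes attached across a target helix (troponin C's
C or E helix, or the myosin regulatory light chain's B-C helices) orient
their fluorescence dipole along that helix. In a permeabilized cardiac
trabecula, the four polarized fluorescence intensity components — excitation
and emission each parallel or perpendicular to the fiber axis — determine
the Legendre orientation order parameters

    <P2> = <(3 cos²θ − 1)/2>,   <P4> = <(35 cos⁴θ − 30 cos²θ + 3)/8>,

with θ the dipole-to-axis angle (`<P2>` is +1 for all-parallel, −0.5 for
all-perpendicular, 0 for isotropic). Titrating bathing calcium (pCa =
−log₁₀[Ca²⁺]) and fitting force-pCa and `<P2>`-pCa curves with the Hill
equation

    Y = baseline + amplitude / (1 + 10^( nH·(pCa − pCa50) ))

yields calcium sensitivity (pCa50) and cooperativity (nH). Comparing these
within the same preparation at sarcomere lengths 1.9 vs 2.3 µm, and
before/after the myosin inhibitor blebbistatin, probes the mechanism of
length-dependent activation (the cellular Frank–Starling effect).

fiberpol provides, as tested reusable modules:

- **Optical model** — exact forward/inverse mapping between feasible
  `(<P2>, <P4>)` pairs and the four intensity components under the static
  uniaxial parallel-dipole model, with feasibility projection and flagging
  of noisy inversions, disorder attenuation, and `<P2>` mixture linearity.
- **Calcium buffer solver** — free Ca²⁺ and pCa for Ca/Mg/EGTA/ATP
  solutions by monotone mass-balance bisection (a MaxChelator replacement),
  plus the inverse solution-design problem.
- **Hill fitting** — Levenberg–Marquardt nonlinear least squares with
  analytic Jacobian, standard errors, degenerate-curve flagging, and the
  pCa 6 → 4.5 activation change Δ`<P2>`.
- **Paired statistics** — paired t-tests and publication-style mean ± SEM
  summary tables with significance flags for the sarcomere-length and
  inhibitor contrasts.
- **Synthetic-data generator** — deterministic cohorts with the study's
  condition structure and calibrated noise, with a ground-truth sidecar for
  parameter-recovery scoring.
- **Pipeline / CLI** — `simulate → invert → fit → report` with CSV/YAML
  schemas and config-hashed outputs (`inst/cli/fiberpol.R`).

## Worked example

Simulate a 5-trabecula C-helix cohort at both sarcomere lengths, invert the
intensities to order parameters, fit Hill curves per trabecula and
condition, and build the paired summary table:

```r
library(fiberpol)
sim  <- generate_cohort(5, probe = "cTnC-C", master_seed = 42)
fits <- fit_records(invert_records(sim$records))
tbl  <- build_summary_table(fits, layout = "table1")
cat(format_summary_table(tbl), sep = "\n")
```

```
== cTnC-C ==
  force  fmax       [SL 1.9] 22.8 +/- 0.19 (n=5)  [SL 2.3] 32 +/- 0.345 (n=5) *
  force  pca50      [SL 1.9] 5.37 +/- 0.0162 (n=5)  [SL 2.3] 5.49 +/- 0.0183 (n=5) *
  force  n_h        [SL 1.9] 4.08 +/- 0.0917 (n=5)  [SL 2.3] 3.97 +/- 0.0557 (n=5)
  p2     pca50      [SL 1.9] 5.37 +/- 0.0214 (n=5)  [SL 2.3] 5.47 +/- 0.019 (n=5) *
  p2     n_h        [SL 1.9] 3.71 +/- 0.455 (n=5)  [SL 2.3] 3.36 +/- 0.237 (n=5)
  p2     resp_pca6  [SL 1.9] 0.11 +/- 0.00518 (n=5)  [SL 2.3] 0.121 +/- 0.00461 (n=5) *
  p2     resp_pca45 [SL 1.9] 0.0295 +/- 0.00282 (n=5)  [SL 2.3] 0.0337 +/- 0.00693 (n=5)
  p2     delta      [SL 1.9] -0.0806 +/- 0.00298 (n=5)  [SL 2.3] -0.0877 +/- 0.00322 (n=5)
flags are single two-tailed paired t-tests; no multiple-testing correction
```

Reading it: stretching from 1.9 to 2.3 µm raises maximal force ~40% and
pCa50 by ~0.12 (force) / ~0.11 (`<P2>`) pCa units — both starred as
significant in the paired test — while the activation change in `<P2>`
(delta, about −0.08 for the C-helix probe) is essentially unchanged, the
signature dissociation that motivates the analysis. The `*` marks p < 0.05
for the paired SL comparison.

Designing a maximally activating solution:

```r
r   <- solution_recipe(total_ca = 0)       # 10 mM EGTA, 5 mM ATP, 1 mM free Mg
tca <- total_ca_for_target_pca(r, 4.5)     # 0.01003 M total calcium
r$total_ca <- tca
solve_free_ca(r)$pca                       # 4.5 (free Ca 31.6 µM)
```

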