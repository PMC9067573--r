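---
title: "Methods: matrix-completed UNIQUAC for activity coefficients and VLE"
author: "mcmuniquac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matrix-completed UNIQUAC for activity coefficients and VLE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its model, its numerical
choices, and the design decisions that were genuinely open. Everything
quantitative stated here is computed by the test suite or by
`scripts/acceptance.R`; nothing is quoted from elsewhere.

## The model

### UNIQUAC engine

For a mixture of $n$ components at temperature $T$ (K) with mole
fractions $x$, the activity coefficient of component $i$ is
$\ln\gamma_i = \ln\gamma_i^C + \ln\gamma_i^R$ with

$$
\Phi_i = \frac{r_i x_i}{\sum_j r_j x_j},\qquad
\vartheta_i = \frac{q_i x_i}{\sum_j q_j x_j},\qquad
l_i = \tfrac{z}{2}(r_i - q_i) - (r_i - 1),
$$

$$
\ln\gamma_i^C = \ln\frac{\Phi_i}{x_i}
 + \tfrac{z}{2} q_i \ln\frac{\vartheta_i}{\Phi_i}
 + l_i - \frac{\Phi_i}{x_i}\sum_j x_j l_j,
\qquad
\ln\gamma_i^R = q_i\Big[1 - \ln\sum_j \vartheta_j\tau_{ji}
 - \sum_j \frac{\vartheta_j \tau_{ij}}{\sum_k \vartheta_k \tau_{kj}}\Big],
$$

$$
\tau_{ij} = \exp\!\big(-(U_{ij}-U_{jj})/(RT)\big).
$$

All parameters are independent of temperature and composition. The
engine is exact for any $n \ge 2$; the binary infinite-dilution limit has
its own closed form (`ln_gamma_inf()`), which avoids the $0\log 0$
ambiguity of evaluating the general expression on the composition
boundary — `ln_gamma()` therefore refuses $x_i \in \{0,1\}$ by design.

Constants: $R = 8.314462618$ J/(mol K); lattice coordination number
$z = 10$, the canonical UNIQUAC choice, fixed and not exposed as a knob.
All interface energies are in J/mol (the literature convention; the data
sources themselves are unit-silent, so this is declared once here).

### Latent-feature completion of the energy matrix

The unlike energies are reconstructed from per-component latent vectors
$\theta_i, \beta_i \in \mathbb{R}^K$:

$$ U_{ij} = \theta_i\cdot\beta_j + \theta_j\cdot\beta_i \quad (i \ne j), $$

symmetric under $i \leftrightarrow j$ by construction; the like energies
$U_{ii}$ are free parameters. Only the reconstructed $U$ is identifiable:
$(\theta M,\ \beta (M^{-1})^\top)$ gives the same $U$ for any invertible
$M$ (verified as a property test), so tests and exports always compare
energies, never raw features. Features are unconstrained — negative
energies are physically meaningful. Components outside the trained
roster are rejected; cold-start prediction is out of scope.

The latent dimension $K$ is a hyperparameter (default 4, grid
{1, 2, 3, 4, 6, 8}) selected on the validation split by
`select_hyperparameters()`.

## Priors, units, and conditioning

Internally every energy is carried as $U/R$ in Kelvin: the natural scale
of $\tau$ exponents, which keeps gradients well conditioned. The
interface converts once at the boundary (features scale with $\sqrt R$,
like energies with $R$).

* Latent features: independent Gaussians with per-entry scale chosen so
  that the implied pair-energy scale $\sqrt{2K}\,\sigma_f^2$ is 300 K at
  `feature_scale = 1`, independent of $K$. `feature_scale` is therefore a
  dimensionless multiplier with the same meaning at every $K$, which
  makes prior-scale grids comparable across $K$.
* Like energies: Gaussian, default location 0 and scale 500 K on
  $U_{ii}/R$ (deliberately weak; the data dominate).
* Likelihood on ln γ: Gaussian with scale 0.15 by default; a Cauchy
  option exists for robustness to gross outliers. Finite-composition and
  infinite-dilution records enter with equal weight — one record, one
  likelihood term — since nothing in the data model justifies
  reweighting.
* $\tau$ exponents are clipped at ±500 before exponentiation so that
  optimizer excursions cannot overflow; every clipped entry increments a
  counter (`tau_clip_count()`) that the command-line layer reports.

## Inference

### MAP with a structured warm start

`fit_map()` maximizes the log joint with L-BFGS driven by hand-derived
analytic gradients (the binary predictor's derivatives with respect to
the three pair energies, chained onto the features through the sparse
pair-incidence structure). The objective is severely nonconvex, and plain
random initialization reliably finds poor basins — large-$|\ln\gamma|$
records make the likelihood surface extremely sharp, because a fixed
error in an energy enters $\ln\gamma$ through a Boltzmann factor.
The default initialization is therefore a deterministic three-stage warm
start:

1. **Per-system fit.** A conventional symmetric UNIQUAC fit: one $U_{ij}$
   per observed system plus shared $U_{ii}$, by joint least squares.
   This is a far easier problem and estimates the observed energies to a
   few K.
2. **Gauge centering and factorization.** Per-system energies are only
   identified up to one global additive shift (predictions depend on
   energy differences), which would add a spurious rank-one component;
   the pair energies are centered before factorizing. The rank-$K$
   factorization itself is found by first solving *overparameterized*
   (at $\max(2K{+}2,8)$ dimensions, where gradient methods reliably find
   the global structure), then compressing through the eigendecomposition
   of the reconstruction — the symmetric form equals
   $AA^\top - BB^\top$ with $A = (\theta+\beta)/\sqrt2$,
   $B = (\theta-\beta)/\sqrt2$, so the top-$K$ positive and top-$K$
   negative eigenpairs convert exactly to rank-$K$ features — and
   refining at rank $K$. Seeded random restarts act as a fallback
   candidate; the best penalized objective wins.
3. **Annealed end-to-end refinement.** The full posterior is then
   maximized with the likelihood scale annealed over stages
   (2 → 0.6 → target), a graduated-optimization schedule that prevents a
   handful of extreme records from ejecting the solution from the
   correct basin before the fine structure is settled.

Every stage is deterministic given `seed`; `init = "random"` retains
plain seeded random restarts for comparison. On the reference recovery
problem (60 components, rank-3 truth, 30 % of systems observed, 20
records per system, noise sd 0.1) the warm-started fit reconstructs
never-observed pair energies with Pearson r ≈ 0.999 in about a minute on
one CPU, while random initialization stalls near r ≈ 0.1 — the test
suite asserts the former.

### Variational inference

`fit_vi()` fits a fully factorized Gaussian family over all parameters
by maximizing the evidence lower bound with reparameterized stochastic
gradients (Adam, step size decayed as $1/(1+t/1000)$, configurable
Monte-Carlo samples per step). The variational means are initialized at
the MAP optimum by default — mean-field VI inherits the same nonconvex
landscape, and starting at the posterior mode lets the method do what it
is used for here: uncertainty quantification around the dominant mode.
Per-pair energy summaries (`pair_energy_summary()`,
`write_pair_energies()`) are Monte-Carlo estimates over the factorized
posterior, 1000 draws by default; pairs backed by data come out tighter
than never-observed pairs, which the tests assert as a median ordering.
A NaN in the ELBO gradient aborts with diagnostics rather than limping
on. MAP exists alongside VI because tests need bitwise determinism; VI
is the uncertainty-bearing mode.

### Baselines and the asymmetry demonstration

`fit_per_system_baseline()` implements the two conventional references:
mode `"deltaU"` fits $\Delta U_{ij}, \Delta U_{ji}$ independently per
system (two parameters per system, multi-started BFGS per system — the
two-parameter $\tau$ surface has genuine local minima); mode `"U"` fits
one symmetric $U_{ij}$ per system with the like energies shared and
co-fitted across systems (joint L-BFGS). The parameter counts follow
`count_parameters()`: $2S$ versus $S + N$. At $N = 3$ with all pairs
observed the two counts coincide (both 6); the strict inequality holds
from $N \ge 4$ — the counting operation is implemented literally and the
boundary case is pinned in a test.

`check_delta_consistency()` solves the overdetermined linear system
$\Delta U_{ij} = U_{ij} - U_{jj}$, $\Delta U_{ji} = U_{ij} - U_{ii}$ in
least squares (base `lm.fit`; the one-dimensional additive null space is
fixed by zeroing aliased coefficients) and declares consistency iff the
maximum equation residual is below 1e-6 J/mol. Exact images of symmetric
sets pass with zero residual; independently fitted noisy tables fail by
hundreds of J/mol — the structural point the symmetric parameterization
rests on. Underdetermined inputs (fewer than 3 components, or missing
pairs) are reported as trivially consistent with a note.

## Phase equilibria

The vapor phase is ideal and the Poynting correction is neglected — the
minimal extended-Raoult reading $y_i P = x_i \gamma_i p_i^s(T)$; fugacity
corrections are out of scope. Antoine vapor pressures use the
log10/kPa/K dialect, declared in the table file header; no dialect
converters are provided on purpose.

Numerics, all deterministic:

* Temperature roots are found by a 60-point bracket scan on [150, 700] K,
  bisection to 1e-8 K, and one secant polish.
* The dew-point liquid composition is solved by Wegstein-accelerated
  successive substitution (weights bounded to [−5, 0.5]); plain
  substitution converges too slowly near weakly attracting fixed points.
  During root bracketing an unconverged inner loop is tolerated (the
  probe temperature may be far from any equilibrium); at the returned
  solution it is an error.
* Components with $x_i = 0$ are dropped to the active sub-mixture, so
  simplex vertices reduce to Antoine inversion and ternary edges reduce
  exactly to the binary calculation (asserted to 1e-8).
* `find_azeotrope()` scans $y_1(x_1) - x_1$ on an interior grid and
  bisects any sign change to $|y_1 - x_1| < 10^{-8}$.

Strongly non-ideal systems can possess multiple equilibrium branches at
one pressure; the solvers return the branch whose temperature bracket is
found first (lowest), and round-trip consistency (dew → bubble) is the
asserted contract. Heteroazeotropes are not resolved — no
liquid–liquid split is computed, and dew/bubble crossing anomalies are
simply surfaced by the round-trip checks. LLE, SLE and excess enthalpies
are out of scope.

## The synthetic-data generator

Real training corpora of this kind (hundreds of thousands of ln γ points
over ~10³ components, <2 % of pairs observed, VLE-derived plus
infinite-dilution records, 183–638 K) are proprietary, so the package
carries a generator whose *structure* emulates them:

* geometries $r \sim U(1, 10)$, $q = r\,U(0.75, 1.1)$;
* like energies $U_{ii}/R \sim N(-300\,\text{K}, 150\,\text{K})$;
* latent features at $K_{true}$ with per-entry scale calibrated so that
  the spread of $(U_{ij}-U_{jj})/R$ across pairs is 300 K (the
  like-energy variance is subtracted from the target, so the calibration
  is exact in expectation; a Monte-Carlo test pins it to 20 %). This
  yields infinite-dilution $\ln\gamma^\infty$ mostly in the low single
  digits with realistic heavy tails;
* per observed system: records at $T \sim U(183, 638)$ K, finite records
  at $x \sim U(0.01, 0.99)$ with the measured species drawn uniformly
  from the pair, infinite-dilution records with probability 0.2 (the
  generator's record mix is explicit metadata, so either a one- or
  two-records-per-VLE-point convention can be emulated), Gaussian (or
  Cauchy) noise on the exact model value;
* Antoine coefficients drawn so normal boiling points land in
  250–550 K, validity ±120 K.

What the generator does *not* emulate: correlated measurement error
within a data series, composition-grid clustering of real VLE data,
chemically structured similarity between components (latent truth is
isotropic Gaussian), or database quality flags. Passing the recovery
tests therefore demonstrates that the estimator recovers the model's own
structure from data with realistic sparsity, magnitudes and noise — not
that it attains any particular accuracy on a real database.

## Problem sizes used by the tests

Chosen as the smallest sizes that still exercise the claimed behavior:
the core recovery test uses 60 components (1770 possible systems, 531
observed, 10,620 records) and runs in about a minute; module tests use
4–24 components; the oracle-equivalence suite checks 1000 random
instances of 2–5 components against an independently written
transcription of the equations at 1e-10. The acceptance script re-runs
the recovery, baseline and VLE computations from scratch with all
randomness derived from `--seed`.

## Known limitations

* Temperature-dependent interaction parameters are deliberately not
  supported; systems whose energies drift with $T$ will show structured
  residuals.
* Mean-field VI underestimates posterior correlations between features;
  pair-energy uncertainties are trustworthy as orderings and rough
  magnitudes, not as calibrated intervals.
* The per-system energy gauge (one global additive shift) means exported
  baseline energies are comparable within a fit, not across fits; the
  hybrid model pins the gauge only softly through its priors.
* The recovery guarantee is for data generated by the model family
  itself; rank misspecification ($K$ well below the truth) degrades
  held-out pairs first.
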