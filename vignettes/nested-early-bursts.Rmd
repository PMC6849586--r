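---
title: "Nested early bursts: models, calibration, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nested early bursts: models, calibration, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstshift)
```

## The model family

An early burst — a high initial rate of morphological evolution that decays
as a clade fills ecological opportunity — is classically modelled by letting
the rate of a Brownian-motion (BM) diffusion decline exponentially through
time over an entire phylogeny. `burstshift` relaxes that assumption: the tree
evolves under background BM, and a single nested monophyletic clade switches
to a different process at its stem. Seven models are compared:

| model | clade process | free parameters (k) |
|---|---|---|
| `BM` | — | $\sigma^2$, $\mu$ (2) |
| `EB` | whole tree: rate $\propto e^{rt}$, $r<0$ | $\sigma^2$, $\mu$, $r$ (3) |
| `OU` | whole tree: attraction $\alpha$ to an optimum | $\sigma^2$, $\mu$, $\alpha$ (3) |
| `nested_shift` | clade rate scaled by $\theta$ | $\sigma^2$, $\mu$, $\theta$ (3) |
| `nested_OU` | OU inside the clade | $\sigma^2$, $\mu$, $\alpha$ (3) |
| `nested_EB` | early burst inside the clade | $\sigma^2$, $\mu$, $r$ (3) |
| `nested_EB_rate` | early burst and rate scalar $\theta \ge 1$ | $\sigma^2$, $\mu$, $r$, $\theta$ (4) |

The shift-node position is searched, not counted as a parameter.

All models are Gaussian: tip values are multivariate normal with mean
$\mu\mathbf 1$ and covariance $\sigma^2 V'$, where $V'$ is a transformation
of the shared-time matrix $V$ ($V_{ij}$ = height of the most recent common
ancestor of tips $i$ and $j$). The log-likelihood is the exact density

$$\ln L = -\tfrac12\left[n\ln(2\pi\sigma^2) + \ln|V'| +
  (y-\mu\mathbf 1)^\top V'^{-1}(y-\mu\mathbf 1)/\sigma^2\right],$$

always including the determinant term — without it likelihoods of
differently transformed $V'$ are not comparable and model selection is
meaningless.

### The nested transforms

$V$ decomposes additively into $V_0$, the time accrued on background
branches, and $V_{eb}$, the time accrued on the clade's branches with the
stem included, so $V_0 + V_{eb} = V$ entrywise (`clade_partition()`). For a
pair of tips inside the clade, $V_0$ holds the constant background time down
to the stem's origin; one verbal reading of the decomposition would zero
those background entries, but only the sum-preserving partition used here is
consistent with $V_0 + V_{eb} = V$, and it is what the transforms below
require.

* `nested_shift`: $V' = V_0 + \theta V_{eb}$ (stem scaled too — the shift is
  a property of the whole clade branch set).
* `nested_EB`: each clade branch segment $[t_0, t_1]$ on a clock that starts
  at the **crown** node is replaced by $\int_{t_0}^{t_1} e^{rt}\,dt =
  (e^{rt_1}-e^{rt_0})/r$. The stem occupies negative time, so its
  transformed length *exceeds* its true length: that stretch is the burst on
  the branch leading into the clade. No separate burst parameter exists.
* `nested_EB_rate`: the transformed clade part additionally multiplied by
  $\theta \ge 1$; at $\theta = 1$ the model collapses to `nested_EB` exactly.
* `nested_OU`: the standard stationary OU covariance
  $e^{-2\alpha(T_c-s)}(1-e^{-2\alpha s})/(2\alpha)$ applied to the clade
  subtree on the same stem-inclusive clock ($T_c$ = stem + crown depth). The
  source method names the nested OU model but prints no covariance formula;
  we use the standard ultrametric form, which collapses to BM at
  $\alpha = 0$ as required, and mirror the stem treatment of the EB forms so
  the two nested processes are comparable.

All four leave the background entries of $V$ untouched, and all collapse to
BM in the appropriate limits ($r \to 0^-$, $\alpha \to 0$, $\theta = 1$);
the test suite asserts each collapse.

## Fitting

`fit_model()` maximizes the likelihood with bounded L-BFGS-B over the shape
parameters, with starting values and bounds chosen for unit-height trees and
traits on roughly unit scale: $\sigma^2$ starts at $\mathrm{var}(y)/\text{age}$
in $[10^{-8}, 20]$; $r$ starts at $-0.01$ with bounds
$[\ln(10^{-5})/\text{age}, -10^{-6}]$, where "age" is the clade age
(stem + crown depth — the span of the EB clock) for nested forms and the
tree height otherwise; $\alpha$ starts at $0.05$ in $[10^{-8}, 2.71]$;
$\theta$ is bounded $[1, 20]$ (`nested_EB_rate`) or $[10^{-8}, 20]$
(`nested_shift`). One optimizer run with at most 100 iterations is the
default; `fit_control(multi_start = TRUE)` adds two extra starts for
robustness studies.

Two numerical choices matter:

* **Profiling.** By default $\mu$ is profiled by GLS and $\sigma^2$ by its
  analytic maximum $Q/n$ (clamped to its bounds) at every step, so the
  numerical search runs only over $r$, $\alpha$, $\theta$. This is exact —
  the profile optimum is the joint optimum — and roughly an order of
  magnitude faster than searching $\sigma^2$ numerically, which is what
  makes the calibrated simulation studies below desk-scale. The joint
  numerical search remains available (`fit_control(profile_sigma2 = FALSE)`)
  and a test asserts both routes agree. The $n-1$ denominator of the
  conventional reported rate estimator is exposed separately in
  `sigma2_estimate()`.
* **Limits.** The $r \to 0^-$ and $\alpha \to 0$ transforms divide by the
  parameter; when the exponent argument magnitude falls below $10^{-9}$ the
  linear (BM) limit is substituted to avoid $0/0$.

Ties in AICc within $10^{-6}$ are broken toward fewer parameters, then BM —
the conservative direction for a null-versus-alternative comparison.
Degenerate inputs are flagged rather than hidden: constant traits drive
$\hat\sigma^2$ to its lower bound, zero-length stems warn, non-ultrametric
trees are rejected by the OU forms (relative tip-height spread above
$10^{-6}$).

## Shift-node search and the AICc correction

`scan_shift_nodes()` fits a nested model at every internal non-root node
subtending at least `min_frac` (default 25%) of the tips and keeps the node
with the lowest small-sample AICc. Searching over nodes inflates the type-1
error of the comparison against BM well beyond what the AICc penalty for one
extra parameter absorbs. `calibrate_penalties()` therefore simulates BM data
on the *same tree* (the correction is idiosyncratic to tree shape and must
be redone per analysis), runs the identical search on each simulation, and
derives an additive AICc penalty per model from the null distribution of its
advantage $D_M = \mathrm{AICc}_{BM} - \mathrm{AICc}_M$.

Each model's penalty is a $(1-\beta)$ empirical quantile (inverse-ECDF,
clamped at zero) of its own $D_M$, with a single per-model exceedance level
$\beta$ shared across models: the largest level at or below the target
(default 5%) at which the *final* null error — the probability that any
non-BM model beats BM after correction — is held at the target. Two
details of that choice matter and were settled by measurement on held-out
null draws:

* **Why the union, not the marginals.** Plain per-model
  $(1-\text{target})$ quantiles bound each model's null win rate at 5%
  individually, but the six alternatives' null advantages are not
  correlated enough for that to bound the user-facing event "some non-BM
  model wins": on 100-tip trees the marginal quantiles leave a held-out
  final error of 15–27%. The final error is what the correction exists to
  control, so $\beta$ is chosen against it; the marginal construction is
  recovered automatically whenever it suffices.
* **Why a confidence margin.** Selecting the largest $\beta$ whose
  *in-sample* union rate sits at the target tunes $\beta$ to the
  calibration draws and generalizes optimistically (held-out final error
  ~2–4 points above target). $\beta$ is therefore accepted only if a
  binomial upper confidence bound (default 85%, `conf`) on the final error
  implied by the in-sample exceedance count stays at or below the target.
  Across independent 100-tip trees this lands the held-out final error at
  roughly 2–8% around the 5% target instead of systematically above it.

Each model's individual null win rate is bounded by $\beta \le$ the target
either way. The validation suite measures the final rate on fresh null
draws rather than assuming it. The trade-off is conservatism: under this
calibration, data sets violating the search's clade-size floor yield
essentially zero support for the nested models rather than a small
residual rate.

`compare_models()` reports both the corrected ranking (with Akaike weights
computed from corrected scores) and the uncorrected one, so either can be
quoted.

## Simulators and the validation design

`simulate_bd_tree()` draws birth-death trees conditioned on the number of
extant tips (speciation 1, extinction 0.5 by default; extinct lineages
pruned) and rescales them to unit height, so parameter grids are comparable
across trees. Traits are simulated by one multivariate-normal draw from
$\sigma^2 V'$ via Cholesky factorization — nested transforms need no
per-branch recursion, and simulation and likelihood share no code path with
the tests' independent density oracle.

The validation design (`sim_study_config()` defaults, and the acceptance
checks) is: unit-height 100-tip trees for the selection studies (500 tips
for parameter recovery); background rate $\sigma^2 = 1$, mean 0; the burst
exponent expressed as fractions of its maximum magnitude
$|\ln(10^{-5})|/1 \approx 11.5$ on a unit tree, the value at which the rate
has decayed to $10^{-5}$ of its initial value at the present; $\alpha$ as
the same fractions of $e$; $\theta \in \{2, 5, 10\}$; shift clades drawn
uniformly from nodes holding at least 25% of the tips. The misplacement
(violation) design instead draws shift clades of at most 5% of the tips
while the search still only considers nodes of 25% and up — measuring how
much support the nested EB model retains when its assumption about the
shift's location is broken (it should, and does, collapse).

Problem sizes are the package's own desk-scale choices: one seeded tree per
study, 200 Brownian null simulations behind each penalty table, and at
least 50 replicates per parameter cell; `sim_study_config()` scales any of
these up (toward the 1000-replicate grids a publication would use) without
code changes. All randomness flows from one master seed through a
deterministic splitting scheme (`derive_seeds()`), so reruns and cell
subsets reproduce exactly.

### What the simulations do and do not show

The generator draws from exactly the Gaussian process families the fitter
assumes, on correctly specified trees. Passing these studies shows the
machinery is correct and calibrated — it does not show that real traits
follow any of these processes. Real data add measurement error, sampling
gaps, topological and branch-length uncertainty, non-Gaussian tails, and
rate heterogeneity beyond a single shift; none of these are emulated. In
particular, models allowing many shifts are known to fit large empirical
clades better than any single-shift model, so a `nested_EB` win within this
family is evidence of an early-burst *pattern*, not proof of a single-burst
history.

## The node-height test

`pic_contrasts()` computes Felsenstein's standardized independent contrasts
(via the pruning algorithm) and records each contrast's node height;
`node_height_test()` regresses $\ln|c_i|$ on node height. Under constant-rate
BM the slope is centred on zero; a significantly negative slope — more
disparity near the root — is the early-burst signature, on the log scale
because the decay is exponential. Outliers can drive the slope, so two
guards are provided: trimming contrasts beyond 3 SD from their mean (applied
to the raw contrasts, before the log), and Huber M-regression
(`method = "robust"`, p-value from the slope's asymptotic normal). Zero
contrasts are dropped before the log with a warning. Whether trimming should
happen before or after the log transform is not settled; trimming raw
contrasts is implemented since outlying *contrast values* are the stated
concern.

## Known limitations

* One shift only; AICc selection over multiple simultaneous shifts is
  statistically unsound (non-identifiable), and lasso or reversible-jump
  methods are the right tools there.
* OU forms require ultrametric trees; fossil tips are out of scope.
* Polytomies are tolerated in the covariance machinery but not by the
  contrast-based test, and shift clades must be bifurcation-defined.
* The candidate floor defaults to clades of 2 tips so small examples work;
  within-clade shape parameters are weakly identified below roughly 4 tips,
  and the selection studies all use the 25% fraction rule.
* AICc is undefined when $n \le k + 1$; fits on such tiny trees carry
  `AICc = NA` and cannot enter model comparison.
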