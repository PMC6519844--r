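---
title: "Growth-fragmentation models of sIgA-enchained bacterial chains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-fragmentation models of sIgA-enchained bacterial chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enchainr)
```

## The biological problem

Secretory IgA (sIgA) is the main adaptive immune effector in the gut
lumen. Rather than killing bacteria, sIgA cross-links daughter cells as
they divide ("enchained growth"): because rod-shaped bacteria such as
*Salmonella* divide across their long axis, a clone that stays linked
grows as a **linear chain** of bacteria joined pole to pole. Chains are
poorly motile and do not reach the epithelium, so only **free bacteria**
(chains of length 1) drive infection. The sIgA-mediated links are not
permanent: shear in the digesta puts them under load and they fail at
some rate. The competition between replication (which lengthens chains)
and link breaking (which releases free bacteria or dumps fragments into
disordered "complex clusters") decides how fast the free-bacteria
population can grow, and it does so as a function of the replication
rate — which is what makes the mechanism immunologically interesting: it
penalizes fast replicators without the host having to identify them.

`enchainr` implements this family of growth-fragmentation models: the
mean-field linear operators, their dominant eigenpairs, the closed-form
approximations, an exact stochastic simulator of the same rules, and
maximum-likelihood fitting of the one free shape parameter to observed
chain-length histograms.

## The mean-field models

All variants track the mean number $n_i(t)$ of linear chains of length
$i$ ($n_1$ = free bacteria). Complex clusters are an absorbing pool:
they never release bacteria and are only counted. Encounters between
unrelated chains are neglected (valid at low density, early in
colonization), so the dynamics are linear: $dN/dt = M N$ with $M$ built
from per-length balance equations. In the long run
$N(t) \to C e^{\lambda t} P$: the dominant eigenvalue $\lambda$ is the
common growth rate of free bacteria and chains, and the normalized
Perron vector $P$ is the stationary length distribution.

**Base model.** Each bacterium replicates at rate $r$ (chain of length
$i$: total rate $ir$), daughters are perfectly enchained, each of the
$i-1$ links breaks at rate $\alpha$. An outermost break always frees the
single bacterium; an inner break sends both fragments to complex
clusters ($q = 0$). This gives the tridiagonal-plus-first-row generator
of `build_base_matrix()`.

**Escape variant** (`build_escape_matrix()`). Imperfect enchainment upon
replication: probability $\delta$ that a dividing free bacterium yields
two free bacteria, $\delta'$ that the outer daughter at a chain tip
escapes, $\delta''$ that an interior division fails to bond and clips
the chain. Loss rates $c$ (free bacteria) and $c'$ (chains) model
washout. With $c = c'$ the generator is the base generator minus $c$
on the diagonal, so the growth rate shifts by exactly $-c$ and the
distribution is unchanged. A modelling subtlety: the printed balance
equations carry **no influx** for the two clipped subchains (each of
length $\ge 2$), i.e. clipping is treated like an inner break whose
fragments are absorbed; the stochastic simulator does the same, so both
layers describe the same process.

**Fixed-replication-time variant** (`build_transfer_matrix()`). All
bacteria divide synchronously every $\tau$; the effective growth rate is
$r_\mathrm{eff} = \log(2)/\tau$. Between divisions only fragmentation
acts ($q = 0$), so a chain of length $n$ shrinks by shedding tip
bacteria until an inner break removes it. The probability that it has
lost exactly $i$ tips by time $t$ is

$$l(n,i,t) = \frac{2^i}{i!}\, e^{-\alpha t (n-1)} (e^{\alpha t}-1)^i,$$

implemented in `survival_prob()`, and the expected number of free
bacteria it sheds during one interval is
$2\alpha \sum_i \int_0^\tau l(n,i,t)\,dt$ (`free_yield()`). Sampling
populations right before each division gives a per-interval transfer
matrix whose dominant eigenvalue $N$ satisfies
$\lambda = \log(N)/\tau$; $N \to 2$ as $\alpha\tau \to \infty$. Because
lengths double at division, the stationary distribution is bumpy:
power-of-two lengths are overrepresented.

**Subchain-escape variant** (`build_q_matrix()`). Fragments of an inner
break survive as two independent chains with probability $q$. At
$q = 1$ the model is exactly solvable: $\lambda = r$ and the length
distribution is geometric with ratio $r/(r+\alpha)$
(`q1_distribution()`), mean length $1 + r/\alpha$. The regimes split at
$q = 1/2$: an inner break produces $2q$ surviving chains on average, so
for $q > 1/2$ the growth rate increases monotonically with $r$ while
for $q < 1/2$ it has an interior maximum, like the base model.

**Force-dependent breaking** (`build_force_matrix()`). Treating the
chain as a string of beads in shear flow, the tension is largest at the
chain centre and grows with length; with an exponential force-rate
coupling of strength $\beta$ the link at signed offset $x$ from the
centre of a length-$L$ chain breaks at
$\alpha \exp(\beta((L/2)^2 - x^2)/2)$ (`per_link_breaking_rate()`). The
offsets are integers for even $L$ and half-integers for odd $L$ — this
coordinate convention is the unique one whose per-link rates sum to the
aggregated even/odd total rates in the balance equations, and whose
outermost rate $\alpha e^{\beta(L-1)/2}$ matches the free-bacteria
production term (the tests verify both). Long chains are hugely
unstable ($e^{\beta L^2/8}$), so the stationary distribution decays
super-geometrically and small truncations suffice.

## Numerical choices

* **Truncation.** Operators act on lengths $1..n_\mathrm{max}$; flux
  into longer chains is dropped, i.e. chains outgrowing the truncation
  are treated as lost to complex clusters (conservative for
  free-bacteria production). Defaults per variant: 40 (base, escape),
  32 (fixed time), 80 (subchain escape), 10–20 (force, smaller for
  larger $\beta$). Adequacy is checked by doubling $n_\mathrm{max}$ and
  requiring the relative change in $\lambda$ to stay below
  `convergence_tol` (default $10^{-6}$); curve and argmax evaluations
  auto-double up to a cap of 400.
* **Eigensolver.** Dense `eigen()` — the matrices are small and
  robustness beats speed. The dominant eigenvalue is selected by
  largest real part (rate matrices) or modulus (transfer matrix); ties
  are broken by eigenvector positivity. The eigenvector is sign-fixed,
  entries in $[-10^{-10}, 0)$ are clipped to zero, and anything more
  negative raises an error, since genuine negativity signals a
  construction bug.
* **Quadrature.** `free_yield()` uses adaptive quadrature
  (`stats::integrate`, absolute tolerance $10^{-10}$) on the
  cancellation-free positive sum $\sum_i l(n,i,t)$; the $n = 2$ case
  uses the closed form $2(1 - e^{-\alpha\tau})$.
* **Overflow guard.** Force-model construction refuses
  $\beta n_\mathrm{max}^2/8 > 700$ (where $e^x$ overflows) and reports
  the maximal safe truncation; silent infinities would corrupt the
  eigensolve.
* **Optimum search.** `argmax_growth_rate()` does a 20-point
  log-spaced coarse scan of the bracket followed by golden-section
  search (default tolerance $10^{-3}$ in $r/\alpha$). A maximum at the
  bracket boundary — the monotone regimes, e.g. $q > 1/2$ — is reported
  as a flagged boundary result, not an error.
* **Time integration.** `integrate_population()` propagates
  $dN/dt = MN$ with matrix exponentials between output times, exact for
  these linear systems. The force model should be integrated at modest
  truncations (the guard bounds what is representable, but
  $e^{\beta L^2/8}$ entries make the exponential ill-conditioned well
  before it overflows).

## The stochastic simulator

`simulate_rates()` is an exact event-driven (Gillespie direct method)
realization of the same rules the generators encode: per-chain
propensities $ir$ for replication and $(i-1)\alpha$ (or the per-link
force sum) for breaking, uniform choice of the breaking link (weighted
by per-link rates in the force variant), always-escaping outermost
singles, $q$-coin for inner fragments, escape coins
$\delta/\delta'/\delta''$ and loss clocks in the escape variant.
`simulate_fixed_tau()` alternates synchronous doubling with exact
within-interval fragmentation and samples right before divisions,
matching the transfer-matrix bookkeeping. Both enforce a population cap
(default $10^6$ bacteria) and flag truncated runs rather than silently
returning them.

The simulator is the package's independent oracle: ensemble means over
replicates must match `integrate_population()` of the corresponding
generator within Monte-Carlo error, and the tests check exactly that
(2000 replicates per variant, five checkpoints, lengths 1–4, all cells
with mean-field expectation at least 0.02, three standard errors per
cell). With roughly eighty such cells a per-cell three-standard-error
criterion can flag a cell by chance under reseeding, so the suite runs
at a fixed seed; the comparison is about detecting systematic
disagreement, not about any single cell.

`sample_histogram()` draws multinomial chain-length histograms from any
normalized distribution — the synthetic-data path used to exercise the
fit. What these synthetic histograms emulate is sampling noise on a
stationary length distribution; what they deliberately do **not**
emulate are the artefacts of real microscopy data (chains leaving the
focal plane, segmentation errors on long chains, uncertain free-cell
counts). Passing the recovery tests therefore validates the fitting
machinery, not the experimental pipeline that produces a histogram.

## Fitting the shape parameter

All variants leave a single identifiable shape parameter for a
stationary histogram: the replication-to-breaking ratio ($r/\alpha$, or
$r_\mathrm{eff}/\alpha = \log 2/(\alpha\tau)$ for the fixed-time
model); $r$ and $\alpha$ separately are not identifiable from a shape.
`fit_ratio()` maximizes the multinomial log-likelihood of the observed
counts under the dominant-eigenvector distribution conditioned on
linear chains of length $\ge 2$ — free-bacteria counts from images are
unreliable, and published comparisons normalize exactly this way. The
support is treated as open-ended: the truncation is raised to four
times the maximum observed length, and proportions are conditioned on
$[2, n_\mathrm{max}]$ at exactly that truncation (the truncation is part
of the declared multinomial family, so trial ratios at the search
extremes need no open-ended convergence). The 95% interval is the
profile likelihood at $\chi^2_1(0.95)/2 = 1.92$ log-units; degenerate
single-length histograms return the search interval with a warning
flag. `goodness_of_fit()` compares the fitted model against the
saturated multinomial with a parametric-bootstrap tail probability
(each bootstrap histogram is refitted).

`conditional_model_distribution()` exposes the conditioned model
distribution directly; at the fixed-time variant's larger ratios it
shows the characteristic power-of-two bumps.

## Problem sizes and runtime

The package targets interactive use: truncations of a few hundred at
most, dense eigensolves of a few milliseconds, transfer-matrix builds
of tens of milliseconds. The test suite uses 2000 stochastic replicates
per variant for the mean-field comparison, $10^4$-chain histograms for
point recovery, a 200-replicate coverage study at 500 chains each, and
19–30 bootstrap replicates for goodness-of-fit calibration — sizes
chosen so the whole suite completes in a few minutes while keeping
Monte-Carlo error well below the tested tolerances.

## Known limitations

* Mean-field only for inference: the fit assumes the histogram samples
  the stationary conditioned distribution; transients and stochastic
  extinction are outside scope.
* No spatial structure, no buckling of long chains (which would fold
  them into complex clusters and thin the tail of the linear-chain
  distribution), no encounters between unrelated chains, no escape
  mutants.
* The escape variant's clipped fragments are absorbed, per the balance
  equations; if one instead let them survive as chains, small-$\delta''$
  behaviour would be intermediate between the escape and subchain-escape
  variants.
* The closed forms are approximations with stated validity ranges: the
  geometric law is best at small $r/\alpha$, the $q$-model growth-rate
  formula fails for $q < 1/2$, the fixed-time ratio formula is an
  order-of-magnitude guide anchored at powers of two, and the
  force-model form degrades at small $\beta$ and at small lengths (it
  tracks the eigenvector within a factor of about two there, which on
  the logarithmic scale of the usual comparisons is close agreement).
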