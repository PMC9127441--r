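---
title: "Selection and drift after a change in population size: model and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection and drift after a change in population size: model and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neqafs)
```

## The model

`neqafs` treats a haploid population of `N` individuals (equivalently, a
diploid population of `N/2` with additive fitness effects) whose genome
consists of a large number of freely recombining sites. Mutations arrive
on monomorphic sites as a Poisson stream with population intensity
$\theta$ per generation, each starting in a single copy, and the derived
frequency at each site evolves independently as a Wright–Fisher diffusion
with genic selection,
$$d\xi_t = \gamma\,\xi_t(1-\xi_t)\,dt
  + \sqrt{\tfrac{1}{\kappa(t)}\,\xi_t(1-\xi_t)}\,dB_t,$$
on the evolutionary timescale of $N$ generations per unit, where
$\gamma$ is the selection coefficient scaled by the reference size $N$
and $\kappa(t)$ is the step function of relative population size: 1
before the change time $t^*$ and $\kappa$ after. In the infinite-sites
limit, the collection of segregating frequencies is a Poisson random
field, so the expected value of any site functional is an integral
against a deterministic intensity — this is what makes exact,
time-dependent results possible.

The ancestral population is assumed to be at equilibrium, with
polymorphic intensity $\theta\,\omega_{\gamma,1}\psi_{\gamma,1}(y)\,dy$.
After the change, the field at time $t > t^*$ is the superposition of
(i) fixations accumulated at the equilibrium rates of the two epochs,
(ii) the new-equilibrium polymorphic intensity, and (iii) a transient
that weighs the path expectation $E_y^{\gamma,\kappa}[f(\xi_{t-t^*})]$
by the *deficit* between the ancestral and new equilibrium intensities.
All measures in the package are this one functional with different
choices of $f$: the pairwise-difference function $f_{pw}(y)=2y(1-y)$
gives diversity, the fixation indicator gives cumulative fixation
counts, and their nonsynonymous/synonymous ratios give
$(\pi_N/\pi_S)(t)$ and $\bar\omega(t)$.

Nonsynonymous selection coefficients follow a negative Gamma DFE with
shape $a$ and mean $-ab$; synonymous sites are neutral. The package
defaults, $a = 0.15$ and $ab = 2500$ with $\theta = 1$ and $N = 1000$,
are the standard parameterization of a vertebrate-like DFE dominated by
deleterious mutations of widely varying strength, and are the conditions
under which all qualitative claims in the test suite are checked.

## Parameters that matter

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `theta` | population mutation intensity per generation | 1 | sets the overall scale of diversity and fixation counts |
| `N` | reference haploid size | 1000 | enters the WF engine and the Neff proxies; dimensionless theory depends only on products like $\gamma\kappa$ |
| `kappa` | post-change size ratio | sweep over 0.1–4 | relaxation timescale of $\pi_S$ is $\kappa$ time units |
| `tstar` | change time (units of $N$ generations) | 1 ("ancient") or 18 ("recent") | with present time 20 |
| `shape`, `mean` | DFE shape $a$ and mean $-ab$ | 0.15, −2500 | the equilibrium log–log slope of both selection measures is $-a$ |
| `gamma_min` | strongest simulated selection | −1000 | $s = \gamma/N \in [-1, 0]$ at the default $N$ |

## Engines and numerical choices

Every path expectation is consumed through a two-method engine
interface, so the deterministic solver and Monte-Carlo simulation are
interchangeable; the measures default to the PDE engine for determinism,
and the Wright–Fisher engine reproduces the forward-simulation protocol.

**Closed forms and quadrature.** All equilibrium quantities use
rearrangements with non-positive exponents only: the intensity is
evaluated as $\omega\psi(y) = 2\kappa\,q_{\gamma,\kappa}(1-y)/(y(1-y))$
and diversity as $4\theta\kappa(\omega-1)/(2\gamma\kappa)$, which are
overflow-free for $|2\gamma\kappa|$ into the thousands (the DFE reaches
$\gamma = -1000$, $\kappa$ up to 4). $|2\gamma\kappa| < 10^{-8}$ is
treated as neutral, with series expansions carrying continuity through
$\gamma = 0$. Frequency integrals of the equilibrium functional use
adaptive quadrature on the bounded integrand with a $10^{-8}$ relative
error report; the DFE integral substitutes $u = w^{1/a}$, which removes
the $a<1$ endpoint singularity exactly, and applies Gauss–Legendre nodes
(200 for analytic expectations; the measure series defaults to 32 and
the scaled-down sweeps in the tests use 12, which costs $\lesssim 1\%$
in the DFE average).

**DFE truncation.** The stochastic engines cannot simulate
$\gamma < \gamma_{\min}$, so engine-based measures integrate the DFE
only over $[\gamma_{\min}, 0]$ and treat the tail as contributing zero —
no renormalization. For the fixation-rate and diversity integrands this
agrees with the untruncated value to $\sim 10^{-6}$ because such
mutations neither segregate nor fix, even though the Gamma mass beyond
$-1000$ is 0.30 at the default DFE. `dfe_expectation()` defaults to the
untruncated distribution so that identities like $E[V] = -ab$ hold.

**PDE engine.** The backward Kolmogorov equation is discretized on a
uniform frequency grid (2000 intervals by default) with Crank–Nicolson
stepping (target $\Delta t = 0.01$), absorbing boundaries, and two
implicit-Euler startup pairs (Rannacher smoothing) to damp the
high-frequency ringing excited by the discontinuous fixation indicator.
Advection uses central differences except at nodes where the mesh
Péclet number $2|\gamma_{\rm eff}|\Delta y$ exceeds 2, which switch to
first-order upwinding so the discrete operator remains a generator
(bounded, oscillation-free solutions) for arbitrarily strong selection.
Each step reuses a cached sparse LU factorization; integration stops
early once the solution has equilibrated to $10^{-12}$ per unit time.
One solve yields $E_y[f]$ for *all* initial frequencies at once, so a
full time series costs one solve per DFE node and functional.

**Size-$\kappa$ reduction.** A size-$\kappa N$ epoch is simulated and
solved as reference-size dynamics with effective selection
$\gamma\kappa$ and time divided by $\kappa$ — the substitution that
leaves the diffusion invariant. In the Wright–Fisher engine this makes
tables reusable across $\kappa$, and with shared derived seeds the
identity is exact replicate by replicate (tested).

**Transient integrals.** The deficit bracket behaves as $1/y$ near
$y = 0$ while $E_y[f] = O(y)$, so the integrand is assembled as
$(E_y[f]/y)\cdot(y \times \text{bracket})$ with the analytic factor kept
symbolic: on the PDE grid the endpoint limits
$y\,\omega\psi \to 2\kappa$ and $\omega\psi(1) = 2\kappa\omega$ are
inserted exactly and the rest is trapezoidal; on the log-spaced
Wright–Fisher grid $E_y[f]/y$ is interpolated in $\log y$ with constant
extrapolation below the smallest node (the small-$y$ linear closure).
The strongly selected DFE nodes have intensity structure on the scale
$1/|2\gamma\kappa|$, which the default grid resolves to $\sim 5\times
10^{-4}$ relative; on deliberately coarse test grids this is the
dominant error and the continuity check at $t^*$ is asserted at 1%.

**Wright–Fisher engine.** Binomial resampling with post-selection
success probability $p^* = y(1+s)/(1+sy)$, $s = \gamma/N$, vectorized
across replicates; paths unabsorbed after the generation horizon are
treated as never fixing, and the induced downward bias of the
fixation-time distribution is bounded using the closed-form fixation
probability and flagged above 1%. Default replicate numbers are
100000 (neutral) / 10000 (selected) for fixation times and 1000 for
moments, with the horizon at 20000 generations; the test suite scales
these down (2000 / 200) to keep the oracle comparisons within a
3-standard-error band at interactive runtimes. Every table derives its
own seed from the master seed and the table labels, so results are
independent of evaluation order.

**Field simulator.** The finite-$N$ Poisson-field simulator draws
standing variation from the discretized equilibrium intensity, feeds
$\mathrm{Poisson}(\theta\kappa)$ new singletons per generation, resamples
each site binomially, and rescales counts binomially at each size
change. It is the package's end-to-end check that the analytic spectrum
functional describes the simulated field (its stationary heterozygosity
target is the discrete-chain value $2\theta(1-1/N)^2$, not the diffusion
limit). Selection stronger than lethal ($\gamma < -N$) is clamped to
$s = -1$. What it does *not* emulate about real data: linkage and
Hill–Robertson interference, dominance, beneficial mutations, population
structure and migration, and sampling noise of finite sequence samples —
so passing checks validate the mathematics of the free-recombination
model, not those effects.

## Multi-epoch histories

The package also evaluates the spectrum functional under an arbitrary
step history. Each size change leaves a deficit between the equilibrium
intensities of the adjoining epochs, and the deficit created at change
$k$ relaxes under the *time-inhomogeneous* dynamics from $t^*_k$ to $t$;
the implementation chains the PDE propagator through the intervening
epochs (effective selection $\gamma\kappa_j$, duration scaled by
$\kappa_j$). With one change this reduces bit-for-bit to the
single-change formula, and for a neutral two-epoch history it matches
the piecewise-exponential closed form of $\pi_S$ — both are asserted in
the tests. The design was genuinely open here: a single-regime
approximation of the relaxation (as a literal reading of the multi-epoch
display suggests) was rejected because it does not reduce to the
single-change form when an intermediate epoch intervenes.

## Problem sizes used by the tests

The suite runs in about two minutes on one CPU by choice of problem
sizes, not by weakened assertions: oracle comparisons use a
$5\times5$ $(y, t)$ grid with 2000/200 replicates against a
1000-interval PDE solve; the measure-curve checks use
$\kappa \in \{0.25, 1, 4\}$ with 12 DFE nodes on a 28-point time grid;
the slope checks use the full $\kappa$ grid with 48 (equilibrium) and
12 (recent-change) nodes; the field check uses $N = 200$, a window of 5
time units and 20 replicates. Monte-Carlo comparisons are asserted
within 3 standard errors throughout.

## Known limitations

- Single-class or Gamma-DFE selection only; no beneficial mass, no
  dominance, no time-varying selection within an epoch.
- The Wright–Fisher engine does not support multi-epoch propagation
  (use the PDE engine there).
- $\psi$ itself overflows double precision near $y = 0$ for
  $\gamma\kappa \lesssim -400$; all integrals use the bounded product
  $\omega\psi$, but `sfs_density()` can legitimately return `Inf` in
  that corner.
- Sample-based estimators (dN/dS from alignments, site-frequency
  spectra of finite samples) are deliberately out of scope; the
  measures are population functionals.
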