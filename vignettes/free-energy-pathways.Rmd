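---
title: "Free-energy and reaction-pathway analysis with pmfpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-energy and reaction-pathway analysis with pmfpath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmfpath)
```

## What the package computes

`pmfpath` implements the analysis layer of a free-energy study of an
enzymatic reaction along explicit reaction coordinates, exercised end to end
on analytic model landscapes.  The chain is:

1. **Model landscape** — a closed-form potential $V(x)$ (kcal/mol) over one
   or two reaction coordinates (Å), standing in for an expensive molecular
   energy function.
2. **Umbrella sampling** — biased Metropolis Monte Carlo per window of a
   regular reaction-coordinate grid.
3. **WHAM** — reconstruction of the unbiased potential of mean force (PMF)
   from the window histograms, with three-block error bars.
4. **Minimum-(free-)energy path** — a weighted-graph shortest path across
   the gridded 2D surface, profiled against accumulated path length.
5. **Stationary-state report** — labelled minima and transition states,
   barrier and reaction energy relative to the state the transfer starts
   from.
6. **Rates** — Eyring transition-state theory converting between a
   first-order rate constant and an activation free energy.

Chain-of-states utilities (equidistant reparameterisation, synchronous
chain minimisation, saddle refinement) and reaction-coordinate projections
complete the toolbox.

Throughout, $k_B = 0.0019872041$ kcal mol$^{-1}$ K$^{-1}$,
$k_B/h = 2.0836612 \times 10^{10}$ s$^{-1}$ K$^{-1}$, and the default
temperature is 300 K.

## The model landscapes

The two `psp_step*_like` surfaces emulate the topology of the two
phosphoryl-transfer steps of phosphoserine phosphatase as functions of the
phosphoryl-transfer coordinate (OPO, the signed combination of the breaking
and forming P–O bond lengths) and the proton-transfer coordinate (OHO, the
signed combination of donor/acceptor O–H distances).  Each is a sum of
inverted Gaussian basins plus a broad quadratic confinement, with a Gaussian
ridge between the basins:

* step 1: intermediate basin near OPO $\approx -1.3$ Å, product basin near
  $+1.0$ Å;
* step 2: intermediate near $-1.6$ Å, product near $+1.6$ Å.

The ridge is deliberately made a function of OPO only (its width along OHO
is effectively infinite), so the transition region is plateau-like — the
dissociative, metaphosphate-like character the analysis must cope with —
and exactly one first-order saddle connects the basins.  `landscape_report()`
locates the basins (quasi-Newton descent) and the saddle (Newton on the
analytic gradient, certified by exactly one negative Hessian eigenvalue);
we verified the reported saddle coincides with a dense-grid minimax crossing
at 0.005 Å resolution.  **The well depths and barrier heights are free
parameters of the fixture, chosen for a clean two-basin topology; they are
not predictions of any molecular energetics.**  Basin *positions* follow the
tabulated reaction-coordinate values of the intermediate and product states;
the paper-scale energies would require the quantum-mechanical engine, which
is out of scope.

`analytic_pmf()` supplies the exact reference for the estimator tests: the
bin-wise Boltzmann integral $F(b) = -k_BT\ln\int_b e^{-V/k_BT}$ (integrating
out the orthogonal axis when projecting 2D to 1D), with the per-bin Simpson
quadrature refined by doubling until successive refinements agree to
$10^{-3}$ kcal/mol.

## Umbrella sampling choices

The emulated protocol biases each window with a harmonic restraint of
**1000** kcal mol$^{-1}$ Å$^{-2}$ during equilibration and **200** during
production, on a **0.1 Å** grid of window centres, at 300 K.  Two choices
deserve comment:

* **Bias convention.** The restraint is $U = k(x-c)^2$ with *no* factor
  $\tfrac12$ — the convention of the simulation engine the protocol derives
  from.  The stated force constants are only meaningful under a fixed
  convention, and WHAM must unbias with exactly the same expression, so one
  shared function (`harmonic_bias()`) defines it for both the sampler and
  the solver.
* **Dynamics.** Sampling uses random-walk Metropolis Monte Carlo rather
  than molecular dynamics.  On an explicit low-dimensional landscape both
  target the same Boltzmann measure $e^{-(V+U)/k_BT}$; MC needs no force
  integration and is exactly reproducible from one integer seed per window.
  The proposal width is auto-tuned towards ~40 % acceptance during
  equilibration only (tuning during production would perturb detailed
  balance); the production width is the tuned width rescaled by
  $\sqrt{k_{equil}/k_{prod}}$.  Proposals leaving the domain are rejected,
  which is Metropolis with $V=\infty$ outside.

The original durations (10 ps equilibration, 60 ps production at 1 fs)
map to 10,000 / 60,000 steps with a recording stride of 10 — preserving the
1:6 ratio and the divisibility of the recorded series into three equal
blocks.  Per-window seeds derive from a single master seed by a fixed affine
map (`derive_seed()`), so windows are independent yet the whole run is
reproducible bit for bit.

## WHAM

`solve_wham()` iterates the standard self-consistent equations

$$p(b) \propto \frac{\sum_i n_i(b)}{\sum_i N_i\,
  e^{(f_i - U_i(b))/k_BT}},\qquad
  f_i = -k_BT \ln \sum_b p(b)\, e^{-U_i(b)/k_BT},$$

with the bias $U_i$ evaluated at bin centres, until
$\max_i|\Delta f_i| \le 10^{-6}$ kcal/mol (a scale-free criterion on the
window shifts, anchored at $f_1=0$).  An adaptive over-relaxation step
accelerates the slowly-converging global modes; the convergence test always
uses the raw update, so the fixed point is untouched.  Defaults: bin width
0.02 Å (five bins per window spacing — fine enough that evaluating the bias
at bin centres is accurate, coarse enough to fill), `min_count = 1` with
masked bins excluded from the min-shift (avoiding $-\infty$), and a warning
plus per-component min-shift if the windows fail to overlap into one
connected component.

Errors follow the three-block recipe: each window's production series is
cut into three contiguous, equal blocks; WHAM is solved per block; block
PMFs — each defined only up to a constant — are aligned by the least-squares
offset over shared occupied bins; and the per-bin standard deviation from
the mean across blocks is reported.

Validation: on a harmonic landscape (half-convention stiffness
10 kcal mol$^{-1}$ Å$^{-2}$) with the full window protocol, the
reconstructed PMF agrees with the exact Boltzmann integral to well under
0.15 kcal/mol RMS over all bins with reference free energy ≤ 4 kcal/mol,
and with an independent sample-level multistate reweighting estimator to
under 0.05 kcal/mol RMS.

## Minimum-energy paths on grids

A gridded 2D surface becomes a weighted graph: occupied bins are nodes,
each node connects to its next neighbours (connectivity 4 by default —
the minimal reading of "next neighbours"; 8 reduces staircase artifacts and
is available), and each edge carries **the higher of the two node energies**
as its weight.  The minimum-energy path is the Dijkstra shortest path by
summed edge weight; a minimax ("lowest bottleneck") criterion is available
behind a flag for comparison only.  Ties in the priority queue break
deterministically towards the smaller node id (lexicographic bin order) and
predecessors update only on strict improvement, so paths are unique and
stable across runs.  Default endpoints are the two lowest distinct local
minima of the grid.  Node energies must be non-negative (the natural state
of a min-shifted PMF); raw negative energies are rejected, since summed
negative edge weights would reward arbitrarily long detours and invalidate
Dijkstra.

On a plateau-like transition region — a ridge that is nearly flat along
one coordinate, as on the step-like surfaces here — the two criteria
behave differently, and the tests pin down both behaviours: the minimax
path crosses exactly at the saddle (only the saddle bin attains the
minimal bottleneck), while the summed-weight path may drift along the
ridge by a few bins (it trades a few hundredths of a kcal/mol of ridge
height against total accumulated energy), though its crossing *height*
still matches the saddle energy closely.

The profile along the path uses the accumulated Euclidean length in
reaction-coordinate space — the *canonical reaction coordinate* — as its
abscissa.  `locate_states()` labels interior strict extrema alternately
(transition states / intermediates), collapses plateau runs to their
midpoint, and computes the barrier as the energy of the **highest**
transition state relative to the reference state (by default the state the
transfer starts from).  A `min_prominence` filter discards noise-scale
wiggles when the profile comes from a stochastic PMF; the bundled demo uses
1 kcal/mol, far below its ~16 kcal/mol barrier but above the PMF noise.

## Chain-of-states utilities

`reparameterize()` resamples a path to equidistant arc length (default
0.01 Å), preserving the endpoints exactly.  `synchronous_chain_minimize()`
moves all interior points simultaneously along the negative gradient
component orthogonal to the local tangent (normalised central difference),
with a per-iteration displacement cap (30 % of the chain spacing) and
backtracking so the chain's maximum energy never increases, and terminates
when the largest orthogonally-projected gradient falls to the tolerance —
interpreted as **0.1 kcal mol$^{-1}$ Å$^{-1}$**; the protocol this emulates
prints the dimensionally anomalous "kcal·mol$^{-2}$/Å", which we read as a
typographical slip for gradient units.  An optional redistribution to
uniform arc length (with mild zig-zag smoothing) every `respace_every`
iterations is available for chains whose points cluster; it is **off by
default** because we found empirically that (i) redistribution at fixed
*spacing* lets a sagging chain grow without bound, and (ii) even
fixed-count redistribution re-excites a finite projected-gradient residual
through interpolation, preventing convergence to tight tolerances, whereas
the displacement cap alone keeps the plain relaxation stable and
convergent on every bundled surface.  Whether the emulated procedure
re-spaced during minimisation is not stated.

`refine_peak()` is a deliberately simplified stand-in for full
conjugate-peak refinement (whose internals are not part of the emulated
protocol): from the chain's interior energy maximum it alternates a line
maximisation along the unstable direction (initially the bracketing path
segment, then the most-negative Hessian eigenvector) with a minimisation in
the orthogonal subspace, and certifies the result by gradient norm and a
one-negative-eigenvalue finite-difference Hessian.  On the bundled surfaces
it agrees with an independent Newton root search on the gradient to
$10^{-3}$ Å.

## Reaction coordinates and projections

Reaction coordinates are signed sums of named interatomic distances, e.g.
step 1's phosphoryl coordinate $d(\mathrm{Ser\,O\gamma\!-\!P}) -
d(\mathrm{P\!-\!O\delta\,Asp11})$ and proton coordinate
$-d(\mathrm{Ser\,O\gamma\!-\!H}) + d(\mathrm{H\!-\!O\delta\,Asp13})$.
Distance labels vary between sources ("P–OD-Asp11" vs "P–O-Asp11",
"watO" vs "Wat-O"), so a registry canonicalises spellings before matching.
Two step-2 proton-transfer variants circulate (acceptor O$_T$-Asp11 vs
O$_\delta$-Asp13); both ship as built-ins and neither is privileged.
`project_profile()` re-labels a path profile by projected coordinate values
*in path order* — non-monotone projections are preserved, so corner cutting
stays visible — with an injectivity report.

The bundled `psp_reference_frames()` table carries the tabulated state
distances; the round-trip tests reproduce every tabulated reaction
coordinate of the scan blocks from its printed distances at one decimal,
with two known internal inconsistencies in the source tables (one product
row per step) documented and excluded rather than silently corrected.
Comparisons against printed values round half away from zero
(`round_half_up()`), since base R rounds half to even.

## Rates

`rate_to_barrier()` / `barrier_to_rate()` implement bare Eyring TST with
transmission coefficient 1,
$k = (k_BT/h)\,e^{-\Delta G^\ddagger/k_BT}$.  Rates must carry an explicit
unit tag (`per_second` / `per_minute`); nothing is guessed.  The worked
example — a turnover of 20 min$^{-1}$ at ~70 °C, mapped to 343.15 K —
gives 20.93 ≈ 21 kcal/mol; the temperature is an explicit argument so the
approximation stays visible.

## The demo pipeline and problem sizes

`step1_demo_config()` runs the whole chain on the step-1-like surface at
desk scale: 2D windows on a 0.2 Å grid over OPO ∈ [−1.8, 1.4] ×
OHO ∈ [−1.0, 1.0] (187 windows), 1000 + 6000 steps per window (stride 10;
600 records, divisible into three blocks), 0.05 Å bins, and a 4-connected
minimum-free-energy path between the two basins.  The bin width matters:
it must stay comparable to the production bias width
$\sigma = \sqrt{k_BT/2k} \approx 0.04$ Å, because WHAM evaluates the bias
at bin centres — we measured that doubling the demo bins to 0.1 Å
inflates the reconstructed surface by several kcal/mol through that
discretisation alone, while at 0.05 Å the median deviation from the
analytic surface is ~0.3 kcal/mol.  These sizes
were chosen so a complete, statistically stable run finishes in about a
minute on one core; the estimator tests use the full 0.1 Å / 0.02 Å
protocol in 1D, where the exact reference is available.  The pipeline
writes every artifact as annotated TSV without timestamps, so a rerun with
the same master seed is byte-identical — that determinism is itself under
test.

## What the synthetic data does and does not show

The generator reproduces the *structure* of the real problem: multi-basin
surfaces with plateau-like transition regions, stiff biased sampling on a
window grid, block-partitionable time series, and reaction-coordinate
bookkeeping.  It does not reproduce molecular reality: there is no
molecular geometry, no orthogonal slow degrees of freedom beyond the 1–2
explicit coordinates, no force-field or electronic-structure error, and
sampling is Markovian with a short, homogeneous correlation time.  Passing
tests therefore certify the **estimators and path algorithms** —
unbiasedness of WHAM against an exact reference, correctness of the graph
path against exhaustive enumeration, saddle location against Newton — not
the physics of any particular enzyme.  Likewise the hysteresis and kink
diagnostics demonstrate the *mechanism* by which an insufficient reaction
coordinate corrupts a scan, on a surface where the true answer is known.

## Numerical choices and degenerate inputs

* Binning is left-closed, `[a, b)`; values outside the bin range are
  dropped and counted.
* Window grids must be commensurate with the spacing to 10⁻⁹; the error
  suggests the nearest commensurate bound.
* Non-convergence (WHAM iteration cap, chain iteration cap) returns a
  flagged result rather than an error; scans flag unconverged points and
  continue.
* A monotone profile yields a no-transition-state report, not an error.
* Saddle certificates that fail (wrong Hessian signature) warn and return
  the point flagged.
* All tie-breaks (Dijkstra queue, predecessor updates) are deterministic.

## Known limitations

* WHAM evaluates the bias at bin centres; with very wide bins and stiff
  biases this discretises the bias poorly — the 0.02 Å default keeps that
  error negligible against the 200 kcal mol$^{-1}$ Å$^{-2}$ production
  bias.
* Block errors assume the three blocks are effectively independent; no
  autocorrelation analysis is attempted (by design — the emulated protocol
  uses blocks).
* `refine_peak()` is not full conjugate-peak refinement; it requires a
  reasonable starting chain and a single dominant peak between re-runs.
* The Metropolis sampler is serial per window; windows are embarrassingly
  parallel but the package does not parallelise them.
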