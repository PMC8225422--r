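---
title: "Potential-driven structural plasticity in Hodgkin-Huxley networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Potential-driven structural plasticity in Hodgkin-Huxley networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

plastinet simulates a network of identical excitatory Hodgkin-Huxley
neurons whose *functional* connectivity — which neurons currently inject
current into which — evolves with the membrane potentials, while the
*structural* connectivity — which neurons are physically wired at all — is
fixed. This vignette is the package's own account of the model, its
assumptions, the tunable parameters, and the numerical and design choices
behind the implementation.

## The node model

Each neuron follows the conductance-based membrane equations

$$C_M \dot V = -g_{Na} m^3 h (V - E_{Na}) - g_K n^4 (V - E_K)
             - g_L (V - E_L) + I_{ext} + I_{coup},$$
$$\dot x = \alpha_x(V)(1 - x) - \beta_x(V)\,x, \qquad x \in \{n, m, h\},$$

with the classic squid-axon rate functions evaluated on the shifted
variable $u = V - V_{rest}$, $V_{rest} = -60$ mV. The defaults
($g_{Na} = 120$, $g_K = 36$, $g_L = 0.3$ mS/cm², $C_M = 1$ µF/cm²,
$E_{Na} = 55$, $E_K = -72$, $E_L = -49.4$ mV) are the original constants
expressed in absolute voltage: the reversal potentials are exactly the
classic values shifted by $-60$ mV, which is what makes the conductance
table and the $e^{u/80}$-style factors of the rate functions mutually
consistent. The voltage convention is a design choice — the constants alone
do not pin it down — and it is the only reading under which both are
simultaneously the textbook values.

The external drive $I_{ext}$ is a constant 10 µA/cm² per neuron by default,
which puts the isolated neuron well inside its periodic-spiking regime
(peaks near $+35$ mV, period about 14 ms). An optional per-neuron
multiplicative jitter (`Iext_jitter`) is available but off by default:
heterogeneity across neurons comes from initial conditions, not from
parameters.

The removable singularities of $\alpha_n$ at $u = 10$ and $\alpha_m$ at
$u = 25$ are implemented through the helper $s/(e^s - 1)$ with a series
branch below $|s| < 10^{-8}$, so the rates are continuous through the
singular points to full precision. The analytic Jacobian needed by the
stability certificate uses the same helper's derivative, with a series
branch below $|s| < 10^{-4}$ where the direct expression cancels
catastrophically.

## Structural network: periodic spatial domains

Every neuron $i$ owns an axis-aligned box (its dendritic/axonal territory)
on a global periodic plane of side $L = 100$. Two neurons are *structurally*
wired when their boxes intersect under periodic wrapping; boundary contact
counts. The reference scenario is an $8\times 8$ lattice of such domains.

A subtlety drove one design decision here: equal *square* domains enlarged
by a uniform overlap fraction also intersect their diagonal neighbours
(corner regions), which yields an 8-regular king graph rather than the
intended 4-regular lattice. `build_lattice()` therefore uses rectangles in
a checkerboard of alternating orientation — cells of one parity elongated
along x, the other along y, long side $\mathrm{spacing}\,(1 + f)$ and short
side $\mathrm{spacing}\,(1 - f/2)$ with `overlap_fraction` $f = 0.25$ by
default. Each rectangle then overlaps exactly its four lattice neighbours:
the overlap graph is the 4-regular torus for even $\sqrt N$ (on the
degenerate $2 \times 2$ torus opposite neighbours coincide and the
distinct-pair degree collapses to 2; for odd $\sqrt N$ the checkerboard
parity breaks across the seam and the graph is connected but not exactly
4-regular).

## Functional network: positions, threshold, plasticity

Neuron $i$ carries a position vector $r_i$ confined to its own domain
(wrapped periodically into the half-open box, so the boundary map is
deterministic). Distances between positions are measured on the *global*
torus with the minimum-image convention — this is what lets positions in
different domains come into contact through the overlaps. Three rules close
the loop:

* **Neighborhood.** $\eta_i = \{ j \ne i : \lVert r_j - r_i \rVert \le R \}$,
  boundary inclusive, with $R = 25$. The neuron itself is excluded: its own
  term carries no direction and would only inflate the coupling
  denominator.
* **Adjacency.** $a_{ij} = 1$ iff $j \in \eta_i$ *and* (by default) the
  pair is structurally wired. The structural mask makes "functional edges
  only where physical wiring exists" a hard, testable constraint;
  `mask_structural = FALSE` recovers the purely emergent behaviour. The
  graph Laplacian convention is $A = \mathcal{A} - D$ (zero row sums,
  negative semidefinite).
* **Plasticity.** Once per `update_period` (1 ms by default) the positions
  move:
  $$r_i \leftarrow \mathrm{wrap}\Big( r_i + \gamma \sum_{j \in \eta_i}
    \hat u_{ij}\, V_i V_j \Big),$$
  with $\hat u_{ij}$ the minimum-image unit vector towards $j$ and
  $\gamma = 6\times 10^{-7}$. Same-sign potentials attract, opposite signs
  repel; coincident positions contribute nothing. The printed form of this
  rule is typographically ambiguous between a per-pair product and a global
  prefactor; the per-pair reading matches the stated semantics (the *pair*
  of potentials decides attraction versus repulsion) and is the default,
  with the prefactor reading available via `update_mode = "prefactor"`.

Between updates the topology is frozen; these windows are exactly the
fixed-topology intervals on which the stability analysis operates. The
coupling strength is $c_i = \varepsilon / N_{\eta_i}$ with
$\varepsilon = 18.82$, computed from the *unmasked* neighborhood size, and
$c_i = 0$ when the neighborhood is empty ($\varepsilon/0$ is otherwise
undefined; the neuron is simply isolated for that window). Whether the
neighborhood count should include the neuron itself is not decidable from
the model statement; excluding it is consistent with excluding the
undirected self-term from the sum.

The coupling enters the membrane equation as a current,
$I_{coup,i} = c_i \sum_j a_{ij}(V_j - V_i)$ — a consensus
(proportional-controller) term that vanishes identically when all
potentials agree. Because $C_M = 1$ µF/cm², injecting it in the current
slot coincides numerically with adding it to $\dot V$.

## Simulation protocol and numerics

The reference protocol integrates $N = 64$ neurons for 3000 ms: isolated on
$[0, 400)$ ms, coupled with evolving topology on $[400, 3000]$ ms. The
integrator is an adaptive Dormand-Prince 4(5) Runge-Kutta pair
(`deSolve::rkMethod("rk45dp7")`, rtol $10^{-6}$, atol $10^{-8}$), restarted
at every window boundary because the vector field is discontinuous there.
The right-hand side of the full $4N$-dimensional system is compiled C for
speed; the per-neuron R implementation (`hh_derivative()`) is the
documented surface and the tests verify the two routes agree. Three
numerical details matter:

* the automatic initial-step heuristic can fail at window starts where the
  fresh consensus current is large, so the initial step is pinned to
  $10^{-4}$ ms and the step size capped at the output interval (0.1 ms);
* gating variables are clipped to $[0, 1]$ at window boundaries and on the
  output grid — adaptive steppers overshoot the invariant region only at
  rounding level, but downstream formulas ($n^4$, $m^3 h$) should never see
  negative inputs;
* the output grid (0.1 ms) is decoupled from the internal adaptive step.

**Initial conditions.** The paper-style protocol needs isolated neurons
with *distinct ongoing behaviour* and membrane potentials inside the
spiking envelope from $t = 0$. Drawing $V(0)$ uniformly with gates at their
voltage-clamped steady state fails the second requirement: steady-state
gates at hyperpolarized voltages carry high sodium availability
($h_\infty(-70) \approx 0.84$), so the first spike overshoots to about
$+50$ mV, well above the $+35$ mV steady spiking peak. The default
(`init_mode = "limit_cycle"`) therefore computes the isolated neuron's
limit cycle once (deterministic burn-in, 150 ms) and starts every neuron on
that cycle at an independent seeded phase. The uniform-draw initialisation
remains available (`init_mode = "uniform"`).

**Initial positions.** Positions start uniformly distributed over their
domains (`jitter_frac = 1`). Edge make/break events — the structural
plasticity under study — happen when drifting positions cross domain walls
or the interaction radius; pinning all positions near the domain centers
suppresses those events for an initial drift period of order a second,
which would contradict the immediate degree evolution the model is supposed
to exhibit. Center-pinned starts are available by shrinking `jitter_frac`.

**Randomness.** A run consumes two seeded streams forked from the single
run seed (initial states; position jitter), so adding a consumer to one
stream cannot perturb the other. Identical config and seed give bit-identical
traces, which the suite checks by running twice.

## Synchronization diagnostics

For any neuron set $M$ at time $t$: mean potential
$\mu = \tfrac1{|M|}\sum V_i$, *population* standard deviation
$\sigma = \sqrt{\tfrac1{|M|}\sum (V_i - \mu)^2}$ (divisor $N$, matching the
index's definition, not the $N-1$ sample form), and synchronization index
$\mathbb{S} = -\ln \sigma$. $\mathbb{S} > 0$ iff $\sigma < 1$ mV. When
$\sigma$ underflows $10^{-12}$ (numerically identical potentials) the index
is clamped at $-\ln 10^{-12} \approx 27.6$ and flagged, so downstream
tables stay finite.

## Per-window exponential-synchronization certificate

On each fixed-topology window the network synchronizes exponentially if
$\lambda_{2,\max} \le \bar d < 0$ and
$\Psi = (Df(\mu) + d\,\Gamma)^T G + G\,(Df(\mu) + d\,\Gamma)$ is negative
definite for $d \le \bar d$, where $Df$ is the single-neuron Jacobian along
the isolated reference trajectory, $\Gamma = \mathrm{diag}(1,0,0,0)$
selects the coupled variable (the membrane potential), and $G = I_4$ by
default. Notes on the implementation:

* $\lambda_{2,\max}$ is the second-largest eigenvalue of $A$ (the largest
  is always 0); it is strictly negative iff the window's graph is
  connected, and exactly 0 in the isolated phase.
* $\Psi$ is built from the analytic Jacobian rather than from transcribed
  closed-form entries; a unit test pins the structural facts that matter
  (symmetry, $d$ entering only $\psi_{11}$ for diagonal $G$, agreement with
  the explicit matrix product).
* Negative definiteness is certified by Sylvester's criterion
  ($(-1)^k \Delta_k > 0$ for all leading principal minors), verified against
  the all-eigenvalues-negative test on random matrices.
* `critical_d()` returns $\sup\{ d : \Psi(d) \text{ negative definite}\}$
  by bracketing and bisection to relative tolerance $10^{-6}$. Because
  $\Gamma$ only adds $d$ on the diagonal, definiteness is monotone in $d$
  and the bracket cannot miss. States at which no $d$ certifies (possible
  in principle when the gate block of $Df + Df^T$ fails on its own) are
  reported as "not certifiable", not as a number. The critical value
  depends strongly on the evaluation state; the function takes the state
  explicitly rather than hard-wiring one, and any published constant for it
  is treated as non-normative.
* `window_report()` uses $\bar d = -10^{-3}$ by default; any negative
  constant close to zero serves, and disconnected windows
  ($\lambda_{2,\max} = 0$) can never pass.

## Communities and their tracking

Per window, communities are detected on the 0/1 coupling matrix (not the
Laplacian) by a deterministic greedy agglomerative modularity optimizer:
starting from singletons, repeatedly merge the community pair with the
largest modularity gain, ties broken towards the lexicographically lowest
pair of community roots, until no merge gains. Determinism and an exact
tie-break make results seed-stable and oracle-checkable — the suite compares
against exhaustive partition search on all benchmark graphs up to 8 nodes
and against an independent greedy backend (igraph) where available. Any
modularity-optimizing backend could be swapped in behind `detect_communities()`.
Disconnected communities never merge (their gain is negative), and the
optimizer can never end below the all-singletons score.

Across windows, the co-membership probability $P_{ij}$ is the fraction of
windows in which $i$ and $j$ share a label. Neurons with
$P_{ij} \ge 0.70$ (inclusive — the verbal rule is quoted both as "70%" and
as "more than 70%", and the inclusive reading keeps the stated example
pair) are considered stably grouped. How pairwise probabilities aggregate
into groups is underdetermined: the default takes connected components of
the thresholded $P$-graph; `mode = "clique"` instead grows groups that
satisfy the threshold on *every* internal pair. Component groups can chain
below-threshold pairs together; clique groups cannot, but depend on scan
order. The per-group synchronization series then reuses the subset index.

## What the scenarios emulate — and what they do not

The built-in scenarios (`make_fixture()`) generate everything
programmatically: toy two/three-neuron bundles, the two-4-clique community
benchmark, the reduced `lattice16` scenario and the full `paper64`
reference. Two scenario choices deserve emphasis:

* `lattice16` puts the $4 \times 4$ grid on a plane of side **50**, not
  100: halving the plane with the grid preserves the lattice spacing
  (12.5), domain sizes and per-neuron neighborhood counts of the
  $8 \times 8$ reference, so the reduced run sits in the same interaction
  regime. A $4\times4$ grid on the full plane has spacing 25 $= R$ — a
  sparse regime with near-empty neighborhoods and a frozen functional
  graph, which reduces nothing.
* the suite runs `lattice16` for 1000 ms and the acceptance script runs
  the full 64-neuron, 3000 ms scenario; these problem sizes are the
  package's chosen trade-off between coverage and turnaround
  (about 2 s and 30 s respectively).

The generator emulates identical, excitatory, constantly driven,
single-compartment neurons with instantaneous (undelayed) electrical
coupling, on a two-dimensional torus. It does not emulate inhibitory
neurons, conduction delays, channel noise, heterogeneous cell parameters,
spike-triggered (event-driven) plasticity, or three-dimensional/arbitrary
domain geometries. Passing tests therefore show that the *mechanism* —
potential-driven edge dynamics that still admit per-window synchronization
certificates and stable communities — behaves as designed, not that the
model quantitatively matches biological tissue.

A known qualitative limitation: with identical neurons and the default
coupling scale, the network synchronizes very tightly shortly after
coupling onset (population deviation far below 1 mV), so the
synchronization index spends most of the coupled phase clamped near its
ceiling rather than fluctuating around zero as it would for weakly
synchronized populations. The community-versus-network index comparison is
still meaningful (and is asserted by the suite), but absolute index values
on the reference scenario should be read as "numerically synchronized"
rather than as graded synchrony levels.
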