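---
title: "Modelling seizure propagation in focal epileptic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling seizure propagation in focal epileptic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(epinetsim)
```

## The model

Each network node is an Epileptor: a five-variable phenomenological
neural-mass oscillator that produces seizure-like events through the
interplay of a fast subsystem (`x1`, `y1`, membrane-potential-like), a
slower subsystem (`x2`, `y2`, spike-and-wave events), and a very slow
permittivity variable `z` standing for extracellular processes (ion
concentrations, metabolism) that gate seizure onset and offset:

$$
\begin{aligned}
\dot x_1 &= y_1 - f_1(x_1, x_2, z) - z + I_1\\
\dot y_1 &= 1 - 5x_1^2 - y_1\\
\dot z   &= \tfrac{1}{\tau_0}\bigl(4(x_1 - x_0) - z + c\bigr)\\
\dot x_2 &= -y_2 + x_2 - x_2^3 + I_2 + 0.002\,g - 0.3(z - 3.5)\\
\dot y_2 &= \tfrac{1}{\tau_2}\bigl(-y_2 + f_2(x_1, x_2)\bigr)\\
\dot g   &= x_1 - \gamma g
\end{aligned}
$$

with the piecewise nonlinearities

$$
f_1 = \begin{cases} x_1^3 - 3x_1^2 & x_1 < 0\\
(x_2 - 0.6(z-4)^2)\,x_1 & x_1 \ge 0 \end{cases}
\qquad
f_2 = \begin{cases} 0 & x_1 < -0.25\\
6(x_2 + 0.25) & x_1 \ge -0.25. \end{cases}
$$

Default constants: $I_1 = 3.1$, $I_2 = 0.45$, $\tau_0 = 2857$,
$\tau_2 = 10$, $\gamma = 0.01$ (all dimensionless model units).  For an
isolated node the epileptogenicity $x_0$ decides the regime: below the
critical value $x_{thr} \approx -2.05$ the node rests at a stable fixed
point; above it, `z` drifts down to a saddle-node-on-invariant-circle
bifurcation where a seizure starts, climbs during the ictal phase, and
ends the seizure at a homoclinic bifurcation, yielding periodic
seizure-like events.  `find_threshold()` recovers the critical value by
bisection on long simulations.

Three printed-formula ambiguities in the source literature are exposed as
switches, with these defaults:

* **Memory filter input.** The convolution
  $g(t) = \int_0^t e^{-\gamma(t-s)}\,x_1(s)\,ds$ is realized exactly as
  the linear filter $\dot g = x_1 - \gamma g$, $g(0)=0$ (an $O(1)$
  state-space form of the exponential-kernel integral, verified against
  trapezoid quadrature in the tests).  The filter reads `x1` by default
  (`g_input = "x2"` is available, as both conventions appear in print).
* **`f2` branch variable**: `x1` by default, switchable to `x2`.
* **SLE observable**: `sle_signal()` returns `x1 + x2` by default
  (`convention = "inverted"` gives `-x1 + x2`, the convention of the
  original model literature).

## Coupling through the permittivity variable

Nodes interact only in the `z` equation, by difference coupling on the
fast variable: node $i$ receives
$c_i = \sum_j S_{ij} (x_{1,i} - x_{1,j})$ (available as
`coupling_term()`).  The sign with which $c_i$ enters $\dot z_i$ decides
whether the coupling spreads or suppresses seizures.  The package
defaults to the *spread* convention
$\dot z_i \propto 4(x_{1,i}-x_0) - z_i + c_i$, the form established for
permittivity coupling: when a neighbour seizes ($x_{1,j}$ jumps up),
$c_i$ drops and pulls $z_i$ down toward the onset bifurcation, so
strongly coupled healthy nodes are recruited after a delay — the delayed
collective onset that the recruitment experiment measures.  The opposite
sign (`coupling_convention = "printed"`, as some papers typeset the
equation) makes seizing neighbours *raise* a healthy node's permittivity;
in our hands that variant fails to recruit and, on prominently coupled
focal networks, diverges numerically.  Both are implemented; all study
drivers use the spread form.

Integration is classic fixed-step RK4 (the coupling vector recomputed at
every substage) in compiled code, `dt = 0.05` model time units — small
enough to resolve the fast ictal spiking, whose period is of order a few
time units.  Runs are bit-reproducible given `(seed, dt)`.  Optional
noise is additive Gaussian on `x2` only, applied Euler–Maruyama style
after the deterministic step; all headline experiments run
deterministically (`noise_sigma = 0`), with stochasticity entering only
through sampled networks, excitability profiles, and initial-condition
jitter.  An overflow guard aborts with the offending step rather than
propagating non-finite values.

## Synthetic study networks

`build_base_network(n)` places nodes on a ring and assigns every pair the
weight $1/d(i,j)$, the reciprocal ring distance — the simplest
fully connected distance-decaying structure ("connection strength
inversely proportional to the path between node pairs"); the decay rule
is pluggable.  A focal (lesion) subnetwork of prominently connected
excitatory nodes is then embedded: `build_focal_adjacency()` draws its
unweighted topology from one of four families — ring lattice (`p = 0`),
Watts–Strogatz small-world (`0 < p < 1`), fully rewired random
(`p = 1`), or scale-free with power-law degree-sequence exponent
$\gamma_{sf}$ (configuration-model realization, minimum degree 1,
simple graph, stray components reattached) — and `embed_focal()`
overwrites those edges with the uniform prominent weight
$K \cdot \max(\text{base})$, leaving the network fully connected.
Scale-free generation works from the degree-sequence exponent directly
(rather than preferential attachment) because the exponent is the
parameter the analyses sweep.

Focal excitabilities are drawn from a truncated normal:
$x_{0,i} \sim N(\mu, \sigma^2)$ conditioned on $x_{0,i} > x_{thr}$
(rejection sampling with a cap — the mean must not sit against the
threshold).  Non-focal nodes share a healthy value below threshold.

## Study conditions and their calibration

The shared defaults (`study_conditions()`):

| parameter | value | meaning |
|---|---|---|
| $\mu$ | $-1.6$ | focal mean excitability, comfortably suprathreshold |
| $x_{0,\text{nonfocal}}$ | $-2.2$ | healthy yet recruitable (subthreshold) |
| $K$ | 10 | focal-edge prominence multiplier |
| coupling budget | 2.15 | per-node total base input (see below) |
| duration | $6\tau_0$ | about 8–12 seizure cycles per run |
| transient | first $\tau_0$ | discarded from every statistic |
| `dt` | 0.05 | integration step |
| jitter | $\pm 0.05$ | uniform initial-condition symmetry breaking |

$\mu = -1.6$ and $x_{0,\text{nonfocal}} = -2.2$ are conventional values
for this model family (the seizing and recruitable-healthy reference
points of the bifurcation diagram).  Two constants the source literature
never states had to be fixed by calibration, once, against the model's
*qualitative* operating regime:

* **Per-node coupling budget.**  The ring-distance weights sum to roughly
  $2\ln(n/2)$ per node, so a fixed global multiplier would make the
  effective drive grow with network size and shift the dynamical regime
  between the differently sized experiments.  All study drivers therefore
  rescale the base network so each node's total base input is a constant
  budget $C = 2.15$ (equivalently, a global scale of about 0.3 on a
  40-node network).  $C$ was placed in the window where the model
  reproduces its defining collective behaviours: full recruitment of
  healthy tissue with clearly delayed onsets in the fully connected focal
  condition, no spontaneous seizures without focal nodes, and a
  homogeneous focal cluster whose functional clique stands out at the
  lesion proportion.  Much below that window recruitment fails entirely;
  much above it every node locks to every other and neither delays nor
  heterogeneity effects survive.
* **Sparse-condition edge weight** (0.5, applied as-is): chosen so the
  sparse random condition sits in the partial-recruitment regime that
  distinguishes it from the fully connected one.

The headline functional-connectivity analysis runs at the study's full
size, $n = 100$ with 20 focal nodes; the recruitment and period
experiments use 20- and 30-node networks, which already express the
relevant effects.  The test suite exercises the same drivers at those
sizes with small replicate counts.

## From trajectories to the study-level quantities

* **Events** (`detect_events()`): hysteresis thresholding on `x1` — onset
  on an upward crossing of $-0.5$, offset after `x1` stays below $-1.0$
  for a tenth of the minimum event length; events shorter than 50 time
  units are discarded.  The thresholds come from the model's known
  interictal ($x_1 \approx -1.6$) and ictal ($x_1 \approx 0\ldots1$)
  ranges; hysteresis makes the detector immune to ictal fast spikes.
* **Period** (`mean_period()`): consecutive onset-to-onset intervals,
  each node's first onset discarded as an initial-condition transient,
  pooled over a node subset.  The period sweeps evaluate the *recruited
  non-focal population*: the focal pacemakers cycle faster than the bulk
  they entrain, and the system-level rhythm of interest is the propagated
  bulk oscillation.
* **Recruitment and delays** (`recruitment_fraction()`,
  `onset_delays()`): a non-focal node is recruited if it has at least one
  event; its delay is its first onset minus the earliest focal onset.
* **Functional networks** (`correlation_matrix()`,
  `threshold_top_fraction()`, `average_degree()`): pairwise Pearson
  correlations on the post-transient window, ranked by signed value, top
  27.5% of all node pairs kept as binary edges (ties broken
  deterministically by index), focal average degree normalized by
  $n - 1$.  Signed (not absolute) ranking is used because the
  co-oscillating signals of interest correlate positively; a switch
  allows magnitude ranking.  The correlations are computed on the slow
  permittivity signal `z`: it carries the seizure envelope that the
  functional-network analysis is about, whereas the raw electrographic
  observable is dominated by ictal fast spikes whose phases decohere even
  between perfectly co-recruited nodes and bury the envelope structure
  (we verified that correlations of the raw SLE signal show essentially
  no dependence on the excitability heterogeneity).  `fc_signal = "sle"`
  switches to the raw observable.

## Experimental design choices

* **Counter-based sub-seeds**: each driver expands one root seed into
  per-replicate seeds, so replicate counts can change without reshuffling
  earlier replicates.
* **Paired comparisons with common random numbers**: within a sweep, a
  replicate reuses the same network draw, jitter and underlying normal
  deviates at every swept value ($\sigma$ scales the same deviates), so
  the contrast along the sweep is a within-replicate comparison rather
  than a difference of independent noisy means.
* **Heterogeneity experiment**: for each focal-topology family
  (lattice $p \in \{0, 0.3, 1\}$, scale-free
  $\gamma_{sf} \in \{2.2, 3.0\}$) and each
  $\sigma \in \{0, 0.05, 0.10, 0.15\}$, replicate (network, x0) pairs are
  simulated and the normalized focal average degree is replicate-averaged.

## Numerical and degenerate-case policy

* Bisection keeps a strict quiescent/oscillatory bracket; a bracket that
  does not straddle the transition is an error, not a guess.
* Regime classification: peak-to-peak `x1` range above 1.0 after the
  transient ⇒ oscillatory.  The ictal excursion is of order 2; fixed-point
  wobble is orders of magnitude below the tolerance.
* Zero-variance channels: excluded (synchrony) or zeroed (correlation
  matrices), always with a warning.
* Equal correlations at the threshold cut are resolved by (row, column)
  index order, so functional networks are reproducible.
* Relabeling network nodes permutes trajectories up to floating-point
  summation order (about $10^{-13}$ relative), since the coupling sums
  are reordered; identical labelled inputs reproduce bitwise.

## What the synthetic data do and do not show

The generators emulate the study's constructs — distance-decaying
fully connected base connectivity, prominently embedded focal topologies,
truncated-normal excitability — not any measured connectome or clinical
EEG.  Passing tests therefore demonstrate the claimed *mechanisms*
(delayed recruitment through permittivity coupling, period dependence on
excitability level and extent, heterogeneity-driven functional
decoherence) in a controlled synthetic setting; they say nothing about
patient data, frequency content of real seizures, or fitted
connectomes.  Known limitations: no delay terms (onset delays are
emergent), no stochastic-integration rigour beyond Euler–Maruyama noise,
and at sizes well below the 100-node reference the scale-free focal
graphs become so sparse (a handful of edges among 8 nodes) that the
heterogeneity effect on their functional degree is attenuated towards
zero — the full-size runs are the meaningful ones for that analysis.
Very strong coupling configurations (large $K$ at high-degree hubs) make
the fast subsystem stiff at `dt = 0.05` and trip the overflow guard; the
guard reports the step rather than silently returning garbage.
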