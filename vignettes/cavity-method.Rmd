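---
title: "Phase diagrams of lattice solution models by the cavity method"
author: "cavsep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase diagrams of lattice solution models by the cavity method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavsep)
```

## The model

`cavsep` studies liquid-liquid phase separation in a minimal microscopic
setting: a regular lattice whose sites hold either solvent (state 0) or one
of $q-1$ solute species, with the generalized-Potts Hamiltonian

$$H(\sigma) \;=\; -\sum_{\langle i,j\rangle} J(\sigma_i,\sigma_j)
\;+\; \sum_i \mu(\sigma_i),$$

couplings $J$ and chemical potentials $\mu$ in units of $k_BT$, solvent
couplings and potential fixed to zero. Note the **sign convention**: $\mu$
enters with a plus sign, so a solute's fugacity is $e^{-\beta\mu}$ and
*larger* $\mu$ means *less* of that solute. This convention is kept
verbatim throughout the package; negate `mu` if you expect the opposite.

Rather than postulating a free-energy functional, the thermodynamics is
derived from the partition function. Exact computation is exponential in
the system size, so three complementary routes are provided:

1. **Exact enumeration** (`exact_partition()`), capped at $3^{12}$
   configurations — the ground-truth oracle for everything else.
2. **Cavity / Bethe-Peierls message passing.** On trees the partition
   function factorizes into directed conditional partition functions
   ("messages") and `tree_messages()` is *exact* (the test suite checks
   agreement with enumeration to $10^{-10}$). On a homogeneous Cayley tree
   of branching $K$ (connectivity $C = K+1$) the messages collapse to one
   or two scalars with closed fixed-point equations — the mean-field
   approximation used for phase diagrams. A 2D square lattice is matched
   by $K = 3$, a 3D cubic one by $K = 5$ (same connectivity).
3. **Kawasaki Monte Carlo** (`kawasaki_sweep()`, `simulate_annealing()`),
   the finite-lattice ground truth that the mean-field maps are judged
   against.

## Binary solutions

For $q = 2$ the homogeneous message obeys
$u = \tfrac1\beta\log\frac{1+e^{\beta(J-\mu+Ku)}}{1+e^{\beta(-\mu+Ku)}}$
and the density is $\varphi = \mathrm{logistic}(\beta(-\mu+(K{+}1)u))$.
Eliminating $\mu$ parametrically yields the spinodal in closed form
(`binary_spinodal()`): for each $\beta J$ a quadratic in $w = e^{\beta u}$
with branches admissible when $1 < w < e^{\beta J}$. Its minimum — the
critical point — is $\beta J_c = 2\log\frac{K+1}{K-1}$ at $\varphi = 1/2$,
equal to $4\,\mathrm{atanh}(1/K)$ through the lattice-gas/Ising mapping.
The classical one-factor (Curie-Weiss / regular solution) result
$\beta J = 1/[(K{+}1)\varphi(1-\varphi)]$ (`cw_binary_spinodal()`) gives
$\beta J_c = 4/(K{+}1) = 1$ at $K=3$ — further from the exact 2D value
$2\ln(1+\sqrt2) \approx 1.763$ than the cavity value $2\ln 2 \approx
1.386$, which is the quantitative argument for the cavity route.

```{r binary}
bp_critical_point(K = 3)
binary_spinodal(2, K = 3)
```

**Binodals** come from the Maxwell equal-area construction
(`maxwell_binodal()`) applied to the parametric isotherm
$\beta\mu(u), \varphi(u)$: the coexistence potential $\mu^*$ is the root
of the signed-area integral between the outer crossings, solved to a
residual below $10^{-8}$ on a $10^4$-point density grid (trapezoidal
quadrature; the geometric description fixes the answer, the quadrature
grid and `uniroot` tolerance are numerical choices).

### Fixed-point solving

Fixed points are found by damped iteration
($u \leftarrow (1-\alpha)u + \alpha\,\mathrm{RHS}(u)$, $\alpha = 0.5$,
tolerance $10^{-12}$) from several starting values. Damped iteration can
only reach *dynamically stable* solutions, while between binodal and
spinodal stable and unstable fixed points coexist; the contract here is to
return all of them. The binary solver therefore adds a dense sign-change
scan of $u - \mathrm{RHS}(u)$ with bisection polish, and the ternary
solver a Newton sweep (numerical Jacobian) over a grid of starts. Multiple
returned solutions are the coexistence signal.

One caveat discovered by the tree oracle: for some repulsive parameter
combinations the exact leaf-to-root recursion on the Cayley tree does not
converge but oscillates between two layer states (a period-2,
antiferromagnet-like structure). The homogeneous fixed point still exists
but does not describe the free-boundary tree in that regime; the deep-tree
consistency tests therefore use contracting parameter sets.

## Ternary solutions and stability

For $q = 3$ (solutes $\pm$, ternary shorthand `ternary_model(J_mm, J_pp,
J_pm, ...)`) two messages $u_\pm$ obey coupled equations, and the phase
diagram lives in the composition plane $(\varphi_+, \varphi_-)$. To label
a *composition* rather than a field point, the state equations are
inverted (`ternary_fields_from_densities()`): with $m_\pm = -\mu_\pm +
Cu_\pm$ the densities become a three-state softmax in $\beta m_\pm$, which
inverts in **closed form**, $\beta m_\pm = \log(\varphi_\pm/\varphi_0)$ —
no iteration is needed for this stage, only the $u_\pm$ stage is iterated.
The $1/\beta$ placement in this transformation is fixed by requiring the
$J=0$ limit to reproduce the ideal-mixture field
$\beta\mu_\pm = \log(\varphi_0/\varphi_\pm)$ exactly.

Local stability is the positive-definiteness of the Hessian of the
de-mixing free energy. Because the Hamiltonian carries $+\mu$, the
thermodynamic conjugate of $\varphi_\pm$ is $g_\pm = -\mu_\pm$ (one checks
$\partial g/\partial\varphi > 0$ for the ideal mixture), so
`ternary_stability()` builds $H = \partial g_\pm/\partial\varphi_\pm$ by
central finite differences (step $10^{-4}$ in volume fraction, shrunk near
the simplex boundary, symmetrized before testing) and applies the
Routh-Hurwitz criterion: **mixed** iff $\det H > 0$ and
$\mathrm{tr}\,H > 0$. Ties $\det H = 0$ are labeled separated (the
boundary *is* the spinodal); the raw determinant and trace are returned so
users can re-threshold. The raw off-diagonal asymmetry (a pure
discretization diagnostic, since $\mu_\pm$ are gradients of one function)
is also reported.

The three classical de-mixing modes are bundled as `demixing_presets()`:
associative ($J_{+-} = 3$, $J_{\pm\pm} = -1$; both solutes condense into
one dense phase), segregative ($J_{\pm\pm} = 1$, $J_{+-} = -3$),
counter-ionic ($J_{++} = 2$, $J_{--} = 0$, $J_{+-} = 0.5$). Associative
diagrams are **re-entrant**: scanning one solute upward at small fixed
other-solute fraction crosses mixed → separated → mixed.

```{r reentrance}
m <- demixing_presets(beta = 1, K = 3)$associative
ternary_stability(rep(0.05, 5), c(0.01, 0.05, 0.1, 0.3, 0.55), m)[,
  c("phi_plus", "phi_minus", "det", "trace", "label")]
```

The regular-solution baseline (`rs_ternary_stability()`, analytic Hessian)
uses the fully connected free energy with $J^{\mathrm{eff}} = (K{+}1)J$.
That scaling is the one under which the classical binary spinodal above
emerges from the same equations, making RS and cavity maps comparable at
identical microscopic couplings; the RS map fails qualitatively for
associative couplings (no bounded re-entrant region), which the test suite
records as a nonzero disagreement fraction against the cavity map.

## Kawasaki simulation

`simulate_annealing()` drives a periodic 2D/3D lattice with
composition-conserving nearest-neighbor swaps (Metropolis acceptance,
proposal = uniform site + uniform neighbor; equal-state swaps count as
accepted proposals with $\Delta H = 0$ — the proposal kernel is a design
choice, detailed balance holds for any symmetric kernel). The inner loop
is compiled (Rcpp) and draws from R's RNG, so `set.seed()` makes entire
studies reproducible. Energies are tracked incrementally and re-checked
against a fresh evaluation at the end of every run (bookkeeping tolerance
$10^{-9}$).

Two full-scale annealing protocols are available as presets
(`preset_schedule()`): a binary ramp $\beta: 0 \to 8$ over $10^4$
iterations of $10^3$ sweeps, and a ternary ramp $\beta: 0 \to 1$ followed
by a long constant-$\beta$ tail with uniformly spaced snapshots. The
desk-scale studies in the tests and the acceptance script use reduced
versions (stated below); "step" nomenclature is normalized to *sweeps*
(one sweep = $L^d$ proposed swaps) everywhere.

**Critical-point estimation.** The specific heat per site is
$C(\beta) = \beta^2\mathrm{Var}(E)/N$. A single iteration is far too short
to sample critical fluctuations, so `specific_heat_peak()` pools the
post-equilibration energy samples of a sliding window of ~50 iterations,
removes a linear trend across the window (the ramp itself), and takes the
variance of the residuals; the peak location estimates $\beta_c$. At
$\varphi = 1/2$, $L = 32$, with a $\beta: 0\to3$ ramp of 600 iterations
$\times$ 300 sweeps, the three-seed mean lands within a few percent of the
exact lattice-gas value $2\ln(1+\sqrt2)$, and the finite-size shift decays
from $L = 8$ to $32$ as expected from $O(L^{-d})$ rounding. Flat series or
boundary maxima are flagged rather than reported as peaks.

## Snapshot detector

The detector (`classify_snapshot()`) mirrors image-based phase detection:
(i) each solute's indicator field is convolved with a periodic Gaussian
kernel (exact circular convolution via FFT; kernel truncated at $4\sigma$
and renormalized, so the field mean equals the volume fraction to machine
precision); (ii) the local-density histogram (64 bins on $[0,1]$) is
turned into a free-energy profile $F(\rho) = -\log P(\rho)$ via the Gibbs
relation; (iii) local minima are counted with a topographic-prominence
filter (secondary minima need $\geq 0.25\,k_BT$ of prominence); (iv) the
continuous separation score is
$\xi = 1 - e^{-\Delta/\Delta_0}$, $\Delta$ the largest secondary-minimum
prominence across components, $\Delta_0 = 1\,k_BT$: 0 for a well-mixed
snapshot, toward 1 for deep bimodality. A system is called separated when
*any* component is bimodal — associative de-mixing condenses both solutes
together, segregative condenses them singly, and both produce at least one
bimodal component. All constants ($\sigma$, bins, smoothing, prominence,
$\Delta_0$) are exposed as arguments; none of them is fixed by theory, so
the binary decision threshold on $\xi$ is **calibrated**
(`calibrate_threshold()`): it minimizes, over calibration annealing runs,
the mean distance between the $\xi$-crossing temperature and the
specific-heat-peak temperature — two independent estimates of the same
transition on the same path. Default $\sigma = 3$ lattice units; the
desk-scale studies at $L = 24$–$32$ use $\sigma = 2$ so the kernel stays
small relative to the box ($\sigma \approx L/12$).

Deep quenches are deliberately avoided in the study protocols: quenching
Kawasaki dynamics far below the transition arrests coarsening in many
small clusters whose density histogram is unimodal; a slow ramp (then a
constant-$\beta$ tail) lets domains coarsen so bimodality is detectable.

## Inverse modeling

`fit_de()` fits the ternary couplings to a *binary-labeled* phase diagram
(mixed/separated on a concentration grid), as for coacervation screens of
a nucleotide with poly-lysine. Concentrations map linearly to volume
fractions ($\varphi_\pm = s_\pm c_\pm$); since no a-priori conversion
exists, $s_\pm$ are fitted alongside $J_{++}, J_{--}, J_{+-}$ — chemical
potentials are eliminated entirely by working in composition space through
the field inversion above. The loss is the misclassification fraction of
Routh-Hurwitz labels (branching default $K = 5$, a 3D cubic lattice);
simplex-violating mappings get infinite loss. The optimizer is classic
rand/1/bin differential evolution (population 32, $F = 0.7$,
$CR = 0.9$, up to 200 generations, early stop after 30 stagnant ones —
the algorithm is standard, the hyperparameters are package defaults), with
box bounds doubling as region constraints: an "associative" fit forces
$J_{+-} > 0 > J_{\pm\pm}$, a "segregative" one the reverse pattern.

`synthesize_dataset()` generates ground-truth diagrams on the default
11 × 112 assay grid ($c_+ \in [0.2, 2.2]$, $c_- \in [0.06, 7.14]$, default
scales $s_+ = 0.1, s_- = 0.05$ chosen once to keep the grid inside the
simplex) with independent label flips as classification noise. What the
generator emulates is the *geometry and labeling* of a screening
experiment; it does not emulate droplet optics, intensity values, buffer
chemistry, or spatially correlated misclassification, so recovery results
speak to the inference machinery, not to wet-lab accuracy. Recovery runs
on noise-free associative data reach zero misclassification while the
recovered couplings are near-degenerate (different seeds, equally good
fits with different parameters) — the loss landscape genuinely has many
optima, and a segregative-constrained refit of the same data fits strictly
worse, which is what makes the de-mixing *mode* identifiable even when
individual couplings are not.

## Study conditions used by the tests and the acceptance script

* Tree-exactness oracle: 50 random trees, $N \le 12$ (binary) / $N \le 9$
  (ternary), $J, \mu \sim U[-2,2]$, $\beta \in \{0.5, 1, 2\}$.
* Binary MC critical point: $L \in \{8, 16, 32\}$, $\varphi = 1/2$,
  $\beta: 0 \to 3$, 600 × 300 sweeps, 3 seeds, window 50.
* Theory-vs-simulation agreement: the three preset interaction sets at
  $\beta = 1$, $K = 3$, 8 × 8 composition grid on $[0.05, 0.40]^2$,
  $L = 24$, slow ramp (200 iterations × 100 sweeps, $\beta: 0 \to 1$) then
  $4\times10^4$ sweeps at $\beta = 1$, 10 snapshots, $\sigma = 2$,
  majority vote. The slow ramp matters: quenching through the transition
  arrests coarsening and blinds the detector. The threshold is calibrated
  on annealing runs of systems *matched to the study being classified* —
  ternary models at the same lattice size, kernel and ramp endpoint,
  spanning the de-mixing modes and including a weakly separating
  off-symmetric composition. Two lessons from developing this: a
  calibration set containing only crisply separating systems pins the
  threshold above the score plateau of marginal condensates and
  misclassifies them wholesale; and mixing calibration systems with very
  different temperature scales (binary ramps to $\beta = 4$ alongside
  ternary ramps to $\beta = 1$) lets the noisier wide-ramp runs dominate
  the crossing objective. Each study therefore calibrates on its own kind
  of systems (the binary detector-vs-specific-heat study below calibrates
  on binary runs).
* Detector-vs-specific-heat comparison: $\varphi \in \{0.03, 0.05, 0.08,
  0.12, 0.2, 0.3, 0.4, 0.5\}$, 4 seeds each, $L = 32$, $\beta: 0 \to 4$,
  500 × 160 sweeps.
* Recovery study: 10 × 20 concentration grid (200 points), no noise,
  truth = associative preset at $K = 5$.

These sizes are the package's chosen desk-scale study conditions; all of
them are plain function arguments, so full-scale replications only change
numbers, not code.

## Known limitations

* The cavity method is mean field: it overestimates the extent of the
  separated region and cannot produce correct critical exponents; the
  agreement study quantifies exactly this gap against simulations.
* Homogeneous fixed points assume a translation-invariant message; regimes
  with spontaneous layer oscillation on the tree (see above) and loopy-BP
  on finite lattices are out of scope.
* The detector needs coarsened domains; arrested morphologies (deep
  quenches, gels) are systematically called mixed.
* K = 1 chains have no finite-temperature transition and are rejected by
  the spinodal/critical-point routines.
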