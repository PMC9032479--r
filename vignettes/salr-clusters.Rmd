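---
title: "Parallel tempering Monte Carlo for SALR colloidal clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parallel tempering Monte Carlo for SALR colloidal clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salrmc)
```

## The model

Charged colloidal particles in the presence of a depletant attract each
other over a short range (depletion) and repel over a long range (screened
electrostatics).  `salrmc` models an isolated cluster of `N` such particles
with a pairwise-additive SALR potential: a Morse attraction

$$V_a(r) = \epsilon_M\, e^{\rho(1 - r/\sigma)}\left(e^{\rho(1 - r/\sigma)} - 2\right)$$

plus the long-range branch of a Yukawa repulsion

$$V_r(r) = \epsilon_Y\, \frac{e^{-\kappa\sigma\,(r/\sigma - 1)}}{r/\sigma},$$

summed over all $N(N-1)/2$ pairs.  Everything is in reduced units: lengths
in particle diameters $\sigma$, energies in the potential scale, $k = 1$.
The default preset `"M30+Y1.0"` ($\rho = 30$, $\epsilon_M = 2$, $\sigma = 1$,
$\kappa\sigma = 0.5$, $\epsilon_Y = 1$) is a type-II SALR interaction: a deep,
very narrow well at contact and a repulsive barrier just beyond it.

```{r potential}
p <- salr_params()
p
r <- seq(0.9, 3, length.out = 400)
plot(r, pair_energy(r, p), type = "l", ylim = c(-1.2, 1.5),
     xlab = "r / sigma", ylab = "V(r)")
abline(v = p$r_cut, col = "red", lty = 2)
barrier_distance(p)
```

The barrier top (about $1.156\,\sigma$) is the only distinguished distance
in the model, so it is the default cutoff `r_cut` that defines a *bound*
pair.  `r_cut` is used solely by the boundedness test; the energy always
sums every pair in full.  Because the exact cutoff behind the published
model is not stated numerically anywhere we could find, `r_cut` is exposed
as an ordinary parameter and the sensitivity of observables to it is a
caveat worth keeping in mind.

## Why the sampling is hard

With $\rho = 30$ the attractive well is extremely stiff: the curvature at
the bond minimum is $\sim 2\rho^2\epsilon_M \approx 3.6\times10^3$, so
thermal bond fluctuations at $T = 0.05$–$0.30$ are only $0.004$–$0.02\,\sigma$.
A Metropolis walk tuned to the standard 50% acceptance rate therefore moves
in steps of that size, and the walk decorrelates very slowly.  This is the
deep reason published studies of these clusters burn through $10^{9}$–$10^{10}$
Monte Carlo steps per replica: the energy landscape is a collection of very
narrow funnels (spirals, necklaces, chains) separated by high barriers.

`salrmc` attacks the problem the standard way, with parallel tempering:
`M` replicas at temperatures covering the range from deep order to beyond
dissociation, exchanging configurations on the deterministic even–odd (DEO)
schedule, plus a *rupture rejection* rule — any proposed move that leaves a
particle (connected mode: any sub-aggregate) beyond `r_cut` of the rest is
rejected outright, which keeps the isolated cluster from evaporating into
unbounded phase space.

## Workflow

```{r workflow, eval = FALSE}
p <- salr_params()
seed <- basin_hopping(9, p, n_hops = 2000, seed = 1)   # putative global minimum
ladder <- build_ladder(0.05, 0.30, 0.01)               # 26 temperatures
runs <- run_ptmc(seed, ladder, p,
                 n_therm = 5e5, n_prod = 2e6,          # desk profile
                 swap_stride = 50, record_stride = 1000,
                 n_runs = 3, master_seed = 1)
cv <- cv_curve(runs)        # heat capacity +/- run-to-run sd
find_features(cv)           # peaks and shoulders
q <- quench_samples(runs)   # inherent structures, motif census
```

Every replica starts from the same relaxed seed structure — normally the
basin-hopping global minimum, never a random configuration, so early
sampling is not contaminated by fragmented geometries.  Each independent
run derives its per-replica PCG32 streams deterministically from
`master_seed` and the run index: a run is bit-reproducible from its
configuration alone.

## Parameters that matter

* **Temperature ladder.** `build_ladder(0.05, 0.30, 0.01)` gives the
  standard 26 temperatures; adding
  `refinements = list(list(interval = c(0.11, 0.18), step = 0.005))` gives
  the 33-temperature ladder used for `N = 11`, where a low-temperature
  structural transition needs finer resolution.
* **Step counts.** The `"desk"` profile (`run_config()`) uses $5\times10^5$
  thermalization and $2\times10^6$ production attempts per replica; the
  `"paper"` profile records the full-scale values ($5\times10^9$ and
  $1.5\times10^{10}$) behind the published curves.  A "step" is one
  attempted single-particle displacement.
* **Swap stride.** Exchanges are attempted every 50 attempts per replica
  (DEO alternates even and odd adjacent pairs).
* **Step-size adaptation.** Every `adapt_block` (default 1000) attempts the
  maximum displacement is rescaled by `rate / 0.5`, clamped to a factor of
  two per update and to $[10^{-4}, 2\sigma]$ overall.  A rupture rejection
  counts as a rejected attempt.  The published step-adjustment recipe is not
  reproduced verbatim (it is not printed); this multiplicative rule hits the
  same 50% target.
* **Heat capacity.** $c_V = \tfrac32 + (\langle V^2\rangle - \langle
  V\rangle^2)/(N T^2)$ per particle, computed from the recorded energy
  trace (population variance; at the recorded sample counts the difference
  from the unbiased estimator is far below the run-to-run spread, which is
  what `cv_curve()` reports as the error bar).
* **Quenching.** Stored configurations are relaxed by L-BFGS with a
  monotone Armijo line search, finished by damped Newton with the analytic
  Hessian once energy differences fall below double resolution; convergence
  is `|g| < 1e-8`.  Relaxed minima are identical when their energies differ
  by less than $10^{-6}$ (the published identity rule); distinct isomers of
  near-equal energy can in principle merge under this rule, which we accept
  for fidelity.

## Motif classification

The field sorts these clusters into three visual families: compact or
Bernal-spiral shapes (Set I), "beaded-necklace" motifs (Set II), and
essentially unrolled linear/branched shapes (Set III).  `classify_shape()`
operationalizes the taxonomy with descriptor thresholds on the bond graph
(edges where $r_{ij} \le r_\mathrm{cut}$) and the gyration tensor:

* **Set I** if the relative shape anisotropy is below 0.25 (compact) *or*
  the bond count is within 2 of the tetrahelix template $3N - 6$ (spiral);
* otherwise **Set III** if the maximum coordination is $\le 3$ or the bond
  graph is a path (unrolled);
* otherwise **Set II** (necklaces: 3-D beads joined by low-coordination
  links).

Compactness is tested first so that small compact clusters (a tetrahedron
has maximum coordination 3) are not mistaken for chains.  The thresholds
are exposed as arguments, and `motif_frequencies()` accepts a manual label
map, because the original taxonomy is a judgement call on pictures, not a
formula.  Entries whose frequency never reaches 4% at any temperature are
pooled as "miscellaneous" regardless of shape; per-temperature frequencies
always sum to 100%.  The published IIa/IIb sub-split of necklaces (an
explicitly arbitrary separation by how thin the terminations are) is
available as a heuristic: `motif_frequencies(..., set2_terminal_split = k)`
relabels necklaces with at least `k` terminal-chain particles as `IIb`.

## What the desk scale can and cannot show

The full-scale runs behind the published heat-capacity curves are about
$10^4\times$ longer than anything a desk machine reproduces in minutes, and
this gap is *physical*, not cosmetic.  Starting every replica from the
ordered global minimum and sampling too briefly under-represents the
extended motifs that carry the transition entropy, so the dominant
dissociation maximum appears *above* its converged temperature and drifts
downward as runs lengthen — a textbook superheating artifact.  Re-running
`run_ptmc()` for `N = 9` at increasing `n_prod` (say $2\times10^6$,
$8\times10^6$, $4\times10^7$) and comparing `cv_curve()` maxima makes the
drift easy to see on any machine.  The package's acceptance script gives the
slowly-converging `N = 9` dissociation signature the deepest sampling a
desk-time budget allows ($1.25\times10^6$ thermalization plus
$4.5\times10^6$ production attempts per replica, 3 runs) and runs the
`N = 10` and `N = 11` structural-transition analyses as single runs at the
standard desk profile ($5\times10^5$ plus $2\times10^6$, quenching 1500
stored configurations per temperature); at these depths an upward bias of
one to three ladder steps should still be expected for the dissociation
peak, and more for the structural transitions.  The test suite uses a
further-reduced profile ($4\times10^5$ plus $1.5\times10^6$, 2 runs) whose
verdicts on these signatures match the acceptance profile's.

The low-temperature *structural* transitions are harder still.  For
`N = 11` the published census has necklaces (Set II) displacing the Bernal
spiral already at $T \approx 0.12$–$0.15$; at desk scale the spiral persists
metastably well past that range, because spiral-to-necklace interconversion
requires a concerted unrolling that the tiny adapted steps realize very
slowly even with replica exchange.  Tests and the acceptance script compute
these quantities exactly as specified — seed at the global minimum, run the
ladder, quench, dedupe at $10^{-6}$, classify, apply the 4% rule — and
report what the scaled-down run actually yields, with the run-to-run spread
as the error estimate.  Where the desk-scale number cannot reach the
published value, the discrepancy is stated rather than smoothed over.

## Synthetic fixtures

`random_bound_cluster()` grows a connected cluster by sequential insertion
within `r_cut` of an existing particle (insertion distances in
$(0.95\sigma, r_\mathrm{cut})$, keeping new particles off the steep Morse
wall).  It emulates the *connectivity* of sampled clusters, not their
Boltzmann statistics: such configurations are mechanically hot, and a
minority fragment during quenching (descent can separate repelling
sub-branches indefinitely, which the quench flags as non-converged).  Tests
use these fixtures for contracts — boundedness, determinism, descent,
gradient correctness — never as stand-ins for equilibrium samples.

## Numerical choices

* All-pairs energies in compiled code with cached pair-energy and distance
  matrices; a single-particle move costs $N-1$ fresh pair evaluations.
* The Monte Carlo hot path evaluates exponentials with a polynomial
  `fast_exp` accurate to $\sim10^{-13}$ relative; energies are
  resynchronized from the cache every adaptation block, and all quench /
  analysis energies use the standard library `exp`.
* Boundedness uses connected-component analysis by default ("connected"
  mode); the literal per-particle criterion is available as
  `mode = "per-particle"`.  A move that breaks none of the moved particle's
  bonds cannot disconnect the graph, which avoids most BFS work.
* The quench accepts a step only if it lowers the energy (Armijo) or — once
  energy differences are below double resolution — if it shrinks the
  gradient norm; a final damped-Newton polish with the analytic Hessian
  reaches $|g| < 10^{-8}$ in a handful of iterations despite the $10^6$
  condition number.
* Ladder construction uses integer grid arithmetic so that the 26- and
  33-point ladders are exact; refinement points must nest into the base
  grid.
* Feature detection smooths with a 3-point moving average by default; peaks
  are interior local maxima, shoulders are curvature sign changes on the
  low-temperature flank of a peak.  Feature temperatures are reported at
  ladder resolution.

## Known limitations

* Desk-scale runs under-sample extended motifs; transition temperatures
  carry an upward bias and Set II/III frequencies a downward one (see the
  convergence table above).
* Energy-only deduplication can merge genuinely distinct isomers that
  happen to be degenerate to $10^{-6}$.
* The descriptor thresholds in `classify_shape()` approximate a visual
  taxonomy; borderline necklaces with one broken bead bond may flip between
  Set I and Set II.
* Single-particle displacements are the only move type (as in the published
  machinery); collective moves, volume moves and grand-canonical moves are
  out of scope.
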