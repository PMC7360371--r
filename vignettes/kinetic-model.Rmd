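---
title: "A kinetic lattice model of multivalent phase separation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A kinetic lattice model of multivalent phase separation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condensateKMC)
```

## The model

Many intracellular condensates form by liquid–liquid phase separation of
multivalent "sticker-spacer" proteins: folded adhesive domains (stickers)
joined by flexible linkers (spacers).  `condensateKMC` implements a
phenomenological kinetic model of this process in which every polymer chain
is coarse-grained to a single particle on a 2D square lattice (periodic in
both axes, von Neumann neighbourhoods).  The model is simulated exactly as
a continuous-time Markov jump process with the Gillespie stochastic
simulation algorithm, which makes *biologically relevant time-scales* —
hours of simulated time — reachable on a desktop.

A configuration changes through four event families:

* **Monomer diffusion.** A particle hops to an empty neighbouring site.
  Each feasible direction is an event at rate
  $k_{diff}\,e^{-E_p}$, where
  $E_p = n_{bonds}(p)\,\epsilon_{sp} + n_{nbrs}(p)\,\epsilon_{ns}$
  is the particle's total interaction energy in units of $kT$.  An escaping
  particle pays for *all* of its interactions, and the hop severs all of its
  bonds and contacts.
* **Cluster diffusion.** Every adjacency-connected cluster of $S_{clus}
  \ge 2$ particles can translate rigidly in a direction whose targets are
  all empty or same-cluster, at the size-scaled rate $k_{diff}/S_{clus}$.
  This is what lets droplets coalesce rather than grow only by
  monomer exchange (Ostwald ripening).
* **Bond formation.** Any adjacent pair in which both particles still have
  unsatisfied valency ($used < \lambda$) can form a specific bond at rate
  $k_{bond}$.  A pair of neighbours can hold several bonds (multiplicity),
  reflecting the several adhesive domains per chain.
* **Bond breakage.** Each existing bond (counting multiplicity) breaks at
  $k_{break} = k_{bond}\,e^{-\epsilon_{sp}}$, i.e. bond kinetics obey
  detailed balance at strength $\epsilon_{sp}$.

After each event the feasible-event list is rebuilt, the waiting time is
drawn as $\delta t = -\ln(z_2)/r_{total}$ and the event as the cumulative
interval containing $z_1 r_{total}$.  Blocked moves are *excluded* from the
list rather than listed at rate zero — a null event would advance the
stochastic clock without changing the state and distort the time axis.

### Parameters

| parameter          | meaning                                   | default | units |
|--------------------|-------------------------------------------|---------|-------|
| `latticeSize` (L)  | sites per side                            | 100     | sites |
| `phi` / `nParticles` | occupied-site fraction / count          | 0.04    | —     |
| `valency` (λ)      | max specific bonds per particle           | 5       | —     |
| `epsSp`            | specific-bond strength                    | 3       | kT    |
| `epsNs`            | non-specific neighbour attraction         | 0.35    | kT    |
| `kDiff`            | free-diffusion rate                       | 1       | 1/s   |
| `kBond`            | bond-formation rate                       | 1       | 1/s   |
| `tEnd`             | simulated horizon                         | 7200    | s     |

Only the ratio $k_{bond}/k_{diff}$ matters for the phase behaviour, so
$k_{diff}$ is fixed at 1 s⁻¹ and phase diagrams scan the ratio.  The weak
non-specific attraction of 0.35 kT keeps cluster formation driven by the
valency-limited specific bonds; densities between 0.01 and 0.1 correspond
to the micromolar concentration range of condensate proteins.  Energies in
the kinetic module are in kT throughout; there is no separate temperature
parameter.

### Design choices

Several aspects of the lattice realization are genuinely open and were
fixed once, as follows:

* **Boundary conditions and lattice size.**  Periodic boundaries (matching
  the simulation-box convention of the underlying bead-spring picture) and
  a default $L = 100$; both are configuration parameters.
* **Rate convention.** "A particle diffuses in any of the four directions
  with rate $k_{diff}$" is read as *rate per direction*.  A
  `rateConvention = "total"` switch divides by 4 for the alternative
  reading.
* **Cluster definition.**  Clusters are adjacency-connected components of
  occupied sites (not bond-connected), used consistently by the mover, the
  labeller and all observables.  The choice is switch-free on purpose: a
  single definition keeps the cluster-diffusion events and the order
  parameters consistent.
* **Cluster collisions.**  A translation that would land on a foreign
  cluster is infeasible; merging happens by diffusing into adjacency, not
  by collision fusion.
* **Escape energetics.**  A mover pays its *total* interaction energy
  (the net interactions it is involved in), not only the contacts broken in
  that direction.
* **Re-enumeration.**  The event list is rebuilt after every event.  The
  only caching is geometric: bond formation/breakage cannot change
  adjacency, so the cluster decomposition and neighbour counts are reused
  across consecutive bond events.  Tests verify the compiled enumeration
  against an independent brute-force oracle on thousands of random states.
* **RNG.**  One dedicated 64-bit Mersenne Twister per trajectory, seeded
  from `seed`; the waiting time is always drawn before the event.
  Replicates use seeds derived deterministically from
  (base seed, cell index, replicate index), so sweep results are
  independent of execution order.

## Order parameters and observables

* $L_{clus}$: largest cluster as a fraction of $N_{tot}$ (macrophase as
  $L_{clus} \to 1$).
* $S_{clus}$ distributions, pooled over snapshots and replicates.
* $\phi_{clus}/\phi$: intra-cluster density via the 2D gyration disk,
  $\phi_{clus} = S_{clus}/(\pi R_g^2)$, normalized by the bulk density.
  Clusters below 4 particles have a degenerate gyration radius and return
  `NA`; clusters spanning at least $L/2$ on either axis are flagged
  percolating and excluded from density statistics.  Clusters are unwrapped
  across the periodic seam (breadth-first traversal accumulating
  minimal-image offsets) before the centroid is taken.
* **Monomer exchange times.**  An exchange event opens when a particle's
  occupied-neighbour count reaches 4 (fully buried) and completes when it
  next reaches 0 (free) — the model's analogue of FRAP-style molecular
  exchange.  Unresolved burials at `tEnd` are censored and never averaged
  in; the censoring fraction is always reported, and a conservative bound
  that treats censored durations as complete is available as a cross-check
  that censoring cannot silently bias the mean downward.  Events are pooled
  across trajectories by default (per-particle averaging is available),
  and the study-scale protocol is 100 trajectories of 10 simulated hours.
* **Phase classification.**  *Macrophase* when mean $L_{clus} \ge 0.5$
  (the largest cluster holds at least half of all monomers); *NoPS* when
  mean $L_{clus} \le \max(5/N_{tot}, 0.05)$ with fewer than 0.5 bonds per
  particle; otherwise *microphase*.  The macrophase threshold is the
  model's operational 50% criterion; the NoPS thresholds are not dictated
  by the model and are exposed as arguments.

## The bead-spring energy module

The kinetic model coarse-grains a bead-spring polymer whose force field the
package implements as static evaluators (no integrator — dynamics are a
non-goal):

* stretching $E = k_s \sum_i (|r_i - r_{i+1}| - r_0)^2$ with
  $k_s = 5\,kT/\text{Å}^2$, $r_0 = 4.5$ Å between linker beads and 20 Å for
  specific bonds;
* bending $E = \kappa \sum_i (1 - \cos\theta_i)$ with $\kappa = 2$ kcal/mol
  for flexible linkers;
* non-bonded $E = 4\epsilon_{ns}\sum_{i<j} [(\sigma/r)^{12} -
  (\sigma/r)^6]$, truncated (not shifted) at $2.5\sigma$, with $\sigma =
  4.2$ Å for linker beads and 20 Å for domains.

Specific bonds between complementary domains form with probability
$P_{form}$ inside a 22.5 Å capture radius (at most one bond per domain) and
break with probability 1 beyond $r_0 + 2.2$ Å; an irreversible mode keeps
bonds forever, matching the stable-interaction variant of the model.

Three conventions required a decision:

* The stretching sum is implemented exactly as written above, without the
  $\tfrac12$ prefactor, but a `halfPrefactor` flag is exposed: the stated
  breakage energy of "about 4 kT" at 2.2 Å stretch with the 2 kT/Å²
  bond spring is consistent only with the half convention
  ($\tfrac12\cdot2\cdot2.2^2 = 4.84$ vs $9.68$ kT), so the ambiguity is
  surfaced rather than resolved.
* Mixed linker–domain Lennard-Jones pairs use the Lorentz arithmetic mean
  $\sigma = (4.2 + 20)/2 = 12.1$ Å.
* The backbone rest length between a linker and a domain bead is not
  specified by the force field; the contact distance of the two radii
  (12.1 Å) is the documented default, overridable per bond.

Energies carry an explicit unit tag (kT or kcal/mol, interconverted at
310 K where 1 kT = 0.61596 kcal/mol); constructor inputs are tagged and
converted once, so untagged unit mixing cannot occur.

## What the simulations show

```{r quick-run}
p <- SimParams(latticeSize = 50, phi = 0.04, valency = 5, epsSp = 3,
               tEnd = 600, snapshotInterval = 300, seed = 7)
tr <- runTrajectory(p)
trajectorySummary(tr)
```

Scanning `epsSp` produces the kinetic phase diagram: no significant phase
separation below about 2 kT, a metastable multi-droplet microphase at low
to intermediate densities, and a system-spanning macrophase only at high
density or strong interaction.  The critical strength (smallest `epsSp`
with mean $L_{clus} \ge 0.5$) decreases with valency, exchange times rise
steeply with `epsSp` (a four-fold slow-down between 2 and 2.5 kT at
valency 5), and slower diffusion leaves smaller clusters at a fixed
horizon — the signature of kinetically arrested, not equilibrium,
droplets.  Each of these statements is recomputed by the test-suite and
by `scripts/acceptance.R`; the vignette intentionally reports nothing the
shipped code does not itself compute.

## Problem sizes and numerical choices

The test-suite runs reduced but statistically meaningful problem sizes,
chosen once as study conditions:

* exchange-time experiments: 20 trajectories of 10 simulated hours at
  $L = 50$, $\phi = 0.04$ (scaled down from the 100-trajectory study
  protocol);
* the critical-strength scan: $\epsilon_{sp} \in \{0.5, 1, \ldots, 4\}$ kT,
  10 replicates × 2 h at $L = 50$;
* no-bonding controls: $k_{bond} = 0$ at $L = 70$ with a 200 s horizon —
  without bonds the system relaxes within seconds
  (diffusive mixing time $\ll$ 200 s), so a longer horizon adds nothing;
* valency ordering and diffusion scans: $L = 40$, 1 h horizons;
* convergence: the package-default point ($L = 100$, $\phi = 0.04$,
  $\lambda = 5$, $\epsilon_{sp} = 3$ kT), paired 2 h vs 4 h comparisons
  within the same trajectories.

Numerical details worth knowing: rates are accumulated in double precision
and the `EventSet` validity check tolerates 1e-9 relative accumulation
error; the event draw uses a single cumulative scan (ties at bin edges go
to the later event, a measure-zero choice); `waitingTime(rTotal, u)`
rejects `u = 0` (log divergence) and maps `u = 1` to 0; a configuration
with no feasible event is frozen forever, so the run fills the remaining
snapshots, flags early termination and warns.

## Limitations

The lattice model collapses every chain to one particle of a single
species: it cannot resolve intra-chain reorganization, linker stiffness
effects, or heterotypic mixtures, and its 2D geometry makes densities only
qualitatively comparable to 3D volume fractions.  The synthetic dynamics
emulate diffusion-limited assembly with instantaneous, saturating bonds;
they do not emulate hydrodynamics, excluded-volume softness, or
concentration-dependent viscosity, so passing tests demonstrate the
internal consistency of the kinetic model and its qualitative phase
behaviour — not quantitative agreement with any particular protein system.
Exchange-time censoring grows near the macrophase boundary (deeply buried
particles rarely free themselves within the horizon), which is why the
censoring fraction is part of every exchange-time result.
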