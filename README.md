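# condensateKMC

Kinetic Monte Carlo simulation of liquid–liquid phase separation by
multivalent sticker-spacer proteins, for researchers studying biomolecular
condensates who need *kinetic* — not equilibrium — predictions at
biologically relevant time-scales (minutes to hours).

Each polymer chain is coarse-grained to one particle on a 2D periodic
lattice.  Particles diffuse (rate k_diff), attract neighbours
non-specifically (ε_ns per contact, in kT), and form valency-limited
specific bonds with adjacent particles (rate k_bond, strength ε_sp, at most
λ bonds per particle, several bonds per neighbour pair allowed).  Bonds
break at k_break = k_bond·exp(−ε_sp), a particle escapes its cage at
k_diff·exp(−E) where E is its total interaction energy, and whole clusters
diffuse at k_diff/S_clus — which is what lets droplets coalesce.  The
system is simulated *exactly* with the Gillespie stochastic simulation
algorithm (waiting times δt = −ln(z)/r_total), so hours of simulated time
are routine.

On top of the engine the package provides:

* Hoshen–Kopelman (union-find) cluster labelling, largest-cluster fraction
  L_clus, pooled cluster-size distributions, and the normalized
  intra-cluster density φ_clus/φ via the 2D gyration disk;
* monomer-exchange first-passage times (buried at 4 neighbours → free at
  0), with explicit censoring accounting — the model's analogue of FRAP
  exchange measurements;
* kinetic phase-diagram sweeps with NoPS / microphase / macrophase
  classification, critical-interaction-strength extraction, and
  diffusion-rate scans;
* tested evaluators of the underlying bead-spring force field (harmonic
  stretching, cosine bending, truncated Lennard-Jones) and the stochastic
  specific-bond formation/breakage rules.

## Worked example

```r
library(condensateKMC)

p  <- SimParams(latticeSize = 50, phi = 0.04, valency = 5, epsSp = 2,
                tEnd = 3600, snapshotInterval = 1200, seed = 7)
tr <- runTrajectory(p)
trajectorySummary(tr)
#>   time largestCluster nClusters nBonds
#> 1    0              2        88      0
#> 2 1200             25        17    189
#> 3 2400             43        23    168
#> 4 3600             45        18    187

st  <- finalState(tr)
lab <- labelClusters(st)
largestClusterFraction(lab)     # 0.45
clusterDensity(st, lab, 1)      # 38.74  (phi_clus / phi of the largest cluster)

m <- meanExchangeTime(recordExchangeEvents(tr))
c(m$mean, m$nCompleted, m$censoringFraction)
#> 619 s over 176 completed events, censoring fraction 0.235
```

Starting from 100 randomly placed particles (88 clusters at t = 0), an
hour of simulated time at ε_sp = 2 kT produces a metastable multi-droplet
state: the largest droplet holds 45% of all particles, is ~39× denser than
the bulk, and monomers still exchange with the dilute phase on a ~10-minute
scale (with 24% of burials unresolved at the horizon and reported as
censored, not averaged in).  Raising ε_sp to 2.5 kT slows that exchange
more than four-fold; lowering it below 2 kT dissolves the droplets — both
statements are recomputed by the test-suite.

A sweep classifies whole parameter grids:

```r
sw <- phaseSweep(data.frame(epsSp = seq(0.5, 4, 0.5)),
                 template = p, replicates = 10, baseSeed = 1)
criticalEpsilon(sw$epsSp, sw$meanLclus)   # smallest eps_sp with mean L_clus >= 0.5
```

A thin CLI over the same functions lives at
`inst/scripts/condensate-kmc.R` (subcommands `simulate`, `sweep`, `mfpt`,
`cluster-stats`, `energy`, `fixtures`).  The methods vignette
(`vignettes/kinetic-model.Rmd`) documents the model, its assumptions and
every numerical design choice.

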