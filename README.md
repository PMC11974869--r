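# nkrsig

Spatial stochastic modeling of how submicron clusters of activating and
inhibitory Natural Killer cell receptors shape early-time ligand
discrimination.

NK cells decide within tens of seconds whether a target cell is diseased,
by integrating activating signals (NKG2D engaging stress ligands, "NKG2DL")
against inhibitory ones (KIR2DL1 engaging HLA-C). In resting cells both
receptor types sit in submicron membrane clusters. This package simulates
membrane-proximal signaling on a lattice of 91 × 91 chambers of 40 nm
(kinetic Monte Carlo / spatial Gillespie: same-chamber reactions, nearest-
neighbour diffusion hops at rate D/l₀²) and quantifies dose discrimination
with information theory. The pipeline covers:

- the reaction network (DAP10 phosphorylation by SFK, Vav1 recruitment and
  phosphorylation; ITIM phosphorylation, SHP-1 recruitment, same-chamber
  dephosphorylation of pVav1; optional kinetic-proofreading resets), built
  from a packaged parameter file with explicit unit/volume classes;
- synthetic binary cluster maps emulating binarized superresolution images,
  and the three resting-state geometries: disjoint, fully overlapping, and
  homogeneous receptor placement;
- an exact C++ simulation engine producing replicate ensembles of total
  phospho-Vav1 (the activation readout, free + complex-bound);
- a deterministic 14-state reference model of the activating module and
  lattice random-walk estimates of diffusion time scales
  (πn / ln 5.692n distinct sites in n steps);
- two-point correlation analysis of binary cluster maps with a
  cluster-randomization null;
- response-distribution analysis: Gamma fits, closed-form Kullback–Leibler
  divergences, plug-in mutual information
  MI(o;s) = Σₛ Σₒ P(o,s) log₂ [P(o,s) / R(o)Q(s)],
  and channel capacity CC = max_Q MI via Blahut–Arimoto.

## Worked example

```r
library(nkrsig)
net <- build_network()                       # full network, KP on

# deterministic activating module: one bound complex
sol <- solve_activating_ode(net, n_complexes = 1)
# per-complex steady-state pVav1: 0.369 (reached by 4.6 s); 53 complexes -> 19.6

# diffusion time scales for ligand-receptor encounter
visit_time(200)        # 13.5 s: full Voronoi cell at 200 ligands/box
visit_time(40, 0.5)    # 39.6 s: half cell at 40 ligands/box

# chance colocalization when receptors are homogeneous: ~75.8%
colocalization_fraction(make_config("homogeneous",
  cell_counts(network = net), network = net, seed = 1))

# dose discrimination at t = 20 s, low HLA-C (30 replicates/dose)
ens <- run_ensemble(net, "disjoint", c(20, 100, 400), hlac = "low",
                    n_reps = 30, t_end = 20, seed = 101)
summary(ens)  # mean pVav1 at 20 s: 1.3 / 7.6 / 14.9 for doses 20/100/400
```

Building the dose→pVav1 channel from those ensembles and maximizing over
input distributions gives, at t = 20 s:

| geometry    | mean pVav1 (dose 20/100/400) | MI (bits) | CC (bits) |
|-------------|------------------------------|-----------|-----------|
| disjoint    | 1.3 / 7.6 / 14.9             | 1.28      | 1.29      |
| overlapping | 0.6 / 2.1 / 5.7              | 0.78      | 0.91      |

Disjoint clusters transmit more than one bit — the cell can separate low
from high NKG2DL doses — while fully overlapping clusters stay below one
bit in both MI and capacity: receptor-cluster geometry alone decides
whether early-time discrimination is possible. The capacity-achieving
input distribution is bimodal, concentrated on the lowest and highest
doses.

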