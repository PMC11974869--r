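---
title: "Spatial receptor-cluster geometry and early-time dose discrimination in NK cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial receptor-cluster geometry and early-time dose discrimination in NK cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the model

Natural Killer cells integrate opposing signals from activating receptors
(here NKG2D, binding stress ligands such as ULBP1--6 and MIC-A/B,
collectively "NKG2DL") and inhibitory receptors (here KIR2DL1, binding MHC
class I HLA-C). In the resting state both receptor types sit in submicron
clusters in the plasma membrane. `nkrsig` implements a spatially resolved
stochastic model of the first minute of signaling at the NK-target cell
interface to ask how the *relative geometry* of those clusters — disjoint,
fully overlapping, or no clusters at all — changes the cell's ability to
tell a low activating-ligand dose from a high one.

The interface is a quasi-two-dimensional box of 91 x 91 chambers, each
40 nm x 40 nm (8281 chambers, 13.2496 um^2). Within a chamber molecules
are well mixed and react; between chambers they hop to one of the four
nearest neighbours. The total per-molecule hop rate is D/l0^2, so the mean
hop time for NKG2DL (D = 0.01 um^2/s) is l0^2/D ~ 1/6 s; with this
convention the ensemble mean-square displacement is D t. Receptors confined
to a cluster never hop across the cluster boundary; unbound ligands and the
cytosolic/membrane pools (SFK, Vav1, SHP-1) diffuse freely. Boundaries are
periodic in x and y.

The signaling cascade is the canonical membrane-proximal one:

* NKG2D + NKG2DL bind (k_on = 2.387e-2 uM^-1 s^-1 across a 2 nm contact
  gap; k_off = 0.023 s^-1); Src-family kinase (SFK) docks on the complex
  and phosphorylates the two DAP10 tyrosines in sequence; fully
  phosphorylated DAP10 recruits Vav1, which SFK then phosphorylates.
  Total pVav1 (free + complex-bound) is the activation readout.
* KIR2DL1 + HLA-C bind (complex lifetime ~0.7 s); SFK phosphorylates the
  ITIMs; phospho-ITIM recruits SHP-1; the *ligand-engaged* ITIM--SHP-1
  complex dephosphorylates any pVav1 in its own 40 nm chamber (free or
  complex-bound). Receptor--ligand binding is resolved at chamber scale, so
  "within 40 nm" is operationalized as same-chamber.
* Kinetic proofreading (KP): phosphorylated complexes additionally carry an
  irreversible unbinding channel that resets the receptor and releases all
  bound partners in unmodified form. Ordinary unbinding, which preserves
  phosphorylation states, is always present; removing a KP flag deletes
  only the flagged reactions.

Simulation is by an exact spatial Gillespie algorithm (direct method with a
binary sum tree over chambers and incremental propensity updates, in C++).
Blocked hops of confined species are executed as null events, which leaves
the sampled process statistically exact.

## Parameters: what is anchored and what is calibrated

The packaged parameter file (`nk_parameter_file()`) records a provenance
tag on every rate and copy number. Anchored values: the lattice and box
geometry; the NKG2D--NKG2DL binding constants; the ~0.7 s inhibitory
complex lifetime; NKG2DL diffusion (0.01 um^2/s, hop time ~1/6 s); the
copy numbers 53 NKG2D, 11686 KIR2DL1, HLA-C 4213 (low) / 11686 (high), and
NKG2DL doses 20--400 per box; the volume factors used to convert
bimolecular rate constants into per-chamber propensities
(l0 x l0 x 2 nm for receptor--ligand, l0^3 for membrane--membrane,
l0 x l0 x 1 um for cytosol--receptor).

Everything else is a calibration constant chosen once against the model's
own reported deterministic behaviour and then frozen: with the default
file, one initially bound complex in the 14-variable deterministic
activating module reaches a steady state of 0.369 pVav1 per complex
(slightly below 0.4) within 4.6 s, so 53 receptors bound at saturation
give ~19.6 pVav1 — the late-time plateau of about 20. The near-synapse
SFK pool is large (20000) with correspondingly weak per-pair docking, so
that inhibitory ITIM cycling cannot titrate the kinase away from the
activating module (the disjoint response must be insensitive to HLA-C
level). SHP-1 (12000) is abundant enough that essentially every engaged
phospho-ITIM is loaded, making total inhibitory capacity track the HLA-C
level; its catalytic propensity is fast enough that a co-chambered pVav1
is removed essentially at contact. One further kinetic choice matters:
SFK does not re-dock onto an already fully phosphorylated ITIM, otherwise
kinase dwell blocks the SHP-1 site and inhibition collapses.

Two printed values are knowingly in tension and were not tuned away: the
"~30 s" activating-complex lifetime versus 1/k_off = 43 s (with the KP
channel the phosphorylated-complex lifetime here is ~22 s), and the image
binarization rule ">= 100 (or < 1000)", implemented as >= 100 with the
threshold configurable.

## Geometry modes and the synthetic maps

The synthetic-map generator emulates binarized superresolution images:
connected cluster templates grown by random lattice accretion, sizes
geometric with mean 8 chambers, placed uniformly at random with same-type
overlap forbidden (large clusters first, otherwise the geometric size tail
makes rejection packing stall). Defaults of 120 NKG2D and 350 KIR2DL1
clusters per box are calibration constants: with 53 NKG2D receptors placed
uniformly over cluster chambers they leave roughly 60% of NKG2D clusters
empty (the study reports 56.4%; the exact value depends on the source
images' cluster statistics, which are not published as numbers) and
essentially no empty KIR2DL1 clusters. Empty clusters are removed.

* **disjoint**: NKG2D clusters first, then KIR2DL1 clusters anywhere that
  does not overlap them.
* **overlapping**: every NKG2D cluster is covered by a KIR2DL1 cluster of
  identical footprint, so centres of mass coincide exactly and the overlap
  is genuinely full; remaining KIR2DL1 clusters avoid NKG2D clusters. We
  deliberately reuse the NKG2D footprint rather than translating an
  independently drawn KIR2DL1 shape: with translated shapes only ~60% of
  NKG2D chambers end up covered, which reproduces neither "fully
  overlapping" nor the reported loss of discrimination.
* **homogeneous**: no clusters; receptors are placed anywhere. With 53
  NKG2D and 11686 KIR2DL1 placed independently, the fraction of NKG2D
  sharing a chamber with at least one KIR2DL1 is 1 - exp(-11686/8281) ~
  0.756, the "about 75% colocalized by chance" benchmark.

## What the analysis layers compute

`two_point_correlation()` gives the variance-scaled two-point correlation
C(r)/sigma^2 of a binary map at exact lattice distances (value 1 at r = 0
by construction), and `randomize_clusters()` rebuilds a map from the same
cluster shapes at uniform random positions — the null used to show that
observed cluster maps are statistically uniform. Image-derived maps omit
pairs that leave the frame; synthetic maps use periodic pairs.

`run_ensemble()` simulates replicate trajectories, each from a freshly
drawn initial configuration, and records total pVav1 every second. The
replicate distribution at a fixed time is read as a clonal NK-cell
population. `build_channel()` turns per-dose response samples into a
discrete channel (histogram bins of 1 molecule by default),
`mutual_information()` evaluates the plug-in MI in bits at a uniform input
distribution over doses, and `blahut_arimoto()` maximizes MI over input
distributions with the standard alternating iteration and capacity-gap
stopping rule. `fit_gamma()`/`kl_gamma()` give the Gamma description of the
response distributions and their closed-form KL divergence; counts
containing zeros are shifted by +0.5 before fitting because the Gamma
support excludes zero, and the KL base (bits by default) is a convention
recorded alongside.

The deterministic reference (`solve_activating_ode()`) integrates the 14
coupled rate equations of the activating module (free ligand, receptor,
SFK, Vav1, pVav1 and nine complex states) in the well-mixed limit,
excluding unbinding: it describes the local biochemistry after complex
formation, which is what gives a true steady state. The diffusion time
scales that set the remaining kinetics come from the distinct-sites
formula pi n / ln(5.692 n) for an n-step lattice walk ("Log" is the
natural logarithm — only that choice reproduces both printed time scales):
`visit_time()` inverts it to get ~13.5 s to cover an average Voronoi cell
at 200 ligands per box (the printed "visited by 15 s") and ~40 s for half
a cell at 40 ligands.

## Problem sizes, reproducibility, and what the tests show

The package's own test profile ("fast": doses {20, 100, 400}, 30
replicates per dose, t = 20 s) is sized to resolve whether MI and capacity
sit above or below 1 bit; that comparison is robust at these replicate
counts. With it we reproduce the headline result: MI ~ 1.4--1.5 bits for
disjoint clusters at both HLA-C levels, MI ~ 0.6--0.8 and capacity < 1 bit
for fully overlapping clusters, homogeneous in between (MI just below 1,
capacity just above), and a capacity-achieving input distribution that is
bimodal with peaks at the lowest and highest doses. Distribution-level
statistics are a different matter: the Gamma-fit KL divergence between the
dose-400 and dose-20 responses is dominated by the fitted parameters of
the near-zero dose-20 distribution, and at 30 replicates only the dominant
ordering — disjoint far above the other two geometries — is stable
(bootstrap probability ~0.99, against ~0.55 for the homogeneous-versus-
overlapping ordering). Resolving the latter, and the KL magnitudes
themselves, needs the "full" profile (5 doses, >= 200 replicates), which
is an hours-scale computation. Replicate seeds are derived from a single
master seed and recorded in every ensemble, so any table reruns
bit-for-bit.

What passing tests do *not* show about real cells: the synthetic maps
reproduce only the mean cluster size, uniform placement and same-type
exclusion of the imaged maps, not their shape or size distributions;
cytoskeletal transport, membrane deformation and everything beyond one
minute are outside the model; and all rates tagged "calibration" are
constrained only through the printed aggregate behaviours, so agreement at
the MI level should be read as a property of the reconstructed model
class, not a parameter-level validation.

## Known limitations

* The KL point values (11.1 / 4.7 / 2.2 in the source analysis) are not
  reproduced quantitatively; they depend on unpublished replicate counts
  and on the calibration rates. The ordering across geometries is.
* The plug-in MI estimator is biased upward at small replicate counts; no
  correction is applied (none is used in the source analysis). Bootstrap
  standard errors are available via `mi_bootstrap()`.
* Packing very dense cluster configurations can fail; the generator
  reports the fill fraction when it gives up rather than silently
  degrading uniformity.
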