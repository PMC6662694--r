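---
title: "Methods: models, parameters and validation in ampdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and validation in ampdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampdyn)
```

ampdyn quantifies the membrane interactions of α-helical antimicrobial
peptides from two kinds of raw data — peptide+bilayer simulation
trajectories and single-channel current recordings — and ships a
synthetic-data generator with exact ground truth so that every analysis
is validated by parameter recovery rather than by eye. This vignette
explains each model, the parameters that matter, the numerical choices,
and what the validation does and does not establish.

## Sequence physico-chemistry

Net charge at neutral pH is the side-chain sum (K, R → +1; D, E → −1;
H → 0) plus the termini: +1 for a free N-terminal amine, −1 for a free
C-terminal carboxylate, 0 when amidated. Amidation matters: both study
peptides are C-terminally amidated, which is why aurein 2.5
(GLFDIVKKVV GAFGSL, 2 Lys + 1 Asp) comes out at +2 rather than +1.
Histidine is counted neutral; a pKa-based titration model is
deliberately out of scope.

Hydrophobicity uses the Fauchère–Pliška octanol/water side-chain scale
(`fauchere_pliska`), the scale behind the HeliQuest server. The helical
hydrophobic moment places residue $i$ (0-based) at angle $i\delta$ with
$\delta = 100^\circ$ (3.6 residues/turn) and takes the length of the
hydrophobicity-weighted vector sum divided by $N$. The phase origin is
irrelevant to the magnitude (asserted in the tests); $\delta$ is
exposed for non-canonical helices. Values are reported to 3 decimals.

## Trajectory model

A `trajectory_set` is a topology table (atom name, residue index,
residue name, chain id; peptide chains are recognized by standard
amino-acid residue names) plus a list of frames of Cartesian coordinates.
Internal units are Angstrom and picoseconds; GRO input (nm) is converted
on read. The membrane normal is fixed to z, as in standard bilayer
setups. Periodicity is handled with the minimum-image convention in x and
y only; z is treated as non-periodic so that insertion depths keep their
sign (peptides are released well above the bilayer and never interact
through the z boundary). Leaflets are assigned per frame: the midplane is
the mean z of all phosphate atoms, upper = above. If all phosphates fall
on one side the code warns and continues in single-leaflet mode.

Readers accept multi-model PDB (via bio3d), concatenated GRO frames, and
a documented delimited format (a `FRAME time lx ly lz` header per block,
then one `x y z` row per atom). Coordinates survive a write/read round
trip to 3 decimals — the precision of the PDB fixed-point format.
Analyses accept an optional frame range; the default is all frames,
since whether an equilibration window should be excluded is a judgement
the caller must make.

## Circular statistics of backbone dihedrals

φ(i) is the torsion C(i−1)–N(i)–CA(i)–C(i) and ψ(i) is
N(i)–CA(i)–C(i)–N(i+1), IUPAC sign convention, degrees in (−180, 180].
φ of the first residue and ψ of the last are *absent*, not zero, and
residues with missing backbone atoms are dropped with a warning.

Angles are circular quantities, so per-residue summaries use the
circular mean $\bar\psi = \mathrm{atan2}(\overline{\sin\psi},
\overline{\cos\psi})$ and circular variance
$\mathrm{Var}(\psi) = 1 - R/n$ with
$R^2 = (\sum\cos\psi_i)^2 + (\sum\sin\psi_i)^2$, so Var ∈ [0, 1] with 0
meaning perfect order. A numerically zero resultant (R/n < 1e−12) leaves
the mean undefined: NA plus a warning, never a silent 0. Flexibility
profiles pool the per-frame samples of all peptide copies by
concatenation — not by averaging per-copy means — so copies with more
defined frames weigh proportionally; per-copy profiles are available
separately.

## Insertion depth

Depth of residue $r$ in a frame is $z_{\text{plane}}^{\text{upper}} -
z_r$, with $z_r$ the Cα z (or the residue centre of mass via
`reference_atom = "COM"`; Cα is the default because it is unambiguous
and side chains are out of scope). Positive depth = below the phosphate
plane = inserted. Peptides acting on the lower leaflet can be analysed
with `leaflet = "lower"`, which reflects z so the sign convention is
preserved. A surface-parallel rigid helix produces a depth oscillation
with the helical repeat; `dominant_depth_period()` finds it by
least-squares sinusoid regression over a continuous period grid rather
than a discrete Fourier transform, because at 13–16 residues the DFT
bins (16/4 = 4.0, 16/5 = 3.2) straddle the 3.6-residue repeat.

## Aggregation

Residue-resolved inter-peptide Cα–Cα distance matrices mask intra-copy
blocks with NA. Two copies are in contact when at least `min_contacts`
(default 1) inter-copy Cα pairs fall within `contact_cutoff` (default
7 Å — a Cα–Cα distance compatible with side-chain packing; no threshold
is canonical, so both parameters are echoed into every output).
Oligomers are connected components of the contact graph (igraph; the
test suite checks 100 random configurations against a hand-written
depth-first-search oracle). Raw per-frame size histograms are reported
alongside "stable" counts in which an aggregate must persist as the
identical copy set for ≥ `persistence` consecutive frames (default 10),
excluding transient brushes. Mediating residues are the residue pairs of
a contacting copy pair ranked by ascending time-averaged distance.

## Channel-trace analysis

The all-points histogram bins every sample (default bin width 0.05 pA,
roughly σ/3 at study-like noise). Level detection identifies modes of a
kernel density estimate (bandwidth = bin width); the most populated mode
is the baseline (mode, not mean — robust to rare openings), and each
level amplitude is refined as the mean of the samples nearest that mode.
Modes whose width exceeds 1.25× the baseline noise are flagged `broad` —
the signature of two unresolved levels merged into one. The alternative
`method = "gmm"` fits unequal-variance Gaussian mixtures per component
count with BIC selection; EM is initialized from evenly spaced k-means
centres because hierarchical initialization can swallow rarely occupied
levels.

Idealization assigns samples to levels by half-amplitude thresholds and
absorbs runs shorter than 2 samples into the preceding event. Latency —
time to first opening — additionally smooths with a 3-sample moving
average and requires the first event to last ≥ 5 samples (0.1 ms at
50 kHz): an isolated noise excursion cannot fire a false first event,
and a single sub-threshold dip inside a genuine opening cannot delay it.
The onset is then refined on the raw trace, giving sub-sample agreement
with the generator's ground-truth first resolvable opening.

Conductance is G = I/V (pA/mV, reported in pS). Pore radius uses the
cylindrical-pore model $G = \kappa\pi r^2/l$ by default, with
electrolyte conductivity κ = 3.5 S/m (250 mM KCl + 50 mM MgCl₂ at room
temperature) and pore length l = 4 nm (a bilayer span). These are
physical estimates, not fitted constants, and both are mandatory
metadata in every report; the access-resistance variant
$1/G = l/(\kappa\pi r^2) + 1/(2\kappa r)$ (solved in closed form via the
quadratic in $1/r$) always yields a wider pore at equal G. Radius
conclusions should be read as calibrated comparisons between levels
measured under the same bath, not absolute geometry.

## The synthetic generator

`generate_helix_trajectory()` rebuilds backbone atoms (N, CA, C, plus
Cβ pseudo-side-chains) every frame from per-residue (φ, ψ) sampled from
von Mises distributions (Best–Fisher sampler), using fixed ideal bond
lengths and angles — only dihedrals vary. Copies are rigid-body placed
parallel to the bilayer on a lateral grid and each copy consumes an
independent seeded random stream, so adding copies never perturbs
existing ones. The bilayer is a lattice of pseudo-phosphates jittered
about two planes (defaults: z = ±19 Å, σ = 1 Å, 100 per leaflet).
Defaults mirror the study conditions: 8 copies released 30 Å above the
upper plane at least 20 Å apart, frames every 2 ps. The default lateral
spacing (36 Å) additionally exceeds the helix length plus the contact
cutoff so that unscheduled copies cannot brush into spurious contacts —
the programmed cluster ground truth is then exact.

Insertion schedules pin scheduled residues' Cα depths to a linear ramp
exactly, frame by frame; aggregation schedules clamp group members'
contact residues together with crossed helix orientations and the
contact Cα rolled to face its partner, making the programmed pair the
closest approach. Both schedules are recorded as ground truth. The
generator reproduces the *statistical structure* the analyses assume —
von Mises dihedral fluctuation, planar jittered leaflets, programmed
contacts — not force-field physics: no lipid tails, electrostatics,
water, or realistic kinetics. Passing recovery tests therefore
establishes that the analysis code measures what it claims to measure,
not that the analyses would be robust to every artefact of real
simulations.

`generate_channel_trace()` samples a continuous-time Markov chain
(closed + K open states) exactly via exponential holding times,
discretizes the state staircase at the sampling rate (default 50 kHz)
and adds Gaussian noise (default σ = 0.15 pA against open levels of
0.8/2.5/5.4 pA — separations well above 4σ). Ground truth includes the
full state path and the chain's stationary distribution.

## Validation scale and determinism

The acceptance suite runs at study-like desk scale, chosen so the
complete validation finishes in minutes on one core while keeping
Monte-Carlo error far below the tolerances: flexibility recovery uses 8
copies × 5000 frames (40 000 samples per residue; the recovered circular
variance sits within ±0.003 of the von Mises closed form
$1 - I_1(\kappa)/I_0(\kappa)$, against a ±0.05 tolerance), depth
recovery 8 × 500 frames, oligomer checks 100 random configurations plus
a 200-frame programmed tetramer, and channel recovery 20 independent
20-second traces. Every stochastic step is seed-driven; identical seeds
give bit-identical trajectories, traces and pipeline outputs.

## Known limitations

* The generator's helices are geometrically ideal; analyses that depend
  on bond-geometry fluctuation (none in scope) would need a richer model.
* Insertion schedules translate whole residues in z, so a steep schedule
  distorts inter-residue geometry; depth analyses are unaffected, but
  dihedral analyses should not be run on steeply scheduled specs.
* Level detection assumes approximately Gaussian, symmetric noise; heavy
  filtering artefacts or open-channel noise excess would bias amplitude
  refinement.
* The cylinder pore model ignores access resistance by default and its
  κ and l are bath-dependent estimates; radii are comparative, not
  absolute.
* Binary trajectory formats (XTC/TRR) are not parsed; convert to PDB,
  GRO or the delimited format first.
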