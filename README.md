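# ampdyn

Quantitative analysis of how short, cationic, α-helical antimicrobial
peptides (AMPs) engage lipid bilayers — for structural bioinformaticians
and membrane biophysicists who have peptide–bilayer simulation
trajectories and/or single-channel patch-clamp recordings and want the
standard comparative read-outs for peptides such as temporin L and
aurein 2.5.

The package covers five analysis stages plus a ground-truth simulator:

1. **Sequence physico-chemistry.** Net charge at neutral pH with
   termini chemistry (K,R → +1; D,E → −1; H → 0; +1 for a free N-terminal
   amine, −1 for a free C-terminal acid, 0 when amidated), mean
   hydrophobicity ⟨H⟩ = (1/N) Σᵢ Hᵢ on the Fauchère–Pliška scale, and the
   helical hydrophobic moment

   μH = (1/N) · | Σᵢ Hᵢ ( cos iδ, sin iδ ) | ,  δ = 100°/residue,

   the magnitude of the hydrophobicity vector sum around an ideal
   α-helical wheel (the HeliQuest convention).

2. **Conformational flexibility.** Backbone φ/ψ dihedrals per residue and
   frame, summarized by the circular mean
   ψ̄ = atan2( (1/n) Σ sin ψⱼ , (1/n) Σ cos ψⱼ ) and circular variance
   Var(ψ) = 1 − R/n with R² = (Σ cos ψᵢ)² + (Σ sin ψᵢ)², pooled across
   peptide copies. Var ∈ [0,1]: 0 = rigid, 1 = fully disordered.

3. **Membrane insertion depth.** Signed per-residue depth relative to the
   upper-leaflet phosphate plane (mean phosphate z), positive = below the
   plane (inserted), averaged over copies and frames.

4. **Self-association.** Inter-peptide Cα–Cα distance heatmaps
   (minimum-image in the bilayer plane), contact-graph connected
   components per frame (monomer/dimer/trimer/tetramer/≥5 populations
   with a persistence filter), and the residue pairs mediating each
   contact.

5. **Channel electrophysiology.** All-points histograms, conductance-level
   detection (kernel-density peak picking or Gaussian mixtures with BIC),
   half-amplitude idealization into dwell events, conductance
   G = I/V (pA/mV → pS), latency to first opening, and pore radius from
   the cylindrical-pore (Hille-type) model G = κπr²/l, optionally with
   access resistance 1/G = l/(κπr²) + 1/(2κr).

The synthetic-data module (`trajectory_spec()` / `trace_spec()`)
generates multi-copy helical trajectories above a jittered two-leaflet
phosphate lattice — dihedrals drawn from von Mises distributions,
programmed insertion and aggregation schedules — and multi-level Markov
channel currents at 50 kHz with Gaussian noise, all with exact ground
truth, so every stage is validated by parameter recovery.

## Worked example

```r
library(ampdyn)

aurein   <- peptide_sequence("GLFDIVKKVVGAFGSL", "aurein2.5",
                             c_term_amidated = TRUE)
temporin <- peptide_sequence("FVQWFSKFLGRIL", "temporinL",
                             c_term_amidated = TRUE)
rbind(physchem_profile(aurein), physchem_profile(temporin))
#>          id length charge     H   muH
#> 1 aurein2.5     16      2 0.622 0.609
#> 2 temporinL     13      3 0.906 0.710
```

Both peptides are short, carry a modest positive charge and are strongly
amphipathic (μH ≈ 0.6–0.7 at δ = 100°), the classic signature of
membrane-active helical AMPs; temporin L is the more hydrophobic.

A synthetic three-level channel trace, analysed back:

```r
g  <- generate_channel_trace(trace_spec(amplitudes = c(0.8, 2.5, 5.4),
                                        duration = 5, seed = 1))
channel_summary(g$trace)        # kappa = 3.5 S/m, pore length 4 nm
#>   level_index mean_amplitude amplitude_sd occupancy broad conductance pore_radius_nm
#> 1           1          0.789        0.160     0.072 FALSE        15.8          0.076
#> 2           2          2.501        0.150     0.151 FALSE        50.0          0.135
#> 3           3          5.404        0.149     0.068 FALSE       108.1          0.198
```

Each detected level's amplitude (pA above baseline) is converted to a
conductance at the +50 mV holding potential and then to a cylindrical
pore radius; at 50 pS ≈ 0.13 nm the pore is about the size of a chloride
ion, while conductances around 500 pS imply radii > 0.4 nm.

An end-to-end synthetic demo (all stages, one output directory):

```sh
Rscript inst/scripts/ampdyn-cli.R demo --seed 1 --out-dir demo_out
```

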