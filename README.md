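# pmhcdyn

Conformational dynamics and biophysics of peptide–MHC complexes in R.

Class I MHC proteins present short peptides in a groove framed by the
alpha1 and alpha2 helices. T-cell receptors can discriminate between
peptides whose crystallographic bound conformations are nearly identical
— within the ~0.7 Å all-atom RMSD reproducibility of replicate pMHC
structures — when the peptides differ in their *dynamics*: which states
a bulky central side chain samples in the groove, whether a position-2
anchor is rigid or mobile, and whether the central side chain can transit
*underneath* the peptide backbone ("limbo" pathway) between the two helix
faces. `pmhcdyn` is a toolkit for that style of study, aimed at
structural immunologists and biophysicists who have trajectories,
structures and instrument data and need the analysis stack around them:

* **Trajectory geometry** — weighted Kabsch superposition;
  fit-then-measure RMSD series (e.g. fit groove Cα 1–180, measure the
  peptide); pairwise (2D) RMSD matrices; per-residue mass-weighted RMSF,
  sqrt(Σᵢ mᵢ⟨|xᵢ−⟨xᵢ⟩|²⟩ / Σᵢ mᵢ); φ/ψ/χ1 torsions; contacts (< 4 Å,
  strict) and hydrogen bonds (≤ 3.5 Å donor–acceptor, distance-only);
  side-chain center-of-mass distances; vdW overlap
  max(0, rₐ + r_b − d); Shrake–Rupley SASA (1.4 Å probe); Ramachandran
  strain counts.
* **Ensemble comparison** — the D-score backbone divergence
  D = 2(1 − cos Δφ) + 2(1 − cos Δψ) ∈ [0, 8] between circular-mean
  torsions of two simulations; voxel occupancy grids (0.1 Å) with
  10%-of-time contouring; agglomerative clustering of RMSD matrices with
  Calinski–Harabasz selection of k; cluster-average structures; LOWESS
  smoothing.
* **Volumetrics** — union-of-spheres residue volumes; enclosed-cavity
  detection between the peptide and groove floor by probe-expanded grid
  + flood fill.
* **Biophysics fits** — SPR steady-state 1:1 isotherms
  (R = R_max·C/(K_D + C)) and exponential dissociation;
  k_on = k_off/K_D; electrostatic destabilization
  ΔΔG° = −2.303·R·T·ΔpKa; bi-Gaussian DSF melt derivatives; Lorentzian
  deconvolution of 1D ¹⁹F spectra with area fractions; slow-exchange
  magnetization kinetics (saturation transfer, EXSY).
* **Synthetic data** — seeded generators for every input class (toy
  groove + flip trajectories with planted Markov states, isotherms,
  decays, spectra, melts), so the full pipeline runs with no MD engine
  or instrument.

## Worked example

Simulate a neoantigen-like groove whose position-6 tryptophan hops
between an alpha1-aligned and an under-backbone pose (planted stationary
populations 0.6/0.4), then run the ensemble stack:

```r
library(pmhcdyn)

groove <- build_toy_groove("neoantigen")
traj <- simulate_flip_trajectory(groove,
                                 flip_sim_spec(n_frames = 1000, seed = 42))

mass_weighted_rmsf(traj)
#>   chain res_seq res_name  rmsf
#> 1     P       1      ALA 0.140
#> 2     P       2      LEU 0.138
#> ...
#> 6     P       6      TRP 2.831
#> ...
#> 9     P       9      LYS 0.139
```

Only position 6 fluctuates (2.8 Å — it is switching conformers); the
rigid leucine anchor sits at the 0.14 Å noise floor. Clustering the
side-chain 2D-RMSD matrix recovers the planted two-state structure:

```r
p6 <- atom_selection(res_seq = 6, sidechain = TRUE)
m <- pairwise_rmsd(traj, measure_sel = p6)
cluster_conformations(m, k_range = 2:8)
#> ClusterModel: k = 2 (average linkage), populations: 66.7% 33.3%
```

k = 2 is selected and the labels match the planted state sequence; the
populations are this realization's empirical occupancy (a sticky Markov
chain at n = 1000 wanders a few points around 60/40). The static groove
carries the designed under-peptide cavity:

```r
find_cavities(groove, atom_selection(chain = c("P", "S")),
              atom_selection(chain = "F"))
#> CavityReport: 1 cavity, total 400.0 A^3, largest 400.0 A^3
#>   (probe 1.40, spacing 0.50)
```

Binding-side: fit a noisy steady-state isotherm generated at
K_D = 62 µM, then derive the association rate from a measured
dissociation rate:

```r
iso <- simulate_isotherm(62e-6, 100, 62e-6 * 2^seq(-3, 4),
                         sigma = 0.02, seed = 7)
fit_steady_state(iso)
#> FitResult (1:1 steady-state)
#>   K_D        6.41653e-05 +/- 1.84e-06
#>   R_max      100.244 +/- 0.787

association_rate(0.039, 62e-6, k_off_se = 0.006, K_D_se = 6e-6)$k_on
#> [1] 629.0323   # M^-1 s^-1

electrostatic_destabilization(pka_bound = 4.9, pka_free = 6.1)
#> [1] 1.637498   # kcal/mol
```

A slow k_on of ~6 × 10² M⁻¹s⁻¹ (10–100× below typical TCR association)
is the kinetic signature of a high-energy conformational barrier in the
ligand; 1.6 kcal/mol is the electrostatic penalty for burying a
histidine anchor whose pKa drops from 6.1 to 4.9 in a hydrophobic
pocket.

An end-to-end demo (`demo_limbo(out_dir, seed = 1)`) chains generation,
RMSF, clustering, occupancy and cavity detection and writes delimited
outputs plus a summary report. A thin command-line wrapper over the same
functions lives at `inst/cli/pmhcdyn.R` (`Rscript pmhcdyn.R <stage>
--config run.yaml`).

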