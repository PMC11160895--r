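---
title: "Methods: peptide-MHC conformational dynamics with pmhcdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peptide-MHC conformational dynamics with pmhcdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmhcdyn)
```

# Scope and model

Class I MHC molecules present short peptides in a groove formed by two
alpha helices over a beta-sheet floor. T-cell receptors can discriminate
between peptides whose *static* bound conformations are nearly identical
when the peptides differ in their *dynamics* — which conformations the
peptide samples while bound, and how easily a bulky central side chain
(here a position-6 tryptophan) can move between the two helix faces of
the groove, including "limbo"-style transits underneath the peptide
backbone. `pmhcdyn` implements the quantitative machinery for this kind
of study:

* **Trajectory geometry**: weighted Kabsch superposition, fit-then-measure
  RMSD series and pairwise (2D) RMSD matrices, per-residue mass-weighted
  RMSF, phi/psi/chi1 torsions, distance-cutoff contacts and hydrogen
  bonds, side-chain center-of-mass distances, van der Waals overlap,
  Shrake-Rupley SASA, and Ramachandran torsional-strain counts.
* **Ensemble comparison**: D-score profiles, voxel occupancy grids,
  agglomerative conformational clustering with Calinski-Harabasz model
  selection, per-cluster average structures, LOWESS smoothing.
* **Volumetrics**: union-of-spheres residue volumes and grid/flood-fill
  detection of enclosed cavities between the peptide and the groove floor.
* **Biophysical fits**: SPR steady-state 1:1 isotherms and exponential
  dissociation, k_on = k_off / K_D, electrostatic destabilization from
  pKa shifts, bi-Gaussian DSF melt derivatives, Lorentzian line-shape
  deconvolution of 1D NMR spectra, and slow-exchange magnetization
  kinetics (saturation transfer and EXSY).
* **Synthetic data**: deterministic or seeded generators for every input
  class, with planted ground truth.

Running MD engines, enhanced-sampling drivers, pKa solvers and
crystallographic refinement are out of scope; their *outputs* (frames,
structures, pKa values) are this package's inputs.

# Key definitions and conventions

**Superposition and RMSD.** `superpose()` minimizes the weighted RMSD via
the Kabsch SVD construction with a determinant correction, so the result
is always a proper rotation. The standard protocol fits each frame on the
Calpha atoms of the groove (author numbering, residues 1–180) and then
measures RMSD over the peptide selection *without re-fitting*
(`rmsd_series(traj, target, fit_sel, measure_sel)`). Both that scheme and
an all-common-atom fit are supported, because bound/free comparisons in
the literature report either depending on the fit selection.

**mwRMSF.** For residue *r* with atoms *i*, masses *m_i* and per-atom
mean-square fluctuations about the trajectory mean,
sqrt( sum_i m_i <|x_i − <x_i>|^2> / sum_i m_i ). Frames must be
pre-aligned; the fluctuation of a single frame is undefined and is an
error, not zero.

**D-score.** Per residue, D = 2(1 − cos Δφ) + 2(1 − cos Δψ),
dimensionless on [0, 8]: 0 for identical backbone torsions, 8 when both
differ by 180°. Two simulation ensembles are compared through their
*circular-mean* torsions (resultant-vector mean, so {175°, −175°}
averages to 180°), composed in `dscore_profile()`. The per-frame average
of D would be a different and noisier statistic; the ensemble-mean-angle
convention is the one used with this metric in the antibody-loop and
peptide/MHC literature.

**Contacts and hydrogen bonds.** Contacts are heavy-atom pairs at
distance strictly below 4 Å (a pair at exactly 4.0 Å does not count);
hydrogen bonds are donor–acceptor heavy-atom pairs at ≤ 3.5 Å with *no*
angle term, so crystal structures without hydrogens and MD frames are
scored identically. Donors/acceptors are validated against standard
residue polar-atom templates, falling back to element rules for
non-standard (synthetic) residues.

**SASA.** Shrake–Rupley with a 1.4 Å probe and a deterministic Fibonacci
spiral point set (default 960 points/atom). Determinism was preferred
over random test points so that areas are bit-reproducible across runs;
at 960 points the isolated-atom closed form is reproduced to well under
1%.

**Occupancy grids.** Default spacing 0.1 Å. Each tracked atom increments
the voxel containing its center; the *fractional occupancy* of a voxel is
the fraction of frames in which at least one tracked atom lies in it
(with a single tracked side chain, per-atom and any-atom definitions
nearly coincide; any-atom is used). Thresholding is inclusive at the
default 10% level. Gaussian smoothing is off by default so reported
volumes are quantitative; a sigma of ~2 voxels is appropriate for
visualization-style contouring only.

**Clustering.** Agglomerative clustering (default average linkage —
the common default for precomputed distance matrices; complete, single
and Ward-on-embedding are selectable) on the pairwise RMSD matrix. The
Calinski–Harabasz index needs coordinates, so frames are embedded by
classical MDS keeping components that capture ≥ 95% of the
positive-eigenvalue variance; k maximizing CH over a default scan of
2–15 is chosen (the scan range is a package choice, not prescribed by
any reference). Cluster labels are reported by decreasing population.

**Cavities.** A voxel (default 0.5 Å spacing) is cavity when its center
lies outside all probe-expanded spheres (r + 1.4 Å) yet cannot reach the
box faces by 6-connected flood fill. "Between the peptide and the groove
floor" is operationalized geometrically: along the axis from the floor
centroid to the peptide centroid, the voxel's nearest peptide atom must
lie above it and its nearest floor atom below it. Interactive cavity
tools make this call visually; the geometric rule is the reproducible
proxy, and volumes on real structures are therefore method-sensitive at
the tens-of-Å³ level. Volumes are voxel counts × spacing³, so estimates
converge as spacing shrinks (the constructed-void fixture moves by < 2%
when spacing is halved).

**Ramachandran strain.** Counts, per frame, non-glycine residues with
defined (φ, ψ) outside the "generously allowed" region. The reference is
a rasterized 2°×2° torus mask built *in code* from a smooth synthetic
density over the canonical basins (beta, PPII, alpha-R, bridge,
alpha-L), thresholded to contain 90% ("allowed") and 99% ("generously
allowed") of the density mass. It is a stand-in for survey-derived
contour data, suitable for counting gross torsional strain; absolute
strain counts on real trajectories will differ slightly from any
specific published reference mask.

**Binding and stability fits.** All nonlinear fits use
Levenberg–Marquardt (`minpack.lm`), unweighted (no weighting scheme is
standard for reference-subtracted SPR responses). The steady-state model
is R = R_max·C/(K_D + C) with a shared K_D and per-series R_max for
replicates; a K_D above the highest tested concentration is flagged as
extrapolated. Dissociation fits include a constant baseline offset by
default (reference-subtracted data retain small baselines); it can be
fixed to zero for strict replication of an offset-free model. Biphasic
fits constrain amplitudes positive and the fast fraction to [0, 1], and
report k1 ≥ k2. Reported uncertainties are 1-sigma values from the fit
covariance; these are *not* the same thing as replicate standard
deviations and are labeled accordingly. Electrostatic destabilization is
ΔΔG° = −2.303·R·T·(pKa_bound − pKa_free) with R = 1.987 cal/K/mol and
T = 298.15 K by default, returned in kcal/mol.

**NMR line shapes and exchange.** Spectra are fit as sums of Lorentzians
plus a constant baseline; areas come analytically from height and FWHM
(area = π·h·w/2), and fractions are over the fitted set. The number of
peaks is user-chosen (inspection chooses it in practice); initial centers
come from local-maxima picking above 5× the median absolute deviation
with a minimum separation of a tenth of the spectral window, and can be
overridden. Exchange models store equilibrium populations, shifts and
pairwise rates with detailed balance enforced at construction.
Saturation transfer clamps the irradiated state to zero and integrates
dM_i/dt = −(Σ_j k_ij)M_i + Σ_j k_ji M_j; EXSY cross-peak fractions are
the matrix exponential of the rate generator over the mixing time, so
rows conserve magnetization exactly. Longitudinal/transverse relaxation
is deliberately omitted (a uniform decay hook exists, default off): the
slow-exchange/no-exchange conclusions these experiments support depend
only on the kinetic skeleton.

# The synthetic-data module

`build_toy_groove()` constructs an idealized groove: a sealed rectangular
chamber of continuum carbon walls (0.6 Å atom spacing — an idealization
chosen so that probe-expanded wall surfaces are effectively smooth
planes) whose roof stands in for the floor-facing surface of the peptide
bulge, enclosing an under-peptide void of designed volume **400 Å³**
(clear span 10 × 8 × 5 Å, sized to the cavity scale reported for
neoantigen-class grooves); open wall rows above the roof stand in for the
alpha1 (+y) and alpha2 (−y) helices; and a 9-residue peptide runs along
the groove axis with a full tryptophan side chain at position 6. The two
presets differ at the position-2 anchor: leucine (neoantigen-like, rigid)
versus histidine (WT-like, mobile).

`simulate_flip_trajectory()` draws a Markov state sequence over
side-chain poses ("alpha1-aligned", "under-backbone", "alpha2-flipped";
the alpha1/alpha2 poses are built ~6.9 Å apart in side-chain RMSD, the
scale of a full under-peptide flip) and adds isotropic Gaussian noise
(default σ = 0.08 Å per coordinate, giving a ~0.14 Å per-residue RMSF
floor — quiet enough that a rigid anchor reads below 0.2 Å while a
mobile anchor's two-rotamer process reads several-fold higher). The
default two-state transition matrix has stationary populations
(0.6, 0.4). All generators are pure functions of (parameters, seed), use
a locally scoped RNG, and restore the caller's random stream.

What the fixtures do *not* emulate: solvent, force-field energetics,
correlated backbone motion, realistic transition pathways, or
experimental artifacts (drift, mass transport, phasing). Passing the
planted-recovery tests therefore demonstrates that the *analysis stack*
is correct — labels, populations, volumes and fitted parameters are
recovered when the generating process is known — not that any particular
real system behaves like the fixture.

# Numerical choices and degenerate inputs

* Altloc policy: highest occupancy wins, ties alphabetical; readers keep
  hydrogens but geometry defaults to heavy atoms.
* Torsions: IUPAC sign, degrees in (−180, 180]; undefined torsions
  (termini, glycine chi1, missing atoms) are `NA`, never zero.
* Collinear fit selections are rejected (the rotation is underdetermined).
* An all-zero RMSD matrix returns k = 1 with a warning (CH undefined).
* Rank-deficient fit solutions (e.g. a zero-amplitude melt component)
  fall back from `nlsLM` to raw `nls.lm`; parameter values are unchanged
  and standard errors come from the LM Hessian.
* Lorentzian windows: fits are reliable when the spectrum covers peak
  centers ± a few widths, but *area-vs-integral* comparisons need windows
  tens of linewidths wide (Lorentzian tails hold ~2% of the area even 15
  widths out).
* Monte Carlo volume estimates take an explicit seed; the grid method is
  deterministic and is the default.

# Problem sizes

The test-suite and demo sizes are chosen so the whole stack exercises
comfortably on a single CPU: flip trajectories of 400–2000 frames over a
~60-atom peptide, clustering of up to 2000 frames, occupancy grids at
0.1–0.5 Å over a single side chain, cavity grids at 0.5 Å over a ~20 Å
box, and 200-realization noise sweeps for the fit-bias checks. These are
fixture scales, not limits; the same code paths handle longer
trajectories linearly in frames and atoms (pairwise RMSD and MDS
embedding are the quadratic-cost steps to watch).

# Known limitations

* PDB parsing is delegated to `bio3d`; exotic records (insertion codes,
  multi-character chains, mmCIF) are out of scope.
* H-bond detection is distance-only by design; it will overcount
  relative to angle-aware definitions.
* The cavity "between peptide and floor" rule is a geometric proxy for
  an interactive call; on real structures expect ±20%-level sensitivity
  to probe, spacing and the restriction rule.
* The Ramachandran mask is synthetic (see above); use it for relative
  strain counting, not validation-grade classification.
* Exchange models omit relaxation, so predicted saturation-transfer
  residuals are upper bounds on what a real CEST experiment would show.
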