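---
title: "Methods: shift, coupling and RDC analysis of peptide preorganization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shift, coupling and RDC analysis of peptide preorganization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confsel)
```

# The scientific question

A disordered peptide that folds upon binding can do so by *induced fit*
(the partner molds it) or by *conformational selection* (the bound
conformation already exists transiently in the free ensemble and is
selected). NMR can distinguish these at two levels:

* **Secondary structure**: if the helices seen in the complex are partially
  populated in the free peptide, chemical shifts sit between their
  random-coil and fully-helical values, ³J(HN-Hα) couplings between their
  coil (~6–7.6 Hz) and helical (~4 Hz) values, and sequential NOE intensity
  ratios between their coil (1.4) and helical (0.25) reference values.
* **Tertiary structure**: ¹D(NH) residual dipolar couplings report bond
  orientations relative to a molecule-wide alignment frame, so they are
  sensitive to the *relative* orientation of the two helices. If the
  free-state couplings are explained best by the bound interhelical
  arrangement — and worse by rotated or broadly sampled alternatives — the
  tertiary arrangement is preorganized.

`confsel` implements both levels plus the infrastructure (coordinates,
synthetic data, pipeline stages) to run them end to end.

# Models and estimators

## Secondary shifts and the SSP score

The secondary shift is `Δδ(a, i) = δ_obs(a, i) − δ_rc(type(i), a)` for
atoms CA, CB, HA against a per-residue-type random-coil table. The SSP
score aggregates a window (default 5 residues, truncated at chain ends):
all secondary shifts in the window are oriented so helix is positive (HA
and CB flipped), summed, and divided by the summed fully-formed-helix
magnitudes when the sum points helix-ward, or by the summed strand
magnitudes (negatively) otherwise. Under the two-state model
`δ = δ_rc + p·Δδ_helix_full` the score equals the helix population *p*
exactly, and because normalization happens after aggregation the estimator
is unbiased under per-shift noise. Windowed estimators are edge-biased by
construction: a residue at the boundary of a helical region averages in
flanking coil residues, shrinking its score (a 10-residue region at p =
0.30 has a whole-region mean near 0.26 with a 5-residue window). Population
recovery is therefore asserted over residues whose full window lies inside
the region; whole-region means are reported as-is in the pipeline stage.

Defaults: window 5, uniform weights, atoms CA + CB (HA optional, off by
default); Gly contributes CA only. The shipped random-coil/full-shift table
(`inst/extdata/random_coil_shifts.tsv`, version 1) carries representative
literature-style values for all 20 residue types; neighbor-sequence
corrections are not applied. All synthetic round-trips are self-consistent
against this table.

## CSI

Per-atom indices by thresholded secondary shift — CA beyond ±0.7 ppm, HA
beyond ±0.1 ppm with the inverted sign convention — combined by majority
vote, then run-length rules (≥4 consecutive helix votes → "H", ≥3 strand
votes → "E"). Thresholds are the field's standard ones; the method is used
here for segment topology, not populations.

## Couplings

Back-calculation uses the Karplus form `J(φ) = A·cos²(φ−60°) +
B·cos(φ−60°) + C` with defaults (A, B, C) = (6.51, −1.76, 1.60) Hz.
Populations invert the two-state mixture `p = (J_coil − J_obs)/(J_coil −
J_helix)` with J_helix = 4.0 Hz and per-residue-type coil values from the
shipped table; p is clipped to [0, 1] with clipping flagged rather than
silent.

## CSP

`Δδ_obs = sqrt((Δδ²_HN + Δδ²_N/25)/2)` per backbone amide, the 1/25
nitrogen weight being the conventional gyromagnetic scaling. The mean over
observed residues is the reference line for calling a residue "perturbed".
Only HN/N enter; residues missing either state are excluded and reported.

## RDCs and the Saupe tensor

Couplings are kept in Hz and the dipolar prefactor is absorbed into the
Saupe matrix: `D_i = v_iᵀ S v_i` with `v_i` the unit N→H vector and S
symmetric traceless. The five independent elements are solved by SVD of the
direction-cosine design matrix (no error weighting by default; 1/σ²
optional). Axial magnitude `Da = Szz/2` and rhombicity
`R = 2(Sxx − Syy)/(3·Szz)` are derived from eigenvalues for reporting, with
|Szz| ≥ |Syy| ≥ |Sxx| and the x/y labels chosen so R ∈ [0, 2/3]; the
Cartesian and principal-frame back-calculation formulas agree to machine
precision (tested). Fit quality is `Q = rms(D_exp − D_calc)/rms(D_exp)`
(exactly this denominator — no Da-based variant) plus Pearson r. For an
in-sample least-squares fit with noise σ the expectation is
`E[Q] ≈ σ·sqrt(1 − 5/N)/rms(D)` (five fitted parameters); this corrected
expectation, verified by simulation, is what the tests assert. Tensor
similarity uses the normalized scalar product
`NSP = ⟨S¹|S²⟩ / sqrt(⟨S¹|S¹⟩⟨S²|S²⟩)` over the nine matrix elements: 1 up
to positive scale, −1 antiparallel, 0 orthogonal frames.

Amide H positions matter for the bond vectors: synthetic structures place H
at 1.02 Å from N, anti to the carbonyl oxygen across the peptide bond.

## Helix axes, θ, and rotated controls

A helix axis is the principal component of the segment's centered CA
coordinates, sign-fixed N→C — well conditioned even for a one-turn,
5-residue helix, where cylinder fits are not. The interhelical angle is
`θ = arccos(a₁·a₂) ∈ [0°, 180°]` with N→C orientation retained (no folding
to 90°). Rotated control models turn helix 1 rigidly about axes
perpendicular to the helix-2 axis, through helix 1's centroid, at four
reproducible in-plane directions (0°, 45°, 90°, 135°). The in-plane frame
is anchored on `a₁ × a₂`: only a rotation axis perpendicular to *both*
helix axes transfers the full rotation into θ, so axis 1 changes θ by
exactly the rotation angle while the other three change it by less. This
geometric fact constrains what a "30°-rotated control" can mean; the
package documents the axis set rather than leaving it implicit.

## Conformer sampling (design choice)

Normal-mode-based samplers are external programs whose trajectories are not
reproducible from a seed, so the ensemble generator here is a documented
pivot-move sampler: both helices stay internally rigid; φ/ψ of the linker
and flexible termini receive Gaussian rotations (σ = 30°, truncated at
±60°) about the actual N–CA and CA–C bonds (proline φ held fixed); a
hard-sphere clash check (heavy atoms, radii scaled by 0.7, residues ≥ 2
apart) rejects and redraws. A zero amplitude reproduces the seed structure
bit for bit, and the whole ensemble is deterministic given the seed. The σ
= 30° amplitude was chosen once as the smallest value whose 300-conformer
ensembles already span > 120° in θ — broad coverage of the tertiary
coordinate is the sampler's only contract. Consequently, cluster and
conformer counts are order-of-magnitude properties of *this* sampler, not
reproductions of any external program's counts.

## Clustering and the penalty cut

Average-linkage agglomerative clustering on pairwise backbone RMSD (N, CA,
C; termini trimmed by default) after Kabsch superposition. The cut level
minimizes an NMRCLUST-style penalty: the average intra-cluster spread,
min–max normalized across cut levels onto [1, N−1], plus the number of
clusters. A `fixed_k` override exists for testing. Representatives minimize
the mean RMSD to their cluster mates.

## The preorganization test

Given free-state couplings and the bound structure:
(a) fit peptide and domain couplings independently and compare tensors by
NSP plus a cross-fit Q; (b) fit the free couplings to the bound peptide
structure (an optimally scaled variant is reported too — for a self-fit the
scale is absorbed by the linear least squares, so both coincide; the
distinction only matters for cross-fits under a foreign tensor); (c) fit
the four rotated controls; (d) sample an ensemble, cluster it, discard
every representative whose θ is **strictly inside** (θ_ref − 30°, θ_ref +
30°) — boundary conformers are retained, the band is open — and fit each
survivor. Preorganization is supported when the bound structure's Q
undercuts all surviving conformers, and refuted (hypothesis recovery in the
other direction) when couplings simulated from a rotated geometry make the
rotated θ-bin win.

# The synthetic world

The generator defaults *are* the stated conditions, chosen once: a
32-residue two-helix peptide (residues 783–814; helix 1 = 786–790 at p₁ =
0.10, helix 2 = 799–808 at p₂ = 0.30 free, both 1.0 bound; linker
791–798; bound θ = 134°); free-form ¹D(NH) magnitudes ≤ 8–10 Hz and
bound-form up to 40 Hz; noise 1.0 Hz on couplings, 0.02 ppm on ¹H and
0.1 ppm on ¹³C/¹⁵N shifts, 0.3 Hz on ³J — typical experimental precision.
The default sequence is a **synthetic stand-in**: the deposited peptide's
sequence is not shipped, so every residue identity stated in the source
data (the Ile/Ile helix-1 anchors, the Pro-Pro-Thr linker, the LXXLL
motif, the glycines) is honored and the unreported positions carry
plausible fillers. The two-helix builder solves linker dihedrals by a
deterministic seeded random search plus Nelder-Mead refinement until θ is
within 3° of target; targets across [0°, 180°] are reachable.

What the generator does **not** emulate: side chains beyond CB, peak
overlap and assignment errors, anisotropic/structured noise,
alignment-medium physics (the generator tensor is arbitrary), and real
conformational averaging of couplings (each conformer is scored as a rigid
structure). A green test therefore establishes that the estimators invert
the stated model at experimental noise levels — not that any particular
experimental dataset will reach the same numbers.

# Numerical choices and degenerate inputs

* Saupe fits require ≥ 5 couplings; a singular design (all bond vectors
  parallel) is an error, and condition numbers above 10³ attach a warning.
* `q_factor` refuses an all-zero experimental vector; CSP requires both
  states per residue and reports exclusions.
* SSP windows truncate at chain ends; scores beyond |1.1| are flagged, not
  clipped.
* The angle filter's boundary rule is strict-interior exclusion, so a
  half-window of 0 excludes nothing.
* PDB I/O is fixed-column (3 decimal places); coordinate round-trips are
  exact to 10⁻³ Å by format.
* Test-budget scaling: clustering properties are exercised at ≤ 400
  conformers (pairwise RMSD is O(n²)); the θ-coverage and preorganization
  properties use 300-conformer ensembles with 50 coupling replicates.

# Known limitations

* With two nearly parallel helices and an extended linker, many N–H
  vectors are close to collinear, so tensor fits on peptide-sized coupling
  sets are intrinsically degenerate-ish: symmetry-related helix
  arrangements can fit comparably well. The ensemble test reports the
  winning θ-bin rather than claiming a unique orientation.
* The sampler explores torsion space near the seed; it is a coverage tool
  for θ, not a thermodynamic ensemble.
* The shipped reference tables are representative, not lab-calibrated;
  users analyzing real data should substitute their preferred random-coil
  set via the `rc` argument.
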