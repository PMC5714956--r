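# confsel

Solution-NMR tools for testing **conformational selection** in the binding
of an intrinsically disordered peptide to a folded partner domain. The
motivating system is a two-helix transactivation peptide (a 32-residue
STAT6-like fragment carrying an LXXLL coactivator-binding motif) docking
onto a ~130-residue PAS-B domain, but every routine is generic.

The package is aimed at structural-biology groups who have assigned
chemical shifts, scalar couplings and residual dipolar couplings (RDCs) for
a peptide in its free and bound states and want to ask, quantitatively:

1. **Is secondary structure preformed?** Secondary chemical shifts, a
   windowed secondary-structure-propensity (SSP) score, the chemical shift
   index (CSI), Karplus-based helix populations from ³J(HN-Hα), and
   sequential-NOE intensity-ratio classes.
2. **Where does the partner bind?** Chemical shift perturbation (CSP)
   mapping with the standard amide-weighted average
   `Δδ_obs = sqrt((Δδ²_HN + Δδ²_N/25)/2)`.
3. **Does the bound structure explain the couplings?** Saupe
   alignment-tensor fits by SVD (`D = vᵀ S v`, five independent elements),
   the quality factor `Q = rms(D_exp − D_calc)/rms(D_exp)`, Pearson r, and
   the normalized scalar product (NSP) between tensors — the Frobenius
   cosine that is 1 when two alignments differ only by scale.
4. **Is the tertiary arrangement preformed?** A conformer sampler (rigid
   helices, pivot moves in the linker), average-linkage clustering on
   pairwise backbone RMSD with an NMRCLUST-style penalty, filtering by the
   interhelical angle θ, and per-conformer Q factors against the free-state
   RDCs: if the bound-like θ fits best, the free ensemble is preorganized.

Multi-model PDB reading/writing, a minimal NMR-STAR chemical-shift reader,
TSV I/O for shifts/RDCs, and a synthetic-data generator (so the entire
pipeline is testable offline) are included.

## Worked example

Everything below is generated by the package itself (no downloads). The
default `peptide_spec()` encodes the stated world: helix 1 (residues
786–790) at 10 % population free, helix 2 (799–808, the LXXLL helix) at
30 %, bound-form interhelical angle θ = 134°.

```r
library(confsel)

spec <- peptide_spec()
sim  <- simulate_shifts(spec, seed = 7)           # shifts + 3J couplings
rep  <- stage_free_peptide(sim$shifts, j = sim$j)
rep$region_summary
#>   region start end mean_ssp  n mean_J_population
#> 1 helix1   786 790   0.0701  5            0.0559
#> 2 helix2   799 808   0.2672 10            0.2332
```

The whole-region SSP means (0.07, 0.27) recover the planted 10 %/30 %
helix populations; the slight shrinkage is the expected edge dilution of a
5-residue smoothing window (interior residues recover the populations
exactly — see the vignette).

```r
pep    <- build_two_helix_peptide(spec)            # theta = 134.0 deg
tensor <- saupe_from_elements(3.2, -1.1, 2.4, -0.8, 1.7)
rdc    <- simulate_rdcs(pep, tensor, d_max_target = 8, noise = 1, seed = 11)
fit_tensor_svd(pep, 1, rdc)
#> <rdc_fit> 29 residues fitted, Q = 0.180, r = 0.975, Da = 4.7
```

A Q of 0.18 on 1–10 Hz couplings with 1 Hz noise is the expected
in-sample fit quality (`σ·sqrt(1 − 5/N)/rms(D)`); it says the structure is
consistent with the couplings at the noise level.

```r
preorg <- stage_preorganization(pep, rdc, n_conformers = 300, rng_seed = 5)
preorg$summary
#>                           quantity value theta
#> 1        Q_free_on_bound_structure 0.180 134.0
#> 2 Q_free_on_bound_structure_scaled 0.180 134.0
#> 3            Q_free_on_rotated_SM1 0.229 104.0
#> 4            Q_free_on_rotated_SM2 0.237 110.3
#> 5            Q_free_on_rotated_SM3 0.232 127.0
#> 6            Q_free_on_rotated_SM4 0.242 148.9
#> 7                   Q_ensemble_min 0.283  96.3
```

Reading the table: the bound two-helix arrangement (θ = 134°) fits the
free-state couplings best (Q = 0.18); every 30°-rotated control (SM1–SM4)
and every sampled conformer outside the θ = 134° ± 30° band fits worse.
That asymmetry — and its reversal when the couplings are simulated from a
rotated geometry — is the conformational-selection signature the package
tests for.

## Command line

```sh
Rscript -e 'confsel::confsel_cli()' fixtures --out fx --seed 3
Rscript -e 'confsel::confsel_cli()' free-peptide --shifts fx/shifts_free.tsv --out out1
Rscript -e 'confsel::confsel_cli()' csp --free fx/shifts_free.tsv --bound fx/shifts_bound.tsv --out out2
Rscript -e 'confsel::confsel_cli()' rdc-fit --structure fx/peptide_bound.pdb --rdcs fx/rdc_bound.tsv --out out3
Rscript -e 'confsel::confsel_cli()' preorg --structure fx/peptide_bound.pdb --rdcs fx/rdc_free.tsv --out out4 --n 300
```

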