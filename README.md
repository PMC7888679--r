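# memsearch

Target-search kinetics of membrane-integrated DNA-binding proteins.

Some bacterial signalling proteins are both membrane-integrated sensors and
transcription factors (one-component systems such as *E. coli* CadC, the pH
receptor of the acid-stress Cad system). After activation they must bind a
specific site on the chromosome **from the membrane**: the protein diffuses
laterally in 2D and captures the DNA locus when chromosome fluctuations
bring it close to the inner membrane. `memsearch` is an R package for
analysing this "diffusion and capture" search quantitatively, for
microscopists and modellers working with single-cell response data.

## What is in the package

**Two-step first-passage model.** The search is a reversible sequential
process S1 ⇌ S2 → S3 (target locus approaches the membrane at rate k₁₊,
retreats at rate k₂₋, is bound at rate k₂₊). Starting from S1 the search
time is hypoexponential with timescales α ≥ β:

    p(τ) = (e^(−τ/α) − e^(−τ/β)) / (α − β),
    α + β = (k₁₊ + k₂₊ + k₂₋) / (k₁₊ k₂₊),   αβ = 1 / (k₁₊ k₂₊)

with a mixed-initial-condition extension (parameter c = x·k₂₊ for the
fraction x of cells whose locus already sits near the membrane). The
`dfpt`/`pfpt`/`qfpt`/`rfpt` family implements the law; `fit_response()`
fits its CDF to the normalized fraction of spot-positive cells
R(t) = (ν(t) − ν(0)) / (ν(∞) − ν(0)) by bounded weighted least squares and
propagates full-covariance errors to the mean and variance of the search
time (delta method).

**Closed-form encounter estimates.** `sphere_trap_time()` (trap on a
spherical membrane), `dimer_encounter_time()` (two diffusing monomers),
`volume_trap_time()` (membrane target from a confined volume).

**Kinetic Monte Carlo lattice simulation.** A phantom bead–spring chromosome
(100 beads, Kuhn-length lattice constant a = 0.1 μm) moves in a cubic cell
while a protein hops on the surface sites; Metropolis acceptance for bead
moves, exact null-event sampling of the master equation, bead rate
calibrated so the free chain's centre of mass diffuses at D₀/N. Limiting
modes isolate protein-only, site-to-membrane and DNA-only searches
(`kmc_config()`, `run_search()`, `run_ensemble()`, `sweep_param()`). The
inner loop is C++ (Rcpp).

**Locus mobility.** `link_spots()` → `ensemble_msd()` → `fit_msd()` fit the
Rouse scaling MSD(τ) = Γτ^0.5 of a tracked chromosomal locus, and
`rouse_d0()` converts Γ to the Kuhn-segment diffusivity via
D₀ = 3πΓ²/(16 l_K²).

**Spot detection.** `detect_spots()` thresholds at mean + f·sd inside each
segmented cell outline (8-connected components, size and separation
filters); `response_fraction()` builds response curves;
`half_axis_localization()` maps spot positions onto the half long axis by
cell-length class.

**Synthetic data.** `sim_response_counts()`, `sim_locus_tracks()` (exact
fractional-Gaussian-noise construction, Hurst 0.25) and `sim_cell_image()`
generate every input with known ground truth, so the whole pipeline is
testable without any external data.

## Worked example

```r
library(memsearch)

g <- sim_response_counts(alpha = 4.5, beta = 0.3, c = 0.05,
                         nu0 = 0.2, nu_inf = 0.75,
                         times = 0:14, n_cells = 3000, seed = 3)
fit <- fit_response(g$series, model = "mixed", nu_inf = "fit")
print(fit)
#> Two-step first-passage fit (mixed initial condition)
#>   parameters:
#>     alpha   4.8534 +/- 0.2781
#>     beta    0.0621 +/- 0.1000
#>     c       0.3906 +/- 0.0332
#>     nu_inf   0.7624 +/- 0.0091
#>   mean search time: 4.798 +/- 0.203 min
#>   variance:         23.546 +/- 2.671 min^2
#>   chi-square: 4.557 on 11 df
```

The fitted mean search time — the average time from receptor activation to
stable DNA binding — is 4.80 ± 0.20 min against a generating truth of
4.73 min (α + β − αβc), recovered within one standard error. The
individual timescales trade off along a ridge (β and c are only weakly
identified when β ≪ α), which is why the derived mean with its
delta-method error, not the raw parameters, is the headline quantity.

```r
# coupled simulation at the realistic parameter set, 1.33 um^3 cell
ens <- run_ensemble(kmc_config(n_cell = 11), n_runs = 1000, seed = 1)
print(ens)
#> KMC search ensemble: 1000 runs (0 censored)
#>   mean search time: 291.5 s  (4.858 min), SEM 12.4 s
#>   1 runs started in contact; mean over the rest: 291.8 s
```

The simulated mean search time of ~5 min for a single binding site — and
its halving-or-better with a second, antipodal site — is what makes the
diffusion-and-capture mechanism kinetically plausible for a
membrane-tethered transcription factor.

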