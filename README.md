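# nmrbind

Quantitative analysis of protein–ligand binding by NMR titration, for
structural biologists who map binding sites and measure affinities from
series of assigned ¹H–¹⁵N HSQC peak lists — with companion tools for NMR
ensemble structure metrics and sequence-conservation analysis. The
motivating systems are DNA-binding double Tudor domains, where a folded
core and a disordered positively charged extension (an AT-hook-like RGR
motif) bind DNA by different, separately detectable mechanisms.

## What it computes

**Weighted CSP.** For each residue, the shift change between apo and
bound states is combined as

    CSP = sqrt(δ_HN² + (δ_N / 5)²)

**Affinity.** Under fast exchange, CSP(r) at ligand:protein molar ratio
*r* follows an *n*-equivalent-independent-sites isotherm with dilution of
the protein by the ligand stock,

    CSP = (CSP_max/2) · [ (1 + n·r + n·K_D·(1/C_pro + r/C_lig))
          − n·sqrt( (1/n + r + K_D·(1/C_pro + r/C_lig))² − 4r/n ) ]

fitted by profiled nonlinear least squares with fixed *n* (one global K_D
with per-residue CSP_max, or per-residue fits), with residual-resampling
bootstrap confidence intervals.

**Binding-site maps.** Residues are classed by CSP against mean and
mean + SD thresholds, and disordered-region binding is detected through
bound/apo peak-height ratios (> 3 strong, 1.5–3 moderate); strong-CSP
residues export as docking "active" residue lists.

**Ensemble metrics.** Multi-model PDB ensembles give per-conformer RMSD
to the iteratively converged mean structure over labelled residue
regions (Kabsch superposition), and salt-bridge statistics as minimum
donor–acceptor atom-pair distances per conformer.

**Conservation.** Percent identity (aligned or Needleman–Wunsch),
p-distances, Saitou–Nei neighbor joining with deterministic tie-breaking,
and column-resampling bootstrap supports, written as Newick.

Every stage has a seed-deterministic synthetic-data generator with known
ground truth (`simulate_titration()`, `simulate_intensities()`,
`make_toy_ensemble()`, `simulate_alignment()`), so the full pipeline is
testable without any external data.

## Worked example

The packaged synthetic fixture emulates a 151-residue extended Tudor
construct titrated with an 18-bp DNA duplex (true K_D 22 μM, n = 3,
designed CSP hotspot and RGR-motif enhancement):

```r
library(nmrbind)

fx   <- td151_fixture(seed = 1)
fx$series
#> <nmr_titration> TD151-like synthetic construct + dsDNA1 (CTCAGGTCAAAGGTCACG)
#>   c_pro = 100 uM, c_lig = 5000 uM
#>   9 points (r = 0, 0.1, 0.2, 0.4, 0.6, 0.8, 1, 1.2, 1.6), 151 residues

prof <- csp_profile(fx$series)
fit  <- fit_kd(prof, n_sites = 3, bootstrap = 200, seed = 2)
fit
#> <kd_fit> mode: global  n_sites (fixed): 3
#>   K_D = 21.77 uM  (95% bootstrap CI 21.2 - 22.31)
#>   residues fitted: 16   RSS = 0.0004344 ppm^2   converged: TRUE
```

The fitted K_D (21.77 μM) recovers the designed 22 μM from noisy data;
`tidy(fit)`, `glance(fit)` and `autoplot(fit)` expose the per-residue
CSP_max table, the one-row summary, and the titration-curve plot. The
classification stage recovers the designed sites exactly:

```r
cl  <- classify_csp(prof)                 # mean / mean+SD rule
act <- derive_active_residues(cl)
attr(act, "active_ranges")
#> [1] "18-22,88-91,99-105"

en <- classify_enhancement(intensity_ratio(fx$series, 1.6))
residue_ranges(en$residue_number[en$enhancement_class == "strong"])
#> [1] "138-146"
```

Ensemble metrics on the synthetic 20-conformer double-Tudor stand-in
(labelled synthetic — no deposited coordinates are bundled):

```r
ens <- synthetic_td151_ensemble(seed = 1)
rmsd_to_mean(ens, htd_regions(), "htd1_ss")
#> <ensemble_rmsd> 20 conformers, 99 atoms, region 'htd1_ss'
#>   RMSD to mean structure: 0.51 +/- 0.02 Angstrom

salt_bridge_stats(ens, list(residue = 50L, atoms = c("OE1", "OE2")),
                  list(residue = 37L, atoms = "NZ"))
#> <salt_bridge_stat> residue 50 {OE1,OE2} -- residue 37 {NZ}
#>   distance 3.70 +/- 0.79 Angstrom; <= 4.0 in 13/20 conformers
```

## Documentation

The methods vignette (`vignettes/nmrbind-methods.Rmd`) describes the
binding model and its assumptions, the classification thresholds, the
superposition and salt-bridge conventions, the phylogeny determinism
rules, what the synthetic generators emulate (and deliberately do not),
and known limitations.
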