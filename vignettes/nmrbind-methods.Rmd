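---
title: "Models and methods behind nmrbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nmrbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrbind)
```

nmrbind analyses protein–ligand binding followed by solution NMR: it turns
assigned 2D ^1^H–^15^N peak lists recorded along a titration into weighted
chemical shift perturbations (CSPs), fits a dissociation constant under an
n-equivalent-sites isotherm with dilution correction, classifies residues
into binding-site maps, and complements the titration analysis with
multi-model ensemble metrics (precision RMSDs, salt-bridge statistics) and
a small sequence-conservation toolchain (percent identity, neighbor-joining
trees with bootstrap supports). The motivating use case is DNA binding by
interdigitated double Tudor domains — compact β-barrel modules whose
folded core binds duplex DNA while a disordered, positively charged
C-terminal extension (an AT-hook-like RGR motif) contributes a second,
intensity-detected binding site — but nothing in the code is specific to
that system.

This vignette records the models, the tunable parameters, the numerical
choices, and what the synthetic data generators do and do not emulate.

## The CSP statistic

For each residue the amide proton and nitrogen shift changes relative to
the apo spectrum are combined as

$$\mathrm{CSP} = \sqrt{\delta_{HN}^2 + (\delta_N/5)^2},$$

the standard weighted form in which the ^15^N change is scaled by 1/5 to
account for its larger shift range (`compute_csp()`, weight configurable).
The sum-under-the-root form is used deliberately: a difference of squares
can go negative, while measured CSPs are nonnegative by construction.
CSPs are referenced to the apo (`r = 0`) point, so the apo CSP is exactly
zero and residues flagged proline / unassigned / overlapped are masked
per point rather than dropped (`csp_profile()`).

## The binding isotherm and K_D fitting

Fast exchange is assumed: the observed CSP is the bound-protein fraction
times the saturation value CSP~max~. The titrant (a DNA duplex) is modelled
as carrying $n$ equivalent and independent protein-binding sites, and the
protein is diluted by each addition from the ligand stock, so at molar
ratio $r$ the protein concentration is
$P_t = (1/C_{pro} + r/C_{lig})^{-1}$ (`total_protein_conc()`). Mass action
with total sites $S_t = n\,r\,P_t$ and macroscopic constant $K = n K_D$
gives a quadratic for the bound concentration whose root yields

$$\mathrm{CSP}(r) = \frac{\mathrm{CSP_{max}}}{2}\Big[\big(1 + nr +
nK_D(\tfrac{1}{C_{pro}} + \tfrac{r}{C_{lig}})\big) -
n\sqrt{\big(\tfrac{1}{n} + r + K_D(\tfrac{1}{C_{pro}} +
\tfrac{r}{C_{lig}})\big)^2 - \tfrac{4r}{n}}\Big].$$

`predict_csp()` implements the algebraically equivalent
$2nr/(A + \sqrt{A^2 - 4nr})$ form, which is immune to the catastrophic
cancellation the printed difference suffers at weak binding; the test
suite verifies agreement with independent mass-action root finding to
1e-10 over random parameter grids, and the exact limits
$\mathrm{CSP}(0)=0$ and $K_D \to 0 \Rightarrow \min(1, nr)\,
\mathrm{CSP_{max}}$. A negative discriminant beyond a 1e-12 relative
guard signals invalid parameters and errors; within the guard it is
clamped to zero.

`fit_kd()` estimates $K_D$ by unweighted nonlinear least squares in ppm
(no per-point uncertainties are generally available). Two modes exist
because published titrations rarely state which residues entered the fit:
`"global"` (default) shares one $K_D$ across residues with per-residue
CSP~max~, selecting by default the residues whose final-point CSP is at or
above the mean; `"per_residue"` fits each residue alone. $n$ is always
fixed by the user from the experimental design — its fitted value also
absorbs concentration errors and is hard to interpret, so estimating it is
off by default. Numerically the model is conditionally linear in
CSP~max~, so CSP~max~ is profiled out in closed form (clamped to
$[0, 10\times$ max observed CSP$]$) and the optimisation is a 1-D search
over $\log_{10} K_D \in [-4, 6]$, run over five log-spaced bracketing
intervals with the best-RSS winner; the convergence flag reports honestly
whether the optimum is interior. An all-zero profile is flagged as "no
binding signal", never fitted.

Uncertainty comes from residual-resampling bootstrap (default 500 draws,
seed-controlled; refits bracket ±1.5 decades around the point estimate). A
pre-freeze Monte-Carlo calibration at the standard design (true $K_D$
22 μM, $n=3$, 12 ratios to $r=2$, shift noise 0.005/0.025 ppm, 10
residues) measured 93% empirical coverage for the nominal 95% interval
and a median $|K_D|$ error of 3%; the package's recovery test requires
median error ≤ 15% and CI coverage in at least 16 of 20 seeded
replicates, reflecting that calibration.

## Binding-site classification

`classify_csp()` uses the conventional mapping rule: with mean $m$ and
standard deviation $s$ of the CSPs over valid residues at one titration
point (default: the final point), classes are strong ($\ge m+s$),
moderate ($\ge m$) and below-mean, with inclusive thresholds ("ties go
up"). The SD is the sample SD by default (configurable); excluded
residues (prolines, unassigned, overlapped) never enter the statistics.
Classification is invariant to residue order and to uniform scaling of
all CSPs.

Disordered-region binding is detected through peak-height ratios
(`intensity_ratio()`, bound/apo at a chosen point): ratios > 3 are strong
enhancement, (1.5, 3] moderate, with strict boundaries at 3 and 1.5. A
zero or missing apo intensity marks the residue invalid rather than
producing an infinite ratio. Physically, enhancement flags residues in
intermediate conformational exchange in the free state that rigidify on
binding; the generator treats the factors phenomenologically and does not
model exchange lineshapes.

`derive_active_residues()` exports the docking restraint rule: strong-CSP
residues become "active"; passive residues are deliberately left to the
docking program or the user. Published active-residue lists are often
manually optimised against initial docking runs, so the rule's output is
a starting point, not a reproduction of any curated list.

## Ensemble metrics

`read_pdb_ensemble()` parses multi-model PDB files with fixed columns,
resolves altlocs by highest occupancy then first, and intersects atom
sets across models (with a warning) when they disagree. The precision
metric `rmsd_to_mean()` follows the usual convention: superpose all
conformers on the first over the selection, average, re-superpose on the
mean and iterate until the mean moves < 1e-6 Å (max 100 iterations) —
a documented stand-in for the exact (unstated) conventions of legacy
ensemble-analysis programs. The default backbone selection is N, CA, C;
N, CA, C, O is available because "backbone heavy atoms" is ambiguous in
the literature. Superposition is by the Kabsch SVD algorithm with a
determinant correction (`kabsch_superpose()`), property-tested against
brute-force rotation sampling. Note the closed form for the two-conformer
toy case: with a single atom displaced by $d$ out of $N$ selected atoms,
re-superposition absorbs part of the displacement, giving
$(d/2)\sqrt{(1-1/N)/N}$ rather than the idealised $(d/2)/\sqrt{N}$; the
two agree to a relative $1/(2N)$.

`salt_bridge_stats()` reports, per conformer, the minimum distance over
all donor-atom × acceptor-atom pairs (so Glu OE1/OE2 need not be
disambiguated), with a default 4.0 Å N–O criterion (no universal cutoff
exists; it is configurable) and ensemble mean ± SD.

## Sequence identity and phylogeny

`percent_identity()` counts identical pairs over columns where both
sequences are non-gap, excluding ambiguous codes (X/B/Z) from the
denominator; `"global_align"` mode first aligns with Needleman–Wunsch
(match +1, mismatch 0, linear gap −1, via Biostrings). `p_distance()`
uses pairwise deletion. `neighbor_joining()` implements Saitou–Nei with
the Q-criterion and two determinism rules: Q-ties break to the lowest
index pair, and a negative branch length is clamped to zero with the
deficit moved to the sister branch of the same join so path lengths are
preserved. On additive matrices the generating tree is recovered exactly
(tested against the generating trees, a least-squares quartet oracle and
an independent NJ implementation). `bootstrap_support()` resamples
columns, rebuilds NJ trees and scores the full-data tree's bipartitions
as percentages; p-distance input is the documented default since distance
settings behind published trees are rarely stated.

## Synthetic data: what it emulates, and what it does not

Every stage has a seed-deterministic generator with known ground truth:

* `simulate_titration()` runs the isotherm forward. A per-residue
  direction angle θ (default uniform in (0, π/2)) splits the combined CSP
  over both nuclei as $\delta_{HN} = \mathrm{CSP}\cos\theta$,
  $\delta_N = 5\,\mathrm{CSP}\sin\theta$, so recombination is exact;
  Gaussian ppm noise is added per nucleus to non-apo points (the apo
  reference is exact, making zero-noise runs reproduce the model to
  machine precision). Apo positions are drawn from plausible amide ranges
  (^1^H 6–10, ^15^N 105–130 ppm) but cancel out downstream.
* `simulate_intensities()` uses multiplicative mean-one lognormal noise —
  peak heights are positive and scale-dependent — on both apo and bound
  heights.
* `make_toy_ensemble()` adds per-region i.i.d. Gaussian atomic scatter,
  optional per-model rigid region translations (internally ordered but
  mutually mobile domains), and constructed salt-bridge contacts (the
  acceptor atom is repositioned along the nearest-donor axis to
  target + jitter, truncated at 1.5 Å).
* `simulate_alignment()` evolves sequences down a known tree under a
  Jukes–Cantor-style uniform 20-state model (no indels, no rate
  heterogeneity).

Two packaged study-scale fixtures tie the stages together.
`td151_fixture()` emulates a 151-residue extended double-Tudor construct
titrated with an 18-bp duplex: true $K_D$ 22 μM, $n=3$, protein 100 μM,
5 mM ligand stock, ratios to 1.6, a folded-core CSP hotspot, RGR-motif
residues 138–146 with enhancement factors > 3 and the linker 110–136
between 1.5 and 3. The ligand stock (5 mM) and the ratio endpoint (1.6)
mirror common practice for such titrations; the protein concentration is
not standardised anywhere, so 100 μM was chosen as a typical HSQC
titration concentration and is configurable.
`synthetic_td151_ensemble()` is the structural counterpart: a 20-model
ensemble whose generator defaults emulate the precision pattern of a
determined double-Tudor solution structure (subdomain scatter tuned so
secondary-structure RMSDs fall near 0.5 and 0.35 Å, a 2.5 Å rigid
inter-domain jitter, disordered termini, and Glu50–Lys37/Lys39 bridges at
3.4/3.5 Å with 1.0/1.8 Å jitter). Both are *synthetic and labelled as
such*: no deposited coordinates or database sequences are bundled, so
tests against them demonstrate pipeline correctness on data of realistic
structure — not agreement with any deposited entry.

What the generators do **not** emulate: spectral lineshapes and peak
overlap, intermediate-exchange broadening physics, assignment errors or
peak-tracking ambiguity across crowded titration points (assignments are
taken as given per point), correlated shift noise, indels and
rate-variation in sequence evolution, and side-chain packing in
ensembles. Passing tests therefore validate the statistics and
algorithms, not robustness to those real-data pathologies.

## Problem sizes and reproducibility

The shipped checks run at desk scale, chosen to keep Monte-Carlo error
well inside the asserted tolerances: 1000-point parameter grids for the
isotherm oracle, 100 seeded replicates for $K_D$ recovery, 20 replicates
× 150 draws for bootstrap coverage, 50 × 1000 rotations for Kabsch
optimality, 100 additive matrices (5–8 taxa) for NJ, 10-kb alignments for
topology recovery. `scripts/acceptance.R` re-runs the main pipeline from
scratch under a caller-supplied seed and writes its headline numbers as
JSON; all generators route randomness through one seed argument, so
identical calls are byte-identical.

## Known limitations

* The isotherm treats sites as equivalent and independent; cooperative or
  overlapping binding, and slow/intermediate exchange, are out of scope.
* The relation between the macroscopic $K = nK_D$ parameterisation and a
  per-site microscopic constant is documented but not reinterpreted:
  fitted values are comparable only under the same fixed $n$ convention.
* Peak tracking between titration points is not implemented.
* The mean-structure iteration approximates, but cannot exactly
  reproduce, unpublished superposition conventions of legacy tools.
* NJ is distance-based only; no likelihood or model-based distances.
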