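---
title: "Quantifying polyproline II helix content: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying polyproline II helix content: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppiihelix)
library(dplyr)
```

## The problem

Chaperonins such as *E. coli* GroEL, mitochondrial Hsp60 and chloroplastic
Cpn60 carry ~24-residue C-terminal tails that are invisible to
crystallography and cryo-EM and are usually written off as disordered. In
GroEL and mHsp60 the distal part of the tail is a Gly/Met-rich stretch
built from tandem Gly-Gly-Met (GGM) repeats — in GroEL, AGGMGGMGGMGGMM,
the "CtS" segment of the complete "CtC" tail PKNDAADLGAAGGMGGMGGMGGMM.
Peptides and simulations of these tails show that they are not featureless
coil: a substantial fraction of the ensemble adopts the polyproline II
(PPII) helix, a left-handed extended helix near φ = −75°, ψ = +150° with
three residues per turn (one GGM repeat ≈ one turn) and no intramolecular
hydrogen bonds.

ppiihelix packages the three independent ways this PPII content is
quantified:

1. **Dihedral classification** of conformational ensembles (e.g. MD
   trajectory frames): a residue conformation is PPII when (φ, ψ) falls in
   a rectangular Ramachandran window.
2. **Circular dichroism**: PPII has a weak positive band near 212 nm
   whose amplitude tracks population; an empirical calibration converts
   the maximum mean residue ellipticity into a percent population, and
   thermal melts at 217 nm are linear for the non-cooperative PPII-to-coil
   transition.
3. **NMR**: near-zero secondary ¹³Cα chemical shifts and ³J(HN-Hα)
   couplings of 5.5–8.0 Hz rule out α-helix and β-strand, leaving
   coil-or-PPII.

A fourth module simulates all three kinds of input with known ground
truth, so every estimator can be validated end to end without a
microsecond trajectory or a spectropolarimeter.

## Dihedral classification

`is_ppii()` tests both angles against a `ppii_window()` — defaults
φ = −75° ± 20°, ψ = +150° ± 20°. Numerical choices:

* **Boundary inclusivity.** "± 20°" does not say whether the boundary is
  in or out; we include it (|circular distance| ≤ half-width) so that
  exact boundary values classify deterministically.
* **Circular distance.** Membership is measured on the circle, so
  windows relocated near ±180° behave correctly; the default window never
  wraps.
* **Undefined angles.** The first residue of a chain has no φ and the
  last no ψ. Such conformations are *never* PPII, and — more importantly —
  they are excluded from denominators rather than counted as non-PPII,
  which would bias short segments (a 14-residue CtS loses 2 of 14
  residues to termini) systematically downward.
* **ω is ignored**; the criterion is φ/ψ only. Proline and glycine get
  no special treatment.

`chain_dihedrals()` computes φᵢ from C(i−1)–N(i)–CA(i)–C(i) and ψᵢ from
N(i)–CA(i)–C(i)–N(i+1) with the IUPAC sign convention, from either
multi-model PDB coordinates (`read_backbone_pdb()`, via bio3d, highest
occupancy altloc kept) or the dihedral TSV dialect.

The geometric oracle is `build_backbone()`: a chain grown by
internal-coordinate placement (ideal bond lengths/angles, trans peptide
bond) from prescribed dihedrals. Build → measure closes to better than
10⁻⁶ degrees over a 5° grid of the whole Ramachandran torus, and the
fraction of uniformly random conformations classified PPII matches the
analytic area fraction (40/360)² ≈ 1.23 %.

## Trajectory aggregation

All estimators share one statistic: PPII-classified observations divided
by defined-dihedral observations.

* `ppii_windowed_content()` reports, at times that are multiples of the
  stride, the content of the *trailing* half-open window (t − w, t] — with
  the 50/50 ns defaults the value at 50 ns averages 0–50 ns. Trailing
  partial windows are dropped, not padded. Missing frames are tolerated;
  fractions are per observation, not per nominal frame.
* `ppii_per_residue()` averages the indicator over the whole run per
  (chain, residue); terminal residues report `NA` with a zero denominator.
* `ppii_per_repeat()` restricts to the four 3-residue GGM repeats and
  pools the chains (a single trace per repeat), while per-segment output
  keeps the chains separate — matching how the two views are usually
  plotted.
* `ppii_run_summary()` collapses a segment to one scalar. Whether such
  quoted scalars weight chains equally or weight observations is usually
  unstated in source data; both are provided (`weights = "observation"`
  default, `"chain"` optional) and the weighting is recorded in the
  output.

Canonical segment maps (`groel_segments()`): CtS positions 2–4, 5–7,
8–10, 11–13 are GGM1–4, leaving the final MM unassigned; in the
24-residue CtC the same repeats sit at 12–14 … 21–23. Solubility tags
present in synthesized peptides (C-terminal KKK or His) are excluded —
they do not exist in the protein.

## The synthetic ensemble generator

`simulate_ensemble()` emulates what the analysis consumes — per-frame
(φ, ψ) for 7 independent chains of the CtS sequence — without any
physics. Per residue, a stationary two-state Markov chain:

* **Occupancy** is the stationary PPII probability. Default 0.25, the
  middle of the 15–35 % range reported for these tails; per-residue
  vectors allowed.
* **Persistence** is the mean dwell of the PPII state in frames (exit
  probability 1/persistence; entry probability set by stationarity).
  persistence = 1 gives single-frame visits; the construction requires
  occupancy ≤ persistence/(1 + persistence). No autocorrelation
  information exists for the real trajectories, so the default
  (persistence = 1) is deliberately the simplest choice and is flagged
  as arbitrary.
* **Angles.** PPII-state angles are uniform strictly *inside* the
  window, coil-state angles uniform on the rest of the torus by
  rejection. This makes nominal occupancy equal classifiable occupancy
  exactly; Gaussian-state sampling would leak across the boundary and
  bias every recovery test.
* **Determinism.** One seeded stream consumed in a fixed order; identical
  specs give bit-identical ensembles.

What it does *not* emulate: real trajectories have correlated residues,
chain–chain contacts, non-uniform within-window densities and slow
conformational drift. Passing recovery tests therefore validates the
*estimators*, not any claim about real chaperonin dynamics. Problem sizes
used in the tests — 7 × 14 residues × 1000–2000 frames — were chosen to
make 3-standard-error recovery bands a few tenths of a percent wide,
tight enough to expose estimator bias below 0.01.

## CD analysis

`ppii_population()` implements the empirical alanine-peptide calibration

$$\%\mathrm{PPII} = 100\,\frac{[\Theta]_{max} + 5560}{15140}$$

with $[\Theta]_{max}$ the maximum mean residue ellipticity (deg cm²
dmol⁻¹) sampled between 210 and 230 nm. Choices:

* **No interpolation** in `theta_max()`: populations are read from
  measured samples; ties break to the lower wavelength for determinism.
* **No clamping**: a population outside 0–100 % almost always means wrong
  units or a missing baseline, so it is flagged with a warning, never
  silently truncated.
* `fit_melt()` is ordinary least squares of MRE on temperature, with
  Pearson r; a flat control trace returns slope 0, r reported as 0 and a
  degeneracy flag instead of an error. `linearity_check()` accepts a
  trace as linear when |r| ≥ 0.95 (motivated by the R ≈ 0.96–0.98 of
  measured PPII melts) and the residuals contain no same-sign run longer
  than 6 (curvature backstop); near-zero residuals break runs so exact
  traces pass.
* `difference_spectrum()` subtracts spectra on identical grids (optional
  common-grid restriction); cold-minus-hot differences isolate the
  spectral shape of the conformation lost on heating.
* `mre_from_millideg()` converts raw millidegrees using the mean residue
  weight per peptide bond (mass/(n − 1)).

The synthetic CD series (`simulate_cd_series()`) builds spectra as
population mixtures p(T)·PPII + (1 − p(T))·coil with p linear in T
(defaults: 43.3 % at 0 °C, −0.0713 %/°C, the behaviour of the GroEL CtS
peptide). The basis anchors are +9580 at 212 nm (the population-equation
numerator zero) and −5560 (its baseline), so the mixture inverts the
population equation *exactly*. Making the difference spectra exactly
proportional to the PPII basis in addition forces the coil basis to be a
scaled inversion of the PPII basis — an idealization, chosen knowingly:
real coil spectra have their own strong negative band near 198 nm and are
not proportional to PPII spectra. The generator exists to close the
analysis loop, not to render photorealistic spectra.

## NMR classification

`classify_residues()` compares secondary shifts Δδ = δ(obs) − δ(coil
reference) and couplings against `class_criteria()`:

| class | Δδ ¹³Cα | ³J(HN-Hα) |
|---|---|---|
| alpha | ≥ +1.0 ppm | missing or < 5.5 Hz |
| beta | ≤ −0.7 ppm | missing or > 8.0 Hz |
| coil_or_ppii | within ±0.4 ppm | missing or 5.5–8.0 Hz |
| ambiguous | anything else | |

The coupling band is the established coil/PPII range; the Δδ cutoffs are
package conventions with the right qualitative structure (published
criteria diagrams are graphical, and exact numbers cannot be recovered),
so they are configuration, not constants. PPII and statistical coil are
deliberately merged — separating them is exactly what residue-level NMR
cannot do here; CD carries that distinction. Missing data propagate as
not-applicable, never as zero; a residue with neither datum is an error.

`segment_verdict()` passes a segment as "no alpha/beta; coil or PPII"
only when the alpha and beta fractions are each ≤ 0.1 **and** the
affirmative coil-or-PPII fraction is ≥ 0.8. The second condition matters:
a table full of large shifts paired with coil-band couplings classifies
as *ambiguous*, and a verdict that only checked for alpha/beta calls
would wave it through.

Coil references (`coil_reference()`) come from a packaged static
Wishart-type consensus table (¹³Cα and ¹Hα, 25 °C, no neighbor or pH
corrections), with an optional linear temperature coefficient (default
0). Neighbor-corrected prediction is an extension point, not a default:
the conclusions these methods support rest on Δδ being *small*, which
the simple table resolves.

## Degenerate inputs and tie-breaks, collected

* Collinear atom triples: error naming the offending triple.
* Chains with < 2 residues: error (no dihedral is defined).
* Windows containing no frames, segments with no residues or no defined
  dihedrals: errors, not silent `NaN`s.
* Flat melt traces: degenerate fit, not an error; identical-temperature
  traces: error.
* theta-max ties: lower wavelength.
* Glycine couplings are left unmeasured by the shift simulator,
  mirroring practice (glycine ³J is rarely resolvable in crowded
  spectra).

## Worked example

```{r example}
set.seed(1)
ens <- simulate_ensemble(simulation_spec(n_frames = 500, occupancy = 0.22, seed = 42))
report <- ppii_report(ens)
report
ppii_run_summary(report, "CtS")

sim <- simulate_cd_series()
cd_populations(sim$spectra) |> head(3)
glance(fit_melt(sim$melt))

shifts <- simulate_shift_table("AGGMGGMGGMGGMM", dca_scale = 0.2, seed = 42)
segment_verdict(shifts)
```

## Known limitations

* The dihedral window is a hard rectangle; real PPII basins are soft and
  anisotropic. Content estimates inherit the window definition.
* The CD population equation is an empirical calibration from short
  alanine peptides; applying it to Gly/Met-rich sequences imports that
  calibration's assumptions, and the 212 vs 217 nm choice (spectrum
  maximum vs melt wavelength) makes populations route-dependent at the
  ~1–2 % level. Outputs record which route produced them.
* NMR classification cannot separate PPII from coil; the merged class is
  a feature, not a shortcut.
* The simulator validates estimators, not force fields: agreement between
  recovered and nominal occupancy says nothing about whether any MD
  ensemble is right.
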