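# ppiihelix

Quantify polyproline II (PPII) helix content in disordered peptide
segments from three independent evidence streams: backbone dihedral
classification of conformational ensembles, far-UV circular dichroism,
and NMR secondary chemical shifts with ³J(HN-Hα) couplings.

The package grew around one system: the Gly/Met-rich C-terminal tails of
chaperonins (GroEL, mitochondrial Hsp60, chloroplastic Cpn60). These
~24-residue tails are invisible to crystallography and cryo-EM, yet a
substantial fraction of their conformational ensemble is PPII helix — a
left-handed extended helix (φ ≈ −75°, ψ ≈ +150°, three residues per turn,
no internal hydrogen bonds) whose tandem Gly-Gly-Met repeats each span
about one turn. Everything is exposed as ordinary data-frame-in /
tibble-out functions, so the same machinery applies to any disordered
sequence.

## What it computes

**From ensembles** (multi-model PDB or per-frame φ/ψ tables). A residue
conformation is PPII when both dihedrals fall within the window
φ = −75° ± 20°, ψ = +150° ± 20° (inclusive, circular). Aggregates:

- windowed content per chain and segment — the fraction of
  PPII-classified observations in the trailing window (t − 50 ns, t],
- content per Gly-Gly-Met repeat, pooled over chains,
- whole-run mean per-residue populations,
- a single time-averaged scalar per segment (observation- or
  chain-weighted).

Denominators count only observations with both dihedrals defined; chain
termini are not-applicable, never zero.

**From CD.** The empirical population estimate

```
%PPII = 100 · ([Θ]max + 5560) / 15140
```

with [Θ]max the maximum mean residue ellipticity (deg·cm²·dmol⁻¹)
sampled between 210 and 230 nm; plus linear thermal-melt fitting at
217 nm (the PPII-to-coil transition is non-cooperative, hence linear),
a linearity diagnostic, and temperature difference spectra.

**From NMR.** Secondary shifts Δδ¹³Cα against a packaged random-coil
reference table; residues classify as alpha / beta / coil-or-PPII /
ambiguous (couplings of 5.5–8.0 Hz are the coil/PPII band), and a
segment-level verdict states whether alpha/beta structure is absent.
PPII and statistical coil are deliberately merged at residue level — NMR
cannot separate them here; CD carries that distinction.

**Synthetic data.** A two-state Markov simulator with known per-residue
PPII occupancy and dwell times, an ideal-geometry backbone builder (the
round-trip oracle for the torsion code), CD spectrum/melt series that
invert the population equation exactly, and near-coil shift tables.

## Worked example

```r
library(ppiihelix)

# simulate 7 chains of the GroEL short tail at 22% PPII occupancy
ens <- simulate_ensemble(simulation_spec(n_frames = 1000, occupancy = 0.22, seed = 42))
report <- ppii_report(ens)
report
#> <ppii_report> 1000 frames, 7 chain(s); window 50 ns / stride 50 ns
#>   CtS: run-average PPII fraction 0.221
ppii_run_summary(report, "CtS")
#> # A tibble: 1 × 5
#>   segment weighting   fraction n_obs n_windows
#>   <chr>   <chr>          <dbl> <int>     <int>
#> 1 CtS     observation    0.221 84000        20
```

The recovered fraction (0.221) agrees with the 0.22 ground truth within
sampling error; `n_obs` records the denominator (1000 frames × 7 chains
× 12 residues with defined dihedrals).

```r
# CD: populations and melt
ppii_population(c(1000, 1600))
#> [1] 43.32893 47.29194
```

Maxima of 1000 and 1600 deg·cm²·dmol⁻¹ — the 0 °C values measured for
the GroEL and mHsp60 short-tail peptides — correspond to 43% and 47%
PPII.

```r
fit_melt(simulate_cd_series()$melt)
#> <melt_fit> [theta]_217nm = 771.4 -8.364 (T C), R = -1.000 (n = 66)

# NMR: a near-coil shift table earns the no-alpha/beta verdict
segment_verdict(simulate_shift_table("AGGMGGMGGMGGMM", dca_scale = 0.2, seed = 42))
#> # A tibble: 1 × 7
#>   n_classified frac_alpha frac_beta frac_coil_or_ppii frac_ambiguous no_alpha_beta verdict
#>          <int>      <dbl>     <dbl>             <dbl>          <dbl> <lgl>         <chr>
#> 1           14          0         0                 1              0 TRUE          no alpha/beta; coil or PPII
```

Plots: `plot_ppii_timecourse()`, `plot_ppii_profile()`,
`plot_cd_spectra()`, `plot_shift_classes()`, and `autoplot()` on melt
fits. A thin command-line wrapper lives at `inst/scripts/ppii.R`
(subcommands `traj`, `cd`, `nmr`, `sim`).

See `vignettes/ppii-quantification.Rmd` for the models, parameter
defaults, numerical choices and limitations.

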