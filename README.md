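# minihelix

Reactive-geometry analysis of RNA minihelix aminoacylation ensembles.

## The problem

Non-enzymatic aminoacylation of an RNA minihelix — the putative progenitor
of tRNA charging — prefers L- over D-amino acids. The reaction starts when
the 3′-oxygen of the terminal adenosine (A3) attacks the carbonyl carbon of
an aminoacyl phosphate attached to the neighbouring deoxythymidine (dT4).
Whether a sampled conformation of this reaction site can react at all is a
question of geometry, and that geometry can be scored frame by frame in a
molecular-dynamics (or synthetic) ensemble.

This package is for structural bioinformaticians and molecular modellers
who want to post-process such ensembles: score every frame, count reactive
conformations per run, test L vs D differences, and dissect the
backbone-dihedral origin of the selectivity.

## The five criteria

A frame is a **reactive conformation** when all of the following hold
(strict inequalities), with Nu the attacking ribose oxygen (O3′ or O2′) and
C<sub>carb</sub>/O<sub>carb</sub> the carbonyl:

| # | measure | window |
|---|---------|--------|
| 1 | attack distance δ<sup>att</sup> = \|Nu···C<sub>carb</sub>\| | < 3.2 Å |
| 2 | Bürgi–Dunitz angle α<sup>BD</sup> (Nu···C=O) | \|α<sup>BD</sup> − 105°\| < 15° |
| 3 | Flippin–Lodge azimuth α<sup>FL</sup> | \|α<sup>FL</sup>\| < 25° |
| 4 | lobe angle α<sup>Lobe</sup> (R−Nu···C, sp³ lone-pair direction) | \|α<sup>Lobe</sup> − 109.5°\| < 15° |
| 5 | SAC contact min(δ(Nu···O<sub>P1</sub>), δ(Nu···O<sub>P2</sub>)) | < 3.5 Å |

Criterion 5 encodes substrate-assisted catalysis: a non-bridging phosphate
oxygen must be close enough to deprotonate the attacking hydroxyl.

The package also computes the backbone dihedrals
τ(C4′-C5′-O5′-P5′) … τ(O<sub>b</sub>-C<sub>carb</sub>-C<sub>α</sub>-N) of
the alanyl phosphate, assigns conformer groups I/II from dihedral windows,
counts Watson–Crick hydrogen bonds in the flanking base pairs, and compares
per-run reactive counts between systems with Welch's unpaired t-test.

A built-in synthetic generator emulates the statistical structure of MD
trajectories of the reaction site: von Mises dihedral sampling (mirror-image
τ₅ modes at ±145° for L/D), internal-coordinate (NeRF) fragment
construction, a fixed A-form-like scaffold pose for the ribose, and
hard-sphere contacts that encode the steric difference between the amino
and methyl substituents at the stereocenter.

## Worked example

```r
library(minihelix)

cfg_l <- synthetic_config("L", n_runs = 5, frames_per_run = 2000, seed = 42)
cfg_d <- synthetic_config("D", n_runs = 5, frames_per_run = 2000, seed = 42)
ens_l <- sample_ensemble(cfg_l)
ens_d <- sample_ensemble(cfg_d)

summarize_ensemble(ens_l)
#> EnsembleSummary 'L-Ala (synthetic)' (5 x 2000 frames)
#>   reactive (O3'): 116 (1.16%)   reactive (O2'): 0 (0%)
#>   groups among O3'-reactive: I = 116 , II = 0 , other = 0
summarize_ensemble(ens_d)
#> EnsembleSummary 'D-Ala (synthetic)' (5 x 2000 frames)
#>   reactive (O3'): 4 (0.04%)   reactive (O2'): 0 (0%)
#>   groups among O3'-reactive: I = 3 , II = 1 , other = 0

welch_t_test(count_reactive(ens_l)$per_run, count_reactive(ens_d)$per_run)
#> Welch's unpaired t-test: t = 10.58, df = 4.258, p = 0.0003236
#>   n = 5 vs 5; mean = 23.2 vs 0.8; var = 21.7 vs 0.7
```

The L system adopts the reactive geometry far more often than the D system,
attack through O2′ is negligible in both, L-reactive frames sit in the
all-trans conformer group I while the D system is relatively enriched in
the carbonyl-flipped group II, and the per-run counts differ significantly
— the qualitative fingerprint of chiral-selective aminoacylation.

Single frames are scored the same way:

```r
m <- measure_frame(make_ideal_geometry("canonical_reactive"))
round(unlist(m[c("delta_att", "alpha_BD", "alpha_FL", "alpha_Lobe",
                 "delta_SAC_OP1")]), 3)
#>     delta_att      alpha_BD      alpha_FL    alpha_Lobe delta_SAC_OP1
#>           3.0         105.0           0.0         109.5           3.3

dihedral_distribution(measure_ensemble(ens_l), "tau_5", 5)
#> CircularHistogram of tau_5: 72 bins x 10000 samples; mode near 147.5 deg
```

A command-line front end over the same functions lives in
`inst/cli/minihelix-tools.R` (subcommands `simulate`, `measure`, `classify`,
`scan`, `groups`, `distributions`, `compare`, `run-all`).

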