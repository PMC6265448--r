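---
title: "Reactive geometry of RNA minihelix aminoacylation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reactive geometry of RNA minihelix aminoacylation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minihelix)
```

## The model

Non-enzymatic aminoacylation of an RNA minihelix transfers an aminoacyl
group from a 5′-aminoacyl phosphate on dT4 to the 3′-hydroxyl of the
terminal adenosine A3. Classical simulations cannot react, but they can
tell us how often the system *visits a geometry from which the reaction
could proceed*. This package scores that geometry frame by frame.

The attack of a hydroxyl nucleophile Nu (O3′ or O2′, with bonded ribose
carbon R = C3′ or C2′) on the trigonal carbonyl carbon is described by one
distance and three angles:

* **attack distance** $\delta^{att} = |Nu \cdots C_{carb}|$;
* **Bürgi–Dunitz angle** $\alpha^{BD}$, the Nu···C=O angle, empirically
  preferred near 105°;
* **Flippin–Lodge angle** $\alpha^{FL}$, the signed azimuth of the approach
  out of the plane that contains the C=O axis and is perpendicular to the
  carbonyl plane. For near-symmetric carbonyl substituents it should be
  near 0°;
* **lobe angle** $\alpha^{Lobe}$, the R–Nu···C angle. The sp³ hydroxyl
  oxygen donates from a tetrahedrally oriented lone pair, so a productive
  approach keeps this near 109.5°.

A fifth, mechanistic constraint comes from substrate-assisted catalysis:
one of the non-bridging phosphate oxygens OP1/OP2 must be close enough to
Nu (within an oxygen diameter of 3.0 Å plus a 0.5 Å buffer) to act as the
deprotonating base. A frame satisfying all five windows — `criteria_config()`
holds the defaults, every inequality strict — is a *reactive conformation*.

## Conventions that needed pinning

Several quantities are signed, and the literature leaves their algebraic
conventions loose; this package pins them as follows and tests them as
contracts.

**Dihedral sign.** `signed_dihedral()` uses the IUPAC convention (cis = 0°,
clockwise positive viewed from the second towards the third atom), returns
values in $(-180°, 180°]$, and satisfies two tested identities: reversal
symmetry $\tau(a,b,c,d) = \tau(d,c,b,a)$ and mirror antisymmetry (negating
x-coordinates negates $\tau$).

**Flippin–Lodge sign.** The carbonyl plane is the least-squares plane of
C~carb~, O~carb~, C~α~, O~b~ — four atoms rather than a single triple, so
slight pyramidalisation in sampled conformers does not pick an arbitrary
plane. Its normal is oriented towards the nucleophile's half-space; the
angle is measured from that normal to the azimuthal component of the
approach vector about the C=O axis, positive when the approach tilts
towards the O~b~ substituent (for the standard approach side). Only
$|\alpha^{FL}|$ enters the classification, and the tested contract is
reflection antisymmetry; the absolute sign convention is documented rather
than load-bearing.

**Chirality.** The stereocenter is encoded by the improper dihedral
τ(N–C~carb~–C~α~–C~β~) (`chirality_improper()`): positive ⇒ L, negative ⇒
D. The sign was pinned against embedded 3D structures of L- and D-alanine
from an independent cheminformatics toolkit, so the package's "L" is
physical L-alanine. Mirror reflection flips the improper and swaps the
label, which validation enforces.

**Indices.** Frames and runs are 0-indexed internally; every report (TSV,
PDB MODEL records, representative indices) is 1-indexed.

## The synthetic ensemble generator

The generator emulates — at the level of reaction-site internal coordinates
— what long MD trajectories of the solvated minihelix provide: 30
independent runs of 4,000 frames per system by default (120,000 frames,
matching 20 ns sampled every 5 ps per run), with per-run RNG substreams
derived from `(seed, run_index)` so each run is independently reproducible.

* **Dihedral models.** The five alanyl-phosphate backbone dihedrals are
  drawn from circular von Mises mixtures (`default_dihedral_models()`).
  τ₁…τ₃ have single components at 180°; τ₄ is a 99:1 mixture of 180° and 0°
  components, keeping the thermodynamically unstable carbonyl-flipped basin
  reachable; τ₅ (O~b~-C~carb~-C~α~-N) peaks at +145° for L and −145° for D
  — mirror images, the *only* model difference between the systems. The
  concentration κ = 10 puts ≈90% of each component's mass within ±30° of
  its mode, the documented default for peak widths the source distributions
  only describe by their modes.
* **Scaffold.** The A3 ribose is held at a fixed pose emulating its A-form
  placement: at the L-system's modal backbone the 3′-oxygen sits on the
  ideal Bürgi–Dunitz approach (FL = 0, lobe = 109.5°) at
  `delta_att0 = 3.5` Å, plus per-frame rigid jitter (4° rotation, 0.25 Å
  translation s.d.) for duplex breathing. Attack geometry is therefore an
  *emergent* function of the sampled backbone dihedrals — the generator
  never writes the attack measures directly.
* **Sterics.** Frames with hard-sphere overlap between the stereocenter
  substituents (amino N, methyl C~β~) and the ribose are rejected and
  redrawn — the hard-wall limit of the Boltzmann weighting an MD ensemble
  applies. Contact distances come from group van der Waals radii (amino
  1.64 Å, methyl 1.88 Å, O 1.52 Å, C 1.70 Å), with donor–acceptor N/O···O
  pairs allowed 0.4 Å closer because they can hydrogen-bond. This single
  asymmetry — the methyl is larger than the amino group and cannot
  hydrogen-bond — is what makes the τ₅ mirror difference chirally
  selective: at the modal L geometry the amino group faces the approaching
  O3′ at comfortable hydrogen-bond distance, while at the modal D geometry
  the methyl would sit 2.3 Å from O3′ and the frame is vetoed.

With these defaults the generator yields reactive fractions of roughly 1%
(L) and 0.04% (D) through O3′ and essentially zero through O2′. The
`delta_att0` scaffold distance was fixed once so these fractions land
within about an order of magnitude of the fractions a published MD study of
this system reports; the contact radii were not tuned. The resulting L:D
ratio (~25:1) is larger than the ~3:1 of soft-potential MD — a hard-sphere
veto is harsher than Boltzmann weighting — so all chirality-related checks
in this package are deliberately qualitative (L > D; O2′ at least
ten-fold below O3′), not count-matching.

**What the generator does not emulate.** Solvent and ions, autocorrelation
in time (frames are i.i.d. given the run), soft steric/electrostatic
gradients, base-pair fraying, and any coupling between the RNA scaffold and
the backbone beyond the rigid jitter. Passing tests therefore demonstrate
correctness of the *analysis* on ensembles with the assumed statistical
structure, not fidelity of any particular MD force field.

**Planting mode.** With `planted_reactive_fraction` set, a Bernoulli subset
of frames is replaced by jittered copies of the canonical reactive geometry
(0.01 Å coordinate noise, far inside every window) and every background
frame is displaced out of the attack-distance window. The planted mask is
then *exact* ground truth for the classifier — a calibration harness, not a
model of nature.

## Numerical choices

* Degenerate geometry (collinear dihedral triples, nucleophile on the C=O
  axis) is detected at vector norms below 1e-8 and raised as errors, never
  silently clamped.
* Superposition uses the Kabsch algorithm via SVD with the determinant
  correction, so reflections are never used to lower an RMSD; the test
  suite cross-checks against an independent quaternion (Kearsley)
  implementation at 1e-9.
* Circular histograms are left-closed: a value exactly on a bin edge goes
  to the higher bin, and +180° wraps into the −180° bin.
* Representative structures minimise the cumulative pairwise RMSD; ties
  break to the lowest index, making reruns deterministic.
* Welch's test reports two-sided p-values (the conservative reading for a
  directional claim); with zero variance in both samples and equal means,
  p = 1 by convention. Means ± s.d. elsewhere use the sample (n−1) standard
  deviation.
* Boundary scans bisect single-parameter ideal-geometry families
  (`make_ideal_geometry("boundary_family", ...)`), which vary exactly one
  measure while holding the others at canonical values, to 1e-6.

## Design decisions on open points

* **Hydrogen bonds.** The geometric criterion is donor–acceptor < 3.0 Å
  with donor–H···acceptor angle > 135° when hydrogens are present, and a
  3.5 Å heavy-atom fallback otherwise — mirroring common trajectory-analysis
  defaults, since no single criterion is canonical.
* **A-form reference.** No ideal reference structure is deposited anywhere
  usable, so `fixture_reference()` builds a synthetic idealised stand-in:
  planar Watson–Crick A3-U10 and dT4-A9 pairs (donor–acceptor ≈ 2.9 Å,
  near-linear, with polar hydrogens), stacked at 2.81 Å rise / 32.7° twist.
  It is labelled synthetic and exists to exercise the hydrogen-bond and
  RMSD code, not to represent a crystallographic helix.
* **Table-2-style RMSD selections** are user-configurable role lists; the
  fixture tests pin one documented choice (base heavy atoms of the two
  residues, hydrogens excluded) without claiming it matches any particular
  published pipeline.
* **The "no-FL" criteria variant** is `fl_halfwidth = 180`, one code path
  rather than a structural switch.
* **Sensitivity grids** are caller-supplied lists of `criteria_config()`
  objects; no fixed grid is hard-coded.

## Problem sizes used by the shipped checks

The package's own verification uses 1,000-frame random suites for the
mirror and oracle properties, a 10,000-frame ensemble for scan
monotonicity, one full 30 × 4,000 planted run for ground-truth recovery,
and one full pair of 30 × 4,000 L/D runs for the chiral-selectivity
property — sizes chosen to match the study design the generator emulates
while keeping a complete run of the suite in the minutes range.

## Known limitations

* The Flippin–Lodge sign convention, while internally consistent and
  mirror-antisymmetric, may differ from other software's; compare absolute
  values across tools.
* The generator's chirality discrimination is sharper than soft-potential
  reality (see above); treat its counts as qualitative.
* `read_frames()` expects the reaction-site atoms to be resolvable by
  (residue name, residue number, atom name) triples; exotic naming schemes
  need a custom `role_map()`.
* Only A:U / A:T Watson–Crick pairs are implemented for hydrogen-bond
  counting; G:C support would need new donor/acceptor tables.
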