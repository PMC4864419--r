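---
title: "Structural and thermodynamic analysis of phosphorothioate DNA duplexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural and thermodynamic analysis of phosphorothioate DNA duplexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptdna)
```

## The problem

Phosphorothioate (PT) modification replaces one non-bridging oxygen of a
DNA backbone phosphate by sulfur. The substitution is chiral at phosphorus:
the *Rp* diastereomer carries sulfur in place of O2P, the *Sp* diastereomer
in place of O1P. In bacteria the modification occurs physiologically, in a
sequence- and stereo-specific (*Rp*) manner, and affects duplex stability,
redox behaviour and recognition by modification-dependent restriction
enzymes. Characterizing how the sulfur sits in the double helix — which
groove it occupies, which short contacts it perturbs, how much the duplex
is destabilized — requires a chain of small quantitative analyses around
NMR and calorimetric data:

* building stereospecifically modified B-form coordinate models,
* converting NOESY cross-peak volumes into distance restraints,
* relating vicinal J-couplings to sugar pucker and backbone torsions,
* measuring RMSDs, contact distances and groove geometry on structure
  ensembles, and
* fitting two-state melting models to DSC traces.

`ptdna` implements that chain as composable R functions, together with a
seeded synthetic-data generator so that every stage is testable offline.

## Duplex specification and B-form templates

A duplex is described by `duplex_spec()`: two strands (5'→3'), validated
Watson–Crick complementarity, continuous residue numbering (strand 1 =
1..n, strand 2 = n+1..2n) and a list of PT sites with chirality. A PT site
modifies the residue's 5'-phosphate, so 5'-terminal residues are invalid
sites. `decamer_spec()` is a convenience constructor for the decamer
d(CGGCCGCCGA)·d(TCGGCGGCCG) — a sequence from a *Streptomyces lividans*
gene region that is physiologically phosphorothioated at the G3 and G17
5'-phosphates.

`build_bform_template()` produces an idealized all-atom B-form model:

* Planar base geometries are fixed numeric tables derived once from
  force-field-optimized N-methylated bases.
* Each Watson–Crick pair is assembled by a closed-form 2D alignment plus a
  small least-squares refinement that places the donor–acceptor distances
  at 2.90 Å and hydrogen–acceptor distances at 1.90 Å.
* Pairs are stacked with fiber-like helical symmetry: rise 3.38 Å, twist
  36°/bp (right-handed).
* Each deoxyribose + 5'-phosphate is grown from its glycosidic attachment
  by internal-coordinate (NeRF) construction: C2'-endo pucker (P = 162°,
  amplitude 36°), χ = −105°, γ = 54°, β = 174°, with exocyclic substituents
  completing tetrahedral centres. The discrete face choices were pinned
  against the stereocentre signs (C1' R, C3' S, C4' R) of
  β-D-deoxyribonucleosides.
* The glycosidic tilt (8°) and helix-axis displacement (−2 Å) were chosen
  so that the inter-residue O3'–P distance equals the true O3'–P bond
  length (1.59 Å); C1'–C1' spans (10.4 Å) and base stacking were secondary
  targets. No measured or published ensemble quantity entered this
  calibration.

The resulting template has consecutive P–P spacings of 6.6 Å, S-type
sugars (δ ≈ 145°), and satisfies all of its own Watson–Crick restraints.
It is a *starting model* in the sense of restrained structure
determination: rigid nucleotides, no propeller twist, no sequence-dependent
fine structure, no energy minimization. Contact distances on the template
are therefore idealized — for example the characteristic
H2''(i)···O2P(i+1) backbone contact is ≈ 3.0 Å on the template, whereas
refined NMR ensembles of this decamer place it at 2.4–2.6 Å.

`apply_pt_modification()` substitutes exactly one atom: *Rp* renames
O2P → S2P, *Sp* renames O1P → S1P, moving the atom along the original P–O
direction to the configured P–S bond length (default 1.98 Å, standard
phosphorothioate geometry; the modified residues are renamed RSG/SSG).
Applying the same substitution twice is an error, never a silent
double-substitution.

## NOE distance restraints

Cross-peak volumes enter through the isolated spin pair approximation
(ISPA): `calibrate_distance()` computes
d = d~ref~ (V~ref~/V)^1/6^ against the cytosine H5–H6 reference
(2.45 Å). Calibration is strictly decreasing in volume and invariant to a
common volume rescaling.

`classify_noe()` bins peaks into the conventional classes:

| class  | non-exchangeable | exchangeable |
|--------|------------------|--------------|
| strong | 1.8–2.9 Å        | 1.8–4.0 Å    |
| medium | 1.8–3.5 Å        | 1.8–5.0 Å    |
| weak   | 1.8–6.0 Å        | 1.8–8.0 Å    |

Explicit class labels take precedence. Otherwise non-exchangeable peaks
are thresholded on the calibrated distance (strong ≤ 2.9 Å, medium ≤
3.5 Å, else weak) — the bins themselves are standard, the volume→class
cutoffs are the package's documented default. Exchangeable peaks are
classified from the two-mixing-time protocol: strong if present at 50 ms
with at least half the reference volume, medium if present at 50 ms below
that, weak if observed only at 200 ms. `noe_restraints()` pools peaks of
the same proton pair across the NOESY build-up series (50–250 ms),
averaging their calibrated distances before classification; this is what
makes restraint generation robust to ~10% volume noise.

`pseudoatom_correction()` widens upper bounds for degenerate groups
(default +1.0 Å for methyls, the common XPLOR convention; pseudoatom
names use the M/Q prefix). `generate_wc_restraints()` emits three hydrogen
bonds per G·C pair and two per A·T pair (heavy–heavy 2.8–3.0 Å,
H–acceptor 1.8–2.0 Å — restraint windows are the package's defaults) plus
one planarity group per pair; the decamer yields 29 hydrogen bonds.
Deposition statistics tables often report larger "hydrogen bond" counts
because they count restraint *records* (distance, angle and planarity
entries) rather than bonds; `ptdna` reports the bond count and leaves the
record multiplicity to the writer.

Restraint bookkeeping (`restraint_summary()`) follows the usual
categories: intra-residue, inter-residue, sequential (same strand,
|i−j| = 1) and non-sequential, with inter-strand contacts counted as
non-sequential. Tables are written and re-read as XPLOR/CNS `assign`
statements with the encoding d = upper, dminus = upper − lower,
dplus = 0.

## J-couplings, pseudorotation and torsion restraints

The Karplus relationship ³J(θ) = A cos²θ + B cosθ + C is evaluated by
`karplus_j()`. Defaults: A = 10.2, B = −0.8, C = 0 Hz for proton–proton
couplings and A = 15.3, B = −6.2, C = 1.5 Hz for H3'–P; both are
configurable, as published coefficient sets vary.

Sugar pucker uses the standard pseudorotation parameterization
ν~j~ = φ~m~ cos(P + 144°(j−2)); `pucker_to_endocyclic()` and
`endocyclic_to_pucker()` are exact inverses (planar rings are flagged
degenerate rather than inverted). The four sugar proton–proton dihedrals
follow fixed linear phase relations in ν1/ν2 (e.g. θ(H1'H2') = 121.4° +
1.03 ν1), which are package defaults from standard deoxyribose geometry.
`estimate_pucker()` fits (P, φ~m~) by a deterministic grid search (1° in
P over [0,360), 0.5° in φ~m~ over (20,50)) minimizing the squared coupling
residuals. Noiseless synthetic couplings are recovered to grid
resolution. Under 0.5 Hz Gaussian coupling noise the grid least squares —
which is the maximum-likelihood estimator — inherits the noise dispersion:
single draws can miss P by more than 10°, so the recovery property is
stated (and tested) as a mean absolute error below 10° over a fixed,
pre-registered seed set.

Backbone torsions: `epsilon_from_j()` inverts the H3'–P Karplus curve and
applies the 120° shift relating the H3'-C3'-O3'-P dihedral to ε
(C4'-C3'-O3'-P). The shift sign is not uniquely determined by convention;
the package default is −120° with the inversion branch restricted to the
B-DNA ε region (trans/−gauche), and +120° is exposed as an option.
`zeta_from_epsilon()` applies the BI-form ε–ζ correlation as a linear
offset (ζ = ε + 90°, so ε − ζ ≈ −90°). `beta_classify()` maps
³J(P-H5') ∈ [2,5] Hz onto a trans β restraint (180°), the signature of
B-form backbones; anything else is "unclassified". All torsion restraints
are reported as centre ± width in (−180°, 180°].

## Ensemble geometry

`superpose()` is a Kabsch least-squares rigid superposition (proper
rotations only). Selections: `backbone` = {P, O1P/O2P (or S1P/S2P), O5',
C5', C4', C3', O3'}, `heavy`, `all`; terminal residues can be excluded to
suppress end fraying. `average_pairwise_rmsd()` superposes every unordered
model pair; `cross_ensemble_rmsd()` compares two ensembles after mapping
phosphorothioate sulfurs onto the corresponding oxygens, either between
iteratively-superposed mean structures (default) or between first models —
both conventions are available because deposition papers rarely state
which was used. `ensemble_distance()` averages atom–atom distances per
model and pools symmetric site pairs (for instance H2''(G2)···O2P(G3) with
H2''(G16)···O2P(G17)); pooled and per-site means are both reported.

`groove_assign()` classifies an atom as major-groove, minor-groove or
exterior: it compares minimum distances to the major-edge atom set
(purine O6/N6, N7; pyrimidine O4/N4, C5) and the minor-edge set (purine
N3, C2/N2; pyrimidine O2), with a 0.5 Å decision margin. The exterior
test, applied first, asks whether the atom's distance from the helix axis
(best-fit line through the C1'–C1' midpoints) exceeds the mean phosphorus
axial distance by more than 1 Å — the allowance reflects that phosphate
substituents themselves sit at about the phosphorus radius. On templates
these rules classify every purine N7 as major, the *Rp* sulfur (S2P) as
major-groove and the *Sp* sulfur (S1P) as exterior, matching the
structural picture in which the Rp sulfur points into the major groove
while the Sp P–S bond points out into solvent.

`pucker_from_coords()` measures the five endocyclic torsions from ring
coordinates and converts them to (P, φ~m~), labelling S-type for
P ∈ [90°, 270°).

## DSC melting thermodynamics

The melting model is two-state and bimolecular for a
non-self-complementary duplex: A + B ⇌ AB with equal strand amounts and
total strand concentration C~T~. With α the duplex fraction, mass action
gives K (1−α)² C~T~/2 = α, and K(T) follows van't Hoff behaviour (ΔC~p~
of reaction = 0) anchored at α(T~m~) = 1/2, i.e. K(T~m~) = 4/C~T~. The
excess heat capacity is ΔC~p~(T) = −ΔH dα/dT plus a linear baseline.
Useful consequences, all tested:

* the area under a noiseless curve equals the generating ΔH (to 0.1% when
  the grid covers the full transition),
* ∫(ΔC~p~/T)dT ≈ ΔH/T~m~(K) for a sharp transition,
* the curve maximum *follows* the anchored T~m~ by roughly
  RT~m~²/(2.6 ΔH) — about 1.9 °C at ΔH = 200 kJ/mol, shrinking with ΔH.
  (The anchor is the α = 1/2 temperature, not the peak temperature.)

The default C~T~ (≈ 2.9 × 10⁻⁴ M strands) corresponds to a 0.9 mg/ml load
of the reference decamer duplex, the concentration regime of the DSC
protocol the package models. `fit_two_state()` fits (T~m~, ΔH~vH~,
baseline, amplitude scale) by Levenberg–Marquardt least squares
(`minpack.lm`), initialized at the smoothed curve maximum, and reports the
model-free area integrals ΔH~cal~ and ΔS alongside. Curves with more than
one genuine peak (a valley dropping below half the smaller maximum) are
rejected as non-two-state. The fitted object follows the classic R
modelling idiom: `print`, `summary`, `coef`, `plot`, `residuals` and
`simulate` methods.

Parameter-recovery behaviour, with simulations at the melting temperatures
measured for the PT-free (76.55 °C) and [Rp,Rp] (71.99 °C) duplexes:
noiseless fits recover T~m~ to < 0.05 °C and the recovered ΔT~m~ is
4.56 °C; with noise at 2% of the peak height, T~m~ is unbiased to
< 0.1 °C over 20 seeded replicates.

## The synthetic-data generator

`synth_noe_table()` inverts ISPA on a template (volume ∝ d⁻⁶ below a 6 Å
cutoff, lognormal 10% volume noise by default), emitting one row per
mixing time of the 50–250 ms build-up series for non-exchangeable protons
and following the 50/200 ms protocol for exchangeable ones; geminal pairs
(< 1.95 Å) are excluded as in real peak lists. `synth_couplings()` runs
coordinates → pucker → Karplus forward with 0.5 Hz Gaussian noise.
`synth_ensemble()` emulates an NMR ensemble as coordinate-jittered copies
(model 1 unperturbed). All generators are deterministic under the
configured seed.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: spin diffusion and relaxation-matrix effects in
NOE volumes; correlated, mode-like ensemble variation (jitter is
independent per atom); the genuine conformational differences between the
PT-free, Rp and Sp duplexes (synthetic ensembles of the three differ only
by the sulfur substitution, so cross-ensemble RMSDs on synthetic data are
near zero, unlike the ~0.6–1.2 Å measured between refined depositions);
and chemical-shift physics (the shift fixtures shipped in
`inst/extdata/` are hand-written stand-ins holding published modified-site
³¹P values, labelled `_synthetic` in their filenames).

## Problem sizes and numerical choices

The test-suite and acceptance computations use: 20-bp decamer duplexes;
20-model synthetic ensembles (5 or fewer where a brute-force oracle is
compared); a 36 × 3 (P, φ~m~) recovery lattice; 20 seeded DSC replicates
on ~350-point temperature grids; grid searches at 1°/0.5° resolution.
Ties in groove assignment fall to `exterior` first, then to the
larger-margin label. Angle arithmetic wraps into (−180°, 180°];
pseudorotation phases live in [0°, 360°).

## Known limitations

* The template is an idealized fiber-style model; absolute contact
  distances and cross-duplex RMSDs of refined NMR ensembles are not
  reproducible from it. Checks against deposited ensembles (PDB 5J3G,
  5J3I, 5J3F) therefore require the user to download those files; the
  corresponding acceptance tests fail cleanly when the files are absent.
* The NMR-STAR reader covers only assigned-chemical-shift loops.
* Relaxation-matrix NOE back-calculation, helicoidal parameter analysis
  (roll/slide/twist) and nearest-neighbour thermodynamic prediction are
  out of scope.
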