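---
title: "Methods: QSAR modelling of Fab hydrophobicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QSAR modelling of Fab hydrophobicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fabqsar)
```

This vignette documents the models, numerical choices and limitations of
`fabqsar`. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The problem

Hydrophobic interaction chromatography (HIC) retention time is a widely used
proxy for an antibody's surface hydrophobicity: column binding is driven by
exposed hydrophobic patches, so retention correlates with aggregation
propensity and manufacturability risk. A QSAR model links structural
descriptors of the Fab region (the antigen-binding fragment: VH + CH1 on the
heavy chain, VL + CL on the kappa light chain) to the measured retention
time in minutes. Because surface properties are only implicit in a primary
sequence, the package supports three levels of structural representation —
sequence-derived (Seq2D), static-structure-derived (Hom3D) and
MD-relaxed-structure-derived (MD3D) descriptors — built over the same 28
substructures so the levels can be compared like for like.

## Substructure annotation

Each variable domain is numbered on the 128-position IMGT frame. The
implementation is an anchor-plus-gap-rule algorithm rather than a
profile-HMM alignment: the four conserved residues (Cys23, Trp41, Cys104
and the J-region Phe/Trp at position 118) are located by windowed scans
constrained to mutually consistent loop lengths, and loop gaps are placed
middle-out — a loop of length L occupies the first ⌈L/2⌉ and last ⌊L/2⌋
slots of its window (CDR1 27–38, CDR2 56–65, CDR3 105–117; CDR3 loops
longer than 13 residues receive insertion labels 111.x/112.x). A failed
anchor scan raises `AnchorNotFound`, which is the intended behaviour for
non-antibody input. Two simplifications are documented deliberately:
framework-1 gaps are left-padded rather than placed at IMGT position 10,
and framework-3 is treated as gap-complete (39 residues) — both are exact
for the package's fixture sequences and for the IgG1-kappa dataset layout
this workflow targets, but sequences with unusual framework deletions would
need a full numbering implementation.

Constant domains are sequence-invariant across IgG1-kappa Fabs (both chains
carry packaged allele constants: the IgG1 CH1 domain and the kappa CL
domain), so their seven β-strand windows (A–G) ship as a fixed boundary
table on those allele sequences, following the IMGT constant-domain strand
layout. `annotate_fab()` therefore always yields exactly 28 regions: 7 per
variable domain and 7 strands per constant domain.

Ambiguity codes (B, Z, X) are rejected at parse time: every descriptor
table is defined only over the 20 canonical residues, and silently dropping
residues would corrupt the region sums.

## Sequence descriptors (Seq2D)

Per variable-domain region (14 per Fab; constant domains are excluded
because their sequence descriptors would be static):

* **Scale sums** — each residue is mapped to the components of an
  amino-acid scale and components are summed over the region. Packaged
  scales: 5-component Z-scale (physicochemical), 5-component T-scale
  (topological) and 3-component MS-WHIM (electrostatic surface), giving
  14 × 13 = 182 scale descriptors.
* **Property-table sums** — scalar sums of registered per-residue tables.
  Defaults: Kyte–Doolittle hydropathy (`kd`), and three thermodynamic-style
  stand-ins — side-chain conformational entropy (`gc`), first-shell
  hydration number (`wf`) and water→octanol transfer energy (`dgw`). The
  registry is pluggable (`register_residue_table()`): the workflow is
  agnostic to the table provider, and exact numerical parity with any
  specific descriptor software is explicitly out of scope.
* **Pepstats-like block** — molecular weight (average residue masses plus
  one water), net charge at pH 7 and isoelectric point from the
  Henderson–Hasselbalch charge function with EMBOSS-style pKa values (pI by
  bisection to 1e-4 pH; the charge function is monotone so bisection is
  exact), Ikai's aliphatic index, and the EMBOSS residue-class fractions.

Summed descriptors are invariant to residue order within a region — a
documented limitation of composition-style descriptors, asserted as a
property test rather than hidden. Empty regions (possible when a numbered
CDR has length 0) emit zeros with a warning so the matrix stays
rectangular.

## Structural descriptors (Hom3D / MD3D)

SASA is computed natively by the Shrake–Rupley method: each atom's sphere
is expanded by the probe radius (1.4 Å) and sampled on a deterministic
Fibonacci lattice (default 960 points; the suite checks convergence
against denser lattices); a sample point is accessible if it lies outside
every neighbouring expanded sphere. Element radii: C 1.70, N 1.55, O 1.52,
S 1.80, H 1.20 Å; reduced one-sphere-per-residue models use per-residue
pseudo-radii sized so an isolated sphere reproduces the residue's maximum
ASA. The lattice is oriented in a body-fixed frame (weighted principal
axes with signs fixed by a weighted third moment, weights taken from an
intrinsic atom key), which makes SASA invariant under rigid motion of the
input to well below 1e-6 relative — a property the test suite asserts —
while remaining deterministic and independent of atom storage order.

Relative solvent accessibility is `RSA_i = SASA_i / MaxASA_i` with the
theoretical Gly-X-Gly maxima of Tien et al. (2013), clamped to [0, 1] with
a warning when the raw ratio exceeds 1 (real and toy structures
occasionally do). Region surface-property descriptors weight accessibility
by Kyte–Doolittle hydropathy over the two polarity groups (NPR = A, G, I,
L, M, F, P, W, V; PLR = the remaining 11 residues):

$$SP_{nonpolar} = \sum_{i \in NPR} \frac{SASA_i}{MaxASA_i} C_i^{KD},
\qquad
SP_{polar} = \sum_{i \in PLR} \frac{SASA_i}{MaxASA_i} C_i^{KD}$$

Raw cumulative SASA is emitted in three variants (all / polar / nonpolar)
alongside, because it is genuinely ambiguous whether the area-style
descriptors of this family should be hydropathy-weighted; emitting both
lets the selection stage decide. Per region that yields 5 surface
descriptors (28 × 5 = 140 columns minimum) plus the registered
property-table sums. Descriptor generation uses a single structure per
sample (for the MD3D level, the final trajectory frame); multi-frame
averaging is a documented possible extension, not a default.

## Trajectory analytics

Trajectories are consumed (multi-MODEL PDB or a plain xyz text format),
never produced. Superposition is the Kabsch SVD solution restricted to
proper rotations; near-collinear selections are rejected
(`DegenerateSelection`). RMSD series superpose each frame on the reference
before measuring. RMSF aligns all frames to their mean structure (two
iterated passes) and reports per-atom root-mean-square deviation from the
mean. Essential motions are the eigenpairs of the 3N × 3N covariance of
superposed coordinates — unweighted, not mass-weighted (a documented
choice; with Cα-level selections mass weighting is a constant factor). The
square root of the leading eigenvalue is reported as the magnitude of the
dominant collective motion. Region SASA series apply the single-frame
engine per frame; the interval difference statistic
`|mean(t < split) − mean(t ≥ split)|` (default split 5 ns) quantifies how
much a region's exposure settled after initial relaxation.

Because superposition removes rigid-body motion, only the component of a
planted displacement orthogonal to the six rigid modes is recoverable —
the test suite constructs its oracles accordingly (and for planar toy
geometries even a sign flip is a proper rotation, which is why the test
fixtures are non-planar).

## Model development

The engine reproduces a standard chemometrics pipeline; every stage that
learns parameters learns them from the calibration partition only.

1. **Variance filter**: descriptors with sd < 1e-4 are removed (boundary
   kept).
2. **Kennard–Stone (CADEX) split**: on autoscaled descriptors, seed with
   the two most distant samples, then repeatedly add the sample maximising
   its minimum Euclidean distance to the selected set, to 80% calibration.
   Ties break to the lowest row index, making the split fully
   deterministic. Stratified mode runs the procedure per class with
   largest-remainder rounding so the global 80/20 ratio is preserved —
   used for the species-classification experiment.
3. **V-WSP reduction** (calibration only): descriptors are ranked by
   absolute correlation with the first principal axis; walking down the
   ranking, each retained descriptor discards all remaining descriptors
   correlated with it above the threshold (default |r| ≤ 0.95 for every
   retained pair; threshold 1 is a no-op).
4. **Consensus GA-PLS** (calibration only): a binary chromosome encodes
   descriptor inclusion; fitness is the cross-validated RMSE of a NIPALS
   PLS model, with the latent-variable count chosen by the same CV up to
   min(10, p) — all component counts are evaluated in one decomposition
   pass per fold, which is what makes the GA affordable. GA settings:
   population 64, ≤100 generations, per-gene mutation 0.005, two-point
   crossover, tournament selection with single-model elitism, 30% initial
   inclusion, early stop when ≥50% of the population shares the best
   fitness. The GA runs 10 times from distinct seeds; the consensus keeps
   descriptors selected by ≥50% of the run winners (threshold
   configurable; an empty consensus falls back to the best single run).
   Fitness values are cached across generations by chromosome, which
   matters once the population converges.
5. **ε-SVR grid search**: C over 10^(−5..4) and ε over 10^(−3..1) in
   half-decade steps — 90 permutations — each evaluated by 5-fold CV
   repeated 20 times with seeded shuffled fold assignments; the pair with
   the lowest mean CV RMSE wins (ties to smaller C, then smaller ε).
   Classification mode (C-SVM, LibSVM via e1071) searches C only and
   maximises the cross-validated multiclass MCC.
6. **Diagnostics**: R² = 1 − SS_res/SS_tot (negative when predictions are
   worse than the mean — deliberately not clamped), RMSE, the generalised
   (Gorodkin) multiclass MCC with per-class sensitivity and specificity,
   Y-randomisation (50 scrambles by default, retrained at the final
   hyperparameters), learning curves grown in Kennard–Stone selection
   order at the final hyperparameters (the full-size point is
   fold-for-fold identical to the final model's CV), and a Student-t
   predictive interval `t(1−α/2, n−1)·sd(residuals)·sqrt(1 + 1/n)` on test
   residuals. Complete-linkage HCA and exploratory PCA support outlier
   inspection.

### The ε-SVR solver

The linear ε-insensitive regression problem is solved by deterministic
dual coordinate descent (one box-constrained dual variable per sample,
cyclic sweeps with a fixed xorshift in-sweep permutation, projected-
gradient tolerance 1e-6; the bias enters as a weakly regularised augmented
feature on the centred response). Generic SMO solvers slow down by orders
of magnitude at the weakly regularised corner of this grid (C = 10³–10⁴
with a linear kernel), which would make 90 × 100 cross-validation fits
impractical; coordinate descent on the linear dual does not. The test
suite cross-checks the solver against LibSVM (e1071) predictions at
moderate C. Two numerical details: cross-validation fits run on a reduced
budget (200 sweeps, tolerance 1e-4) — the CV RMSE surface is stable to
about 2% against a 10× budget and hyperparameter rankings are unchanged —
while final refits use the full budget; and with a large ε every sample
can sit inside the insensitivity tube, in which case the solution is the
constant mean model, which is exactly what the solver returns.

## The synthetic-data generators

The generators define the package's study conditions; they are test
infrastructure of equal standing with the analysis code.

* **Fab sequences**: gap-complete V domains with correct anchors, CDR
  lengths drawn per region (H3 6–20; H1/H2/L1/L3 5–12; L2 fixed at 3, as
  in kappa light chains), random loop residues excluding Cys/Trp so the
  anchor scans stay unambiguous, constant domains appended. Every
  generated Fab annotates to 28 regions by construction.
* **Toy structures**: one pseudo-atom per residue in extended, helical or
  sphere-cluster geometry (default spacing 5 Å). Chemically naive but
  geometrically valid; pseudo-radii reproduce each residue's maximum ASA
  when isolated, so an extended tripeptide's central residue has RSA near
  (not exactly) 1.
* **Trajectories**: base coordinates plus i.i.d. Gaussian noise, with an
  optional linear drift of a labelled atom subset from a start frame to a
  programmed magnitude — emulating the gradual domain-shift phenomenology
  seen in a minority of Fab simulations. Default 51 frames × 1 ns
  (0–50 ns, split at 5 ns): the full 40-ps sampling of a production run is
  deliberately not reproduced; the statistics of interest (plateau, drift,
  interval difference) are invariant to the thinning.
* **Regression matrices**: standard-normal descriptors, sparse linear
  signal (defaults n = 80, p = 50, 5 informative, coefficients 1, noise
  sd 0.1), optional collinear pairs (|r| ≈ 0.98 by construction), optional
  right-skewed response, and an optional class-structured confounder: the
  response is formed first, then per-class offsets (3 classes, strength
  1.5) are added to the informative columns. That is systematic variation
  correlated with a class label but not with the response — the mechanism
  by which composition-sum descriptors encode antibody species — and it
  lets a classifier recover the class from the descriptors while the
  regression's external performance degrades relative to the clean
  generator. The effect is checked qualitatively (classifiable at
  MCC ≥ 0.7; regression test R² strictly worse than clean), not against
  any numeric target.

What passing these tests shows — and does not show. The generators plant
linear, additive signal in homoscedastic Gaussian descriptors; real
descriptor–retention relationships are partly non-linear, heteroscedastic
and collinear in structured ways, and real HIC datasets are small and
right-skewed. Success on the generators validates the machinery
(selection recovers a recoverable support; validation statistics behave as
designed), not the biological accuracy of any particular fitted model.

## Degenerate inputs and tie-breaking

Duplicate samples are permitted in Kennard–Stone (ties to lowest index);
constant responses are rejected (`DegenerateResponse`); collinear atom
selections are rejected in superposition; rank-deficient PLS caps its
components with a warning; a V-WSP threshold of 1 retains everything; a
single-descriptor table short-circuits GA-PLS. All stochastic stages
(fold assignments, GA populations, permutations, generators) are seeded
explicitly and reproduce byte-identical results under a fixed seed.

## Known limitations

* The IMGT implementation targets IgG1-kappa Fabs: no lambda chains, no
  Kabat/Chothia numbering, simplified FR1/FR3 gap handling.
* Sequence descriptors are composition sums — order-blind within regions.
* SASA parity with any specific MD package's implementation (radii sets,
  point densities) is not attempted; within-package convergence and
  invariances are what the tests guarantee.
* Homology modelling and MD simulation are out of scope: structures and
  trajectories are consumed, never produced.
* The problem sizes used by the test suite and acceptance script (e.g.
  ten seeds of the n = 80 generator; 10 Y-randomisation scrambles there
  versus the 50-scramble package default) are the package's own choices
  for routine verification; all are configurable upward.
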