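---
title: "Methods: chemometrics of DPDA TRPV1 antagonists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemometrics of DPDA TRPV1 antagonists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpdaqsar)
```

## Scope and scientific setting

TRPV1 is a tetrameric cation channel whose vanilloid pocket, located
between adjacent subunits, binds both agonists (capsaicin,
resiniferatoxin) and antagonists (capsazepine).  The
5,5-diarylpentadienamides (DPDAs) are a series of 64 antagonists built
from a heterocyclic *head* (isoquinoline in series A,
3-hydroxy-3,4-dihydroquinolin-2(1H)-one in series B, other bicycles in
series C), a pentadienamide *neck*, and aryl *tails* at the 5-position.
This package implements the chemometric layer used to rationalize their
antagonism from docked complexes and the activity table: topological
QSAR, pose comparison, interaction fingerprints, and the
vanilloid-pocket distance rule.  Docking itself (pose generation,
protonation, receptor preparation) is out of scope: the functions
consume structures and pose files, they do not produce them.

## The activity fixture and reconstructed structures

`load_paper_dataset()` returns the 64-compound table (experimental and
model-predicted log(1/IC50), IC50 in nM against human TRPV1; Glide XP
scores in kcal/mol; 52/12 training/test flags) from a versioned CSV
whose md5 checksum is verified at load time.  The source table prints
substituent *names*, not structures, so SMILES are reconstructed in
code from the series scaffolds plus a substituent-name lookup
(`dpda_smiles()`), and the dataset carries
`attr(d, "smiles_source") == "reconstructed"`.  R enantiomers are
encoded for the stereocentres in series B and the two series C
tetrahydroquinolinols, reflecting that only the R forms were modelled.
No deposited coordinates or SMILES exist to verify the reconstruction
against; descriptors computed from these structures are therefore
internally consistent but not certified against the original
descriptor software's inputs (see "The fixture model" below).

## Molecular graphs and atomic properties

Descriptors operate on the hydrogen-suppressed graph: hydrogens carry
no autocorrelation signal under the conventions used here, and
suppressing them is the standard choice for this descriptor family.
Topological distances are bond counts from breadth-first search.  For
formats without bond records (PDB ligands) bonds are perceived by a
covalent-radius criterion with a 0.45 Å tolerance — generous enough for
cryo-EM-quality coordinates, tight enough not to fuse contacts into
bonds.

The four atomic properties (mass *m*, van der Waals volume *v*,
Sanderson electronegativity *e*, polarizability *p*) are shipped as a
documented CSV (`inst/extdata/atomic_properties.csv`) using the
standard handbook tabulation.  The default `carbon_scaled` mode divides
each property by its carbon value, the convention of the classic
descriptor programs; `raw` mode is kept for sensitivity checks.  The
exact constants inside the original (closed-source) descriptor software
are not public, so the handbook values are this package's documented
stand-in.

## The 2D autocorrelation descriptors

At lag *l* ∈ 1…8 and property *k*:

* `ats()` — Broto–Moreau autocorrelation: the sum of
  p<sub>ki</sub>·p<sub>kj</sub> over *unordered* atom pairs at
  topological distance *l*; 0 when no pair exists.  No logarithmic
  transform is applied.
* `mats()` — Moran's index, with the numerator averaged over the 2L
  ordered pair terms and the denominator the *mean squared* deviation.
* `gats()` — Geary's coefficient, with the squared-difference numerator
  over unordered pairs and the (N−1)-denominator variance.

Two printed-formula issues were resolved in favour of the canonical
Moran/Geary statistics: journal typesettings of these equations
commonly drop the square on the denominator deviations (which would
make the denominator sum to zero identically) and print the Moran-style
cross-product in the Geary numerator.  The standard forms are
dimensionally consistent, reduce to the textbook spatial statistics,
and give the exact closed-form values −1 (Moran) and +1 (Geary) for a
two-atom heteronuclear graph at lag 1 — both asserted in the tests.
For audit, `as_printed = TRUE` evaluates the literal printed variants.

Cells where no pair exists at the lag, or where the property is
constant over the molecule, are *flagged undefined* (`NA`), never
silently zeroed; the filter stage then treats such columns as
uninformative.  `descriptor_block()` always emits the full 96-column
census (3 families × 4 properties × 8 lags) in deterministic
family–property–lag order.  Correctness is established against an
independent brute-force pair-enumeration oracle on random graphs
(4–12 atoms, 50 graphs × 96 descriptors, 10⁻¹⁰ relative tolerance) and
by invariance under atom relabeling.

## QSAR modelling

`filter_descriptors()` removes undefined/constant columns, then prunes
collinear pairs (pairwise squared Pearson > 0.90) greedily in canonical
column order, discarding the lower-variance member; variance ties break
by column name so the result is deterministic.

`fit_mlr()` is ordinary least squares with the usual reporting
conventions: R², regression standard deviation *s* with an n−k−1
denominator, and the F statistic with (k, n−k−1) degrees of freedom.
`loo_q2()` computes leave-one-out Q² = 1 − PRESS/SS<sub>tot</sub> via
the hat-matrix identity; the tests pin the shortcut to an explicit
refit-per-observation loop at 10⁻¹⁰.

`ga_select()` evolves fixed-size descriptor subsets (default 6, the
size of the published model; exposed as `model_size` since the original
size-selection protocol is not documented).  Fitness is the mean
squared error of the OLS fit; operators are tournament selection
(size 3), uniform crossover of the two parents' gene pools (the
published operator is unspecified; uniform is the natural choice for
set-encoded chromosomes and is configurable), single-point mutation
(swap one descriptor for an outsider, rate 0.3) and one-elite survival.
The stop criterion is population convergence — at least
`convergence_fraction` (default 90%) of chromosomes sharing the best
fitness — which is how this package reads the original "90% of the
generations reached the same target fitness" phrasing, the literal
wording not being actionable; a `max_generations` cap (default 150)
guards non-convergence, and at the default mutation rate it is the cap
that usually terminates the search (a steady ~30% of each generation is
freshly mutated, so the 90% share is rarely reached).  The search is
deterministic given `seed`.  Defaults were fixed by planted-model
recovery experiments: with 52 training rows, 96 block-correlated
candidates and activity noise σ = 0.1, the planted 6-descriptor subset
is recovered in 20/20 seeds in about 45 s total.

`y_scramble()` reruns the *full* pipeline (filter → GA → OLS → LOO →
external test) on permuted activities.  Note an important statistical
point: the scrambled *training* R² does not collapse to k/(n−1),
because re-running subset selection on noise picks the best-fitting 6
of ~90 candidates — the expected maximum R² is then ≈ 0.5 at this
problem size.  Chance correlation is instead diagnosed where selection
cannot help: the scrambled Q² and external R²<sub>test</sub> collapse
(measured means ≈ 0.34 and ≈ 0.06 against ≈ 0.999 for the true
model), and a *fixed* planted model refit on scrambled responses drops
to R² ≈ k/(n−1) ≈ 0.12.  Both views are exercised in the tests and the
acceptance script.

### The fixture model

The published six-descriptor activity model
(4.76·ATS1m + 32.3·MATS1e + 6.42·MATS7e + 3.07·MATS8e + 14.9·MATS1p −
5.62·GATS5e − 12.7; N = 52, R² = 0.674, s = 0.586, F = 15.5,
Q² = 0.549) is packaged as a literal `qsar_model` (`eq1_model()`)
usable with `predict()`.  Its coefficients are **not** re-derived here:
they are tied to the original descriptor software's internal property
constants and possible transforms, which are not published, so exact
coefficient reproduction is not a meaningful target.  What *is*
reproduced from the packaged table are the model's external statistics:
training R² 0.674, test R² 0.788, the residual distribution and the
B11ab outlier (|residual| = 1.5).  One discrepancy is worth recording:
recounting residual bins from the printed experimental/predicted
columns yields 9 training compounds in [0.5, 0.75), not the 8 stated in
the source narrative; no bin-edge or rounding convention reconciles the
two, so the package reports the recount.

## Pose comparison

`mcs_match()` finds a maximum common *connected induced* subgraph by
exact branch-and-bound backtracking — adequate for DPDA-sized ligands
(≤ 40 heavy atoms); a node limit aborts with an explicit error rather
than silently approximating.  Strict mode requires element equality;
flexible mode additionally lets {C, N, O, S} ring atoms of equal degree
substitute for one another, the package's interpretation of treating
pyridinyl/pyrimidinyl nitrogens as equivalent to phenyl carbons (the
original tool's exact equivalence rules are unpublished; the rule is
configurable in code).  %Ref and %Mol match are the matched-atom count
as a percentage of each molecule's heavy atoms.

`pose_rmsd()` reports *in-place* heavy-atom RMSD over the matched
atoms — docked poses share the receptor frame, so no superposition is
applied — minimized over all maximum-size matchings, which makes it
symmetry-aware (a relabeled benzene ring scores 0).  Ties among
equal-size substructures resolve to the minimal-RMSD mapping.  A
least-squares (Kabsch) superposition is available behind an explicit
flag only.  `fragment_rmsd()` restricts the reference to a connected
atom selection (neck, head) and requires the whole fragment to match.

## Interaction fingerprints

`detect_contacts()` records a contact (C) for any residue with a heavy
atom within 4.0 Å of a ligand heavy atom, sub-typed polar (both atoms
N/O/S), hydrophobic (both carbon), aromatic (both atoms ring members,
with protein aromatic atoms named per residue type) and charged
(formally charged residue group near a polar ligand atom).  The
backbone/side-chain label follows the closest contacting residue atom;
backbone atoms are N/CA/C/O(/OXT) of standard residues.  The atom-class
rules live in `ifp_atom_classes()` as a documented, overridable
configuration, since the reference implementation's internal typing is
not public.

`detect_hbonds()` applies the geometric criteria H⋯A ≤ 2.5 Å, donor
angle (D–H⋯A, at the hydrogen) ≥ 120.0°, acceptor angle (H⋯A–antecedent,
at the acceptor) ≥ 90°; all three comparisons carry a 10⁻⁶ tolerance so
exactly-at-boundary geometries are accepted.  The residue role is D
when the residue donates the hydrogen, A when it accepts.  When
explicit hydrogens are absent, idealized donor hydrogens are placed
deterministically: secondary-amide N–H in-plane opposite the
heavy-neighbour bisector (1.01 Å), hydroxyl O–H (0.96 Å, tetrahedral
angle) with the rotatable orientation scanned in 30° steps and the
orientation closest to an opposing polar atom kept.  Only plausible
donors are protonated — carbonyl/carboxylate oxygens and ether oxygens
never receive a hydrogen.

`aggregate_ifp()` counts, per residue and category, the fraction of
complexes showing the interaction (a complex counts once per
residue–category regardless of how many atom pairs realize it — the
package's reading of occurrence percentages) and enforces that a
hydrogen bond implies a contact for the same residue.

## The distance rule

`measure_distances()` resolves named atom selectors (chain/residue/atom
or ligand atom) to unique atoms — ambiguity is an error naming the
spec — and reports Euclidean distances at 0.1 Å precision.
`antagonist_rule()` pairs receptor-side D1–D3 with ligand-side d1–d3 by
numeric suffix and returns per-pair booleans D<sub>i</sub> >
d<sub>i</sub> plus the verdict: compatible (antagonist-bound-like,
closed-state) only if every supplied pair passes.  Series A ligands
define only d1, so a single-pair verdict is legitimate; the
agonist-bound conformation characteristically fails the D3/d3 pair.

## Synthetic data: what it emulates, and what it does not

`gen_planted_qsar()` mirrors the modelling scale of the study —
64 compounds × 96 candidate descriptors, 6 true descriptors, 52/12
splits — with block-correlated Gaussian descriptors (blocks of 8,
within-block correlation 0.5, i.e. pairwise r² = 0.25, safely below the
0.90 collinearity cut), coefficients of magnitude 1–3 with random sign,
and additive Gaussian activity noise (default σ = 0.1).  Gaussian noise
is an explicit modelling choice; the original data's error model is
unknown.  Real descriptor tables differ in ways the generator does not
emulate: heavy-tailed and discrete columns, lag-structured correlation
far above 0.25, and activity noise correlated with chemical series.
Passing the planted-recovery tests therefore demonstrates that the
machinery is correct and well-conditioned at the study's scale, not
that a 6-descriptor model is recoverable from any real 64-compound
series.

`gen_toy_complex()` builds a minimal amide ligand
(CH₃–C(=O)–NH–CH₃, explicit amide hydrogen) and places one residue per
prescribed interaction along well-separated icosahedral directions,
constructing hydrogen-bond geometry (H⋯A distance, donor angle,
acceptor angle) exactly; placements are validated post hoc — steric
clash or a missed prescribed distance raises an "unsatisfiable
prescription" error rather than returning a subtly wrong complex.  Toy
complexes exercise the detector's geometry and bookkeeping; they do not
emulate real binding-site density, water, or multi-residue
cooperativity.

`gen_perturbed_pose()` applies a rigid rotation/translation and
i.i.d. per-coordinate Gaussian noise; over replicates the expected
RMSD is σ√3, which the tests check within 10% over 100 replicas.

## Numerical conventions and degenerate inputs

* Undefined descriptor cells are `NA`, and any column containing them
  is dropped by the filter, not imputed.
* Boundary comparisons: contact cutoff and hydrogen-bond criteria use
  inclusive thresholds with a 10⁻⁶–10⁻⁹ absolute guard for floating
  roundoff; lag-with-no-pairs yields ATS = 0 but MATS/GATS = `NA`.
* Rank-deficient regression matrices, empty filtered tables,
  disconnected heavy-atom graphs (salts), unknown elements, ambiguous
  distance selectors and sub-3-atom common substructures are all
  explicit errors, never silent results.
* All stochastic components (GA, generators, scrambling, splits) run
  inside a seed-scoped RNG that restores the caller's random state.

## Problem sizes used in the shipped checks

The test suite and acceptance script run at the study's own scale where
that is cheap (64 × 96 descriptor tables, 52-row fits, 20-seed GA
recovery ≈ 45 s) and at reduced scale for the heavily iterated unit
tests (40 × 15–20 tables with population 40, 60 generations), sizes
chosen so the full suite completes in a few minutes while still
exercising every code path at realistic dimensionality.

## Known limitations

* Reconstructed SMILES cannot be verified against deposited structures;
  attachment-point choices within the head groups follow the series
  descriptions but are not certifiable.
* The published model's coefficients are a fixture, not a reproduction
  target (descriptor-software conventions unpublished).
* Flexible-mode atom equivalence and the interaction atom-class rules
  are documented interpretations of unpublished tool internals.
* The exact MCS search is exponential in the worst case; highly
  symmetric molecules beyond ~40 heavy atoms hit the node limit by
  design.
* Figure-level quantities that depend on the original docked pose
  ensemble (per-compound pose RMSDs, per-residue occurrence
  percentages of the real complexes, crystal-structure D distances) are
  not reproducible without those inputs; the package validates the
  operators on constructed geometries instead.
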