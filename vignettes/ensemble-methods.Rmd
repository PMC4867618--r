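---
title: "Models and methods behind nmrens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nmrens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrens)
```

`nmrens` analyzes solution-NMR ensembles of proteins that mix a folded
core with long disordered segments — the motivating system is the isolated
histone H2A–H2B heterodimer, whose histone-fold core is flanked by three
~30-residue tails. This vignette explains the models each stage
implements, the defaults and why, the numerical choices, and what the
synthetic-data generators do and do not emulate.

## Residue addressing and containers

A model is a plain data.frame of atom records; an ensemble
(`nmr_ensemble`) stores one shared atom table plus a coordinate array, so
the invariant "every model has the same atoms in the same order" holds by
construction and is validated with a named first-discrepancy error when
ensembles are assembled from files. Residue numbers are bare integers and
may be zero or negative: expression constructs routinely leave cloning
scars numbered Met0 or Gly(−3), and histone tail numbering depends on
them. Insertion codes are deliberately unsupported; supporting them would
complicate every downstream window operation for a case that does not
arise in this problem class. Only the first alternate location is kept,
with a warning. The NMR-STAR reader interprets exactly one construct — the
atom-shift loop of a BMRB-style deposition — because nothing else in the
grammar is needed to feed this pipeline; column layouts of real
depositions should be checked against it before use.

## Chemical shift index

The secondary shift Δδ = δ_obs − δ_rc measures the deviation of a backbone
shift from its residue-specific random-coil value (a Wishart-style
reference table ships with the package and can be swapped). Cα shifts
move downfield (+) in helices and upfield (−) in strands; Cβ moves the
other way. The composite Δδ(Cα) − Δδ(Cβ) doubles the separation between
the two classes while cancelling part of the referencing error, which is
the standard way to combine the two nuclei into one bar-graph statistic.
The index is +1 when the composite strictly exceeds +0.7 ppm, −1 below
−0.7 ppm, else 0. The 0.7 ppm default is the conventional dead band for
composite Cα/Cβ indices: small enough to catch fractional helicity,
large enough that referencing offsets (typically ≤ 0.3 ppm) do not
produce spurious calls. It is configurable. Missing atoms contribute zero
(glycine has no Cβ, so its call rests on Cα alone); no sequence-dependent
neighbour corrections are applied. Per-atom Δδ tracks are returned
alongside the composite so either can be plotted.

## Geometric secondary structure

`assign_ss()` is a Kabsch–Sander implementation: a backbone hydrogen bond
is called between an amide donor and a carbonyl acceptor when the
electrostatic energy

E = 0.084 · 332 · (1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) kcal/mol

falls below −0.5 kcal/mol. Amide hydrogens are built geometrically when
absent (1.0 Å from N, along the preceding C=O direction, the classic
convention that makes X-ray and heavy-atom-only models assignable);
prolines never donate. α-helix (H) needs two consecutive i→i+4 turns,
3₁₀ (G) two i→i+3 turns, strand (E) a bridge inside a ladder, isolated
bridges stay B, any 3/4/5-turn interior is T, and a Cα(i−2)–Cα(i)–Cα(i+2)
angle above 70° is a bend (S). Overlaps resolve with priority
H > G > E > B > T > S > C. Donor–acceptor pairs adjacent in sequence are
excluded, a 9 Å Cα cutoff bounds the search, and chain breaks (numbering
gaps or C–N distance > 2.5 Å) cut all patterns. Residues missing backbone
atoms are assigned C with a warning rather than erroring, so sparse tails
do not kill an ensemble run. The test suite checks the assignment against
an independent reference implementation (mdtraj's DSSP) — exact agreement
on ideal helices and hairpins, ≥ 95% across a perturbed battery, with
disagreement allowed at element boundaries where the bond energies sit on
the cutoff.

Ensemble propensity is the per-residue class frequency across models.
Element definition takes maximal runs whose helix (H, optionally + G — the
system of interest has a 3₁₀ segment, so H+G is the default) or strand
(E+B) propensity *strictly exceeds* a threshold, 0.8 by default: with a
10-model ensemble that reads "9 or 10 models agree", and strictness
matters because 8/10 is exactly 0.8. Runs shorter than 3 (helix) or 2
(strand) residues are dropped as physically meaningless.

## Ensemble geometry

Superposition is the Kabsch least-squares fit over selected Cα atoms,
computed by SVD with the determinant correction so the result is always a
proper rotation; collinear selections are rejected because the rotation
about the line is undetermined. RMSF uses two rounds of iterative
superposition onto the ensemble mean rather than onto model 1 — the mean
reference is order-invariant, which the tests exercise; alignment onto the
first model is available as a flag for exact mimicry of published figures
that used it.

The window distance d(Cα_{i−4}, Cα_{i+4}) summarizes local chain shape in
one number per residue: a straight chain at the 3.8 Å Cα spacing gives
exactly 30.4 Å, an ideal extended strand ~27.6 Å, an ideal α-helix
~12.8 Å, and values well below the extended reference flag bends in
otherwise disordered segments. The half-window of 4 is the convention for
this metric and is configurable; ensemble profiles report the per-residue
mean over models (with min/max), since an averaged bend signal is what
distinguishes persistent local structure from one-off conformers. One
calibration caveat is worth stating plainly: the commonly quoted
"~11 Å for helices" is looser than what ideal geometry produces. A
mathematically ideal straight helix (φ = −57°, ψ = −47°, rise 1.5 Å,
radius ~2.3 Å) gives 12.3–12.8 Å for the i−4 → i+4 distance, and DSSP
helix interiors of real crystal structures measure 12.3–12.4 Å; 11 Å
corresponds to a 7-step (i−4 → i+3) window. The package reports what the
geometry gives.

Backbone accessible surface area uses Shrake–Rupley sphere sampling with a
1.4 Å probe, 960 deterministic points per atom (a golden-spiral set, so
results are reproducible without an RNG), and vdW radii N 1.55, C 1.70,
O 1.52, S 1.80 Å; amide hydrogens are excluded from the backbone set. The
sampling error of the per-model total is well under 2% versus a 4000-point
reference, and the per-atom areas match the analytic two-sphere
intersection formula. Relative exposure divides by a per-residue-type
reference maximum computed from an extended Gly-X-Gly-style tripeptide
built with the package's own ideal geometry — note that a residue with no
neighbours at all therefore scores above 1, since nothing occludes the
peptide-bond faces that the reference tripeptide covers.

## Chemical-shift rescoring and model selection

The shift-agreement statistic is χ² = Σ ((δ_pred − δ_obs)/σ)² over all
matched (chain, residue, atom-type) keys of the six backbone nuclei, with
σ the predictor's per-value uncertainty; unmatched keys are ignored and
the matched count is reported so sparse overlap is visible. The rescored
energy is E_CS = E + c·χ² with c = 0.25. Shift prediction itself is a
pluggable function (any `model → shift table` callable); a table-lookup
predictor ships for tests, keeping predictor internals out of scope.

Selection is the two-stage rule: the single lowest-E_CS model anchors the
Cα-RMSD axis (RMSD after Kabsch superposition, optionally restricted to
core residue ranges, since disordered tails would otherwise dominate);
the 20 lowest-E_CS models form the pool; the 10 lowest-RMSD pool members
are returned. The reference is fixed as the global lowest-E_CS model and
not recomputed after pooling — with the pool defined by energy, its
lowest-energy member is the same model, so the distinction never changes
the anchor, and fixing it keeps the rule a pure function of the table.
All ties break deterministically by (E_CS, then model id), an invented but
explicit convention; the tests verify equivalence with a brute-force
enumerate-and-sort oracle on random pools and the monotonicity property
that improving a selected model's energy can never eject it. Tail-model
choice is the χ² argmin per core, ties to the lowest id.

## Exchange dynamics

**H/D protection.** After transfer to D₂O, each residue is classified by
the latest spectrum in which its amide signal is still identifiable;
absence already at the first timepoint means fast exchange. Observation
sets should be prefix-closed in time; violations (noise flickers) produce
a warning and classification by the latest sighting, which errs toward
calling a residue protected.

**Fast exchange.** The forward model is a two-site Bloch–McConnell
treatment of the amide proton: starting from zero after the readout, it
recovers toward equilibrium at rate R1 while exchanging with water at
k_ex. Under water saturation the water term is zero and

I_sat(d) = I_eq · R1/(R1+k_ex) · (1 − e^{−(R1+k_ex)d});

without saturation water recovers as w(t) = 1 − a·e^{−R1w·t} and the
linear ODE solves to

I_nosat(d) = I_eq · (1 − e^{−(R1+k_ex)d} − a·k_ex·(e^{−R1w d} − e^{−(R1+k_ex)d})/(R1+k_ex−R1w)),

with the removable singularity at R1w = R1+k_ex handled explicitly. The
limits anchor the transcription: k_ex = 0 makes the two conditions
coincide, permanently saturated water collapses the unsaturated curve onto
the saturated one, and instantly recovered water removes the exchange
penalty. One function implements the model; the generator and the fitter
both call it, so parameter-recovery tests are self-consistent. The water
parameters (a, R1w) are estimated from the measured water intensities when
present; the defaults a = 0.3, R1w = 1 s⁻¹ describe a band-selective
(BEST-type) readout, which by design leaves water mostly at equilibrium —
that is why the experiment records the water signal at each delay: to
correct the residual dip, not a full saturation recovery.

Fitting is bounded nonlinear least squares (Levenberg–Marquardt via
minpack.lm) in (k_ex, R1, I_eq) over both conditions jointly, with five
k_ex starts spanning the sensitive window to avoid local minima, and
relative (1/intensity) residual weighting by default — the
maximum-likelihood choice when intensity errors scale with the signal;
absolute weighting is available. Fits outside 0.1 < k_ex < 10 s⁻¹ are
flagged `in_window = FALSE` rather than suppressed, supporting both
readings of "too fast to fit" bars in published profiles. Non-convergence
returns a flagged record. Residues adjacent to Ser/Thr can show inflated
apparent rates through hydroxyl-relayed NOE; `flag_st_neighbors()` marks
them for exclusion instead of attempting an automatic correction.

**Heteronuclear NOE.** The ratio I_irr/I_unirr classifies backbone ps–ns
dynamics: negative values flexible, above 0.5 rigid (strictly — 0.5 itself
is intermediate), between the two intermediate. Thresholds are arguments.
Region summaries collapse per-residue classes into maximal runs with a
minimum length.

## Synthetic data: what it emulates, what it does not

The generators produce every input with known ground truth: peptides built
from ideal bond geometry (Engh–Huber-style lengths and angles) with
per-class dihedrals H (−57, −47), E (−135, +135) and coil sampled from the
broad β/PPII basin (φ ∈ [−180°, −60°], ψ ∈ [60°, 180°]) under a 2.5 Å
Cα-clash rejection; ensembles as Gaussian coordinate perturbations with
separate core/tail amplitudes; shift tables as random-coil + class offsets
(H: +2.8/−0.5 ppm, E: −1.5/+2.2 ppm for Cα/Cβ — textbook mean secondary
shifts) + Gaussian noise; saturation-transfer tables straight from the
forward model with multiplicative noise; and scored model pools with
configurable energy and coordinate-noise laws. All generators are pure
functions of (spec, seed) and restore the caller's RNG state.

Limits worth knowing. Gaussian perturbation of one conformer emulates a
tight core well but a disordered tail only crudely: real tail ensembles
decorrelate along the chain, so tests that need genuinely independent tail
conformations build each model with its own seed instead. The coil basin
deliberately excludes the α region, so synthetic "random coil" is
extended-ish and produces few DSSP bends/turns — useful as a null model,
but it cannot reproduce the bend-rich tails seen in real ensembles of this
system, and passing tests on it says nothing about such structure in real
data. Peptides carry no sidechains beyond Cβ, so ASA values are
backbone-meaningful only. Shift simulation ignores neighbour effects and
ring currents. Problem sizes used in the tests (20–60-residue peptides,
10-model ensembles, 1000-model score pools, 100-residue exchange panels)
were chosen as the smallest sizes at which every statistic of interest is
stable; all complete in seconds on one CPU.

## Known limitations

Full NMR-STAR parsing, π-helix and PPII detection, sidechain ASA,
protection-factor thermodynamics (ΔG_HX) and any shift-prediction
implementation are out of scope. The ~11 Å helix reference discussed
above should be read as a rounded field convention, not a number ideal
geometry can reproduce. The H/D classifier works on identifiability bars,
not intensities — it cannot distinguish slow exchange from overlap-caused
disappearance.
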