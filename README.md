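# nmrens

Chemical-shift and dynamics analysis of solution-NMR structure ensembles,
built around the workflow used to characterize the isolated histone
H2A–H2B heterodimer: a folded histone core flanked by long disordered
tails, studied through backbone chemical shifts, an ensemble of calculated
models, and three amide hydrogen-exchange/NOE experiments.

The package is for structural biologists who have (i) a multi-model
structure ensemble (PDB/mmCIF), (ii) backbone chemical-shift tables, and
(iii) per-residue amide intensity tables, and want the standard per-residue
descriptors that connect them.

## What it computes

**Chemical shift index (CSI).** Secondary shifts Δδ = δ_obs − δ_rc for Cα
and Cβ are combined into the composite Δδ(Cα) − Δδ(Cβ) and thresholded
(default 0.7 ppm): index +1 marks helix-like residues, −1 strand-like,
0 coil (`csi_profile()`).

**Geometric secondary structure.** A Kabsch–Sander assignment
(`assign_ss()`) from the backbone hydrogen-bond energy
E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) kcal/mol (bond when
E < −0.5), aggregated over an ensemble into per-residue class propensities
(`ensemble_propensity()`) and helix/strand elements defined by a strict
propensity threshold (`define_elements()`, default > 0.8).

**Ensemble geometry.** Kabsch superposition with explicit
rotation/translation (`superpose()`), per-residue Cα RMSF after iterative
alignment to the mean structure (`ca_rmsf()`), the bend metric
d(Cα_{i−4}, Cα_{i+4}) — ~12–13 Å inside an α-helix, ~28 Å in an extended
strand, low values flag bends in disordered tails
(`ca_window_distance()`) — and Shrake–Rupley backbone accessible surface
area with Gly-X-Gly-referenced relative exposure (`backbone_asa()`).

**Chemical-shift model selection.** χ² = Σ ((δ_pred − δ_obs)/σ)² over
matched shifts (`chi2_shift_agreement()`), the rescored energy
E_CS = E + c·χ² with c = 0.25 (`rescore()`), and the two-stage rule that
keeps the 10 lowest-Cα-RMSD models out of the 20 lowest-E_CS models
(`select_core_models()`), plus the per-core χ² argmin used for tail models
(`select_tail_model()`). Shift prediction is pluggable
(`lookup_predictor()`).

**Exchange dynamics.** H/D-exchange protection classes from identifiable
signals at successive D₂O timepoints (`hd_protection()`); fast amide–water
exchange rates k_ex from a two-site saturation-transfer model fitted to
paired saturated/unsaturated intensities at several relaxation delays,
sensitive for 0.1 < k_ex < 10 s⁻¹ (`fit_kex()`); heteronuclear NOE ratios
classified flexible (< 0), intermediate, rigid (> 0.5) with run-length
region summaries (`het_noe()`, `classify_regions()`).

**Synthetic data.** Every input can be generated with known ground truth:
ideal-geometry peptides with prescribed helix/strand/coil segments,
rigid-core/mobile-tail ensembles, shift tables, saturation-transfer
intensity tables and scored model pools (`build_ideal_peptide()`,
`perturb_ensemble()`, `simulate_shifts()`, `simulate_hetex()`,
`simulate_score_table()`).

## Worked example

```r
library(nmrens)

# a 20-residue peptide: helix flanked by disordered ends, 10-model ensemble
spec <- peptide_spec(strrep("A", 20), paste0("CCC", strrep("H", 13), "CCCC"),
                     core_range = 4:16, noise_core = 0.2, noise_tail = 2,
                     n_models = 10, seed = 1)
ens <- perturb_ensemble(build_ideal_peptide(spec), spec)

r <- ca_rmsf(ens, align_selection = list(A = 4:16))
round(range(r$rmsf[r$resno %in% 4:16]), 2)   # core:  0.25 0.39
round(range(r$rmsf[!r$resno %in% 4:16]), 2)  # tails: 2.87 3.54

p <- ensemble_propensity(ens)
define_elements(p, threshold = 0.8)
#    type chain start end
#   helix     A     5  15

f <- fit_kex(simulate_hetex(kex = 1, r1 = 1.5, i_eq = 100,
                            noise_frac = 0.02, seed = 2))
print(f)
# Amide-water exchange fit:
#   kex  = 0.8891 1/s (within sensitive window 0.1-10 1/s)
#   R1   = 1.381 1/s
#   I_eq = 101.9
#   residual SS = 0.0001911
```

The RMSF separates the rigid core (~0.3 Å, i.e. √3 × the generator's 0.2 Å
per-axis core noise) from the fanned-out tails; the propensity threshold recovers the helix
(trimmed by one residue at each end, where fraying across models drops the
propensity to ≤ 0.8); and the exchange fit recovers the generating
k_ex = 1 s⁻¹ within ~11% from six noisy intensities.

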