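---
title: "Validating atomic models against cryo-EM maps with emval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating atomic models against cryo-EM maps with emval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emval)
```

## The problem

An atomic model refined into a cryo-EM reconstruction can have impeccable
stereochemistry and still describe the experimental density poorly: geometry
restraints and density fit are different axes of model quality, and a model
can sit at a good point on one axis and a bad point on the other. emval
scores both axes — globally and per residue — and then *collates*: residues
that score poorly on several complementary metrics, in the same spatial
neighbourhood, are grouped and ranked so that the most serious problem
regions surface first. Multiple independent flags on the same neighbourhood
usually indicate a real modelling error (a mis-traced backbone, a
mis-docked segment) rather than noise in any single metric.

## Fit to data

**FSC and FSCavg.** The Fourier shell correlation between the experimental
map and a theoretical map simulated from the model,

$$\mathrm{FSC}(k) = \frac{\mathrm{Re}\sum_{s \in k} F_1 \bar F_2}
{\sqrt{\sum_{s \in k}|F_1|^2 \sum_{s \in k}|F_2|^2}},$$

is computed in equal-width spherical frequency shells up to the Nyquist
frequency of the grid. FSCavg is the Fourier-voxel-count-weighted mean of
the FSC over all shells up to the stated nominal resolution. The
resolution cutoff is always a user input — it is the reference frame the
score is defined in, and emval never estimates it from the map. A soft
mask (atoms dilated 3 Å, cosine falloff over a further 3 Å) is applied to
both maps before the FSC so the score reflects the modelled region.

**SMOC.** Per residue, the segment-based Manders' overlap coefficient:
voxels within 2.5 Å of the heavy atoms of a 5-residue window
(`half_window = 2`) centred on the residue are collected, and
$\mathrm{SMOC} = \sum EM / \sqrt{\sum E^2 \sum M^2}$ over those voxels
between experimental (E) and simulated (M) density. The window is the
essence of the score — it trades per-residue resolution for robustness —
and both window and contour distance are echoed in report metadata. SMOC
is invariant to positive rescaling of either map.

**Theoretical maps.** Each atom contributes an isotropic Gaussian with
weight occupancy × atomic number and variance from
$B_\mathrm{eff} = B_\mathrm{atom} + 4d^2$ (d = nominal resolution in Å),
using $\sigma^2 = B_\mathrm{eff}/8\pi^2$. The $4d^2$ broadening is a
stated, reproducible stand-in for the unpublished blurring kernels of
production simulators; it is recorded in report metadata. Gaussians are
truncated at $3\sigma$ + 1 voxel (<1% mass loss), and the rasterised map
is low-pass filtered with a raised-cosine edge spanning
$[0.9, 1.1] \times 1/d$. Single-Gaussian atoms (not 5-Gaussian form
factors) are adequate at the ≥3 Å resolutions where map-model validation
is usually performed.

## Confidence maps and the FDR-backbone score

Voxels are tested against a Gaussian background model (mean and sd
estimated from the eight corner cubes of the grid, or from a supplied
solvent mask); one-sided right-tail p-values are adjusted over all voxels
with the Benjamini–Yekutieli procedure. BY rather than Benjamini–Hochberg
is the default because voxel values are spatially correlated and BY's
$\sum 1/i$ correction is valid under arbitrary dependence; BH remains
available via `method = "BH"`. Background normality is asserted, not
assumed silently: a skew/kurtosis diagnostic warns on heavy-tailed input.

The FDR-backbone score of residue i is the fraction of backbone atoms
(N, CA, C, O) of residues $[i-2, i+2]$ whose nearest voxel is confident at
the chosen level (default 1%, a declared constant). "Nearest voxel" is the
maximum-confidence voxel among the 2×2×2 grid neighbours of the atom's
fractional grid position, which makes the score robust to half-voxel
origin offsets. Low scores localise backbone mis-tracing.

## Geometry

Clashes are non-bonded atom pairs (1-2/1-3/1-4 bonded paths excluded, from
a distance-derived bond graph) with van der Waals overlap ≥ 0.4 Å, after
riding hydrogens are placed from ideal internal coordinates;
clashscore = 1000 × clashes / atoms. One deliberate deviation from the
element-radius-only design: pairs consisting of a polar hydrogen (riding
on N/O/S) and an N/O/S acceptor receive a 0.8 Å overlap allowance.
Without it, every α-helical i,i+4 hydrogen bond (O···H ≈ 1.95 Å) counts
as a clash and no hydrogen-bonded structure could ever reach clashscore 0
— including the package's own all-green baseline fixture.

Ramachandran, rotamer and CA-trace (CaBLAM-style) classification use
packaged smoothed reference grids: analytic mixtures of wrapped Gaussians
placed on the well-established basins of high-resolution structure
statistics (α, β, polyproline-II and left-handed α for φ/ψ, with separate
Gly/Pro/pre-Pro grids; gauche/trans wells per residue type for χ; helix
and sheet basins for the CA virtual dihedrals μ_in/μ_out). Thresholds are
highest-density-region contours and are declared constants: φ/ψ favored =
within the 98% region, outlier = outside 99.95%; rotamer outlier = outside
99.7%; CA-trace outlier = outside 99%. These grids make the package fully
self-contained; absolute percentages can differ from empirically contoured
reference tables by small margins, which is why no test asserts agreement
with external percentage values. The Ramachandran Z-score is
$z = \sqrt{n}\cdot\mathrm{mean}_i[(\log p_i - \mu_t)/\sigma_t]$ with
per-type reference moments computed from the grids themselves under the
favored-region distribution — self-consistent, with no external
calibration data.

The composite geometry score is the published logarithmic combination
0.426·ln(1+clashscore) + 0.33·ln(1+max(0, rota%−1)) +
0.25·ln(1+max(0, (100−favored%)−2)) + 0.5, so a perfect model scores
exactly 0.5.

CA-trace scoring splits chains where consecutive CA atoms are more than
4.5 Å apart, and residues flanking a break are unscorable. A consequence
worth knowing: a rigid 3 Å displacement of a helix segment often ruptures
the junctions past 4.5 Å, in which case the junction residues are
reported as unscorable (a break) rather than flagged as outliers. Both
behaviours point at the same defect; the per-residue table distinguishes
them.

## Difference maps and local sharpening

The model map is amplitude-scaled to the experimental map shell by shell
(phases untouched) before voxelwise subtraction in both directions, so
the difference map reflects shape disagreement, not amplitude-profile
mismatch. Scale factors for empty or vanishing shells are clamped to
[1e-3, 1e3] with a warning — this engages routinely beyond the low-pass
cutoff of a simulated reference and is benign there. Voxels beyond the
Nyquist sphere take the last shell's factor.

Local sharpening applies the same shell scaling in a rolling cubic window
(centre-voxel write-back) over every voxel inside a 3 Å-dilated model
mask, against the model-derived reference; outside the mask the output is
zero. A Wilson plot (log shell-mean amplitude vs squared frequency) and a
least-squares slope over the top quarter of shells provide the
over-sharpening diagnostic: under the B-factor convention a deliberate
exp(+B s²/4) sharpening shifts the slope by +B/4, and a positive slope —
amplitudes rising toward Nyquist — flags pathology. Slope analysis is
performed on unfiltered simulated references, because shells inside the
low-pass ramp would otherwise contaminate the fit.

## Collation

Per-residue tables are outer-joined on the residue key; SMOC and
FDR-backbone are flagged below 0.5 (the same half-scale convention used
for reading FSCavg globally, applied per residue; configurable), geometry
outliers directly; missing scores are never flagged. Flagged residues are
clustered by single linkage at 8 Å CA–CA (roughly two residues' reach —
"the same structural neighbourhood") and ranked by severity (total flag
count), then distinct-metric count, then chain/residue — a deterministic
total order. Reports echo every tunable parameter, and the JSON is
byte-deterministic apart from an isolated timestamp field.

## The synthetic world

`make_helix()` builds an ideal poly-Ala α-helix (φ = −57°, ψ = −47°,
ω = 180°, Engh–Huber-like bonds and angles, B = 30 Å², occupancy 1) — the
all-green baseline every release must hold. `make_test_pair()` simulates
its map at voxel = resolution/3 (comfortable oversampling for FSC shells)
and adds white Gaussian noise with sd expressed as a fraction of the
signal RMS inside a 3 Å model mask; `noise_sigma = 0.3` is the default
demonstration setting (in-region SNR ≈ 11 in power — a good-quality ~3 Å
single-particle map), chosen once and used throughout the acceptance
tests. `perturb()` injects the defect classes that per-residue metrics
must localise: rigid segment shifts, register shifts, rotamer scrambles,
injected clashes, deletions — all seeded and bit-reproducible.

What the generator does *not* emulate: coloured/structured noise, CTF
effects, local resolution variation, solvent/detergent backgrounds,
B-factor heterogeneity beyond what the user sets. A green suite therefore
establishes that the scores are computed correctly and localise
constructed defects at desk scale — not that their absolute values match
any production tool on real reconstructions.

## Numerical choices and degenerate inputs

- Shell convention everywhere: equal-width in |s| up to the Nyquist of the
  smallest-voxel axis; default shell count = smallest grid dimension / 2.
- Empty FSC shells are dropped with a warning; an all-zero map is a hard
  error for the Wilson curve (log of zero).
- Alternate conformers: scores use the highest-occupancy conformer only,
  ties broken by first altloc id alphabetically — deterministic
  single-conformer scoring.
- Origin precedence on map input: the ORIGIN record wins over
  NXSTART-derived origins when both are set and disagree (warning), which
  matches prevailing single-particle practice.
- Rank tie-breaks are stable sorts by (score, chain, residue number).
- Atoms outside the grid (beyond a 5-voxel pad) are skipped with a count;
  residues with no heavy atoms get explicit NA scores, never 0.

## Limitations

No half-map workflows (FSCwork/FSCfree-style cross-validation), no
anisotropic B-factors or electron scattering form factors, no probe-style
dot-surface contact analysis, no restraint-dictionary RMSZ, and the
packaged reference grids are smooth analytic stand-ins, not MolProbity's
empirical contours — comparisons across software should use trends, not
absolute percentages.
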