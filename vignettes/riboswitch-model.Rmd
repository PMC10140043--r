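---
title: "The riboswitchr thermodynamic model and its design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The riboswitchr thermodynamic model and its design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`riboswitchr` models synthetic riboswitches in which a protein-binding RNA
aptamer, embedded in a bacterial 5′ UTR, couples protein occupancy to
translation initiation. This vignette is the package's own account of the
science it implements: the model and its assumptions, the calibration
parameters and their defaults, the synthetic-data generators, the numerical
conventions, and the design choices made where several reasonable options
existed.

## The ribosome-binding free-energy model

Translation initiation is treated as an equilibrium between the folded free
mRNA (the *initial* state) and the 30S pre-initiation complex (the *final*
state). The total binding free energy is

$$\Delta G_\mathrm{total} = \Delta G_\mathrm{final} - \Delta G_\mathrm{initial},$$

with the final state decomposed into five terms:
mRNA:rRNA hybridization at the Shine–Dalgarno (SD) sequence, start-codon/tRNA
pairing, a spacing penalty, a standby-site penalty, and the folding energy of
the mRNA outside the ribosome footprint. The footprint runs from the 5′ end
of the SD-paired span through 13 nt past the first start-codon nucleotide;
everything inside it is held single-stranded in the final state. The
initiation rate follows the Boltzmann relation
$\mathrm{TIR} = k\,e^{-\beta\,\Delta G_\mathrm{total}}$, so rate *ratios*
depend only on free-energy differences and are independent of $k$.

`ribosome_final_state()` enumerates candidate SD placements: for every
spacing value in the configured range (0–15 nt) it scores the best
RNA–RNA duplex between the 9-nt anti-SD and an 11-nt mRNA window ending at
that spacing, then evaluates the full five-term sum for each distinct
placement and returns the minimum. A construct whose upstream region forms
no favorable duplex at all is returned as a flagged sentinel with zero
hybridization energy rather than an error, so that sequence designers can
still rank dead candidates.

All folding is delegated to the ViennaRNA programs `RNAfold` and
`RNAduplex` with the Turner 2004 nearest-neighbor parameters and dangling
ends disabled (`-d0`). Fold results are memoised per
(sequence, constraint, temperature), which is what makes the enumeration,
the genetic algorithm, and the subconstraint grids affordable.

Two engine behaviors worth knowing about: `RNAduplex` reports hybrid spans
that can include unpaired flanking positions, which the wrapper trims back
to the outermost paired bases before any spacing arithmetic; and duplex
energies are mildly end-context dependent (a helix scored inside a longer
strand can differ from the same helix at the strand ends by a few tenths of
a kcal/mol), which is why tests assert flank-invariance of the *alignment*
rather than of the energy.

## The four riboswitch states and the regulation ratios

Only the four predominant states are modeled: protein-bound and unbound,
each free or ribosome-bound. The unbound branch folds without constraints;
the bound branch locks the aptamer positions into the aptamer's declared
protein-bound structure (in both initial and final states). Forced pairs
that would overlap the ribosome footprint are displaced by the ribosome.

From the two $\Delta G_\mathrm{total}$ values:

* $R_\mathrm{max}$ — fold-change at ligand saturation,
  $\mathrm{TIR}_\mathrm{bound}/\mathrm{TIR}_\mathrm{unbound}$ for ON
  switches, the reciprocal for OFF switches. All ratios are reported
  oriented by mode, so ≥ 1 means "works as designed".
* $R_\mathrm{conc}(P)$ — the ensemble average at protein concentration $P$.
  *Rates*, not free energies, are averaged:
  $\mathrm{TIR}(P) = f\,\mathrm{TIR}_\mathrm{bound} +
  (1-f)\,\mathrm{TIR}_\mathrm{unbound}$, because each mRNA molecule in the
  ensemble translates at the rate of its own conformation. Occupancy is
  single-site Langmuir binding, $f = P/(P+K_d)$, with the protein assumed
  in excess of mRNA — the simplest law consistent with a specified
  concentration input.
* $R_\mathrm{actual}(P)$ — as $R_\mathrm{conc}$ but with
  $K_d^\mathrm{eff} = K_d\,e^{\Delta G_\mathrm{refold}/RT}$, where
  $\Delta G_\mathrm{refold} \ge 0$ is the folding-energy cost of
  rearranging the free mRNA's MFE structure into one compatible with the
  bound aptamer structure. The exact functional form of this stability
  correction was an open design choice; the Boltzmann reweighting of the
  dissociation constant is the simplest form in which a refolding cost of
  $RT$ reduces apparent affinity $e$-fold, and it guarantees the hierarchy
  $1 \le R_\mathrm{actual} \le R_\mathrm{conc} \le R_\mathrm{max}$, which
  the test suite checks on over a thousand randomized construct ×
  concentration cases.

A corollary of the mixing law, also under test: an OFF switch needs a
higher protein concentration than an ON switch of equal $R_\mathrm{max}$
and $K_d$ to show the same output fold-change, because repression of an
ensemble is dominated by the unrepressed fraction.

Note what the model does *not* contain: protein-induced steric blocking of
the 30S subunit. A construct engineered so that its structure is identical
with and without protein evaluates to $R_\mathrm{max}=1$ here even though
a bulky protein parked next to the SD can repress translation in reality.
The model captures conformational switching only.

## Calibration parameters

All constants live in `calibration_params()` and can be serialized to YAML.

| parameter | default | units | provenance |
|---|---|---|---|
| `beta` | 0.45 | (kcal/mol)⁻¹ | in vivo apparent Boltzmann factor; cell-free assays show ≈ 0.23, refittable with `fit_beta()` |
| `k_tir` | 36400·e^(−0.45·7.52) | au | anchors ΔG_total = −7.52 kcal/mol to 36,400 au, the standard no-aptamer control UTR |
| `temperature` | 310.15 | K | folding and RT; see below |
| `anti_sd` | `ACCUCCUUA` | — | 3′-terminal nine nucleotides of the *E. coli* 16S rRNA |
| `footprint_past_start` | 13 | nt | footprint extent into the CDS |
| `spacing_optimum` | 5 | nt | optimal SD-to-start spacing |
| `spacing_penalty_coeffs` | 0.15 / 0.04 | kcal/mol/nt² | compression / stretch quadratic coefficients — calibration data, not thermodynamic constants |
| `standby_window` | 15 | nt | standby-site accessibility window |
| `start_codon_energies` | AUG −1.19, GUG −0.50, UUG −0.30 | kcal/mol | calibration data; AUG strongest |

The folding temperature is not dictated by the assay literature the model
serves: designs are evaluated at the biophysical convention of 37 °C even
though TX-TL incubations run cooler (about 29 °C). Nearest-neighbor
parameters are much better characterized at 37 °C, and because all ratio
predictions depend on free-energy *differences*, a uniform temperature
offset largely cancels; the apparent β refit absorbs most of what remains.
The spacing coefficients and start-codon energies are likewise calibration
data with defaults chosen once to give penalties of a few kcal/mol at
strong compression and a fraction of that for stretching; they are
deliberately exposed in the configuration rather than buried in code.

The standby-site term is a documented simplification: the unfolding free
energy of whatever structure forms within the 15-nt window immediately 5′
of the SD span (honoring locked aptamer pairs that fall wholly inside the
window), clamped at ≥ 0. The published surface-area standby model is out
of scope; the simple form is isolated in one function
(`standby_penalty()`) so it can be replaced without touching the
enumeration.

## Sequence design

`design_switches()` runs an NSGA-II-style genetic algorithm (fast
non-dominated sorting, crowding distance, binary tournaments, μ+λ survivor
selection) over the designed pre- and post-aptamer regions, maximizing
$(R_\mathrm{max}, \mathrm{TIR}_\mathrm{high\ state},
-\mathrm{TIR}_\mathrm{low\ state})$ at ligand saturation; $R_\mathrm{actual}$
is intended for post-hoc ranking at the experiment's concentration. The
aptamer itself is never touched by any operator.

Design choices here:

* The 44–55 nt default length range bounds the *combined* designed length;
  the consistency $4^{44} \approx 10^{26}$, $4^{55} \approx 10^{33}$ fixes
  that reading, and `log10_design_space()` encodes the arithmetic.
  Lengths are themselves evolvable through bounded single-nucleotide
  insertions and deletions.
* Forbidden motifs (default: any `AUG`, in or out of frame, in designed
  regions) are enforced at generation time to avoid spurious start codons.
* Every random draw flows from the recorded seed, and the returned Pareto
  set is the non-dominated front over *all* candidates evaluated during
  the run, with deterministic ordering (descending $R_\mathrm{max}$, ties
  lexicographic on sequence). The best $R_\mathrm{max}$ individual is
  explicitly preserved each generation, so its trace is non-decreasing.
* `brute_force_design()` exhaustively enumerates spaces up to 10⁵
  candidates and serves as the oracle the GA is tested against on a
  48-candidate toy space (16-individual populations, 15 generations).

## The aptamer subconstraint scan

The declared protein-bound structure of an aptamer is an experimental
input, and often the least certain one. `enumerate_subconstraints()` builds
all $L(L+1)/2$ contiguous subregions of an aptamer, refolds each in
isolation (subregions shorter than 5 nt cannot pair and are assigned dots
directly), and `rebuild_construct()` re-partitions the construct so that
only the subregion stays "locked" — the assembled mRNA sequence is
provably unchanged, only the constraint moves. `scan_r_actual()`
recomputes $R_\mathrm{actual}$ per cell, and `select_constraint()` picks
the cell whose log-predictions correlate best (squared Pearson correlation
on natural logs, matching the log–linear accuracy analyses used for such
data) with measured log-ratios across riboswitches sharing the aptamer,
reporting the within-2-fold fraction alongside.

Accuracy ties (within 10⁻⁹) are broken toward the smallest region, then
the 5′-most — the most parsimonious locked structure. Selection is
per-aptamer; no joint optimization across aptamers is attempted. On toy
aptamers many cells are prediction-equivalent (the grid is far smoother
than for a real 50-nt aptamer), so recovery of a generating cell is
guaranteed only up to prediction equivalence; the test fixtures use the
full-aptamer cell, whose prediction profile is unique in the panel used.
With four constructs and 10% lognormal measurement noise the generating
cell is the usual winner (the acceptance script reports the recovery rate
over 50 noise draws at 5% and 10% noise); exact recovery is reliable at
noise up to about 5%.

## Cell-free assay analysis

`endpoint()` implements the standard endpoint arithmetic: the mean of the
last 15 points minus the mean of the first 15 points, minus the same
quantity computed on a no-DNA reaction (the non-specific fluorescence
drift). The window size is a flag; the two windows must not overlap, which
fixes the 30-point minimum trace length. `regulation_ratio()` orients
ratios by switch mode, and `correct_nonspecific()` divides by the
no-aptamer control's ratio *expressed in the same orientation* — a control
that rises 2.37-fold while an OFF switch falls has repression ratio
1/2.37, so dividing by it multiplies the raw repression up. This single
convention reproduces both the multiply-when-opposite and
divide-when-same corrections seen in practice.

`fit_dose_response()` fits a Hill curve by bounded Levenberg–Marquardt
(`minpack.lm`), initialized from the zero-dose endpoints, the observed
span, the median tested concentration and $n=1$; flat data short-circuits
to a degenerate-flagged result and non-convergence is flagged, never
silent. `fit_beta()` is ordinary least squares of log endpoint on
$-\Delta G_\mathrm{total}$, reporting the slope (the apparent β), $R^2$,
the two-sided slope p-value and a 95% confidence interval. Ratio
uncertainty for small replicate counts (6–8) is handled on the log scale
(delta method) rather than by exact ratio intervals.

## Synthetic data: what it emulates and what it does not

`generate_trace()` emulates a plate-reader mRFP1 kinetic read: baseline
autofluorescence, a slow linear drift present even without DNA, a logistic
rise to an expression plateau, and Gaussian reader noise, sampled every
10 min for 16 h (97 points). Defaults put the logistic midpoint at 480 min
with rate 0.08 min⁻¹, so the first and last 15-point windows sit fully on
the asymptotes and the corrected endpoint of a noiseless trace equals the
generator plateau to floating-point accuracy — that identity is an
acceptance check, not a coincidence. Seeds are mandatory, every generated
artifact is byte-reproducible, and generation never perturbs the caller's
RNG stream.

`generate_study()` wires the pieces together: a toy aptamer (verified by
folding to declare its own MFE structure as its bound structure), a panel
of random constructs around it, model-true endpoints at chosen doses under
a chosen true β and true subconstraint, and plate/well-map CSVs plus a
truth file. What the synthetic studies deliberately do *not* emulate:
steric repression (absent from the model, see above), resource competition
and toxicity at high ligand dose, mRNA degradation, cotranscriptional
folding, and the rugged subconstraint response surfaces of large natural
aptamers. Passing tests therefore demonstrate internal consistency and
recoverability of the modeled mechanisms, not predictive accuracy on real
sensors.

## Numerical conventions

* Sequence positions are 1-based inclusive everywhere user-visible; T is
  transparently mapped to U and whitespace stripped on input.
* Constraint strings use `.` (unconstrained), `x` (forced unpaired) and
  matched `()` (forced pair). Constraints are validated in R — balanced
  brackets, canonical pairs (Watson–Crick plus GU), hairpin loops ≥ 3 nt —
  before the engine sees them, because the engine silently accepts
  non-canonical forced pairs with an energy penalty instead of failing.
* Placement ties in the final-state search are broken toward the spacing
  closest to optimum, then the 5′-most span; energy comparisons use a
  10⁻⁹ kcal/mol tolerance.
* The no-SD sentinel, degenerate dose–response data and non-positive
  endpoints are all reported as flagged values or typed errors, never
  silently clipped.
* Switch predictions serialize to JSON with 17 significant digits, which
  round-trips doubles bit-exactly.

## Problem sizes used by the test and acceptance suites

Chosen as the package's own benchmark conditions: the ratio-hierarchy suite
evaluates 120 randomized toy constructs at 9 concentrations each (1,080
cases); β recovery uses a 34-construct panel with 200 simulated replicate
experiments at 0.3 lognormal noise on endpoints; subconstraint recovery
uses four switching constructs over the 136-cell grid of a 16-nt toy
aptamer; the GA oracle comparison runs 16 × 15 generations against a
48-candidate exhaustive enumeration; dose–response recovery uses 8
concentrations × 6 replicates at 2% noise around a 403 nM half-max.

## Known limitations

* The standby model is a one-window unfolding penalty, not the published
  surface-area treatment; both it and the spacing coefficients are
  calibration-grade approximations.
* Steric protein–ribosome exclusion is not modeled.
* Ligand depletion, cooperative binding and protein oligomerization are
  outside the occupancy law; users supply an effective monomer
  concentration.
* Folding is equilibrium MFE only — no ensemble averaging beyond the four
  states and no cotranscriptional kinetics.
* Duplex energies inherit the engine's mild end-context dependence noted
  above.
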