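---
title: "Single-model quality assessment with knowledge-based potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-model quality assessment with knowledge-based potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(massqa)
```

## The problem

In protein structure prediction, a *decoy* is one candidate 3D model of a
target sequence. Quality assessment (QA) asks: given a single decoy and no
pool of alternatives to compare against, how close is it to the (unknown)
native structure? The standard closeness measure is GDT-TS, on a 0–100
scale: after superposition, the mean over thresholds 1, 2, 4, 8 Å of the
percentage of Cα atoms within the threshold.

`massqa` predicts GDT-TS for a single model by combining knowledge-based
statistical potentials with sequence- and structure-derived descriptors in
a random-forest regressor, and evaluates predictions with the criteria the
CASP experiment uses for its QA track.

## The potential family

All ten potentials share one scoring rule. A *state* is a small tuple of
discretised structural descriptors observed for a residue, atom, or pair
(e.g. "helical residue whose pseudo-bond angles fall in classes 4, 3, 5").
Counting states over a set of experimental structures gives, for each type
$R$ (a residue type, heavy-atom type, or residue-type pair):

* $M_R$ — the total number of observations of type $R$;
* $f_{observed} = f(R, s) / M_R$ — the frequency of state $s$ within
  type $R$;
* $f_{reference} = \sum_{R'} f(R', s) \big/ \sum_{R'} M_{R'}$ — the pooled
  frequency of $s$ across all types.

The energy of observing type $R$ in state $s$ is

$$E = RT\,\ln(1 + M\sigma) - RT\,\ln\!\left(1 + M\sigma\,
\frac{f_{observed}}{f_{reference}}\right),$$

with $\sigma = 1/50$ and $RT = 0.582$ kcal/mole. States enriched in a type
relative to the pooled background score negative (favourable); depleted
states score positive; a state with $f_{observed} = f_{reference}$ scores
exactly zero, and $M = 0$ gives zero. The $M\sigma$ factor damps sparsely
observed types toward zero, acting as a sample-size-aware shrinkage. A
model's score under one potential is the sum of its residues' (or atoms',
or pairs') energies; 0 states never observed in the reference contribute
nothing.

The ten state definitions, with their binning defaults (`mass_config()`):

| Potential | Level | State tuple | Binning |
|---|---|---|---|
| pseudo-bond angle (PAP) | residue | ss + angle classes at N, Cα, C | [0, 180]° into 6 |
| torsion pattern (TAP) | residue | ss + φ/ψ triple equality patterns | (−180, 180]° into 9, then 5-way and 4-way patterns |
| centrosymmetric burial (CSP) | atom (Cα, Cβ) | ss + distance to centroid | [0, 3·Rg] into 30, Rg = 0.395·N^0.6 + 7.257 |
| residue surface (ASPR) | residue (Cα, Cβ) | ss + neighbours within 11 Å | [0, 50] into 25 |
| atomic surface (ASPA) | heavy atom (40 types) | neighbours within 8 Å | [50, 200] into 30 |
| distance (DDP) | pair (Cα, Cβ) | unordered type pair + distance | [5, 25] Å into 40, separation ≥ 3 |
| sequence separation (SSDP) | pair (Cα, Cβ) | unordered type pair + separation | [0, 300] into 60, distance ≤ 8 Å |
| contact (CDP) | ordered pair (Cα, Cβ) | focal type + ss + partner type | separation ≥ 6, distance < 9 Å |
| solvent accessibility (RSAP) | residue | ss + relative accessibility | [0, 1] into 10 |
| volume (VDP) | residue | ss + bounded Voronoi volume of Cα | [10, 30] Å³ into 10 |

Five of these (CSP, ASPR, DDP, SSDP, CDP) are computed twice, once with Cα
and once with Cβ representatives (Cα substituted for glycine), giving 15
potential scores per model.

### Numerical choices

Several conventions are not forced by the formulas and were fixed once:

* **Bin edges.** `bin_index()` maps $[lo, hi]$ evenly onto $n$ classes
  with the top edge closed (`hi` lands in class $n-1$). Bounded point
  descriptors (angles, counts, RSA, volumes, centroid distances) *clamp*
  out-of-range values into the edge bins so no residue is lost; pair
  potentials *reject* pairs outside their distance/separation ranges, the
  usual convention for cutoff-based pair potentials.
* **Pair-potential types.** DDP and SSDP carry no secondary-structure
  term (CDP's state definition has one; theirs do not), and their "type"
  axis is the unordered residue-type pair (210 pairs), each with its own
  $M$. CDP events are emitted per ordered (focal, partner) pair so that
  $M_R$ sums over the focal residue type.
* **Unseen states.** $f_{reference} = 0$ implies $f_{observed} = 0$
  (both derive from the same counts), and the energy is defined as the
  $0/0 \to 0$ limit rather than through pseudo-counts.
* **Angles.** Planar angles use the arccos of a clamped normalised dot
  product, so collinear triples give exactly 180° instead of NaN; a
  dihedral of exactly −180° is mapped to +180° before binning.
* **Atom typing.** The 40-type heavy-atom table groups (residue, atom
  name) by chemical environment — backbone N/Cα/C/O shared across residues
  (glycine Cα and proline N kept separate), side-chain atoms grouped by
  chemistry. It sits behind `atom_type_40()` so another scheme can be
  swapped in.
* **Volumes.** The Cα volume is the cell of the Voronoi partition of all
  Cα atoms intersected with an 8 Å ball, estimated by deterministic grid
  sampling at 0.8 Å. The grid is laid out in the principal-axes frame of
  the Cα cloud (axes sign-fixed by their largest component), which makes
  the volumes — and hence the VDP score — invariant under rigid-body
  transforms of the input coordinates, a property the lab-frame grid would
  not have.
* **Sparse structures.** ASPA's count range [50, 200] reflects dense
  side-chain packing; backbone-only synthetic chains fall below 50
  neighbours and all land in class 0, which degenerates ASPA to zero on
  such data. This is a documented consequence of the published range, not
  an error.

## The 70-feature descriptor

`assemble_features()` produces a fixed-order vector
(`feature_names()`):

1. positions 1–6: agreement between *predicted* (sequence-based) and
   *assigned* (structure-based) annotation — Q3, SOV'99, a
   scalable-allowance SOV variant, and burial agreement at the 25%
   exposure threshold among predicted-buried, predicted-exposed, and all
   residues;
2. positions 7–9: externally computed RWplus, GOAP and DFIRE energies,
   read from tabular files (`read_external_energies()`);
3. positions 10–32: type-I pseudo amino acid composition, 20 composition
   terms plus λ = 3 sequence-order correlation factors built from
   standardised hydrophobicity, hydrophilicity and side-chain mass, weight
   w = 0.05 (the 23 terms sum to 1);
4. position 33: radius of gyration over backbone N/Cα/C with equal
   masses;
5. positions 34–35: mean sequence separation of Cα contacts (separation
   ≥ 6, distance < 8 Å) and separation-weighted mean contact distance;
6. positions 36–50: the 15 potential scores;
7. positions 51–70: 19 Rosetta REF15 terms plus their total,
   pass-through.

Features whose inputs are absent (external energies, prediction strings)
are zero-filled — deliberately the same masking that the occlusion
analysis (`occlude_features()`) applies to whole groups, so a missing
input degrades gracefully rather than failing.

On SOV: the SOV'99 allowance is
$\min(maxov - minov,\ minov,\ \lfloor len_1/2 \rfloor,\ \lfloor len_2/2
\rfloor)$ per overlapping segment pair. The refined variant here scales
that allowance by λ (halves unfloored); λ = 0 is the raw overlap ratio
and λ = 1 essentially the classic allowance. This is this package's
reading of the "refined, scalable allowance" idea; identical strings
score 1 and disjoint assignments 0 under every λ.

## The regressor

`qa_grid_search()` fits a random forest over a grid of `ntree`
(published grid 500–5000 by 500) and `mtry` (10–34), selecting by mean
per-fold Pearson correlation under 5-fold cross-validation. Folds are
split **by target**: decoys of one target are strongly correlated, so
letting them straddle a fold boundary would leak information and inflate
CV scores. The selection criterion itself is chosen to match the headline
evaluation statistic (per-target Pearson correlation); the published
account does not state which criterion its grid search used, nor whether
folds were target-grouped, so both are this package's design choices.
Ties prefer the smaller `ntree` then the smaller `mtry`. Everything is
seeded: a fixed seed reproduces folds, forests, CV tables and predictions
bit for bit.

Predictions are the ensemble mean clipped to [0, 100];
`qa_feature_importance()` returns impurity-based importances normalised
to sum 1.

## Evaluation statistics

`evaluate_predictions()` implements the four CASP QA criteria:

* **wmPMCC** — per-target Pearson $r$ between predicted and true GDT-TS,
  Fisher-transformed ($z = \tfrac12 \ln\frac{1+r}{1-r}$), averaged, and
  transformed back. Correlations are clamped to $|r| \le 1 - 10^{-6}$
  first; a degenerate (constant) target contributes $r = 0$ with a
  warning rather than propagating NaN.
* **Average loss** — per target, the true-GDT gap between the actually
  best model and the model the predictor ranks first (ties: first index).
* **Average ΔGDT** — mean |true − predicted| per model, reported both on
  the 0–100 input scale and divided by 100 (the scale CASP tables print).
* **MCC and ROC AUC at GDT-TS 50** — a model is good iff its true score
  is ≥ 50; predicted good iff the predicted score is ≥ 50. MCC is 0 when
  any denominator factor vanishes; AUC is the rank-based (Mann–Whitney)
  statistic with ties counting ½, undefined when only one class is
  present.

`compare_potentials()` reports pairwise Pearson and Spearman correlations
between the 15 potential scores over a model set, plus paired t-test and
Wilcoxon signed-rank p-values; the paired tests run on column-standardised
scores because raw potentials differ in scale by orders of magnitude, and
zero-difference pairs get p = 1 by convention.

## The synthetic benchmark

`make_dataset()` builds labeled decoy pools with no external data: per
target, a random length in 20–60 residues, a random fold (ideal α-helix
at φ/ψ = −57/−47°, fully extended chain at 180/180°, or half-and-half),
a random sequence, and decoys generated by adding zero-mean Gaussian
displacement to every atom with amplitudes cycled through
{0.25, 0.5, 1, 2, 4, 8} Å to guarantee label spread. Labels come from the
package's own GDT-TS implementation: a *single* global Kabsch
superposition of shared Cα atoms followed by the standard four-threshold
count — deterministic and symmetric, but deliberately simpler than LGA's
segment search, which can find higher-scoring local superpositions. For
same-topology perturbation decoys the two agree closely; for hard decoys
the single-superposition score is a lower bound.

What the generator emulates: backbone-complete chains with correct bond
geometry and dihedrals, graded decoy quality, per-target model pools with
shared sequence-based "predictions" (stood in by the native's own
assignment). What it does not emulate: side-chain packing, compact
globular tertiary structure (so ASPA and long-range contact features are
weak or degenerate), realistic error modes of structure predictors, or
native-like reference-state statistics (the shipped reference is built
from whatever structures the user supplies — the published method used
~8000 high-resolution chains). Passing tests on this benchmark therefore
demonstrate the machinery is correct and self-consistent, not that the
desk-scale model matches production accuracy on real CASP data.

Internal annotation (`assign_ss_rsa()`) is likewise a documented
stand-in for STRIDE: helix/strand from φ/ψ boxes with run-length minima
(helix ≥ 4, strand ≥ 2), and accessibility from a heavy-atom
neighbour-count ramp (≤ 10 neighbours fully exposed, ≥ 80 fully buried,
within 10 Å of Cα). When a STRIDE file is supplied (`read_stride()`,
areas normalised by the Tien et al. theoretical maxima), it always wins.

## Problem sizes

The bundled test-suite and acceptance runs use 5 targets × 30 decoys
(lengths 20–60), a 2 × 2 parameter sub-grid (ntree 500/1000,
mtry 10/24) and 5 target-grouped folds — sizes chosen so the whole
pipeline (reference extraction through evaluation) completes in about a
minute while still exercising every code path; the defaults expose the
full published grid for real training sets.

## Known limitations

* Residue-level (local) quality is not predicted — all outputs are
  global scores.
* Single-chain only; the first (or named) chain of a PDB file is used.
* The exact binning-edge rules, atom-typing table and volume method of
  the original implementation are unpublished; this package's choices are
  documented above and isolated behind swappable interfaces, so exact
  numeric agreement with the original potentials is not expected.
* The GDT-TS labeler is not LGA; see above.
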