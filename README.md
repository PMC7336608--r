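# massqa

Single-model protein quality assessment: predict the global GDT-TS of an
individual protein 3D model, with no pool of alternative models to compare
against.

When a structure-prediction pipeline emits a handful of candidate models,
clustering-based quality estimates are unavailable; a single-model method
must judge each decoy on its own. `massqa` does this by combining a family
of **knowledge-based statistical potentials** with sequence- and
structure-derived descriptors in a **random-forest regressor**, and
evaluates predictions with the criteria the CASP experiment applies to its
QA track.

## The method in brief

Every potential scores a discretised structural *state* `s` observed for a
*type* `R` (a residue type, a 40-class heavy-atom type, or a residue-type
pair) against reference counts collected from experimental structures:

    E = RT·ln(1 + M·σ) − RT·ln(1 + M·σ · f_observed / f_reference)

with `σ = 1/50`, `RT = 0.582` kcal/mole, `M` the number of observations of
type `R`, `f_observed = f(R, s)/M_R` and
`f_reference = Σ_R' f(R', s) / Σ_R' M_R'`. A model's score under one
potential is the sum of its residues' (atoms', pairs') energies. Ten state
definitions — pseudo-bond angles, torsion-angle patterns, centrosymmetric
burial, residue- and atomic-level accessible surface, inter-residue
distance, sequence separation, contacts, relative solvent accessibility,
and Cα Voronoi volume — five of them computed with both Cα and Cβ
representatives, give 15 potential scores.

These join a 70-feature descriptor (secondary-structure and burial
agreement scores, pseudo amino acid composition, radius of gyration,
contact statistics, and optional RWplus/GOAP/DFIRE/Rosetta pass-through
energies) that a cross-validated random forest maps to GDT-TS on [0, 100].
The methods vignette (`vignettes/methods.Rmd`) documents every formula,
binning rule and design choice.

## Worked example

Everything below runs with no external data — the synthetic module builds
labeled decoy pools from scratch.

```r
library(massqa)

## one target: a 56-residue chain with four decoys of graded quality
ds <- make_dataset(n_targets = 1, models_per_target = 4, seed = 42)
tg <- ds[[1]]
round(tg$labels, 1)
#> [1] 100.0  94.6  75.0  45.1
```

The labels are GDT-TS scores of each decoy against its native, from a
Kabsch superposition of Cα atoms and the standard 1/2/4/8 Å thresholds:
the gently perturbed decoys score near 100, the 2 Å-amplitude decoy 45.

```r
## reference states from the native, then potential scores for a decoy
ref <- build_reference(list(assign_ss_rsa(tg$native)))
round(score_model(tg$decoys[[4]], ref), 2)
#>     pap     tap    aspa    rsap     vdp aspr_ca aspr_cb  cdp_ca  cdp_cb
#>    0.00    0.00    0.00   -0.21    1.11   -0.01   -0.01    0.00    0.00
#>  csp_ca  csp_cb  ddp_ca  ddp_cb ssdp_ca ssdp_cb
#>   -0.21   -0.24   -1.60   10.86    0.00    0.00
```

Positive energies flag geometry depleted in the reference set — here the
heavily perturbed decoy's Cβ distance distribution (`ddp_cb` = 10.86
kcal/mole) departs strongly from the native's. The full pipeline —
features, grouped cross-validated grid search, CASP-style evaluation of
the held-out predictions — is what `scripts/acceptance.R` runs (below);
on 5 targets × 30 decoys it prints:

```
<evaluation_report> 5 targets, 150 models
  wmPMCC 0.956 | ave loss 0.87 | ave dGDT 11.78 (0.11777 norm) | MCC 0.821 | AUC 0.981
```

meaning: per-target Pearson correlation between predicted and true GDT-TS,
pooled via Fisher z, is 0.956; picking the predictor's top-ranked model
costs 0.87 GDT-TS units against the true best on average; absolute score
error averages 11.8 units; and good/bad classification at the GDT-TS 50
threshold reaches MCC 0.82 with ROC AUC 0.98.

A command-line wrapper (`exec/mass`) exposes the same pipeline as
subcommands: `synth`, `build-ref`, `parse`, `potentials`, `features`,
`train`, `predict`, `evaluate`.

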