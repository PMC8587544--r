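# ligfunnel

A multi-step **ligand-based virtual screening funnel** for small-molecule
libraries, written for computational chemists who want the machinery of a
deep-learning + pharmacophore + docking-cascade campaign as a tested,
scriptable R library rather than a chain of GUI tools.

The package covers the whole pipeline against a receptor target (the
motivating use case is a GPCR antagonist campaign):

* **Curation** — activity tables (id, SMILES, pKi) are labeled by
  thresholds (pKi > 8 active, pKi < 6 inactive, mid-range excluded),
  split 7:2:1 by stratified largest-remainder apportionment, and potent
  actives are clustered (average linkage on 1 − Tanimoto) to medoid
  representatives. Property-matched decoys are selected DUD-E-style
  (MW/logP/HBD/HBA/rotatable-bond windows + maximum Tanimoto cap).
* **Fingerprints** — circular ECFP4-style bit fingerprints with Tanimoto
  similarity Tc(A,B) = |A∩B| / |A∪B|, also used for novelty scoring
  (max Tc of a candidate against known actives; lower = more novel).
* **Two classifiers** — a dense ReLU network on fingerprint bits and a
  graph-convolutional neural-fingerprint network on the molecular graph,
  both trained with Adam + L2 + early stopping, evaluated by SE, SP, Q+,
  Q−, MCC and AUC, with a batch-size sweep for model selection.
* **Pharmacophore** — typed 3D features (A/D/H/R/P/N) perceived from a
  documented SMARTS-free rule dictionary, common-arrangement hypothesis
  generation across actives by distance-geometry hashing, and k-of-n
  partial matching by Kabsch superposition (default: match ≥ 4 of 5
  features within 2 Å).
* **Enrichment metrics** — EF at a fraction, BEDROC(α) in the
  Truchon–Bayly exact normalization (α = 160.9 ≈ top 1%), ROC area, AUAC.
* **Funnel** — classifier consensus (intersection), pharmacophore filter,
  cascade top-25% filtering over externally produced docking score
  tables (docking itself is consumed, never computed), a top-K shortlist
  with novelty annotation, and a complete per-compound elimination trace.
* **Synthetic generators** — labeled fingerprint sets, motif-planted
  molecule libraries, rigid 3D pharmacophore realizations and ranked
  screens with prescribed active placement, so every stage is testable
  without external data.

## Worked example

Validate a screen of 29 actives among 858 decoys (N = 887, top-1% bin =
ceiling(8.87) = 9 compounds) with 4 actives in the top bin:

```r
library(ligfunnel)
screen <- make_ranked_screen(N = 887, A = 29,
                             active_ranks = c(1:4, seq(40, 64)))
enrichment_report(screen)
#>         EF    BEDROC      ROC      AUAC   N  A
#> 1 13.59387 0.5194968 0.964834 0.9490728 887 29
```

`EF = 13.59` says the top 1% of the list is 13.59-fold richer in actives
than a random 1% slice would be; BEDROC weights that early recognition
smoothly, and ROC/AUAC summarize the whole ranking.

Build a pharmacophore from planted actives and screen a synthetic library:

```r
ps <- make_pharmacophore_set(n_active = 5, n_decoy = 150, seed = 42)
actives <- names(ps$labels)[ps$labels == 1]
hyps <- generate_hypotheses(ps$mols[actives], sizes = 4:5,
                            min_actives_matched = 5)
hyps[[1]]
#> <pharm_hypothesis> AADH_1: 4 features, k=4, matched 5 active(s), score 1.000

scr <- screen_with_hypothesis(ps$mols, hyps[[1]], is_active = actives)
enrichment_report(scr)
#>   EF BEDROC ROC      AUAC   N A
#> 1 31      1   1 0.9806452 155 5
```

All 5 planted actives match the hypothesis and rank on top; all 150
geometry-violating decoys fail and sit at the bottom with score −Inf, so
EF1% reaches its maximum (31 = (1/2)/(5/155) with both top-bin slots
active).

A command-line interface with subcommands (`curate`, `train`, `sweep`,
`evaluate`, `pharm-build`, `pharm-screen`, `decoys`, `enrich`, `novelty`,
`funnel`) is installed at `inst/cli/ligfunnel.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/ligfunnel.R", package="ligfunnel"))')" \
    curate --activities activities.csv --out curated.csv
```

## Documentation

The methods vignette (`vignettes/ligfunnel-methods.Rmd`) describes the
models, the parameter defaults and why, what the synthetic generators do
and do not emulate, the numerical conventions (tie-breaks, rounding,
undefined-metric policy), and known limitations.
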