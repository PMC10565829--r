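# rxnscheme

Machine reading of chemical reaction scheme images.

Reaction schemes — 2-D structure diagrams joined by reaction arrows, with
chemical labels below the diagrams and conditions text around the arrows —
are how synthetic chemistry is communicated, and they are opaque to
machines. `rxnscheme` converts a raster image of a scheme into a
machine-readable **reaction graph**: nodes are chemical diagrams and each
directed edge is a reaction step, `reactants → products` via one arrow,
with conditions regions attached to the step.

The package contains the full tool chain:

* a **scheme engineer** that composes artificial, fully annotated reaction
  schemes (procedural diagram skeletons, four arrow types, label and
  conditions text, decoy symbols) from a layout schema — the training and
  test bed for everything else;
* a **two-branch arrow model**: connected-component proposals, 64×64
  patches, and a small convolutional network with a binary detector head
  and a 4-way subtype head (solid / curly / equilibrium / resonance),
  trained under the combined loss
  `L = λ₁·BCE + λ₂·CE` with `λ₁ = 10, λ₂ = 1`;
* a pluggable **region detector** for diagrams / labels / conditions — a
  reduced learned backend plus a ground-truth oracle backend with
  perturbation knobs;
* **symbolic postprocessing**: diagram completion by locally sized
  dilation, text-region reclassification (label vs conditions) and
  pairing;
* **arrow geometry**: rotated-rectangle direction estimation, center of
  mass for the head side, curly-arrow endpoint detection with hook/end
  classification;
* **graph formation**: directional step scanning with an
  arrow-encountered stop rule and multi-line fallback, step stitching,
  JSON/GraphML export;
* **evaluation**: precision / recall / F-score
  (`R = TP/(TP+FN)`, `P = TP/(TP+FP)`, `F = 2PR/(P+R)`), greedy IoU
  region matching, and traversal-based reaction-graph comparison that
  handles cyclic schemes.

## Worked example

Compose an artificial two-step scheme, run the pipeline with the
ground-truth (oracle) detection backend, and compare the recovered graph
with the ground truth:

```r
library(rxnscheme)

bank   <- build_element_bank(seed = 1)
schema <- schema_spec("linear", n_steps = 2, p_label = 1, p_conditions = 1)
sc     <- compose_scheme(schema, bank, seed = 42)

ex <- extract_scheme(sc$image, pipeline_config("oracle"),
                     annotation = sc$annotation)
ex
#> <scheme_extraction: 8 region(s), 2 arrow(s), 2 step(s)>
#> <reaction_graph: 3 node(s), 2 step(s)>
#>   [arrow 2] {1} -> {3}  (conditions 9)
#>   [arrow 4] {3} -> {5}  (conditions 10)

prf_metrics(match_graphs(ex$graph, sc$annotation$graph))
#> recall 100.0%  precision 100.0%  F-score 100.0%  (tp=2 fn=0 fp=0)
```

The printed graph reads: diagram 1 reacts to diagram 3 (under the
conditions in region 9), which reacts on to diagram 5 — the two steps of
the generated chain, recovered exactly. Detection metrics work on plain
counts:

```r
prf_metrics(confusion_counts(tp = 1131, fn = 43, fp = 51))
#> recall 96.3%  precision 95.7%  F-score 96.0%  (tp=1131 fn=43 fp=51)
```

To train the arrow model at desk scale and run a learned extraction, see
`make_arrow_patch_dataset()`, `train_arrow_model()`,
`train_region_model()` and `extract_scheme()` with
`pipeline_config("learned", ...)`; a thin command-line front end with
verbs `generate`, `train-arrows`, `train-regions`, `extract`, `evaluate`
lives at `inst/cli/rxnscheme.R`.

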