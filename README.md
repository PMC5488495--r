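# cellpath

Semisupervised cell detection in 2-D microscopy images from dot
annotations on extremal-region trees.

## The problem

Counting and localizing cells in dense microscopy images normally requires
painstaking mask annotation. `cellpath` needs only *dots* — one click
inside each training cell, and only inside a few small subimages. Cell
candidates are the maximally stable extremal regions (MSER) of the image
(or of a learned pixel-probability map), organized by nesting into a
component tree per connected component. A one-hidden-layer perceptron
f̃<sub>w</sub>(x) scores each candidate region on intensity, area, shape,
and texture features, and is trained by maximum a posteriori estimation of

L(w, σ<sub>s</sub>, σ<sub>u</sub>) = N<sub>p</sub> log σ<sub>u</sub> +
‖**1** − F̃<sub>w</sub>‖² / 2σ<sub>u</sub>² + ‖w‖²/2 +
‖y<sub>s</sub> − f̃<sub>w</sub>(X<sub>s</sub>)‖² / 2σ<sub>s</sub>² +
N<sub>s</sub> log σ<sub>s</sub>,

where the supervised quadratic loss uses region labels induced from the
dots (the largest region on each path containing exactly one dot) and the
unsupervised term is a differentiable relaxation of the *path-consistency
constraint* — along every root-to-leaf chain of nested candidates at most
one region may be a cell:

F̃<sub>i</sub> = 1 − ∏<sub>j=0..n</sub> (1 − ∏<sub>k</sub>
f̃<sub>j</sub>(x<sub>d<sup>k</sup></sub>)),  with f̃<sub>j</sub> = f̃ for
j = k and 1 − f̃ otherwise (the j = n disjunct negates every node).

This DNF relaxation equals the exact at-most-one indicator at binary
scores. The noise scales σ<sub>s</sub>, σ<sub>u</sub> are re-estimated in
closed form during training. Final detections are the energy-minimizing
set of non-overlapping regions, found exactly by a bottom-up/top-down
dynamic program on each tree (a greedy per-path argmax is also provided),
and are evaluated by Hungarian matching of centroids to ground-truth dots
(precision / recall / F-score) and DICE against instance masks.

Everything is testable without downloads: a synthetic-scene module renders
reproducible fields of touching, jittered elliptical cells with dots and
instance masks.

## Worked example

```r
library(cellpath)

# a reproducible synthetic scene with ground truth
scene <- generate_scene(scene_spec_easy())
scene
#> synthetic scene: 192x192 px, 60 cells, polarity bright, seed 1

# candidate regions: the stability-selected component forest
forest <- build_forest(scene$image, min_area = 25, max_area = 369,
                       max_variation = 1, min_diversity = 0.5)
forest
#> region forest: 76 regions, 55 trees, image 192x192

# dot-induced supervision: the largest single-dot region per path
labels <- induce_region_labels(forest, scene$dots)
sum(labels)
#> [1] 58            # 58 of the 60 cells have a usable candidate region
```

76 candidate regions in 55 trees for 60 cells means most cells contribute
one clean candidate and touching pairs contribute a small tree (pair blob
plus the two cells) whose ambiguity the path constraint and the dynamic
program resolve. The full pipeline — training both arms on one annotated
subimage and scoring held-out scenes — is wrapped in the benchmark:

```r
res <- benchmark_run(benchmark_config(seed = 1))
benchmark_summary(res)
#>   k        arm method transductive    f_mean        f_sd
#> 1 1         ss     dp        FALSE 0.8814661 0.000776383
#> 2 1 supervised     dp        FALSE 0.9170555 0.017977696
```

Both arms detect with F ≈ 0.9 from a single annotated subimage; the
semisupervised arm is an order of magnitude more stable across annotation
draws (f_sd), the supervised arm slightly ahead on the mean under these
clean conditions. The methods vignette
(`vignettes/cell-detection-methods.Rmd`) discusses when each effect
dominates and why.

A command-line driver for the staged pipeline (synthesize, probability
maps, trees, train, detect, evaluate, benchmark) is installed at
`inst/cli/cellpath`:

```sh
Rscript inst/cli/cellpath synth --config run.yaml --seed 1 --out out/
```

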