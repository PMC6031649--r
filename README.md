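# popcontext

Neighbourhood-aware phenotyping for microscopy: classify each cell or
tissue superpixel not just from its own appearance, but from the
population context it sits in.

## Why

Single-cell analysis pipelines (CellProfiler-style) score each segmented
object from *regular* features — intensity, texture and shape of its own
pixels. That throws away the micro- and macroenvironment: colonies create
microenvironmental gradients, and tissue is a structured mosaic in which
neighbouring components predict each other. Two objects can share
near-identical regular features (a urothelial cancer cell and a
fibroblast in an HE section) while their surroundings differ completely.
`popcontext` implements and evaluates the population-context remedy, for
image cytometrists and digital-pathology researchers.

## What it computes

For each object with centroid $c_i$ (within one image), a neighbourhood
is selected either as the $K$ nearest objects by Euclidean distance
(*KNN*) or as all objects with $\lVert c_j - c_i \rVert \le n$ pixels
(*N-distance*). For $F$ regular features the neighbourhood contributes

* $5F$ aggregates — mean, median, sd, min, max of each regular feature
  over the neighbours,
* 5 distance statistics (mean, median, sd, min, max of the neighbour
  distances),
* and, for the radius rule, the neighbour count (the extent of the
  neighbourhood),

giving $5F+5$ (KNN) or $5F+6$ (radius) context columns that can be used
alone or combined with the regular set. Classifiers (Naive Bayes, random
forest, linear SVM, multinomial logistic, MLP) are scored by *image-level*
k-fold cross-validation — whole images are assigned to folds so spatial
context can never leak across the train/test split — with z-scoring and
99%-coverage PCA fitted per training fold where applicable. Sweeps over
neighbourhood extent and SLIC superpixel size map where context helps
most. Segmentation front-ends (adaptive-Otsu nuclei + seeded cytoplasm
for cultures, SLIC with connectivity enforcement for tissue), feature
extraction, and synthetic culture-/tissue-like data generators complete
the pipeline; external CSV feature tables are accepted anywhere.

## Worked example

Generate a tissue-like dataset (virtual HE section, superpixel grid at
SLIC size 35), augment with 10-nearest-neighbour context, and compare the
regular-only and combined views under 10-fold image-level CV:

```r
library(popcontext)

ds       <- simulate_tissue(tissue_sim_params(seed = 1))
tab      <- ds$tables[["35"]]
ann      <- ds$annotations[["35"]]
combined <- augment_features(tab, neighbourhood_config("knn", K = 10))

spec    <- classifier_spec("random_forest", seed = 1)
regular <- cross_validate(combined, ann, 10, spec, view = "regular")
context <- cross_validate(combined, ann, 10, spec, view = "combined")
print(combined)
print(regular)
print(context)
```

```
<feature_table> 3380 objects x 65 features (distance_stat: 5, neighbourhood: 50, regular: 10)
<eval_result> random_forest / regular view: accuracy 0.5583 (1200 objects, 10 folds)
<eval_result> random_forest / combined view: accuracy 0.6950 (1200 objects, 10 folds)
```

Regular features alone reach 55.8% on the nine tissue classes — capped by
a deliberately confusable cancer/fibroblast pair whose local features are
statistically identical. Adding the neighbourhood block lifts accuracy to
69.5%, a 13.7-point gain: the context (lumen and endothelium around
cancer, stroma and muscle around fibroblasts) resolves what local
appearance cannot. `sweep_neighbourhood()` traces accuracy against K or
radius (cultures rise to a plateau; tissue peaks at an interior size),
and `sweep_superpixel_surface()` locates the best superpixel size.

A thin CLI over the same functions is in `inst/cli/popcontext`
(`simulate`, `segment`, `features`, `neighbours`, `evaluate`).

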