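# unisig

One gene signature for two clinical questions. `unisig` selects a single
expression signature that simultaneously classifies tumour subtype and
stratifies survival risk, for settings — such as diffuse large B-cell
lymphoma with its ABC and GCB subtypes — where the two outcomes are
entangled. It is aimed at computational biologists who want the full
selection chain (ranking, cross-validated evaluation, signature-size
choice) as reusable, tested functions rather than a one-off script.

## Method

Samples carry a four-class label: the cross of subtype and vital status,
(ABC, GCB) × (dead, alive). The pipeline is:

1. **Preprocess**: average duplicate probes to genes, drop low-mean genes,
   quantile-normalize.
2. **Rank genes by mRMR**: expression is discretized to three levels at
   mean ± t·sd; relevance of gene *g* is the mutual information
   *I(g; c)* with the four-class label *c*, redundancy is the mean
   *I(g; s)* over already-selected genes *s*, and genes are picked greedily
   to maximize relevance − redundancy.
3. **Classify by nearest neighbour** under the cosine-derived distance
   *D(x, y) = 1 − ⟨x, y⟩ / (‖x‖‖y‖)*, with leave-one-out cross-validation.
4. **Incremental feature selection**: for every prefix size *k* of the
   ranked list, the four-class predictions are merged two ways —
   subtype (ABC vs GCB, scored as overall accuracy) and risk
   (dead-labelled predictions = high risk, scored by the log-rank test on
   observed survival) — giving two curves over *k*.
5. **Balanced choice**: within *k* < 100, both curves are min-max
   normalized and summed; the argmax is the unified signature.

Kaplan–Meier estimation and the two-group log-rank test are implemented in
the package and cross-checked against the `survival` package in the test
suite. A seeded generator (`simulate_dataset()`) produces four-group
expression/survival cohorts with planted subtype- and survival-informative
genes so that the entire chain is testable without external data.

## Worked example

```r
library(unisig)

d <- simulate_dataset(simulation_config(
  n_genes = 500, group_sizes = c(40, 40, 40, 40),
  n_subtype_genes = 10, n_survival_genes = 10,
  effect_size = 2, hazard_ratio = 3, seed = 1))

ranked <- rank_features(d$expression, phenotype_groups(d$phenotype), n_select = 100)
curve  <- ifs_run(d$expression, ranked, d$phenotype, k_max = 100)
select_balanced(curve, ranked, k_max = 100)
#> Signature of 29 genes (window k in [1, 100))
#>   subtype accuracy: 0.9812
#>   log-rank p:       1.87e-20
#>   genes: g0001, g0016, g0011, g0005, g0004, g0019, g0018, g0009, g0013, g0002, ...
```

From a 500-gene background with 20 planted informative genes, the selected
29-gene signature assigns 98.1 % of the 160 samples to the correct subtype
after merging, and its predicted high- and low-risk groups separate in
survival at p ≈ 2 × 10⁻²⁰. `run_pipeline()` wraps the same chain with
artifact persistence and a JSON report; the `analysis/` directory holds
numbered driver scripts (`01_simulate.R` … `05_signature.R`) that run the
study step by step and write their tables under `results/`.

## Documentation

The methods vignette (`vignettes/unified-signature-selection.Rmd`) explains
the model, the synthetic generator and its statistical quirks, all
tie-breaking and degenerate-input rules, and the design decisions taken
where the procedure left choices open.
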