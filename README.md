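# mcoselect

Deterministic gene selection by multiple criteria optimization: rank genes
by Pareto-efficient frontiers over conflicting expression-change measures,
with no significance thresholds, no distributional assumptions and no
user-tuned parameters.

## The problem and who this is for

Given a case/control expression experiment (microarray, bulk or single-cell
counts summarized to a matrix — any comparative layout with replicates),
"which genes changed most?" has no single answer: the gene with the largest
mean shift is rarely the gene with the largest median shift. Threshold- and
test-based pipelines resolve the conflict with parameters the analyst must
pick, which costs objectivity (different analysts, different lists) and
repeatability. `mcoselect` instead treats each gene as a point in a space of
*performance measures* (PMs) and keeps the genes that no other gene beats in
every measure simultaneously — the Pareto-efficient frontier of a
minimization problem. It is aimed at bioinformaticians who want a
reproducible first-pass biomarker shortlist, especially from sex-annotated
studies or from several small studies that should be analyzed jointly.

## The method

For gene *g* and location statistic *c* (mean, median, mode, a quantile),
compute the absolute between-group difference and flip it to a minimization
criterion with a linear map:

    PM_gc = | stat_c(g in group A) − stat_c(g in group B) |
    x_gc  = max_h PM_hc − PM_gc

Gene *u* **dominates** *v* when `x_u ≤ x_v` in every criterion and `<` in at
least one. Frontier 1 is the non-dominated set ("no other gene offers a
better compromise"); removing it and repeating yields frontiers `1..F`, a
hierarchy with decreasing significance. Two modes are supported:

* **single** — one dataset, 2–3 PMs on one comparison;
* **meta** — 2–5 datasets, one PM each (median by default), joined on gene
  ids by strict intersection, so Pareto efficiency spans datasets without
  unit harmonization.

With sex annotations, `run_four_way()` runs the analysis on four group
pairs — MaleControl–MaleCase (MCO 1), FemaleControl–FemaleCase (MCO 2),
MaleControl–FemaleControl (MCO 3), MaleCase–FemaleCase (MCO 4) — and
returns the condition-specific genes of interest
`(MCO1 ∩ MCO2) \ (MCO3 ∪ MCO4)`.

## A worked example

```r
library(mcoselect)

sim <- simulate_dataset(n_genes = 3000, effect_size = 8, seed = 1)
fw  <- run_four_way(sim$dataset, mode = "single",
                    pm_specs = c("mean", "median"), n_frontiers = 10)
fw
#> <mco_fourway> single mode, F = 10
#>   MCO1 (MaleControl vs MaleCase): 14 gene(s)
#>   MCO2 (FemaleControl vs FemaleCase): 39 gene(s)
#>   MCO3 (MaleControl vs FemaleControl): 14 gene(s)
#>   MCO4 (MaleCase vs FemaleCase): 14 gene(s)
#>   genes of interest (MCO1 & MCO2, not MCO3 | MCO4): 10
```

The simulation plants 10 condition-responsive genes (shifted in the case
groups of both sexes) and 10 sex-dimorphic genes (shifted in both female
groups) among 2980 nulls. The four-way scheme selects exactly the 10
planted condition genes — the sex genes populate MCO 3/MCO 4 and are
subtracted away:

```r
td <- tidy(fw)
head(td[td$selected, c("gene", "frontier_MCO1", "frontier_MCO2")])
#> # A tibble: 6 × 3
#>   gene      frontier_MCO1 frontier_MCO2
#>   <chr>             <int>         <int>
#> 1 gene00001             6             2
#> 2 gene00002             2             1
#> 3 gene00003             1             1
#> 4 gene00004             8             2
#> 5 gene00005             3             1
#> 6 gene00006             7             3
```

`frontier_MCO1 = 1` means the gene was on the first (most significant)
frontier of the male disease comparison; larger indices are later peels.
`autoplot(fw$fits$MCO1)` draws the criteria-space scatter with frontier
genes highlighted — solutions toward the origin are the most significant.

Real data enters through TSV files (`read_expression()`: a matrix with
feature ids in the first column and sample ids in the header, plus a sheet
with `sample`, `condition`, optional `sex`), with optional probe-to-gene
collapsing (`collapse_probes()`). The same flows are scriptable from a
shell via `inst/cli/mco` (`single`, `meta`, `fourway`, `simulate`, `plot`
subcommands); every run writes TSV outputs plus a timestamp-free manifest,
so reruns are byte-identical.

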