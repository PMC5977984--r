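# miRResponse

Not every patient responds to a given drug, and for slow-acting
anti-rheumatic therapies a failed three-month trial is three months lost.
`miRResponse` implements an integrative systems-biology pipeline for
nominating **circulating miRNA biomarkers of drug response** from paired
miRNA/mRNA expression profiles of responder and non-responder cohorts, and
for predicting responder status from the resulting miRNA panel with an
RBF-kernel support vector machine. It is aimed at translational
transcriptomics groups working with small clinical cohorts (microarray or
qPCR read-outs of PBMC samples) who need every stage — screening, network
integration, panel assembly, cross-validated classification — reproducible
and testable.

## The method

Given log2 expression matrices for miRNAs and mRNAs over the same samples,
two target-prediction tables, and a scored gene–gene interaction table, the
pipeline runs:

1. **Differential screening (RVM moderated t-test).** Per-feature pooled
   variances s² are shrunk toward an inverse-gamma prior fitted across all
   features; under the random variance model s²·a·b ~ F(d, 2a) with
   d = n₁+n₂−2. The moderated statistic

       t = (x̄₁ − x̄₂) / √(σ̃² (1/n₁ + 1/n₂)),   σ̃² = (d·s² + 2/b) / (d + 2a)

   has d + 2a degrees of freedom — the extra 2a is what rescues power at
   n = 6 vs 6. Features with |log2FC| > 0.5 and P < 0.05 (both strict) are
   kept; BH q-values are reported. Hierarchical clustering (1 − Pearson r,
   average linkage) summarises the expression patterns.
2. **Target intersection and co-expression network.** Only miRNA–target
   pairs predicted by *both* programs survive. An edge requires both
   endpoints differentially expressed, Pearson r < 0 across all samples
   with correlation-test P < 0.05, and opposite fold-change directions.
   miRNAs are ranked by degree ("key miRNA" = biggest degree).
3. **Signal-transduction network topology.** Interactions scoring strictly
   above the global combined-score median, restricted to DE target genes,
   form an undirected gene graph. For each node the pipeline computes
   degree, relative betweenness C′B(v) = [2/(n²−3n+2)] Σ σₛₜ(v)/σₛₜ and
   closeness C(i) = 1/Σ d(y,i); **hub genes** exceed all three medians
   simultaneously (strictly). Markov clustering (expansion 2, inflation 2)
   partitions the graph into functional modules, tested for gene-set
   enrichment with the hypergeometric tail. **Edge betweenness** ranks
   interactions; the top-scoring edges are the key signal-transfer
   interactions.
4. **Panel assembly.** The endpoint genes of the top edge-betweenness
   interactions anchor the panel: for each anchor gene, its most
   significantly dysregulated upstream miRNA (smallest DE p-value) in the
   co-expression network is selected, de-duplicated.
5. **Response classification.** An RBF-kernel SVM,
   K(xᵢ,xⱼ) = exp(−γ‖xᵢ−xⱼ‖²), on the panel miRNA levels, evaluated by
   repeated stratified 5-fold cross-validation (fold-internal feature
   scaling; pooled confusion counts; sensitivity = TP/(TP+FN),
   specificity = TN/(TN+FP), accuracy = (TP+TN)/N; AUC as the
   tie-corrected Mann–Whitney probability), by independent-cohort testing,
   and by DeLong comparisons against single-marker and clinical-covariate
   ROC curves. A comparative-CT helper (2^−ΔΔCt) converts qPCR read-outs.

A synthetic-cohort generator with planted ground truth (group-shifted
miRNAs, anti-correlated targets, decoy predictions, a community-structured
interaction graph with a high-betweenness bridge) makes the whole pipeline
testable end to end without clinical data.

## Worked example

```r
library(miRResponse)
demo <- runDemo(seed = 1, validation = c(15, 16))

demo$sim$mirna
#> ExpressionMatrix (miRNA): 30 features x 12 samples
#>   groups: 6 responder / 6 non_responder

panelTable(demo$result$panel)
#>  mirna_id anchor_gene log2fc  p_value
#>   miR-001     GENE001   1.59 1.95e-08
#>   miR-002     GENE005  -1.79 1.04e-09

demo$result$cv
#> CVReport: 5 repeats x 5 folds (seed 1)
#>   accuracy 1.000 +/- 0.000, sensitivity 1.000, specificity 1.000, AUC 1.000

demo$result$topology$partition
#> ModulePartition: 7 nodes in 2 modules (sizes 4/3); converged in 9 iterations
```

The simulated discovery cohort (6 responders vs 6 non-responders) carries
two planted miRNAs with |log2FC| = 1.5 of opposite sign; the pipeline
recovers exactly those two as the panel, anchored by the two hub genes
joined by the planted bridge interaction (`GENE001–GENE005`, edge
betweenness 12, the unique maximum). Cross-validated accuracy and AUC are
1.0 on this cohort, and the model trained on the discovery cohort
classifies an independent 31-sample synthetic validation cohort with
accuracy 1.000 and AUC 1.000. A tiny fixed cohort of the same design ships
under `inst/extdata/worked_example/` in the package's plain-text formats.

Real data enter through `readExpression()` (TSV or GEO series-matrix
dialect), `readTargetPairs()`, `readInteractions()` and
`readSampleAnnotation()`, then `runPipeline()` with a `runConfig()`.

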