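# bcl2panel

Cross-entity analysis of BCL2-family gene expression in mature B-cell
malignancies, and the search for an expression-ratio biomarker of
venetoclax sensitivity.

## The problem

Venetoclax (a BCL2-selective BH3-mimetic) shows very unequal
monotherapy overall response rates (ORR) across B-cell malignancies:
roughly 79% in CLL, 75% in MCL, 38% in FL, 21% in MM and 18% in DLBCL.
The hypothesis behind this package is that the transcriptional balance
between venetoclax *efficacy* genes — *BCL2*, *BCL2L11* (Bim), *BAX* —
and *resistance* genes — *MCL1*, *BCL2L1* (Bcl-xL), *BCL2A1* — explains
that spread, and that the best predictor among ratios of the form

```
          sum of log2 expression over N ⊆ {BCL2, BCL2L11, BAX}
score  =  ----------------------------------------------------
          sum of log2 expression over D ⊆ {MCL1, BCL2L1, BCL2A1}
```

is the candidate (BCL2 + BCL2L11 + BAX) / BCL2L1, found by ranking all
(2³−1)² = 49 subset pairs by their correlation with entity-level ORR.

Getting there requires a pipeline that the package implements end to
end, for anyone who works with pooled public microarray compendia:

1. **synthetic corpus** (`generate_dataset`) — a multi-series,
   multi-entity expression simulator with planted ground truth (entity,
   tissue-niche and subtype effects; batch offsets; multi-probe genes of
   heterogeneous fidelity; a planted ratio→ORR link), so that every
   later stage is testable by parameter recovery;
2. **harmonization** (`quantile_normalize`, `flag_outliers`,
   `anchor_qc`) — pooled quantile normalization, removal of
   decorrelated samples, and anchoring-gene QC (CCND1/SOX11 in MCL,
   SDC1/CD38 in MM, …);
3. **probe selection** (`select_probes`, `collapse_to_genes`) — one
   probe per gene, chosen by Pearson concordance with matched cell-line
   RNA-seq (19 lines), discarding non-concordant genes (BAD, HRK) and
   the a-priori exclusion BBC3;
4. **differential profiling** (`compare_profiles`, `median_profile`,
   plus `rank_sum_test`, `kruskal_wallis_test`, `fisher_exact_test`) —
   nonparametric contrasts with the figure star convention;
5. **factor maps** (`pca_fit`, `confidence_ellipse`,
   `variable_correlation_circle`) — correlation PCA with 95% barycenter
   confidence ellipses of the group mean (Hotelling form);
6. **transformation analysis** (`train_entity_classifier`,
   `score_transformation`) — a 1,000-tree random forest on the 12-gene
   family space; transformed FL/MALT being re-labeled DLBCL is
   quantified by a 2×2 odds ratio and Fisher p;
7. **ratio search** (`enumerate_ratio_specs`, `rank_ratio_candidates`,
   `compare_ratio_by_group`) — the 49-candidate enumeration against
   ORR, and niche/subgroup comparisons of the winning score.

`run_pipeline()` chains all stages; the numbered scripts under
`analysis/` run them as a narrative workflow writing tables under
`results/`.

## Worked example

```r
library(bcl2panel)
cfg <- synth_config(seed = 7, n_genes = 100, n_probes = 250,
                    sample_sizes = c(MCL = 40, DLBCL = 60, FL = 50, CLL = 50,
                                     MM = 50, MBC = 8, CC = 7, CB = 8, BMPC = 7))
result <- run_pipeline(cfg, n_trees = 1000)

result$harmonized$qc$pass
#> [1] TRUE

head(as.data.frame(result$ranking), 3)
#>   rank        numerator denominator         r            p   n
#> 1    1 BAX+BCL2+BCL2L11      BCL2L1 0.8821109 4.753189e-83 250
#> 2    2         BAX+BCL2      BCL2L1 0.8794929 6.111772e-82 250
#> 3    3     BCL2+BCL2L11      BCL2L1 0.8782550 2.002768e-81 250

result$transformation$FL$table
#>            status
#> predicted   aggressive indolent
#>   DLBCL             11        0
#>   not_DLBCL          0       39
signif(result$transformation$FL$p, 3)
#> [1] 2.68e-11
```

Reading: the anchoring-gene QC accepted the pooled normalization; the
planted (BAX+BCL2+BCL2L11)/BCL2L1 ratio is ranked 1 of 49 by per-sample
Pearson correlation with entity ORR (r = 0.88 over 250 samples of the
five trial entities); and the random forest re-labels all 11 transformed
FL samples as DLBCL while calling none of the 39 indolent ones DLBCL
(infinite sample odds ratio, Fisher p = 2.7e-11).

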