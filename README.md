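# comormine

Literature-based comorbidity mining and multimorbidity gene-set analysis
in R.

Clinicians and bioinformaticians who want to know which diseases travel
together with an index disease — and which genes those diseases share —
usually start from electronic health records. `comormine` implements the
lighter, literature-first route: it mines the MeSH indices of
MEDLINE/PubMed records for co-occurring diseases, ranks and tests them,
and then intersects disease gene sets to expose multimorbidity
signatures.

The pipeline has four stages:

1. **Lexicon** — a dictionary of MeSH disease descriptors (term +
   disease-category provenance), deduplicated after normalization, with
   category-level exclusion (e.g. `Animal Diseases`). Headings are matched
   exactly after stripping the major-topic marker `*` and any `/qualifier`.
2. **Co-occurrence ranking** — for an index disease *D*, every article
   whose MeSH index contains *D* and at least one other lexicon disease
   contributes to `P_all`; each co-disease *c* is ranked by its **sort
   ratio**

   ```
   sort ratio(c) = P_eachPair(c) / P_all
   ```

   where `P_eachPair(c)` counts articles indexed with both *D* and *c*.
3. **Significance** — each pair is summarised by four counts over the
   comorbidity-tagged corpus (joint articles; co-disease articles; index
   articles; corpus size) and tested with a one-sided **Fisher exact
   test** computed in log space (log-gamma terms combined by
   log-sum-exp), so p-values near the double-precision floor (~1e-300)
   are returned without underflow. Significance uses the strict
   genome-wide-style threshold `p < 5e-8` by default. How the four counts
   map onto the 2×2 table is configurable (`margins`, `direct`,
   `remainder`); the default `margins` convention treats the co-disease
   and index counts as inclusive margins, which is the convention that
   reproduces published worked-example p-values from their printed counts
   (see the vignette).
4. **Gene sets** — disease gene sets (GMT format, e.g. exported from
   GeneWeaver) are grouped by *exact membership signature*: each gene is
   assigned the precise set of diseases whose sets contain it, and every
   signature holding the index disease plus at least two others becomes a
   multimorbidity row. Grouping is maximal, so rows partition the
   multimorbid genes.

A synthetic-data module (`simulate_corpus()`, `simulate_genesets()`)
generates MEDLINE corpora with planted conditional co-occurrence lift and
GMT collections with planted shared cores, so every stage is testable
without network access.

## Worked example

The package ships the published four-count rows for Alzheimer disease
(AD) and its top five co-occurring diseases. Sort ratios from the printed
counts:

```r
library(comormine)
sort_ratio(c(142, 95, 60, 51, 43), 843)
#> [1] 0.16844603 0.11269277 0.07117438 0.06049822 0.05100830
```

Fisher significance from the printed four counts:

```r
counts <- tibble::tibble(
  co_disease = c("Dementia", "Type 2 diabetes", "Hypertension",
                 "Parkinson's disease", "Down syndrome"),
  n_both  = c(142L, 95L, 60L, 51L, 43L),
  n_cd    = c(220L, 11209L, 6726L, 683L, 346L),
  n_idx   = c(1066L, 1113L, 1148L, 1157L, 1165L),
  n_total = 125924L)
comorbidity_significance(counts)
#> <comorbidity_result> 5 pair(s), 3 significant at alpha = 5e-08 (margins, greater)
#> # A tibble: 5 × 7
#>   co_disease          n_both  n_cd n_idx n_total   p_value significant
#> * <chr>                <int> <int> <int>   <int>     <dbl> <lgl>
#> 1 Dementia               142   220  1066  125924 1.30e-238 TRUE
#> 2 Down syndrome           43   346  1165  125924 1.88e- 34 TRUE
#> 3 Parkinson's disease     51   683  1157  125924 6.28e- 30 TRUE
#> 4 Hypertension            60  6726  1148  125924 5.88e-  1 FALSE
#> 5 Type 2 diabetes         95 11209  1113  125924 6.82e-  1 FALSE
```

Dementia, Down syndrome and Parkinson's disease are flagged as
significant comorbidities of AD; hypertension and type 2 diabetes
co-occur frequently but not beyond what their overall literature volume
predicts. `tidy()`, `glance()` and `autoplot()` methods are available on
the result.

Multimorbidity signatures from a (synthetic, exact-membership) gene-set
collection shipped with the package:

```r
gmt <- system.file("extdata", "synthetic_ad_genesets.gmt", package = "comormine")
coll <- read_gmt(gmt, index_disease = "Alzheimer Disease")
multimorbidity_table(coll)
#> # A tibble: 8 × 4
#>   diseases                                                        n_diseases n_genes genes
#> 1 Alzheimer Disease, Dementia, Down syndrome, Parkinson's disease          4       4 APOE, APP, MAPT, PSEN1
#> 2 Alzheimer Disease, Dementia, Hypertension, Parkinson's disease           4       2 HFE, NOS3
#> 3 Alzheimer Disease, Dementia, Parkinson's disease                         3       5 A2M, ABCA7, MPO, PLAU, PSEN2
#> 4 Alzheimer Disease, Dementia, Down syndrome                               3       2 COL18A1, SYNJ1
#> 5 Alzheimer Disease, Dementia, Hypertension                                3       1 TGFB2
#> 6 Alzheimer Disease, Dementia, Type 2 diabetes                             3       1 LAMA1
#> 7 Alzheimer Disease, Down syndrome, Parkinson's disease                    3       1 SORL1
#> 8 Alzheimer Disease, Hypertension, Type 2 diabetes                         3       1 NOTCH2
```

Each gene appears in exactly one row — `MAPT` is listed only under the
four-disease signature, never under its sub-signatures.

End-to-end runs over files are driven by `run_mine()` / `run_genesets()`
(config list or YAML), or from a shell via the thin CLI:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "comormine.R", package = "comormine"))')" \
  mine --lexicon lexicon.tsv --corpus corpus.txt --index "Alzheimer Disease" --out results/
```

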