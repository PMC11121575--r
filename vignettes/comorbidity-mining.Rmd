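---
title: "Comorbidity mining from MEDLINE records: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comorbidity mining from MEDLINE records: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comormine)
```

## The problem and the model

Comorbidity — the co-presence of another disease alongside an index
disease — is usually estimated from patient records. `comormine`
implements the literature-based alternative: PubMed articles are indexed
with MeSH descriptors, and when an article about the index disease is
*also* indexed with another disease descriptor and the `Comorbidity`
MeSH term, that co-indexing is treated as one literature report of the
pair. Aggregated over a corpus, these reports support two statistics.

**Ranking.** For index disease $D$, let $P_{\mathrm{all}}$ be the number
of articles whose MeSH index contains $D$ and at least one other lexicon
disease, and $P_{\mathrm{eachPair}}(c)$ the number containing both $D$
and co-disease $c$. The sort ratio

$$\mathrm{sort\ ratio}(c) = \frac{P_{\mathrm{eachPair}}(c)}{P_{\mathrm{all}}}$$

is the fraction of $D$'s pairing literature devoted to $c$. It is a
ranking device, not a test: a disease with an enormous literature can
rank high through volume alone.

**Testing.** Significance therefore comes from a Fisher exact test per
pair, built from four counts over the comorbidity-tagged corpus:
(i) articles with $D$ and $c$; (ii) articles with $c$; (iii) articles
with $D$; (iv) all articles. Under the default `margins` convention,
(ii) and (iii) are read as inclusive margins of the 2×2 table:

$$a = n_i,\quad b = n_{ii} - n_i,\quad c = n_{iii} - n_i,\quad
  d = n_{iv} - n_{ii} - n_{iii} + n_i,$$

i.e. the ordinary contingency table of "has $D$" against "has $c$" over
$N = n_{iv}$ articles, tested one-sided for enrichment of the joint
cell.

### Why `margins` is the default convention

The four-count scheme does not by itself fix the 2×2 table: one can also
treat (ii) and (iii) as overlap-free counts and use (iv) verbatim as the
fourth cell (`direct`) or use the remainder $N - a - b - c$
(`remainder`). We calibrated the choice on a published worked example
(an Alzheimer disease corpus of 125,924 comorbidity-tagged articles)
whose printed counts and p-values are both available. Only the
`margins` + `greater` combination reproduces all five printed p-values
from the printed counts (to within 1% relative, across 236 orders of
magnitude); `direct` + `greater` matches the two non-significant rows
but misses the extreme ones by ~50 orders of magnitude. All three
conventions remain selectable (`fet.convention` in pipeline configs),
as does the sidedness.

Two further testing choices: significance uses a *strict* inequality at
`alpha` (default `5e-8`, the conventional genome-wide threshold), and no
multiple-testing correction is applied by default, matching fixed-
threshold practice for this kind of screen; Benjamini–Hochberg
adjustment is available via `p_adjust = "BH"`.

## Numerical design of the Fisher test

The joint cell of a strongly comorbid pair can be so extreme that the
hypergeometric tail is far below anything a naive summation reaches.
`fisher_exact_pvalue()` therefore works entirely in log space: point
probabilities are log-gamma expressions (`lchoose`), and the tail is
combined by log-sum-exp, which keeps relative error near machine
precision regardless of magnitude. p-values down to the double floor
(~1e-300) are representable; the worked example's 1.3e-238 is returned
exactly rather than as 0.

The `two_sided` rule sums all tables whose point probability does not
exceed the observed one, with relative slack `1e-7` against ties lost to
floating-point rounding — the convention of the common implementations.
Degenerate all-zero tables are an error; a joint cell of 0 returns
p = 1 under `greater`, as it must at the bottom of the support.

Correctness is cross-checked along three independent routes in the test
suite: (1) `fisher_bruteforce_oracle()`, a compiled enumeration of every
table with the observed margins whose point probabilities are built by
multiplicative binomial-coefficient recurrences in 80-bit extended
precision (no log-gamma anywhere on that path; restricted to
$N \le 200$, where extended precision is exact to ~1e-17) — agreement is
required to 1e-10 relative over 500 random tables; (2) linear-space
tails via `stats::phyper` wherever $p > 10^{-10}$; (3) the discrete
complement identity
$p_{\mathrm{greater}} + p_{\mathrm{less}} = 1 + \Pr(\text{observed
table})$ on random tables.

## Lexicon and matching assumptions

Headings are normalized by stripping the major-topic marker `*`,
truncating at the first `/` (so qualifier-bearing index entries like
`Disease/therapy` collapse onto their descriptor — MEDLINE exports
qualify headings, and matching must not depend on that), mapping Unicode
apostrophes to ASCII, collapsing whitespace and lower-casing. Matching
is **exact** on the normalized string: MeSH entry terms and synonyms are
not expanded, because the MeSH index itself uses descriptor names
verbatim; fuzzy matching would manufacture false co-occurrences.

Category exclusion drops a descriptor only when *all* of its categories
are excluded: a disease cross-listed under both `Animal Diseases` and a
human category must survive. Descriptor counts before and after
deduplication are recorded as lexicon metadata (`source_count`,
`unique_count`) but never asserted — they depend on the MeSH release.

When contingency counts are derived from a long article–disease
membership table rather than a full corpus, the corpus size must be
passed explicitly (`n_total`): articles with no matched disease are
invisible in the membership representation, and silently using its
article count would shrink the fourth cell and bias every test toward
the null. The function refuses to guess.

## The synthetic-data generator

`simulate_corpus()` emulates the object the miner consumes: MEDLINE
records whose MeSH index carries an index disease (prevalence
`index_prevalence`), planted co-diseases with conditional probabilities
`p_given_index` / `p_given_not_index` (their ratio is the planted
lift), independent background diseases, and the `Comorbidity` tag on
every article. Diseases are sampled independently given index status —
the pipeline's statistics only ever see pairwise margins, so
higher-order dependence would add realism the tests cannot detect.
PMIDs are sequential integers prefixed `SYN` so synthetic corpora can
never collide with real ones. A single integer seed drives one
generator scoped to the call (`withr::with_seed`), leaving the session
RNG untouched, and fixed seeds give byte-identical corpora.

What passing the synthetic recovery tests shows — and does not show:
the pipeline correctly recovers pairwise conditional structure planted
under the model's independence assumptions. Real MeSH indexing is not
independent across diseases, indexing depth varies by journal and era,
and descriptor vocabularies drift; none of that is emulated, so the
synthetic results validate the *computation*, not literature mining as
an epidemiological instrument.

`simulate_genesets()` plants shared gene cores in exactly the declared
disease subsets plus disjoint private genes, so the exact-membership
signatures recovered by `multimorbidity_table()` are the declared cores
by construction — a round-trip check of the grouping semantics.

## Multimorbidity grouping

Genes are grouped by exact membership signature (the precise set of
disease gene-sets containing them); rows are signatures holding the
index disease and at least two comorbid diseases. Grouping is maximal:
a gene shared by four diseases appears only under its four-disease row,
never under the sub-signatures, so rows partition the multimorbid genes
and gene counts add up. Rows sort by signature size, then gene count,
then label; gene symbols are compared case-insensitively after
uppercasing, with no alias resolution (gene-set exports from curated
resources arrive already harmonized). Homology-expanded sets are out of
scope — single-species symbols only.

## Validation problem sizes

The packaged validation uses corpora of 20,000 articles: planted-lift
recovery (lift 15:1 at `p_given_index = 0.15` against 20 background
diseases at 0.01) over 20 replicate seeds, requiring the planted disease
to rank first and clear `p < 5e-8` in at least 95% of replicates; and a
null calibration (zero lift) over 200 replicates, requiring the
one-sided false-positive fraction at 0.05 to stay within [0.01, 0.10]
(the discreteness of the exact test makes it conservative, so the
fraction sits below the nominal 5%). The enumeration-oracle comparison
uses 500 random tables with $N \le 100$.

## Known limitations

- Co-indexing is an imperfect comorbidity proxy: an article can discuss
  two diseases without asserting their co-occurrence in patients, and
  indexing practice changes over time.
- Exact descriptor matching misses diseases mentioned only in free text
  or under entry-term synonyms.
- The corpus-level counts depend on the access date of the underlying
  query; published tallies are reproducible only from the archived
  corpus, not from a live query.
- The multimorbidity table is purely set-theoretic; it inherits whatever
  curation biases the input gene sets carry, and pathway, network and
  drug-perturbation layers downstream of the gene intersections are
  outside the package's scope.
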