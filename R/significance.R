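#' Assemble 2x2 contingency cells from the four literature counts
#'
#' The mining step summarises each index/co-disease pair by four counts
#' obtained from Boolean MeSH queries over the comorbidity corpus:
#' \describe{
#'   \item{`n_both`}{articles with the index disease and the co-disease (i);}
#'   \item{`n_cd`}{articles with the co-disease (ii);}
#'   \item{`n_idx`}{articles with the index disease (iii);}
#'   \item{`n_total`}{total comorbidity-tagged articles (iv).}
#' }
#' How the four counts map onto the 2x2 table is governed by `convention`:
#' \describe{
#'   \item{`"margins"`}{counts (ii) and (iii) are read as *inclusive* margins
#'     (they contain the joint articles), giving the standard table
#'     `(a, b - a, c - a, N - b - c + a)`. This is the default: it is the
#'     convention calibrated to reproduce the published p-values from the
#'     published counts (see the package vignette).}
#'   \item{`"direct"`}{counts (ii) and (iii) are overlap-free and count (iv)
#'     is used verbatim as the fourth cell: `(a, b, c, N)`.}
#'   \item{`"remainder"`}{counts (ii) and (iii) are overlap-free and the
#'     fourth cell is the remainder `N - a - b - c`.}
#' }
#'
#' @param counts Data frame with integer columns `n_both`, `n_cd`, `n_idx`,
#'   `n_total` (one row per co-disease; extra columns are preserved).
#' @param convention One of `"margins"`, `"direct"`, `"remainder"`.
#' @return The input tibble with integer cell columns `a`, `b`, `c`, `d`
#'   appended.
#' @examples
#' assemble_table(data.frame(n_both = 142, n_cd = 220, n_idx = 1066,
#'                           n_total = 125924), convention = "direct")
#' @export
assemble_table <- function(counts,
                           convention = c("margins", "direct", "remainder")) {
  convention <- match.arg(convention)
  stopifnot(is.data.frame(counts))
  need <- c("n_both", "n_cd", "n_idx", "n_total")
  if (!all(need %in% names(counts))) {
    abort(paste0("`counts` needs columns ", paste(need, collapse = ", "), "."))
  }
  counts <- as_tibble(counts)
  if (any(counts[need] < 0)) abort("Counts must be non-negative.")
  out <- counts %>% mutate(
    a = as.numeric(.data$n_both),
    b = switch(convention,
               margins = .data$n_cd - .data$n_both,
               .data$n_cd * 1),
    c = switch(convention,
               margins = .data$n_idx - .data$n_both,
               .data$n_idx * 1),
    d = switch(convention,
               margins = .data$n_total - .data$n_cd - .data$n_idx + .data$n_both,
               direct = .data$n_total * 1,
               remainder = .data$n_total - .data$n_both - .data$n_cd - .data$n_idx))
  if (any(out$b < 0 | out$c < 0 | out$d < 0)) {
    abort(sprintf("Inconsistent counts under convention %s: negative cell.",
                  dQuote(convention)))
  }
  out
}

#' Exact Fisher test p-value, computed in log space
#'
#' One- or two-sided Fisher exact test on a 2x2 table, accumulating the
#' hypergeometric tail as log-gamma terms combined by log-sum-exp, so
#' p-values far below the reach of naive summation (down to the
#' double-precision floor, around 1e-300) are returned without underflow.
#' The `two_sided` rule sums all tables whose point probability does not
#' exceed that of the observed table, within relative slack 1e-7 (the
#' convention used by common implementations).
#'
#' @param a,b,c,d Integer vectors (recycled): the 2x2 cells, `a` being the
#'   joint (index AND co-disease) cell.
#' @param alternative `"greater"` (enrichment of the `a` cell, the
#'   default), `"less"`, or `"two_sided"`.
#' @return Numeric vector of p-values in `(0, 1]`.
#' @examples
#' fisher_exact_pvalue(2, 0, 0, 2, alternative = "greater")   # 1/6
#' fisher_exact_pvalue(142, 78, 924, 124780)                  # ~1.3e-238
#' @export
fisher_exact_pvalue <- function(a, b, c, d,
                                alternative = c("greater", "less", "two_sided")) {
  alternative <- match.arg(alternative)
  n <- max(length(a), length(b), length(c), length(d))
  cells <- tibble(a = rep_len(as.numeric(a), n), b = rep_len(as.numeric(b), n),
                  c = rep_len(as.numeric(c), n), d = rep_len(as.numeric(d), n))
  if (any(cells < 0)) abort("Cells must be non-negative.")
  if (any(rowSums(cells) == 0)) abort("Degenerate all-zero table.")
  vapply(seq_len(n), function(i) {
    fisher_logspace_one(cells$a[i], cells$b[i], cells$c[i], cells$d[i],
                        alternative)
  }, numeric(1L))
}

# log P(X = k) for X ~ Hypergeometric(N, K, n) via log-gamma
log_hyper_pmf <- function(k, N, K, n) {
  lchoose(K, k) + lchoose(N - K, n - k) - lchoose(N, n)
}

logsumexp <- function(x) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

fisher_logspace_one <- function(a, b, c, d, alternative) {
  K <- a + b          # first-row margin
  n <- a + c          # first-column margin
  N <- a + b + c + d
  lo <- max(0, n - (N - K))
  hi <- min(K, n)
  support <- lo:hi
  lp <- log_hyper_pmf(support, N, K, n)
  lp_obs <- lp[support == a]
  p <- switch(alternative,
    greater = exp(logsumexp(lp[support >= a])),
    less = exp(logsumexp(lp[support <= a])),
    two_sided = exp(logsumexp(lp[lp <= lp_obs + log1p(1e-7)])))
  min(p, 1)
}

#' Classify significant comorbidities from four-count tables
#'
#' Assembles the contingency cells for every co-disease, computes exact
#' Fisher p-values in log space, and flags the significant comorbidities by
#' strict comparison against `alpha`. The published analysis applies a
#' fixed genome-wide-style threshold of 5e-8 with no multiple-testing
#' correction; a Benjamini-Hochberg option is available but off by default.
#'
#' @param counts Data frame with columns `co_disease`, `n_both`, `n_cd`,
#'   `n_idx`, `n_total`.
#' @param alpha Significance threshold in `(0, 1)`; default `5e-8`.
#' @inheritParams assemble_table
#' @inheritParams fisher_exact_pvalue
#' @param p_adjust `"none"` (default) or `"BH"` for Benjamini-Hochberg
#'   adjustment before thresholding.
#' @return A `comorbidity_result` tibble with the four counts, the cells,
#'   `p_value` and logical `significant`, sorted by `p_value` ascending with
#'   alphabetical tie-break; `alpha`, `convention` and `alternative` are
#'   carried as attributes.
#' @export
comorbidity_significance <- function(counts, alpha = 5e-8,
                                     convention = c("margins", "direct", "remainder"),
                                     alternative = c("greater", "less", "two_sided"),
                                     p_adjust = c("none", "BH")) {
  convention <- match.arg(convention)
  alternative <- match.arg(alternative)
  p_adjust <- match.arg(p_adjust)
  if (!(alpha > 0 && alpha < 1)) abort("`alpha` must be in (0, 1).")
  stopifnot(is.data.frame(counts))
  if (nrow(counts) == 0L) {
    out <- tibble(co_disease = character(), n_both = integer(),
                  n_cd = integer(), n_idx = integer(), n_total = integer(),
                  p_value = double(), significant = logical())
    return(new_comorbidity_result(out, alpha, convention, alternative))
  }
  if (!"co_disease" %in% names(counts)) {
    counts$co_disease <- as.character(seq_len(nrow(counts)))
  }
  cells <- assemble_table(counts, convention = convention)
  cells$p_value <- fisher_exact_pvalue(cells$a, cells$b, cells$c, cells$d,
                                       alternative = alternative)
  if (p_adjust == "BH") {
    cells$p_value <- stats::p.adjust(cells$p_value, method = "BH")
  }
  out <- cells %>%
    mutate(significant = .data$p_value < alpha) %>%
    arrange(.data$p_value, .data$co_disease) %>%
    select(-"a", -"b", -"c", -"d")
  new_comorbidity_result(out, alpha, convention, alternative)
}

new_comorbidity_result <- function(df, alpha, convention, alternative) {
  structure(df, alpha = alpha, convention = convention,
            alternative = alternative,
            class = c("comorbidity_result", class(tibble())))
}

#' @export
print.comorbidity_result <- function(x, ...) {
  cat(sprintf(
    "<comorbidity_result> %d pair(s), %d significant at alpha = %.3g (%s, %s)\n",
    nrow(x), sum(x$significant), attr(x, "alpha"),
    attr(x, "convention"), attr(x, "alternative")))
  NextMethod()
}

#' Derive the four literature counts from a corpus
#'
#' Computes, for every co-disease co-occurring with the index disease, the
#' inclusive four-count summary of the Boolean-query scheme: joint articles,
#' all co-disease articles, all index-disease articles, corpus size. Feed
#' the result to [comorbidity_significance()] with the default `"margins"`
#' convention (under which these inclusive counts yield the standard 2x2
#' table).
#'
#' @inheritParams count_pairs
#' @param n_total Corpus size (count (iv)). Required when `corpus` is a
#'   long membership tibble, because articles without any matched disease
#'   are absent from it; inferred as the number of articles when `corpus`
#'   is a `medline_corpus`.
#' @return Tibble with columns `co_disease`, `n_both`, `n_cd`, `n_idx`,
#'   `n_total`.
#' @export
contingency_counts <- function(corpus, lexicon, index_disease,
                               n_total = NULL) {
  if (inherits(corpus, "medline_corpus")) {
    membership <- disease_set(corpus, lexicon)
    n_total <- n_total %||% nrow(corpus)
  } else {
    stopifnot(is.data.frame(corpus),
              all(c("pmid", "disease") %in% names(corpus)))
    membership <- distinct(as_tibble(corpus), .data$pmid, .data$disease)
    if (is.null(n_total)) {
      abort("Supply `n_total` (the corpus size) when passing a membership tibble: articles without matched diseases are not represented in it.")
    }
  }
  idx_pmids <- membership$pmid[membership$disease == index_disease]
  n_idx <- length(unique(idx_pmids))
  per_disease <- membership %>%
    filter(.data$disease != index_disease) %>%
    group_by(co_disease = .data$disease) %>%
    summarise(n_both = sum(.data$pmid %in% idx_pmids),
              n_cd = n(), .groups = "drop")
  per_disease %>%
    filter(.data$n_both > 0L) %>%
    mutate(n_idx = n_idx, n_total = n_total) %>%
    arrange(.data$co_disease)
}

#' Write a Table-2-style comorbidity report
#'
#' TSV with columns `co_disease`, `n_both`, `n_cd`, `n_idx`, `n_total`,
#' `p_value` (scientific notation, 3 significant digits) and `significant`.
#'
#' @param results A `comorbidity_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comorbidity <- function(results, path) {
  out <- as.data.frame(results)
  out$p_value <- sprintf("%.2e", out$p_value)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
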