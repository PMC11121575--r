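#' Sort ratio for ranking co-occurring diseases
#'
#' The ranking statistic of the mining step: the fraction of index-disease
#' pairing articles that mention a given co-disease,
#' `p_each_pair / p_all`, where `p_each_pair` counts articles containing
#' both the index disease and the co-disease, and `p_all` counts articles
#' containing the index disease together with at least one co-occurring
#' disease.
#'
#' @param p_each_pair Integer vector of joint-article counts.
#' @param p_all Scalar (or equal-length) count of index articles with at
#'   least one co-occurring disease; must be positive.
#' @return Numeric vector of ratios in `[0, 1]`, at full precision
#'   (reports round to 4 decimals).
#' @examples
#' sort_ratio(142, 843)
#' @export
sort_ratio <- function(p_each_pair, p_all) {
  if (any(p_all <= 0)) abort("`p_all` must be positive.")
  if (any(p_each_pair < 0) || any(p_each_pair > p_all)) {
    abort("`p_each_pair` must satisfy 0 <= p_each_pair <= p_all.")
  }
  p_each_pair / p_all
}

#' Count index/co-disease article pairs and rank by sort ratio
#'
#' For every lexicon disease that appears in at least one article together
#' with `index_disease`, counts the joint articles (`p_each_pair`) and the
#' number of index-disease articles carrying at least one other lexicon
#' disease (`p_all`), and ranks by [sort_ratio()] (descending, ties broken
#' alphabetically).
#'
#' @param corpus A `medline_corpus` (or a long `pmid`/`disease` membership
#'   tibble as returned by [disease_set()]).
#' @param lexicon A `disease_lexicon`; ignored when `corpus` is already a
#'   membership tibble.
#' @param index_disease Canonical term of the index disease; must be in the
#'   lexicon.
#' @return A `cooccurrence_result` tibble with columns `co_disease`,
#'   `p_each_pair`, `p_all`, `sort_ratio`, carrying the index disease and
#'   corpus size as attributes.
#' @export
count_pairs <- function(corpus, lexicon, index_disease) {
  if (inherits(corpus, "medline_corpus")) {
    if (!normalize_term(index_disease) %in% lexicon$normalized_term) {
      abort(sprintf("Index disease %s is not in the lexicon.",
                    dQuote(index_disease)))
    }
    membership <- disease_set(corpus, lexicon)
    n_articles <- nrow(corpus)
  } else {
    stopifnot(is.data.frame(corpus),
              all(c("pmid", "disease") %in% names(corpus)))
    membership <- distinct(as_tibble(corpus), .data$pmid, .data$disease)
    n_articles <- n_distinct(membership$pmid)
  }

  idx_pmids <- membership$pmid[membership$disease == index_disease]
  co <- membership %>%
    filter(.data$pmid %in% idx_pmids, .data$disease != index_disease)
  p_all <- n_distinct(co$pmid)

  if (p_all == 0L) {
    warn("No article contains the index disease together with another disease.")
    out <- tibble(co_disease = character(), p_each_pair = integer(),
                  p_all = integer(), sort_ratio = double())
  } else {
    out <- co %>%
      count(co_disease = .data$disease, name = "p_each_pair") %>%
      mutate(p_all = p_all,
             sort_ratio = sort_ratio(.data$p_each_pair, p_all)) %>%
      arrange(desc(.data$sort_ratio), .data$co_disease)
  }
  structure(out,
            index_disease = index_disease,
            n_articles = n_articles,
            class = c("cooccurrence_result", class(tibble())))
}

#' Keep the top-k ranked co-occurring diseases
#'
#' @param results A `cooccurrence_result` (or any tibble ordered the same
#'   way).
#' @param k Number of rows to keep (`k >= 1`); if `k` exceeds the number of
#'   results all rows are returned with a warning.
#' @return The first `k` rows in ranking order.
#' @export
top_k <- function(results, k = 5L) {
  stopifnot(is.data.frame(results), k >= 1L)
  if (k > nrow(results)) {
    warn(sprintf("Requested top %d of only %d results; returning all.",
                 as.integer(k), nrow(results)))
    k <- nrow(results)
  }
  head(results, k)
}

#' @export
print.cooccurrence_result <- function(x, ...) {
  cat(sprintf("<cooccurrence_result> index disease: %s — %d co-disease(s), P_all = %s\n",
              attr(x, "index_disease") %||% "?", nrow(x),
              if (nrow(x)) x$p_all[1L] else 0L))
  NextMethod()
}

#' Write a Table-1-style co-occurrence report
#'
#' TSV with columns `co_disease`, `p_each_pair`, `p_all`, `sort_ratio`
#' (ratio rounded to 4 decimals for display; full precision is kept in the
#' R object).
#'
#' @param results A `cooccurrence_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cooccurrence <- function(results, path) {
  out <- as.data.frame(results)
  out$sort_ratio <- sprintf("%.4f", out$sort_ratio)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
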