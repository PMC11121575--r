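#' Simulate a MEDLINE corpus with planted comorbidity structure
#'
#' Generates articles whose MeSH indices carry an index disease, planted
#' co-diseases with configurable conditional co-occurrence lift, and
#' independent background diseases, every article also receiving the
#' `Comorbidity` MeSH tag — the shape of a comorbidity-query download.
#' Per article, independently: the index disease is included with
#' probability `index_prevalence`; each planted disease with
#' `p_given_index` or `p_given_not_index` according to the article's index
#' status; each background disease with its baseline probability.
#'
#' @param n_articles Number of articles.
#' @param index_disease Name of the index disease heading.
#' @param index_prevalence Probability an article's index includes the
#'   index disease.
#' @param planted Data frame with columns `disease`, `p_given_index`,
#'   `p_given_not_index` (may have zero rows).
#' @param background Data frame with columns `disease`, `p` (baseline
#'   probability; may have zero rows).
#' @param seed Integer seed; all randomness flows through one generator
#'   scoped to this call (the session RNG state is untouched).
#' @return A `medline_corpus` with synthetic sequential PMIDs (prefixed
#'   `SYN` to avoid collision with real PMIDs).
#' @examples
#' simulate_corpus(5, index_prevalence = 1,
#'                 planted = data.frame(disease = "Dementia",
#'                                      p_given_index = 1,
#'                                      p_given_not_index = 0))
#' @export
simulate_corpus <- function(n_articles,
                            index_disease = "Alzheimer Disease",
                            index_prevalence = 0.5,
                            planted = NULL,
                            background = NULL,
                            seed = 1L) {
  stopifnot(n_articles >= 1L)
  planted <- normalise_planted(planted, index_disease)
  background <- normalise_background(background, index_disease)
  probs <- c(index_prevalence, planted$p_given_index,
             planted$p_given_not_index, background$p)
  if (any(probs < 0 | probs > 1)) abort("Probabilities must lie in [0, 1].")

  withr::with_seed(as.integer(seed), {
    has_index <- rbinom(n_articles, 1L, index_prevalence) == 1L
    cols <- list()
    if (nrow(planted)) {
      for (i in seq_len(nrow(planted))) {
        p <- ifelse(has_index, planted$p_given_index[i],
                    planted$p_given_not_index[i])
        cols[[planted$disease[i]]] <- rbinom(n_articles, 1L, p) == 1L
      }
    }
    if (nrow(background)) {
      for (i in seq_len(nrow(background))) {
        cols[[background$disease[i]]] <-
          rbinom(n_articles, 1L, background$p[i]) == 1L
      }
    }
    membership <- cbind(has_index, if (length(cols)) do.call(cbind, cols))
    colnames(membership)[1L] <- index_disease
    # long (article, heading) pairs, diseases in column order then the
    # Comorbidity tag; one split() builds all heading vectors at once
    hit <- which(membership, arr.ind = TRUE)
    art <- c(hit[, 1L], seq_len(n_articles))
    col <- c(hit[, 2L], rep(ncol(membership) + 1L, n_articles))
    heading <- c(colnames(membership)[hit[, 2L]],
                 rep("Comorbidity", n_articles))
    o <- order(art, col)
    headings <- unname(split(heading[o],
                             factor(art[o], levels = seq_len(n_articles))))
    new_medline_corpus(
      tibble(pmid = sprintf("SYN%07d", seq_len(n_articles)),
             headings = headings,
             extra = rep(list(character()), n_articles)),
      provenance = sprintf(
        "synthetic corpus: n=%d, index prevalence %.3g, %d planted, %d background, seed %d",
        n_articles, index_prevalence, nrow(planted), nrow(background),
        as.integer(seed)))
  })
}

normalise_planted <- function(planted, index_disease) {
  if (is.null(planted)) {
    planted <- tibble(disease = character(), p_given_index = double(),
                      p_given_not_index = double())
  }
  stopifnot(is.data.frame(planted),
            all(c("disease", "p_given_index", "p_given_not_index") %in%
                  names(planted)))
  planted <- as_tibble(planted)
  if (index_disease %in% planted$disease) {
    abort("Planted diseases must be distinct from the index disease.")
  }
  planted
}

normalise_background <- function(background, index_disease) {
  if (is.null(background)) {
    background <- tibble(disease = character(), p = double())
  }
  stopifnot(is.data.frame(background),
            all(c("disease", "p") %in% names(background)))
  background <- as_tibble(background)
  if (index_disease %in% background$disease) {
    abort("Background diseases must be distinct from the index disease.")
  }
  background
}

#' Lexicon covering the diseases of a simulated corpus
#'
#' Convenience builder: a `disease_lexicon` whose entries are exactly the
#' disease names used by a [simulate_corpus()] specification (the
#' `Comorbidity` tag is not a disease and is deliberately absent).
#'
#' @inheritParams simulate_corpus
#' @param category Category label recorded for every term.
#' @return A `disease_lexicon`.
#' @export
simulated_lexicon <- function(index_disease = "Alzheimer Disease",
                              planted = NULL, background = NULL,
                              category = "Simulated Diseases") {
  planted <- normalise_planted(planted, index_disease)
  background <- normalise_background(background, index_disease)
  build_lexicon(tibble(
    term = c(index_disease, planted$disease, background$disease),
    category = category))
}

#' Simulate a gene-set collection with planted multimorbid cores
#'
#' Builds one gene set per declared disease: each *core* places a block of
#' genes in exactly the diseases of its subset (and no others), and every
#' set additionally receives private genes found nowhere else — so the
#' exact-membership signatures recovered by [multimorbidity_table()] are
#' the declared cores by construction.
#'
#' @param diseases Character vector of disease labels; the first is the
#'   index disease.
#' @param cores List of `list(diseases = <subset>, n_genes = <int>)`
#'   entries; subsets must reference declared diseases.
#' @param per_set_private Number of private genes added to every set.
#' @param universe_size Total size of the synthetic gene universe; the
#'   requested genes must fit.
#' @param seed Integer seed.
#' @return A `geneset_collection`.
#' @export
simulate_genesets <- function(diseases, cores = list(),
                              per_set_private = 5L,
                              universe_size = 10000L, seed = 1L) {
  stopifnot(is.character(diseases), length(diseases) >= 1L,
            !anyDuplicated(diseases))
  for (core in cores) {
    if (!all(core$diseases %in% diseases)) {
      abort("Core subsets must reference declared diseases.")
    }
    if (is.null(core$n_genes) || core$n_genes < 0) {
      abort("Core sizes must be non-negative.")
    }
  }
  n_core <- sum(vapply(cores, function(x) as.integer(x$n_genes), integer(1L)),
                0L)
  n_needed <- n_core + per_set_private * length(diseases)
  if (n_needed > universe_size) {
    abort(sprintf("Gene universe exhausted: need %d of %d.",
                  n_needed, universe_size))
  }
  withr::with_seed(as.integer(seed), {
    pool <- sample(sprintf("G%06d", seq_len(universe_size)), n_needed)
    sets <- setNames(vector("list", length(diseases)), diseases)
    taken <- 0L
    for (core in cores) {
      if (core$n_genes == 0L) next
      genes <- pool[taken + seq_len(core$n_genes)]
      taken <- taken + core$n_genes
      for (dd in core$diseases) sets[[dd]] <- c(sets[[dd]], genes)
    }
    for (dd in diseases) {
      if (per_set_private > 0L) {
        sets[[dd]] <- c(sets[[dd]], pool[taken + seq_len(per_set_private)])
        taken <- taken + per_set_private
      }
      sets[[dd]] <- sets[[dd]] %||% character()
    }
    as_geneset_collection(sets, index_disease = diseases[1L])
  })
}
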