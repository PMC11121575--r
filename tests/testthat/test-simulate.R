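test_that("corpus simulation is deterministic and honours degenerate probabilities", {
  planted <- data.frame(disease = "Dementia", p_given_index = 1,
                        p_given_not_index = 0)
  c1 <- simulate_corpus(50, index_prevalence = 1, planted = planted, seed = 3)
  c2 <- simulate_corpus(50, index_prevalence = 1, planted = planted, seed = 3)
  expect_identical(write_medline(c1), write_medline(c2))
  # every article carries index, planted disease, and the Comorbidity tag
  expect_true(all(vapply(c1$headings, function(h)
    all(c("Alzheimer Disease", "Dementia", "Comorbidity") %in% h),
    logical(1))))
  # different seeds diverge once probabilities are non-degenerate
  half <- data.frame(disease = "Dementia", p_given_index = 0.5,
                     p_given_not_index = 0.5)
  c3 <- simulate_corpus(50, planted = half, seed = 4)
  c4 <- simulate_corpus(50, planted = half, seed = 5)
  expect_false(identical(write_medline(c3), write_medline(c4)))

  expect_error(simulate_corpus(10, index_prevalence = 1.5), "\\[0, 1\\]")
  expect_error(
    simulate_corpus(10, planted = data.frame(
      disease = "Alzheimer Disease", p_given_index = 1, p_given_not_index = 0)),
    "distinct from the index")
  # RNG state of the session is untouched
  withr::local_seed(1)
  before <- .Random.seed
  simulate_corpus(5, seed = 99)
  expect_identical(.Random.seed, before)
})

test_that("planted conditional lift is recovered empirically at large n", {
  planted <- data.frame(disease = "Dementia", p_given_index = 0.05,
                        p_given_not_index = 0.01)
  corpus <- simulate_corpus(20000, index_prevalence = 0.5, planted = planted,
                            seed = 12)
  lex <- simulated_lexicon(planted = planted)
  ds <- disease_set(corpus, lex)
  idx <- unique(ds$pmid[ds$disease == "Alzheimer Disease"])
  co <- unique(ds$pmid[ds$disease == "Dementia"])
  p_co_idx <- mean(idx %in% co)
  p_co_not <- mean(setdiff(corpus$pmid, idx) %in% co)
  expect_equal(p_co_idx / p_co_not, 5, tolerance = 0.1)
})

test_that("gene-set simulation plants exact cores and private genes", {
  diseases <- c("Index", "A", "B", "C", "D")
  coll <- simulate_genesets(
    diseases,
    cores = list(list(diseases = c("Index", "A", "B", "C"), n_genes = 4L)),
    per_set_private = 3L, seed = 5)
  multi <- multimorbidity_table(coll)
  expect_identical(nrow(multi), 1L)
  expect_identical(multi$n_genes, 4L)
  expect_identical(multi$diseases, "Index, A, B, C")

  # no cores -> empty multimorbidity table
  coll0 <- simulate_genesets(diseases, per_set_private = 2L, seed = 5)
  expect_identical(nrow(multimorbidity_table(coll0)), 0L)

  expect_identical(
    tibble::as_tibble(simulate_genesets(diseases, per_set_private = 2L, seed = 8)),
    tibble::as_tibble(simulate_genesets(diseases, per_set_private = 2L, seed = 8)))
  expect_error(simulate_genesets(diseases, per_set_private = 10L,
                                 universe_size = 20L),
               "universe exhausted|exhausted")
  expect_error(
    simulate_genesets(diseases,
                      cores = list(list(diseases = "Nope", n_genes = 1L))),
    "declared diseases")
})

test_that("a published-shape core specification rounds trip through grouping", {
  diseases <- c("AD", "DA", "T2D", "HT", "PN", "DS")
  cores <- list(
    list(diseases = c("AD", "DA", "PN", "DS"), n_genes = 4L),
    list(diseases = c("AD", "DA", "PN"), n_genes = 5L),
    list(diseases = c("AD", "DA", "DS"), n_genes = 2L),
    list(diseases = c("AD", "DA", "HT", "PN"), n_genes = 2L),
    list(diseases = c("AD", "PN", "DS"), n_genes = 1L),
    list(diseases = c("AD", "T2D", "HT"), n_genes = 1L),
    list(diseases = c("AD", "DA", "HT"), n_genes = 1L),
    list(diseases = c("AD", "DA", "T2D"), n_genes = 1L))
  coll <- simulate_genesets(diseases, cores, per_set_private = 4L, seed = 21)
  multi <- multimorbidity_table(coll)
  expect_identical(nrow(multi), 8L)
  expect_identical(sort(multi$n_genes, decreasing = TRUE),
                   c(5L, 4L, 2L, 2L, 1L, 1L, 1L, 1L))
})
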