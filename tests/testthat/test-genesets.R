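gmt_lines <- function() {
  c("SetA\tdescription A\tAPP\tAPOE\tMAPT",
    "SetB\tdescription B\tAPOE\tMAPT\tHFE\tHFE")
}

test_that("GMT parsing collapses duplicates and validates structure", {
  coll <- read_gmt(gmt_lines(), index_disease = "SetA")
  expect_s3_class(coll, "geneset_collection")
  expect_identical(sum(coll$disease == "SetA"), 3L)
  expect_identical(sum(coll$disease == "SetB"), 3L)  # repeated HFE collapsed
  expect_error(read_gmt(c(gmt_lines(), "SetA\tdup\tX"), "SetA"),
               "Duplicate gene-set name")
  expect_error(read_gmt(c(gmt_lines(), "OnlyName\tdesc"), "SetA"),
               "line 3")
  expect_error(read_gmt(gmt_lines(), "NotThere"), "no gene set")
})

test_that("GMT files round trip through write_gmt, agreeing with fgsea", {
  path <- withr::local_tempfile(fileext = ".gmt")
  coll <- ad_collection()
  write_gmt(coll, path)
  back <- read_gmt(path, index_disease = "Alzheimer Disease")
  expect_identical(dplyr::arrange(tibble::as_tibble(back), disease, gene),
                   dplyr::arrange(tibble::as_tibble(coll), disease, gene))
  ref <- fgsea::gmtPathways(path)
  expect_identical(sort(names(ref)), sort(attr(coll, "set_names")))
  for (nm in names(ref)) {
    expect_setequal(ref[[nm]], coll$gene[coll$disease == nm])
  }
})

test_that("pairwise intersections are exact, symmetric and case-insensitive", {
  coll <- as_geneset_collection(
    list(A = c("App", "APOE", "MAPT"), B = c("apoe", "MAPT", "HFE"),
         C = "TP53"),
    index_disease = "A")
  expect_identical(common_genes(coll, "A", "B"), c("APOE", "MAPT"))
  expect_identical(common_genes(coll, "A", "C"), character())
  expect_identical(common_genes(coll, "A", "B"), common_genes(coll, "B", "A"))
  expect_error(common_genes(coll, "A", "Z"), "Unknown disease")
})

test_that("multimorbidity grouping reproduces the published row structure", {
  multi <- multimorbidity_table(ad_collection())
  expect_identical(nrow(multi), 8L)
  expect_identical(sort(multi$n_genes, decreasing = TRUE),
                   c(5L, 4L, 2L, 2L, 1L, 1L, 1L, 1L))
  # maximal-signature semantics: the 4-disease genes never reappear below
  row4 <- multi[multi$diseases ==
                  "Alzheimer Disease, Dementia, Down syndrome, Parkinson's disease", ]
  expect_identical(row4$genes, "APOE, APP, MAPT, PSEN1")
  others <- multi$genes[multi$diseases != row4$diseases]
  expect_false(any(grepl("MAPT|PSEN1\\b|\\bAPP\\b|APOE", others)))
  # sorted by signature size then gene count
  expect_identical(multi$n_diseases, sort(multi$n_diseases, decreasing = TRUE))
  expect_identical(multi$n_genes[1:2], c(4L, 2L))
})

test_that("signature rows partition the multimorbid genes", {
  multi <- multimorbidity_table(ad_collection())
  coll <- ad_collection()
  genes_by_row <- strsplit(multi$genes, ", ", fixed = TRUE)
  all_genes <- unlist(genes_by_row)
  expect_identical(anyDuplicated(all_genes), 0L)
  multimorbid <- tibble::as_tibble(coll) |>
    dplyr::count(gene) |>
    dplyr::filter(n >= 3)
  expect_setequal(all_genes, multimorbid$gene)
  # every row's genes lie in the index's intersection with each row disease
  for (i in seq_len(nrow(multi))) {
    ds <- strsplit(multi$diseases[i], ", ", fixed = TRUE)[[1]]
    for (dd in setdiff(ds, "Alzheimer Disease")) {
      expect_true(all(genes_by_row[[i]] %in%
                        common_genes(coll, "Alzheimer Disease", dd)))
    }
  }
})

test_that("grouping is invariant to set insertion order and trivial edits", {
  base <- multimorbidity_table(ad_collection())
  shuffled <- multimorbidity_table(ad_collection(shuffle_seed = 99))
  expect_identical(tibble::as_tibble(base), tibble::as_tibble(shuffled))

  # no gene shared by index + 2 others -> empty table
  coll <- as_geneset_collection(
    list(I = c("A1", "B2"), X = "A1", Y = "B2", Z = "C3"),
    index_disease = "I")
  expect_identical(nrow(multimorbidity_table(coll)), 0L)
  expect_error(
    multimorbidity_table(as_geneset_collection(list(I = "A1", X = "A1"), "I")),
    "at least two")
})

test_that("pairwise summary ranks dementia first on the worked example", {
  pw <- pairwise_summary(ad_collection())
  expect_identical(pw$co_disease[1], "Dementia")
  expect_identical(pw$n_common[1], 15L)
  # a gene private to the index set changes no counts
  coll2 <- ad_collection()
  sets <- split(coll2$gene, coll2$disease)
  sets[["Alzheimer Disease"]] <- c(sets[["Alzheimer Disease"]], "ZZZ9")
  pw2 <- pairwise_summary(
    as_geneset_collection(sets, index_disease = "Alzheimer Disease"))
  expect_identical(dplyr::arrange(pw2, co_disease),
                   dplyr::arrange(pw, co_disease))
})
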