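# Shared fixtures, all built in code.

toy_descriptors <- function() {
  tibble::tibble(
    term = c("Alzheimer Disease", "Dementia", "Dementia",
             "Diabetes Mellitus, Type 2", "Hypertension",
             "Parkinson Disease", "Down Syndrome", "Foot Rot"),
    category = c("Nervous System Diseases", "Nervous System Diseases",
                 "Mental Disorders", "Nutritional and Metabolic Diseases",
                 "Cardiovascular Diseases", "Nervous System Diseases",
                 "Congenital Abnormalities", "Animal Diseases"))
}

toy_lexicon <- function(excluded = "Animal Diseases") {
  build_lexicon(toy_descriptors(), excluded_categories = excluded)
}

# the published four-count rows for the worked AD example (inputs)
ad_counts <- function() {
  tibble::tibble(
    co_disease = c("Dementia", "Type 2 diabetes", "Hypertension",
                   "Parkinson's disease", "Down syndrome"),
    n_both = c(142L, 95L, 60L, 51L, 43L),
    n_cd = c(220L, 11209L, 6726L, 683L, 346L),
    n_idx = c(1066L, 1113L, 1148L, 1157L, 1165L),
    n_total = 125924L)
}

# exact-membership gene-set collection matching the published
# multimorbidity rows (synthetic construction: each gene belongs to
# precisely its row's diseases)
multimorbid_rows <- function() {
  list(
    list(diseases = c("Dementia", "Parkinson's disease", "Down syndrome"),
         genes = c("MAPT", "PSEN1", "APP", "APOE")),
    list(diseases = c("Dementia", "Parkinson's disease"),
         genes = c("A2M", "ABCA7", "PLAU", "PSEN2", "MPO")),
    list(diseases = c("Dementia", "Down syndrome"),
         genes = c("COL18A1", "SYNJ1")),
    list(diseases = c("Dementia", "Hypertension", "Parkinson's disease"),
         genes = c("HFE", "NOS3")),
    list(diseases = c("Parkinson's disease", "Down syndrome"),
         genes = "SORL1"),
    list(diseases = c("Type 2 diabetes", "Hypertension"),
         genes = "NOTCH2"),
    list(diseases = c("Dementia", "Hypertension"), genes = "TGFB2"),
    list(diseases = c("Dementia", "Type 2 diabetes"), genes = "LAMA1"))
}

ad_collection <- function(shuffle_seed = NULL) {
  diseases <- c("Alzheimer Disease", "Dementia", "Type 2 diabetes",
                "Hypertension", "Parkinson's disease", "Down syndrome")
  sets <- stats::setNames(rep(list(character()), length(diseases)), diseases)
  for (row in multimorbid_rows()) {
    for (dd in c("Alzheimer Disease", row$diseases)) {
      sets[[dd]] <- c(sets[[dd]], row$genes)
    }
  }
  if (!is.null(shuffle_seed)) {
    sets <- withr::with_seed(shuffle_seed, sets[sample(names(sets))])
  }
  as_geneset_collection(sets, index_disease = "Alzheimer Disease")
}

# random 2x2 table with all margins positive and N <= n_max
random_table <- function(n_max = 100L) {
  repeat {
    N <- sample(4:n_max, 1L)
    K <- sample(1:(N - 1L), 1L)   # row margin
    n <- sample(1:(N - 1L), 1L)   # column margin
    a <- sample(max(0L, n - (N - K)):min(K, n), 1L)
    tab <- c(a = a, b = K - a, c = n - a, d = N - K - n + a)
    if (all(tab >= 0)) return(tab)
  }
}

medline_fixture <- function() {
  c("PMID- 100",
    "TI  - A very long title that keeps going and going and going and",
    "      keeps wrapping over the continuation line.",
    "MH  - *Alzheimer Disease/genetics",
    "MH  - Comorbidity",
    "MH  - Dementia/epidemiology",
    "",
    "PMID- 101",
    "MH  - Diabetes Mellitus, Type 2",
    "MH  - Congenital, Hereditary, and Neonatal Diseases and Abnormalities",
    "      with a continuation segment")
}
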