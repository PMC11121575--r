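#' Read a GMT gene-set collection
#'
#' Parses the Gene Matrix Transposed format (`name<TAB>description<TAB>
#' gene1<TAB>gene2...`), one set per line. Gene symbols are trimmed and
#' uppercased; duplicates within a line collapse. Lines with fewer than
#' three fields are a parse error reporting the line number; duplicated set
#' names are an error.
#'
#' @param path GMT file path (or character vector of lines).
#' @param index_disease Label of the index disease's set; must be one of
#'   the set names.
#' @return A `geneset_collection`: a long tibble with columns `disease`
#'   and `gene`, carrying `index_disease` and per-set descriptions as
#'   attributes.
#' @export
read_gmt <- function(path, index_disease) {
  lines <- if (length(path) == 1L && file.exists(path)) {
    readLines(path, encoding = "UTF-8", warn = FALSE)
  } else {
    path
  }
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort("Empty GMT input.")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    abort(sprintf("Malformed GMT line %d: expected at least 3 tab-separated fields.",
                  bad[1L]))
  }
  nm <- vapply(fields, `[[`, character(1L), 1L)
  dup <- unique(nm[duplicated(nm)])
  if (length(dup)) {
    abort(sprintf("Duplicate gene-set name(s): %s", paste(dup, collapse = ", ")))
  }
  sets <- lapply(fields, function(f) {
    g <- toupper(trimws(f[-(1:2)]))
    unique(g[nzchar(g)])
  })
  names(sets) <- nm
  descriptions <- setNames(vapply(fields, `[[`, character(1L), 2L), nm)
  as_geneset_collection(sets, index_disease = index_disease,
                        descriptions = descriptions)
}

#' Build a gene-set collection from a named list
#'
#' @param sets Named list of character vectors of gene symbols, one per
#'   disease label.
#' @param index_disease Label of the index disease; must name one of `sets`.
#' @param descriptions Optional named character vector of set descriptions.
#' @return A `geneset_collection` (long `disease`/`gene` tibble).
#' @export
as_geneset_collection <- function(sets, index_disease, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  if (!index_disease %in% names(sets)) {
    abort(sprintf("Index disease %s has no gene set in the collection.",
                  dQuote(index_disease)))
  }
  long <- tibble(
    disease = rep(names(sets), lengths(sets)),
    gene = toupper(trimws(unlist(sets, use.names = FALSE) %||% character()))) %>%
    filter(nzchar(.data$gene)) %>%
    distinct(.data$disease, .data$gene)
  structure(long,
            index_disease = index_disease,
            descriptions = descriptions %||%
              setNames(rep("", length(sets)), names(sets)),
            set_names = names(sets),
            class = c("geneset_collection", class(tibble())))
}

#' @export
print.geneset_collection <- function(x, ...) {
  cat(sprintf("<geneset_collection> %d set(s), %d genes; index disease: %s\n",
              length(attr(x, "set_names")), n_distinct(x$gene),
              attr(x, "index_disease")))
  NextMethod()
}

#' Write a gene-set collection as GMT
#'
#' @param collection A `geneset_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "geneset_collection"))
  desc <- attr(collection, "descriptions")
  lines <- vapply(attr(collection, "set_names"), function(s) {
    genes <- collection$gene[collection$disease == s]
    d <- if (!is.null(desc) && s %in% names(desc)) desc[[s]] else ""
    paste(c(s, d, genes), collapse = "\t")
  }, character(1L))
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' Genes common to two disease sets
#'
#' @param collection A `geneset_collection`.
#' @param disease_a,disease_b Set labels present in the collection.
#' @return Sorted character vector: the exact intersection.
#' @export
common_genes <- function(collection, disease_a, disease_b) {
  stopifnot(inherits(collection, "geneset_collection"))
  for (lab in c(disease_a, disease_b)) {
    if (!lab %in% attr(collection, "set_names")) {
      abort(sprintf("Unknown disease label %s.", dQuote(lab)))
    }
  }
  sort(intersect(collection$gene[collection$disease == disease_a],
                 collection$gene[collection$disease == disease_b]))
}

#' Group shared genes into multimorbidity signatures
#'
#' Assigns every gene its exact disease-membership signature (the precise
#' set of disease gene-sets containing it) and emits one row per signature
#' that contains the index disease plus at least two comorbid diseases —
#' the multimorbidity rows. Grouping is maximal: a gene shared by four
#' diseases appears only under the four-disease row, never under its
#' sub-signatures, so rows partition the multimorbid genes.
#'
#' @param collection A `geneset_collection` with at least three sets.
#' @return A `multimorbidity_table` tibble with columns `diseases`
#'   (comma-joined, index first then alphabetical), `n_diseases`, `n_genes`
#'   and `genes` (comma-joined, sorted), sorted by `n_diseases` then
#'   `n_genes` descending, then label.
#' @export
multimorbidity_table <- function(collection) {
  stopifnot(inherits(collection, "geneset_collection"))
  index <- attr(collection, "index_disease")
  if (length(attr(collection, "set_names")) < 3L) {
    abort("Need the index disease plus at least two comorbid gene sets.")
  }
  sig <- collection %>%
    group_by(.data$gene) %>%
    summarise(
      has_index = index %in% .data$disease,
      n_diseases = n(),
      diseases = paste(c(index, sort(setdiff(.data$disease, index))),
                       collapse = ", "),
      .groups = "drop") %>%
    filter(.data$has_index, .data$n_diseases >= 3L)

  out <- sig %>%
    group_by(.data$diseases, .data$n_diseases) %>%
    summarise(n_genes = n(),
              genes = paste(sort(.data$gene), collapse = ", "),
              .groups = "drop") %>%
    arrange(desc(.data$n_diseases), desc(.data$n_genes), .data$diseases) %>%
    select("diseases", "n_diseases", "n_genes", "genes")
  structure(out, index_disease = index,
            class = c("multimorbidity_table", class(tibble())))
}

#' Pairwise common-gene counts with the index disease
#'
#' @param collection A `geneset_collection`.
#' @return Tibble with columns `co_disease` and `n_common` (size of the
#'   intersection with the index set), sorted descending then
#'   alphabetically.
#' @export
pairwise_summary <- function(collection) {
  stopifnot(inherits(collection, "geneset_collection"))
  index <- attr(collection, "index_disease")
  others <- setdiff(attr(collection, "set_names"), index)
  tibble(
    co_disease = others,
    n_common = vapply(others, function(dd)
      length(common_genes(collection, index, dd)), integer(1L),
      USE.NAMES = FALSE)) %>%
    arrange(desc(.data$n_common), .data$co_disease)
}
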