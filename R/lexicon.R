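#' Normalize a MeSH heading or descriptor term
#'
#' Reduces a raw MeSH index heading (as found on an `MH` line of a
#' MEDLINE/PubMed record) or a descriptor name to the canonical lookup key
#' used by the disease lexicon: the major-topic marker `*` is stripped, any
#' subheading (everything from the first `/`) is dropped, Unicode
#' apostrophes are mapped to ASCII, whitespace is trimmed and collapsed, and
#' the result is lower-cased.
#'
#' @param raw Character vector of headings or descriptor terms.
#' @return Character vector of normalized terms, same length as `raw`.
#' @examples
#' normalize_term("*Alzheimer Disease/genetics")
#' normalize_term("Diabetes Mellitus, Type 2/epidemiology")
#' @export
normalize_term <- function(raw) {
  if (!is.character(raw)) abort("`raw` must be a character vector.")
  x <- sub("^\\*", "", raw)
  x <- sub("/.*$", "", x)
  # U+2018/U+2019 single quotation marks appear in MeSH terms such as
  # Parkinson's disease depending on the export dialect
  x <- gsub("‘|’", "'", x)
  x <- gsub("\\s+", " ", x)
  x <- trimws(x)
  if (any(is.na(raw)) || any(!nzchar(x))) {
    abort("Headings must be non-empty, non-missing strings.")
  }
  tolower(x)
}

#' Build a disease lexicon from MeSH descriptor records
#'
#' Takes one row per term-category pair (the shape of a MeSH browser export
#' flattened to two columns), optionally drops descriptors that belong
#' exclusively to excluded categories (e.g. `"Animal Diseases"`), and
#' deduplicates by normalized term. A descriptor cross-listed under both an
#' excluded and a retained category survives.
#'
#' @param descriptors Data frame with character columns `term` and
#'   `category`, one row per term-category pair.
#' @param excluded_categories Character vector of category labels to
#'   exclude; a term is dropped only when *all* of its categories are in
#'   this set.
#' @return A `disease_lexicon`: a tibble with columns `normalized_term` and
#'   `canonical_term`, sorted by `normalized_term`, carrying attributes
#'   `source_count` (raw rows seen), `unique_count` (entries kept) and
#'   `excluded_categories`.
#' @examples
#' lex <- build_lexicon(
#'   data.frame(
#'     term = c("Alzheimer Disease", "Dementia", "Foot Rot"),
#'     category = c("Nervous System Diseases", "Nervous System Diseases",
#'                  "Animal Diseases")
#'   ),
#'   excluded_categories = "Animal Diseases"
#' )
#' nrow(lex)
#' @export
build_lexicon <- function(descriptors, excluded_categories = character()) {
  stopifnot(is.data.frame(descriptors))
  if (!all(c("term", "category") %in% names(descriptors))) {
    abort("`descriptors` needs columns `term` and `category`.")
  }
  descriptors <- as_tibble(descriptors)
  if (nrow(descriptors) == 0L) abort("Empty descriptor input: lexicon would be empty.")

  entries <- descriptors %>%
    mutate(normalized_term = normalize_term(.data$term)) %>%
    group_by(.data$normalized_term) %>%
    summarise(
      canonical_term = canonical_display(.data$term[1L]),
      keep = !all(.data$category %in% excluded_categories),
      .groups = "drop"
    ) %>%
    filter(.data$keep) %>%
    select("normalized_term", "canonical_term") %>%
    arrange(.data$normalized_term)

  if (nrow(entries) == 0L) {
    abort("No descriptors survive category exclusion: lexicon would be empty.")
  }
  new_disease_lexicon(entries,
                      source_count = nrow(descriptors),
                      excluded_categories = excluded_categories)
}

# display form: qualifier/topic markers stripped but original case kept
canonical_display <- function(term) {
  x <- sub("^\\*", "", term)
  x <- sub("/.*$", "", x)
  x <- gsub("‘|’", "'", x)
  trimws(gsub("\\s+", " ", x))
}

new_disease_lexicon <- function(entries, source_count, excluded_categories) {
  structure(
    entries,
    source_count = as.integer(source_count),
    unique_count = nrow(entries),
    excluded_categories = excluded_categories,
    class = c("disease_lexicon", class(tibble())))
}

#' @export
print.disease_lexicon <- function(x, ...) {
  cat(sprintf(
    "<disease_lexicon> %d unique terms (from %d source records, %d categor%s excluded)\n",
    attr(x, "unique_count"), attr(x, "source_count"),
    length(attr(x, "excluded_categories")),
    if (length(attr(x, "excluded_categories")) == 1L) "y" else "ies"))
  NextMethod()
}

#' Match raw MeSH headings against a disease lexicon
#'
#' Normalizes each heading and looks it up with exact-match semantics (no
#' substring or fuzzy matching); non-disease headings such as `Comorbidity`
#' come back as `NA`.
#'
#' @param lexicon A `disease_lexicon` from [build_lexicon()].
#' @param heading Character vector of raw MH strings.
#' @return Character vector of canonical terms, `NA` where a heading is not
#'   in the lexicon.
#' @export
match_heading <- function(lexicon, heading) {
  stopifnot(inherits(lexicon, "disease_lexicon"), nrow(lexicon) > 0L)
  key <- normalize_term(heading)
  lexicon$canonical_term[match(key, lexicon$normalized_term)]
}

#' Read / write a disease lexicon as TSV
#'
#' `read_lexicon()` expects the two-column descriptor export consumed by
#' [build_lexicon()] (`term<TAB>category`, with header); `write_lexicon()`
#' writes the built lexicon as `normalized_term<TAB>canonical_term`, sorted
#' for reproducible diffs.
#'
#' @param path File path.
#' @param excluded_categories Passed to [build_lexicon()].
#' @return `read_lexicon()` returns a `disease_lexicon`;
#'   `write_lexicon()` returns `path` invisibly.
#' @export
read_lexicon <- function(path, excluded_categories = character()) {
  tab <- utils::read.delim(path, sep = "\t", quote = "", header = TRUE,
                           colClasses = "character", fileEncoding = "UTF-8")
  build_lexicon(tab, excluded_categories = excluded_categories)
}

#' @rdname read_lexicon
#' @param lexicon A `disease_lexicon`.
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "disease_lexicon"))
  utils::write.table(
    as.data.frame(lexicon[order(lexicon$normalized_term), ]),
    path, sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
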