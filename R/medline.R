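#' Parse MEDLINE/PubMed-format records
#'
#' Parses the plain-text "PubMed format" download dialect: records separated
#' by blank lines, 4-character-padded tags followed by `"- "`, continuation
#' lines indented with whitespace and joined by a single space. Only `PMID`
#' and `MH` lines are interpreted; all other tag lines are carried along
#' verbatim so a round trip preserves them. Records without a `PMID` are
#' skipped with a warning; a duplicated `PMID` is an error.
#'
#' @param text Character vector: either lines, or a single string containing
#'   newlines.
#' @param provenance Free-text description of where the records came from
#'   (e.g. the PubMed query), stored as an attribute.
#' @return A `medline_corpus`: a tibble with one row per article and columns
#'   `pmid` (character), `headings` (list of character vectors of raw MH
#'   strings, in order) and `extra` (list of verbatim non-PMID/MH lines).
#' @examples
#' txt <- c("PMID- 100", "MH  - Alzheimer Disease", "MH  - Comorbidity",
#'          "", "PMID- 101", "MH  - Dementia")
#' parse_medline(txt)
#' @export
parse_medline <- function(text, provenance = NA_character_) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  }
  lines <- text
  blank <- !nzchar(trimws(lines))
  if (length(lines) == 0L || all(blank)) {
    return(new_medline_corpus(
      tibble(pmid = character(), headings = list(), extra = list()),
      provenance))
  }
  rec_id <- cumsum(blank)[!blank]
  lines <- lines[!blank]

  records <- split(lines, rec_id)
  parsed <- purrr::map(records, parse_medline_record)
  skipped <- purrr::map_lgl(parsed, is.null)
  if (any(skipped)) {
    warn(sprintf("Skipped %d record(s) without a PMID tag.", sum(skipped)))
    parsed <- parsed[!skipped]
  }
  out <- bind_rows(parsed)
  if (nrow(out) == 0L) {
    out <- tibble(pmid = character(), headings = list(), extra = list())
  }
  dup <- unique(out$pmid[duplicated(out$pmid)])
  if (length(dup)) {
    abort(sprintf("Duplicate PMID(s) in stream: %s",
                  paste(dup, collapse = ", ")))
  }
  new_medline_corpus(out, provenance)
}

# one record: character lines -> one-row tibble, or NULL when PMID missing
parse_medline_record <- function(lines) {
  is_tag <- grepl("^[A-Z0-9]{1,4}\\s*- ", lines)
  if (!any(is_tag)) return(NULL)
  # continuation lines before the first tag line are malformed; drop them
  lines <- lines[cumsum(is_tag) > 0L]
  is_tag <- is_tag[cumsum(is_tag) > 0L]
  grp <- cumsum(is_tag)
  tag <- sub("^([A-Z0-9]{1,4})\\s*- .*$", "\\1", lines[is_tag])
  value <- sub("^[A-Z0-9]{1,4}\\s*- ", "", lines[is_tag])
  # join continuations onto their tag line with a single space
  cont <- vapply(split(trimws(lines[!is_tag], "left"), grp[!is_tag]),
                 paste, character(1L), collapse = " ")
  full <- value
  idx <- as.integer(names(cont))
  full[idx] <- paste(full[idx], cont)
  full <- trimws(full, "right")

  if (!"PMID" %in% tag) return(NULL)
  pmid <- trimws(full[match("PMID", tag)])
  keep_raw <- !(tag %in% c("PMID", "MH"))
  raw_grp <- grp %in% which(keep_raw)
  tibble(
    pmid = pmid,
    headings = list(full[tag == "MH"]),
    extra = list(lines[raw_grp]))
}

new_medline_corpus <- function(df, provenance = NA_character_) {
  if (!"extra" %in% names(df)) df$extra <- rep(list(character()), nrow(df))
  structure(as_tibble(df),
            provenance = provenance,
            class = c("medline_corpus", class(tibble())))
}

#' @export
print.medline_corpus <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat(sprintf("<medline_corpus> %d article(s)%s\n", nrow(x),
              if (is.na(prov)) "" else paste0(" — ", prov)))
  NextMethod()
}

#' @rdname parse_medline
#' @param path File path of a MEDLINE-format text file (UTF-8).
#' @export
read_medline <- function(path, provenance = path) {
  parse_medline(readLines(path, encoding = "UTF-8", warn = FALSE),
                provenance = provenance)
}

#' Write a corpus back to MEDLINE/PubMed text format
#'
#' Emits records readable by [parse_medline()]; `parse_medline(write_medline(x))`
#' reproduces PMIDs and headings exactly. MH lines longer than 80 characters
#' are wrapped at word boundaries onto indented continuation lines, as in
#' PubMed downloads.
#'
#' @param corpus A `medline_corpus`.
#' @param path Output file path, or `NULL` to return the lines invisibly
#'   without writing.
#' @return The formatted lines, invisibly.
#' @export
write_medline <- function(corpus, path = NULL) {
  stopifnot(inherits(corpus, "medline_corpus"))
  recs <- purrr::pmap(
    list(corpus$pmid, corpus$headings, corpus$extra),
    function(pmid, mh, extra) {
      c(paste0("PMID- ", pmid),
        unlist(lapply(mh, wrap_medline_value, tag = "MH  - ")),
        extra)
    })
  out <- unlist(purrr::map(recs, function(r) c(r, "")), use.names = FALSE)
  if (length(out)) out <- out[-length(out)]
  if (!is.null(path)) {
    writeLines(out, path, useBytes = FALSE)
  }
  invisible(out)
}

# greedy word wrap to width 80 with the 6-space continuation indent
wrap_medline_value <- function(value, tag, width = 80L) {
  first_budget <- width - nchar(tag)
  if (nchar(value) <= first_budget) return(paste0(tag, value))
  words <- strsplit(value, " ", fixed = TRUE)[[1L]]
  lines <- character()
  cur <- ""
  budget <- first_budget
  for (w in words) {
    cand <- if (nzchar(cur)) paste(cur, w) else w
    if (nchar(cand) > budget && nzchar(cur)) {
      lines <- c(lines, cur)
      cur <- w
      budget <- width - 6L
    } else {
      cur <- cand
    }
  }
  lines <- c(lines, cur)
  paste0(c(tag, rep("      ", length(lines) - 1L)), lines)
}

#' Extract per-article disease mentions from a corpus
#'
#' Runs every MH heading through [match_heading()] and returns the
#' deduplicated article-disease membership in long form. Non-disease
#' headings (e.g. `Comorbidity`) and qualifiers are dropped by the
#' lexicon's exact-match rule.
#'
#' @param corpus A `medline_corpus`.
#' @param lexicon A `disease_lexicon`.
#' @return Tibble with columns `pmid`, `disease` (canonical term), one row
#'   per distinct article-disease pair.
#' @export
disease_set <- function(corpus, lexicon) {
  stopifnot(inherits(corpus, "medline_corpus"))
  n_mh <- lengths(corpus$headings)
  long <- tibble(
    pmid = rep(corpus$pmid, n_mh),
    heading = unlist(corpus$headings, use.names = FALSE) %||% character())
  long <- filter(long, nzchar(trimws(.data$heading)))
  long$disease <- match_heading(lexicon, long$heading)
  long %>%
    filter(!is.na(.data$disease)) %>%
    distinct(.data$pmid, .data$disease)
}
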