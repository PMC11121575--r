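#' Tidy and summarise mining results
#'
#' Broom-style accessors: `tidy()` returns the per-disease rows as a plain
#' tibble; `glance()` returns a one-row summary of the run.
#'
#' @param x A `cooccurrence_result` or `comorbidity_result`.
#' @param ... Unused.
#' @return A tibble.
#' @name comormine-tidiers
NULL

#' @rdname comormine-tidiers
#' @export
tidy.cooccurrence_result <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' @rdname comormine-tidiers
#' @export
glance.cooccurrence_result <- function(x, ...) {
  tibble(index_disease = attr(x, "index_disease"),
         n_articles = attr(x, "n_articles"),
         p_all = if (nrow(x)) x$p_all[1L] else 0L,
         n_co_diseases = nrow(x))
}

#' @rdname comormine-tidiers
#' @export
tidy.comorbidity_result <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' @rdname comormine-tidiers
#' @export
glance.comorbidity_result <- function(x, ...) {
  tibble(n_tested = nrow(x),
         n_significant = sum(x$significant),
         alpha = attr(x, "alpha"),
         convention = attr(x, "convention"),
         alternative = attr(x, "alternative"))
}

unclass_result <- function(x) {
  attr(x, "index_disease") <- NULL
  attr(x, "n_articles") <- NULL
  attr(x, "alpha") <- NULL
  attr(x, "convention") <- NULL
  attr(x, "alternative") <- NULL
  class(x) <- class(tibble())
  x
}
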