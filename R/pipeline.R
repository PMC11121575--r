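#' Run the literature-mining stage end to end
#'
#' Reads a lexicon and a MEDLINE corpus, counts index/co-disease pairs,
#' ranks them by sort ratio, computes Fisher exact significance for every
#' co-occurring disease, and writes `cooccurrence.tsv`, `comorbidity.tsv`
#' and a `manifest.json` (config, input checksums, package version) to
#' `output_dir`. Stage tallies (articles parsed, index articles, P_all,
#' co-occurring and significant disease counts) are logged to stderr.
#'
#' @param config Named list (or YAML path accepted by [read_pipeline_config()])
#'   with fields `lexicon_path`, `corpus_path`, `index_disease`, optional
#'   `excluded_categories`, `top_k` (default 5), `output_dir` (default
#'   `"."`), and an optional `fet` list with `convention`, `alternative`,
#'   `alpha`.
#' @return Invisibly, a list with elements `cooccurrence` (full ranking),
#'   `top` (top-k rows) and `comorbidity` (significance results).
#' @export
run_mine <- function(config) {
  config <- read_pipeline_config(config)
  for (field in c("lexicon_path", "corpus_path", "index_disease")) {
    if (is.null(config[[field]])) {
      abort(sprintf("Config field `%s` is required for the mining stage (set it in the config list or YAML).",
                    field))
    }
  }
  for (field in c("lexicon_path", "corpus_path")) {
    if (!file.exists(config[[field]])) {
      abort(sprintf("Input file not found: %s (check `%s`).",
                    config[[field]], field))
    }
  }
  fet <- fet_settings(config$fet)
  top_n <- config$top_k %||% 5L
  out_dir <- config$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  lexicon <- read_lexicon(config$lexicon_path,
                          excluded_categories = config$excluded_categories %||% character())
  corpus <- read_medline(config$corpus_path)
  inform(sprintf("Parsed %d article(s); lexicon has %d disease term(s).",
                 nrow(corpus), nrow(lexicon)))

  membership <- disease_set(corpus, lexicon)
  if (!config$index_disease %in% membership$disease) {
    warn(sprintf("Index disease %s not found in any article; reports will be empty.",
                 dQuote(config$index_disease)))
  }
  cooc <- count_pairs(corpus, lexicon, config$index_disease)
  counts <- contingency_counts(membership, index_disease = config$index_disease,
                               n_total = nrow(corpus))
  comorb <- comorbidity_significance(counts, alpha = fet$alpha,
                                     convention = fet$convention,
                                     alternative = fet$alternative)
  inform(sprintf(
    "P_all = %s; %d co-occurring disease(s); %d significant at alpha = %.3g.",
    if (nrow(cooc)) cooc$p_all[1L] else 0L, nrow(cooc),
    sum(comorb$significant), fet$alpha))

  write_cooccurrence(cooc, file.path(out_dir, "cooccurrence.tsv"))
  write_comorbidity(comorb, file.path(out_dir, "comorbidity.tsv"))
  write_manifest(config, c(config$lexicon_path, config$corpus_path), out_dir)
  invisible(list(cooccurrence = cooc,
                 top = if (nrow(cooc)) suppressWarnings(top_k(cooc, top_n)) else cooc,
                 comorbidity = comorb))
}

#' Run the gene-set stage end to end
#'
#' Reads a GMT collection, writes `multimorbidity.tsv` (exact-membership
#' signature rows) and `pairwise.tsv` (common-gene counts with the index
#' disease) plus a manifest.
#'
#' @param config Named list (or YAML path) with fields `gmt_path`,
#'   `index_disease`, optional `output_dir`.
#' @return Invisibly, a list with elements `multimorbidity` and `pairwise`.
#' @export
run_genesets <- function(config) {
  config <- read_pipeline_config(config)
  for (field in c("gmt_path", "index_disease")) {
    if (is.null(config[[field]])) {
      abort(sprintf("Config field `%s` is required for the gene-set stage.", field))
    }
  }
  if (!file.exists(config$gmt_path)) {
    abort(sprintf("Input file not found: %s (check `gmt_path`).", config$gmt_path))
  }
  out_dir <- config$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  collection <- read_gmt(config$gmt_path, index_disease = config$index_disease)
  multi <- multimorbidity_table(collection)
  pair <- pairwise_summary(collection)
  inform(sprintf("%d gene set(s); %d multimorbidity signature(s); %d multimorbid gene(s).",
                 length(attr(collection, "set_names")), nrow(multi),
                 sum(multi$n_genes)))

  utils::write.table(as.data.frame(multi), file.path(out_dir, "multimorbidity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  utils::write.table(as.data.frame(pair), file.path(out_dir, "pairwise.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  write_manifest(config, config$gmt_path, out_dir)
  invisible(list(multimorbidity = multi, pairwise = pair))
}

#' Read a pipeline configuration
#'
#' Accepts either a named list (returned unchanged) or the path of a YAML
#' file whose keys mirror the config fields of [run_mine()] and
#' [run_genesets()].
#'
#' @param config Named list or YAML file path.
#' @return Named list.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      abort(sprintf("Config file not found: %s", config))
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

fet_settings <- function(fet) {
  list(convention = fet$convention %||% "margins",
       alternative = fet$alternative %||% "greater",
       alpha = fet$alpha %||% 5e-8)
}

write_manifest <- function(config, inputs, out_dir) {
  manifest <- list(
    package = "comormine",
    version = as.character(utils::packageVersion("comormine")),
    config = config[!vapply(config, is.function, logical(1L))],
    inputs = lapply(setNames(inputs, basename(inputs)),
                    function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
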