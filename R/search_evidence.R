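#' Literature-search evidence channel
#'
#' Scores a drug--target pair against a set of n search results. Each result
#' r_i contributes an indicator sum
#'
#'   S(r_i) = I(d,t in r_i) + I(any positive keyword in r_i)
#'          + I(any strong keyword in r_i)           (each indicator 0 or 1)
#'
#' and the channel score is D = round(T / M, 2) with T = sum_i S(r_i) and
#' M = 3n (0 when there are no results). Matching is case-insensitive plain
#' substring over the concatenated title and content; links are excluded.
#'
#' @name search_evidence
NULL

#' Default interaction keyword lists
#'
#' Positive keywords signal that an interaction is asserted; strong keywords
#' signal emphasis on its magnitude. Both lists are user-extensible through
#' the scoring functions' arguments.
#' @export
default_positive_keywords <- c("interacts", "binds", "activates", "modulates")

#' @rdname default_positive_keywords
#' @export
default_strong_keywords <- c("strong", "significant", "potent", "effective")

#' Construct a search result / result set
#'
#' @param title,link,content character scalars (may be empty).
#' @return `search_result`: a named list with those three fields.
#' @export
search_result <- function(title = "", link = "", content = "") {
  structure(list(title = as.character(title), link = as.character(link),
                 content = as.character(content)),
            class = "search_result")
}

#' @rdname search_result
#' @param results list of `search_result` (or bare lists with the same fields).
#' @return `search_result_set`: list with `results` and count `n`.
#' @export
search_result_set <- function(results = list()) {
  results <- lapply(results, function(r) {
    search_result(r$title %||% "", r$link %||% "", r$content %||% "")
  })
  structure(list(results = results, n = length(results)),
            class = "search_result_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the search query for a pair
#'
#' The query is the drug name, the target name and the literal term
#' "interaction", joined by single spaces.
#'
#' @param drug,target non-empty names.
#' @return query string.
#' @export
build_query <- function(drug, target) {
  drug <- trimws(drug); target <- trimws(target)
  if (!nzchar(drug) || !nzchar(target))
    dg_input_error("drug and target names must be non-empty")
  paste(drug, target, "interaction")
}

kw_hit <- function(text, keywords) {
  any(vapply(tolower(keywords), grepl, NA, x = text, fixed = TRUE))
}

#' Score one search result
#'
#' Evaluates the three indicators over the result's title + content
#' (case-insensitive substring matching): both names present; any positive
#' keyword present; any strong keyword present.
#'
#' @param r a `search_result` (or list with `title`/`content`).
#' @param drug,target pair names.
#' @param positive_keywords,strong_keywords non-empty keyword vectors.
#' @return `result_score`: fields `pair_hit`, `positive_hit`, `strong_hit`,
#'   `s` (their sum, in 0..3).
#' @export
score_result <- function(r, drug, target,
                         positive_keywords = default_positive_keywords,
                         strong_keywords = default_strong_keywords) {
  if (length(positive_keywords) == 0 || length(strong_keywords) == 0)
    dg_config_error("keyword lists must be non-empty")
  text <- tolower(paste(r$title %||% "", r$content %||% ""))
  pair_hit <- as.integer(grepl(tolower(trimws(drug)), text, fixed = TRUE) &&
                         grepl(tolower(trimws(target)), text, fixed = TRUE))
  positive_hit <- as.integer(kw_hit(text, positive_keywords))
  strong_hit <- as.integer(kw_hit(text, strong_keywords))
  structure(list(pair_hit = pair_hit, positive_hit = positive_hit,
                 strong_hit = strong_hit,
                 s = pair_hit + positive_hit + strong_hit),
            class = "result_score")
}

#' Score a result set for a pair
#'
#' Applies [score_result()] to each result and normalizes: T is the indicator
#' total, M = 3n the attainable maximum, and D = round(T/M, 2) (round half to
#' even, as base `round()` does) or 0 when there are no results. The summary
#' text comes from [summarize_results()] and never influences the score.
#'
#' @inheritParams score_result
#' @param results a `search_result_set`.
#' @param text_backend backend for the summary (default deterministic template).
#' @return `search_evidence`: fields `drug`, `target`, `per_result`, `total`,
#'   `maximum`, `score`, `summary`.
#' @export
score_search <- function(results, drug, target,
                         positive_keywords = default_positive_keywords,
                         strong_keywords = default_strong_keywords,
                         text_backend = template_text_backend()) {
  if (!inherits(results, "search_result_set"))
    results <- search_result_set(results)
  per <- lapply(results$results, score_result, drug = drug, target = target,
                positive_keywords = positive_keywords,
                strong_keywords = strong_keywords)
  total <- sum(vapply(per, `[[`, 0L, "s"))
  maximum <- 3L * results$n
  d <- if (maximum > 0) round(total / maximum, 2) else 0
  summary <- summarize_results(results, backend = text_backend,
                               drug = drug, target = target,
                               positive_keywords = positive_keywords,
                               strong_keywords = strong_keywords)
  structure(list(drug = as.character(drug), target = as.character(target),
                 per_result = per, total = total, maximum = maximum,
                 score = d, summary = summary),
            class = "search_evidence")
}

#' @export
print.search_evidence <- function(x, ...) {
  cat(sprintf("<search_evidence> %s - %s: T=%d, M=%d, D=%.2f\n",
              x$drug, x$target, x$total, x$maximum, x$score))
  cat(x$summary, "\n")
  invisible(x)
}

#' Summarize a result set
#'
#' Renders a digest of the result set through a text backend. The default
#' template backend is deterministic: result count, which keywords matched,
#' and up to three titles. A backend failure degrades to the fixed fallback
#' string "summary unavailable" with a warning; scores are unaffected.
#'
#' @inheritParams score_search
#' @param backend a text backend (see [template_text_backend()]).
#' @return summary string (never empty).
#' @export
summarize_results <- function(results, backend = template_text_backend(),
                              drug = "", target = "",
                              positive_keywords = default_positive_keywords,
                              strong_keywords = default_strong_keywords) {
  if (!inherits(results, "search_result_set"))
    results <- search_result_set(results)
  text <- tolower(paste(
    vapply(results$results, function(r) paste(r$title, r$content), ""),
    collapse = " "))
  matched <- c(positive_keywords[vapply(tolower(positive_keywords), grepl, NA,
                                        x = text, fixed = TRUE)],
               strong_keywords[vapply(tolower(strong_keywords), grepl, NA,
                                      x = text, fixed = TRUE)])
  titles <- vapply(results$results, `[[`, "", "title")
  titles <- titles[nzchar(titles)]
  req <- list(kind = "search_summary", drug = drug, target = target,
              n = results$n, matched_keywords = matched,
              top_titles = utils::head(titles, 3))
  out <- tryCatch(generate_text(req, backend), error = function(e) {
    warning(sprintf("text backend failed (%s); using fallback summary",
                    conditionMessage(e)))
    "summary unavailable"
  })
  if (!is.character(out) || length(out) != 1 || !nzchar(out))
    out <- "summary unavailable"
  out
}

#' Search backends
#'
#' `fixture_search_backend()` serves results from a JSON file (or an already
#' parsed list) mapping query strings to lists of `{title, link, content}`
#' records; it is the offline default and the only backend tests exercise.
#' `live_search_backend()` is a placeholder for a web-search API client: it
#' must be explicitly constructed with `opt_in = TRUE` and raises a typed
#' retrieval error here, keeping the package network-free.
#'
#' @param source path to a JSON fixture file, or a named list.
#' @return a search backend object.
#' @export
fixture_search_backend <- function(source) {
  mapping <- if (is.character(source)) {
    jsonlite::fromJSON(source, simplifyVector = FALSE)
  } else {
    source
  }
  if (!is.list(mapping)) dg_parse_error("search fixture must be a JSON object")
  structure(list(mapping = mapping), class = c("fixture_search_backend",
                                               "search_backend"))
}

#' @rdname fixture_search_backend
#' @param opt_in must be TRUE to construct (guards against accidental use).
#' @export
live_search_backend <- function(opt_in = FALSE) {
  if (!isTRUE(opt_in))
    dg_config_error("live search backend requires explicit opt_in = TRUE")
  structure(list(), class = c("live_search_backend", "search_backend"))
}

#' Fetch search results for a query
#'
#' @param query query string (see [build_query()]).
#' @param backend a search backend.
#' @param n maximum number of results (default 10); the first `n` results in
#'   backend order are kept.
#' @return a `search_result_set` with at most `n` results.
#' @export
fetch_results <- function(query, backend, n = 10) {
  if (n < 0) dg_config_error("n must be >= 0")
  UseMethod("fetch_results", backend)
}

#' @export
fetch_results.fixture_search_backend <- function(query, backend, n = 10) {
  hits <- backend$mapping[[query]]
  if (is.null(hits)) {
    warning(sprintf("no fixture entry for query '%s'", query))
    return(search_result_set(list()))
  }
  search_result_set(utils::head(hits, n))
}

#' @export
fetch_results.live_search_backend <- function(query, backend, n = 10) {
  dg_backend_error("live search retrieval is not available in this build")
}

#' @export
fetch_results.default <- function(query, backend, n = 10) {
  dg_backend_error("unknown search backend")
}
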