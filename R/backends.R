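#' Pluggable evidence backends
#'
#' The ML channel and the text-generation stages are backend-pluggable so the
#' full pipeline runs deterministically offline. The mock predictor hashes
#' the pair names into [0, 1]; the lookup predictor reads scores from a
#' user-supplied table (e.g. precomputed output of a structure-based binding
#' model); the function predictor adapts any user function, which is how a
#' trained binding-affinity model (SMILES + protein sequence in, probability
#' out) is wrapped. Text generation defaults to a deterministic template
#' renderer; live LLM backends are out of scope and represented by a typed
#' stub.
#'
#' @name evidence_backends
NULL

ai_reason_string <- "This agent used an ML model"

#' Predictor input
#'
#' @param drug_name,target_name pair names (required by every backend).
#' @param smiles molecular structure line notation, or NULL.
#' @param sequence amino-acid sequence of the target, or NULL.
#' @return a `predictor_input` list.
#' @export
predictor_input <- function(drug_name, target_name, smiles = NULL,
                            sequence = NULL) {
  if (!nzchar(trimws(drug_name)) || !nzchar(trimws(target_name)))
    dg_input_error("drug_name and target_name must be non-empty")
  structure(list(drug_name = drug_name, target_name = target_name,
                 smiles = smiles, sequence = sequence),
            class = "predictor_input")
}

#' Predictor backends
#'
#' `mock_predictor(seed)` maps (seed, drug, target) deterministically onto
#' [0, 1] via a string hash: same seed and names, same score, across
#' processes, with an approximately uniform spread so downstream code sees
#' realistic score diversity. `lookup_predictor(table)` serves scores from a
#' `drug,target,score` data frame or CSV file (names matched after
#' normalization). `function_predictor(fn)` wraps any `function(inp) -> score`
#' for structure-aware models; it requires `smiles` and `sequence` to be
#' present on the input.
#'
#' @param seed integer mixed into the hash.
#' @return a predictor backend object.
#' @export
mock_predictor <- function(seed = 0) {
  structure(list(seed = as.integer(seed)),
            class = c("mock_predictor", "predictor_backend"))
}

#' @rdname mock_predictor
#' @param table data frame with columns `drug,target,score`, or a CSV path.
#' @export
lookup_predictor <- function(table) {
  if (is.character(table))
    table <- utils::read.csv(table, stringsAsFactors = FALSE)
  need <- c("drug", "target", "score")
  if (!all(need %in% names(table)))
    dg_parse_error("lookup table needs columns drug,target,score")
  table$score <- as.numeric(table$score)
  if (any(!is.finite(table$score) | table$score < 0 | table$score > 1))
    dg_parse_error("lookup scores must be finite and in [0,1]")
  key <- paste(normalize_id(table$drug), normalize_id(table$target), sep = "|")
  scores <- stats::setNames(as.numeric(table$score), key)
  structure(list(scores = scores),
            class = c("lookup_predictor", "predictor_backend"))
}

#' @rdname mock_predictor
#' @param fn `function(inp)` returning a finite score in [0,1].
#' @export
function_predictor <- function(fn) {
  stopifnot(is.function(fn))
  structure(list(fn = fn),
            class = c("function_predictor", "predictor_backend"))
}

#' Predict a drug--target interaction score
#'
#' Dispatches to the configured predictor backend and wraps the score with
#' the channel's standardized reason string.
#'
#' @param inp a [predictor_input()].
#' @param backend a predictor backend.
#' @return `ai_evidence`: fields `drug`, `target`, `score` in [0,1], `reason`.
#' @export
predict_interaction <- function(inp, backend) {
  if (!inherits(inp, "predictor_input")) inp <- do.call(predictor_input, inp)
  score <- predictor_score(backend, inp)
  if (!is.numeric(score) || length(score) != 1 || !is.finite(score) ||
      score < 0 || score > 1)
    dg_backend_error("predictor backend returned a score outside [0,1]")
  structure(list(drug = inp$drug_name, target = inp$target_name,
                 score = as.numeric(score), reason = ai_reason_string),
            class = "ai_evidence")
}

predictor_score <- function(backend, inp) UseMethod("predictor_score")

#' @export
predictor_score.mock_predictor <- function(backend, inp) {
  dg_hash01(paste(normalize_id(inp$drug_name), normalize_id(inp$target_name),
                  backend$seed, sep = "|"))
}

#' @export
predictor_score.lookup_predictor <- function(backend, inp) {
  key <- paste(normalize_id(inp$drug_name), normalize_id(inp$target_name),
               sep = "|")
  if (!key %in% names(backend$scores))
    dg_backend_error(sprintf("no lookup entry for pair %s-%s",
                             inp$drug_name, inp$target_name))
  unname(backend$scores[[key]])
}

#' @export
predictor_score.function_predictor <- function(backend, inp) {
  if (is.null(inp$smiles) || is.null(inp$sequence))
    dg_input_error("structure-aware predictor requires smiles and sequence")
  backend$fn(inp)
}

#' @export
predictor_score.default <- function(backend, inp) {
  dg_backend_error("unknown predictor backend")
}

#' Text-generation backends
#'
#' `template_text_backend()` renders deterministic strings from a structured
#' request's slots; it is the default everywhere. `live_text_backend(label)`
#' stands for an external LLM API and raises a typed error when invoked; the
#' orchestrator falls back to the template backend with a warning.
#'
#' @return a text backend object.
#' @export
template_text_backend <- function() {
  structure(list(), class = c("template_text_backend", "text_backend"))
}

#' @rdname template_text_backend
#' @param label backend label (e.g. a model name) recorded on the object.
#' @export
live_text_backend <- function(label) {
  structure(list(label = label), class = c("live_text_backend", "text_backend"))
}

#' Generate text from a structured request
#'
#' @param request named list with a `kind` field (`search_summary` or
#'   `reasoning`) and the slots that kind renders.
#' @param backend a text backend.
#' @return a character scalar.
#' @export
generate_text <- function(request, backend = template_text_backend()) {
  UseMethod("generate_text", backend)
}

#' @export
generate_text.template_text_backend <- function(request,
                                                backend = template_text_backend()) {
  switch(request$kind %||% "",
    search_summary = render_search_summary(request),
    reasoning = render_reasoning(request),
    dg_input_error(sprintf("unknown text request kind '%s'", request$kind))
  )
}

#' @export
generate_text.live_text_backend <- function(request, backend) {
  dg_backend_error(sprintf("live text backend '%s' is not available in this build",
                           backend$label))
}

#' @export
generate_text.default <- function(request, backend) {
  dg_backend_error("unknown text backend")
}

render_search_summary <- function(req) {
  if (req$n == 0)
    return(sprintf("No search results for %s-%s.", req$drug, req$target))
  kw <- if (length(req$matched_keywords) > 0)
    paste(sort(unique(req$matched_keywords)), collapse = ", ") else "none"
  titles <- if (length(req$top_titles) > 0)
    paste0(" Top results: ", paste(req$top_titles, collapse = "; "), ".")
  else ""
  sprintf("Reviewed %d search results for %s-%s. Interaction keywords matched: %s.%s",
          req$n, req$drug, req$target, kw, titles)
}

render_reasoning <- function(req) {
  chans <- req$channels  # named numeric vector of present channel scores
  lab <- c(ai = "ML", kg = "KG", search = "Search")
  parts <- sprintf("%s=%s", lab[names(chans)], format_score(chans))
  level <- if (req$final >= 0.7) "strong" else if (req$final >= 0.3) "moderate"
           else "weak"
  spread <- if (length(chans) > 1 && (max(chans) - min(chans)) > 0.5)
    " Evidence channels disagree; the mean tempers the extremes." else ""
  mech <- if (!is.null(req$mechanism)) paste0(" ", req$mechanism) else ""
  sprintf("Combined evidence (%s) supports a %s interaction between %s and %s (final %s).%s%s",
          paste(parts, collapse = ", "), level, req$drug, req$target,
          format_score(req$final), mech, spread)
}

# Render a score compactly but losslessly enough for traces.
format_score <- function(x) {
  vapply(x, function(v) trimws(formatC(v, format = "g", digits = 8)), "")
}
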