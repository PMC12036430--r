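#' Evidence aggregation (the reasoning stage)
#'
#' Fuses the available evidence channels (ML prediction, knowledge-graph
#' path score, literature-search score) into one final score with a
#' Thought -> Action -> Observation trace. The fusion rule is the weighted
#' arithmetic mean of the channels that are present (default weights all 1,
#' i.e. the plain mean), rounded to five decimals; an ablated or failed
#' channel simply drops out of the mean.
#'
#' @name aggregation
NULL

#' Bundle the evidence channels for one pair
#'
#' @param drug,target pair names.
#' @param ai an `ai_evidence` or NULL.
#' @param kg a `kg_evidence` or NULL.
#' @param search a `search_evidence` or NULL.
#' @return an `evidence_bundle`; at least one channel must be present and all
#'   present scores must be finite and in [0,1].
#' @export
evidence_bundle <- function(drug, target, ai = NULL, kg = NULL, search = NULL) {
  if (is.null(ai) && is.null(kg) && is.null(search))
    dg_input_error("evidence bundle needs at least one channel")
  for (ch in list(ai = ai, kg = kg, search = search)) {
    if (is.null(ch)) next
    s <- ch$score
    if (!is.numeric(s) || length(s) != 1 || !is.finite(s) || s < 0 || s > 1)
      dg_input_error("channel score must be a finite number in [0,1]")
  }
  structure(list(drug = as.character(drug), target = as.character(target),
                 ai = ai, kg = kg, search = search),
            class = "evidence_bundle")
}

bundle_scores <- function(bundle) {
  out <- c(ai = if (!is.null(bundle$ai)) unname(bundle$ai$score),
           kg = if (!is.null(bundle$kg)) unname(bundle$kg$score),
           search = if (!is.null(bundle$search)) unname(bundle$search$score))
  out
}

#' Aggregate an evidence bundle into a prediction record
#'
#' Computes `final = round(weighted mean of present channel scores, 5)` and
#' builds (a) a `prediction_record` -- the seven-field output contract
#' [drug, target, ai, kg, search, final, reasoning] -- and (b) a
#' `reasoning_trace` whose ANALYZE_EVIDENCE observation lists the channel
#' scores, whose EVALUATE_MECHANISMS observation (emitted only when the KG
#' channel found a path) describes the best path, and whose CALCULATE_SCORES
#' observation renders the arithmetic actually performed.
#'
#' @param bundle an [evidence_bundle()].
#' @param text_backend backend rendering the reasoning prose (template
#'   default; a live-backend failure falls back to the template with a
#'   warning).
#' @param weights named channel weights (`ai`, `kg`, `search`), default all 1.
#' @return list with elements `record` (class `prediction_record`) and
#'   `trace` (class `reasoning_trace`).
#' @export
aggregate_evidence <- function(bundle, text_backend = template_text_backend(),
                               weights = c(ai = 1, kg = 1, search = 1)) {
  if (!inherits(bundle, "evidence_bundle"))
    dg_input_error("bundle must be an evidence_bundle")
  scores <- bundle_scores(bundle)
  w <- weights[names(scores)]
  if (any(is.na(w)) || any(w < 0) || sum(w) <= 0)
    dg_config_error("channel weights must be non-negative with positive sum")
  final <- round(sum(scores * w) / sum(w), 5)

  steps <- list(
    list(phase = "Thought",
         text = sprintf("Analyze %s evidence for %s-%s interaction.",
                        paste(c(ai = "ML", kg = "KG",
                                search = "Literature Search")[names(scores)],
                              collapse = ", "),
                        bundle$drug, bundle$target)),
    list(phase = "Action", text = "ANALYZE_EVIDENCE"),
    list(phase = "Observation",
         text = paste(sprintf("%s = %s",
                              c(ai = "ML", kg = "KG",
                                search = "Search")[names(scores)],
                              format_score(scores)),
                      collapse = ", ")))

  mechanism <- NULL
  if (!is.null(bundle$kg) && !is.null(bundle$kg$best_path)) {
    bp <- bundle$kg$best_path
    nodes <- bp$display %||% bp$path
    via <- if (length(nodes) > 2)
      sprintf(" via %s", paste(nodes[-c(1, length(nodes))], collapse = ", "))
    else ""
    mechanism <- sprintf("KG shows %d-hop connection%s.", bp$hops, via)
    steps <- c(steps, list(
      list(phase = "Action", text = "EVALUATE_MECHANISMS"),
      list(phase = "Observation", text = mechanism)))
  }

  arithmetic <- sprintf("Final Score = (%s) / %d = %s",
                        paste(format_score(scores), collapse = " + "),
                        length(scores), format_score(final))
  if (!isTRUE(all(w == w[[1]])))
    arithmetic <- sprintf("Final Score = (%s) / %s = %s",
                          paste(sprintf("%s*%s", format_score(w),
                                        format_score(scores)), collapse = " + "),
                          format_score(sum(w)), format_score(final))
  steps <- c(steps, list(
    list(phase = "Action", text = "CALCULATE_SCORES"),
    list(phase = "Observation", text = arithmetic)))

  req <- list(kind = "reasoning", drug = bundle$drug, target = bundle$target,
              channels = scores, final = final, mechanism = mechanism)
  reasoning <- tryCatch(generate_text(req, text_backend), error = function(e) {
    warning(sprintf("text backend failed (%s); falling back to template",
                    conditionMessage(e)))
    generate_text(req, template_text_backend())
  })

  record <- structure(list(
    drug = bundle$drug, target = bundle$target,
    ai_score = if (is.null(bundle$ai)) NA_real_ else bundle$ai$score,
    kg_score = if (is.null(bundle$kg)) NA_real_ else bundle$kg$score,
    search_score = if (is.null(bundle$search)) NA_real_ else bundle$search$score,
    final_score = final, reasoning = reasoning),
    class = "prediction_record")
  trace <- structure(list(steps = steps), class = "reasoning_trace")
  list(record = record, trace = trace)
}

#' @export
print.reasoning_trace <- function(x, ...) {
  for (s in x$steps) cat(sprintf("%s: %s\n", s$phase, s$text))
  invisible(x)
}

#' @export
print.prediction_record <- function(x, ...) {
  cat(sprintf("<prediction_record> %s - %s\n", x$drug, x$target))
  cat(sprintf("  ai=%s kg=%s search=%s final=%s\n",
              format_score(x$ai_score), format_score(x$kg_score),
              format_score(x$search_score), format_score(x$final_score)))
  cat("  ", x$reasoning, "\n", sep = "")
  invisible(x)
}

#' Convert a prediction record to / from the seven-field output list
#'
#' The inter-agent output contract is the ordered list
#' `[drug, target, ai, kg, search, final, reasoning]`; an absent channel
#' score is rendered as the empty string `""`. `output_list_to_record()` is
#' the exact inverse.
#'
#' @param rec a `prediction_record`.
#' @return `to_output_list()`: an unnamed 7-element list.
#' @export
to_output_list <- function(rec) {
  as_slot <- function(x) if (is.na(x)) "" else x
  list(rec$drug, rec$target, as_slot(rec$ai_score), as_slot(rec$kg_score),
       as_slot(rec$search_score), rec$final_score, rec$reasoning)
}

#' @rdname to_output_list
#' @param lst a valid seven-field list.
#' @export
output_list_to_record <- function(lst) {
  validate_agent_output(lst, "seven_field")
  as_score <- function(x) if (identical(x, "")) NA_real_ else as.numeric(x)
  structure(list(drug = lst[[1]], target = lst[[2]],
                 ai_score = as_score(lst[[3]]), kg_score = as_score(lst[[4]]),
                 search_score = as_score(lst[[5]]),
                 final_score = as.numeric(lst[[6]]), reasoning = lst[[7]]),
            class = "prediction_record")
}

#' Write a reasoning trace to a sidecar text file
#'
#' @param trace a `reasoning_trace`.
#' @param path output file path.
#' @export
write_trace <- function(trace, path) {
  writeLines(vapply(trace$steps, function(s)
    sprintf("%s: %s", s$phase, s$text), ""), path)
  invisible(path)
}
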