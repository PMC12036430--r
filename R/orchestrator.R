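#' Workflow orchestration
#'
#' The orchestrator plays the coordinator role: it drives the per-pair
#' workflow (invoke each enabled evidence channel, validate its output
#' against the inter-agent format contract, aggregate, validate the final
#' record), batches pairs into fixed-size chunks, and writes the CSV output.
#' Format contracts are enforced strictly: any payload that deviates in
#' arity, type, or score range raises a typed format error.
#'
#' @name orchestrator
NULL

#' Assemble a pipeline configuration
#'
#' Central configuration for [run_pair()] / [run_batch()]. Fixture-backed and
#' deterministic defaults mean a config with a graph, a search fixture and
#' the mock predictor runs fully offline.
#'
#' @param kg_graph a `dti_kg`, or NULL to disable the channel.
#' @param search_backend a search backend (see [fixture_search_backend()]),
#'   or NULL to disable the channel.
#' @param ai_backend a predictor backend (default [mock_predictor()] seeded
#'   with `seed`).
#' @param text_backend text backend for summaries and reasoning prose.
#' @param ablate character subset of `c("ai","kg","search")` to switch off.
#' @param max_hops,path_cap knowledge-graph scoring controls.
#' @param search_n number of search results scored per pair (default 10).
#' @param positive_keywords,strong_keywords keyword lists for the search
#'   channel.
#' @param weights channel weights for the fusion mean (default all 1).
#' @param batch_size pairs per processing chunk (default 10, the
#'   multiple-pairs-at-once submission size).
#' @param failure_policy `"skip"` (a failed channel drops out of the mean,
#'   with a warning) or `"fail"` (abort the pair).
#' @param seed integer seed for the mock predictor default.
#' @param allow_overrides permit pinned KG scores (test/simulation only).
#' @param kg_overrides named list `"drug|target" -> score` consulted only
#'   when `allow_overrides` is TRUE; keys are normalized pair names.
#' @return a `dti_config` list.
#' @export
dti_config <- function(kg_graph = NULL, search_backend = NULL,
                       ai_backend = NULL,
                       text_backend = template_text_backend(),
                       ablate = character(0),
                       max_hops = 4, path_cap = 10000, search_n = 10,
                       positive_keywords = default_positive_keywords,
                       strong_keywords = default_strong_keywords,
                       weights = c(ai = 1, kg = 1, search = 1),
                       batch_size = 10,
                       failure_policy = c("skip", "fail"),
                       seed = 0,
                       allow_overrides = FALSE,
                       kg_overrides = list()) {
  failure_policy <- match.arg(failure_policy)
  bad <- setdiff(ablate, c("ai", "kg", "search"))
  if (length(bad) > 0)
    dg_config_error(paste0("unknown ablation channel(s): ",
                           paste(bad, collapse = ", ")))
  if (batch_size < 1) dg_config_error("batch_size must be >= 1")
  if (is.null(ai_backend)) ai_backend <- mock_predictor(seed)
  structure(list(kg_graph = kg_graph, search_backend = search_backend,
                 ai_backend = ai_backend, text_backend = text_backend,
                 ablate = ablate, max_hops = max_hops, path_cap = path_cap,
                 search_n = search_n,
                 positive_keywords = positive_keywords,
                 strong_keywords = strong_keywords,
                 weights = weights, batch_size = batch_size,
                 failure_policy = failure_policy, seed = seed,
                 allow_overrides = allow_overrides,
                 kg_overrides = kg_overrides),
            class = "dti_config")
}

#' Construct a query pair
#'
#' @param drug,target names, non-empty after trimming.
#' @return a `query_pair` list.
#' @export
query_pair <- function(drug, target) {
  drug <- trimws(drug); target <- trimws(target)
  if (!nzchar(drug) || !nzchar(target))
    dg_input_error("drug and target must be non-empty")
  structure(list(drug = drug, target = target), class = "query_pair")
}

#' Validate an agent payload against a format contract
#'
#' Two contracts exist: `triple` = `[drug, target, score]` (every specialist
#' channel) and `seven_field` = `[drug, target, ai, kg, search, final,
#' reasoning]` (the final record; channel slots may be the empty string for
#' an absent channel). Any deviation -- wrong arity, wrong type, non-finite
#' score, or score outside [0,1] -- raises a `dtifuse_format_error` naming
#' the offending position.
#'
#' @param payload an ordered list.
#' @param schema `"triple"` or `"seven_field"`.
#' @return the payload, unchanged, if valid.
#' @export
validate_agent_output <- function(payload, schema = c("triple", "seven_field")) {
  schema <- match.arg(schema)
  arity <- if (schema == "triple") 3L else 7L
  if (!is.list(payload) && !(is.vector(payload) && schema == "triple"))
    dg_format_error(sprintf("%s payload must be a list", schema))
  if (length(payload) != arity)
    dg_format_error(sprintf("%s payload must have %d fields, got %d",
                            schema, arity, length(payload)))
  payload <- as.list(payload)

  check_name <- function(i, what) {
    x <- payload[[i]]
    if (!is.character(x) || length(x) != 1 || !nzchar(trimws(x)))
      dg_format_error(sprintf("position %d (%s) must be a non-empty string", i, what))
  }
  check_score <- function(i, what, allow_absent = FALSE) {
    x <- payload[[i]]
    if (allow_absent && identical(x, "")) return(invisible())
    if (!is.numeric(x) || length(x) != 1)
      dg_format_error(sprintf("position %d (%s) must be a number", i, what))
    if (!is.finite(x))
      dg_format_error(sprintf("position %d (%s) must be finite", i, what))
    if (x < 0 || x > 1)
      dg_format_error(sprintf("position %d (%s) out of range [0,1]: %g", i, what, x))
  }

  check_name(1, "drug name")
  check_name(2, "target name")
  if (schema == "triple") {
    check_score(3, "score")
  } else {
    check_score(3, "AI score", allow_absent = TRUE)
    check_score(4, "KG score", allow_absent = TRUE)
    check_score(5, "Search score", allow_absent = TRUE)
    check_score(6, "final score")
    if (!is.character(payload[[7]]) || length(payload[[7]]) != 1 ||
        !nzchar(payload[[7]]))
      dg_format_error("position 7 (reasoning) must be a non-empty string")
  }
  payload
}

# Run one evidence channel under the configured failure policy. Returns the
# evidence object or NULL (channel treated as absent) under "skip".
run_channel <- function(name, fn, config) {
  tryCatch(fn(), error = function(e) {
    if (config$failure_policy == "fail") stop(e)
    warning(sprintf("%s channel failed for this pair (%s); skipping channel",
                    name, conditionMessage(e)))
    NULL
  })
}

#' Score one drug--target pair through the full pipeline
#'
#' Invokes every enabled channel (honoring `config$ablate`), validates each
#' channel's `[drug, target, score]` triple, aggregates the surviving
#' channels, and validates the final seven-field record.
#'
#' @param pair a [query_pair()] (or list with `drug` and `target`).
#' @param config a [dti_config()].
#' @param smiles,sequence optional structure inputs passed to structure-aware
#'   predictor backends.
#' @return list with `record` (a `prediction_record`) and `trace`
#'   (a `reasoning_trace`).
#' @export
run_pair <- function(pair, config = dti_config(), smiles = NULL,
                     sequence = NULL) {
  if (!inherits(pair, "query_pair")) pair <- query_pair(pair$drug, pair$target)
  enabled <- setdiff(c("ai", "kg", "search"), config$ablate)
  if (length(enabled) == 0)
    dg_config_error("all channels ablated; nothing to aggregate")

  ai <- kg <- search <- NULL
  if ("ai" %in% enabled) {
    ai <- run_channel("ai", function() {
      inp <- predictor_input(pair$drug, pair$target, smiles = smiles,
                             sequence = sequence)
      predict_interaction(inp, config$ai_backend)
    }, config)
  }
  if ("kg" %in% enabled) {
    kg <- run_channel("kg", function() {
      key <- paste(normalize_id(pair$drug), normalize_id(pair$target), sep = "|")
      if (!is.null(config$kg_overrides[[key]])) {
        if (!isTRUE(config$allow_overrides))
          dg_config_error("KG score overrides are refused outside test/simulate modes")
        return(structure(list(drug = pair$drug, target = pair$target,
                              score = config$kg_overrides[[key]],
                              best_path = NULL, all_paths = list(),
                              truncated = FALSE,
                              reason = "Pinned knowledge-graph score (simulation override)."),
                         class = "kg_evidence"))
      }
      if (is.null(config$kg_graph))
        dg_config_error("no knowledge graph configured")
      dti_kg_score(config$kg_graph, pair$drug, pair$target,
                   max_hops = config$max_hops, path_cap = config$path_cap)
    }, config)
  }
  if ("search" %in% enabled) {
    search <- run_channel("search", function() {
      if (is.null(config$search_backend))
        dg_config_error("no search backend configured")
      res <- fetch_results(build_query(pair$drug, pair$target),
                           config$search_backend, n = config$search_n)
      score_search(res, pair$drug, pair$target,
                   positive_keywords = config$positive_keywords,
                   strong_keywords = config$strong_keywords,
                   text_backend = config$text_backend)
    }, config)
  }

  for (ch in list(ai, kg, search)) {
    if (!is.null(ch))
      validate_agent_output(list(ch$drug, ch$target, ch$score), "triple")
  }
  bundle <- evidence_bundle(pair$drug, pair$target, ai = ai, kg = kg,
                            search = search)
  out <- aggregate_evidence(bundle, text_backend = config$text_backend,
                            weights = config$weights)
  validate_agent_output(to_output_list(out$record), "seven_field")
  out
}

#' Score a batch of pairs and write a CSV
#'
#' Pairs are processed in consecutive chunks of `config$batch_size`. Under
#' the default policy a failing pair yields a row with empty scores and an
#' error note rather than aborting the batch. The CSV has header
#' `drug,target,ai_score,kg_score,search_score,final_score,reasoning`
#' (RFC 4180, UTF-8) with absent scores as empty fields; given fixture
#' backends and a fixed seed the bytes are identical across runs.
#'
#' @param pairs data frame with columns `drug,target`, or list of pairs.
#' @param config a [dti_config()].
#' @param out_csv path for the CSV, or NULL to skip writing.
#' @param on_pair_error `"record"` (default: emit an error row) or `"abort"`.
#' @return invisibly, the list of `prediction_record`s (error rows included).
#' @export
run_batch <- function(pairs, config = dti_config(), out_csv = NULL,
                      on_pair_error = c("record", "abort")) {
  on_pair_error <- match.arg(on_pair_error)
  if (is.data.frame(pairs)) {
    pairs <- lapply(seq_len(nrow(pairs)), function(i)
      query_pair(pairs$drug[i], pairs$target[i]))
  }
  if (!is.null(out_csv)) {
    ok <- tryCatch({ con <- file(out_csv, open = "wb"); close(con); TRUE },
                   error = function(e) FALSE)
    if (!ok) dg_error(sprintf("cannot write to '%s'", out_csv), "dtifuse_io_error")
  }
  n <- length(pairs)
  chunks <- if (n == 0) list() else
    split(seq_len(n), ceiling(seq_len(n) / config$batch_size))
  records <- vector("list", n)
  for (ci in seq_along(chunks)) {
    idx <- chunks[[ci]]
    message(sprintf("processing chunk %d/%d (%d pair%s)",
                    ci, length(chunks), length(idx),
                    if (length(idx) == 1) "" else "s"))
    for (i in idx) {
      rec <- tryCatch(run_pair(pairs[[i]], config)$record, error = function(e) {
        if (on_pair_error == "abort") stop(e)
        structure(list(drug = pairs[[i]]$drug, target = pairs[[i]]$target,
                       ai_score = NA_real_, kg_score = NA_real_,
                       search_score = NA_real_, final_score = NA_real_,
                       reasoning = paste0("ERROR: ", conditionMessage(e))),
                  class = "prediction_record")
      })
      records[[i]] <- rec
    }
  }
  if (!is.null(out_csv)) write_records_csv(records, out_csv)
  invisible(records)
}

#' Write prediction records to CSV / read them back
#'
#' @param records list of `prediction_record`s.
#' @param path CSV path.
#' @export
write_records_csv <- function(records, path) {
  df <- records_to_df(records)
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = c(1, 2, 7),
                   fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' @rdname write_records_csv
#' @return a data frame with one row per record.
#' @export
records_to_df <- function(records) {
  data.frame(
    drug = vapply(records, `[[`, "", "drug"),
    target = vapply(records, `[[`, "", "target"),
    ai_score = vapply(records, `[[`, 0, "ai_score"),
    kg_score = vapply(records, `[[`, 0, "kg_score"),
    search_score = vapply(records, `[[`, 0, "search_score"),
    final_score = vapply(records, `[[`, 0, "final_score"),
    reasoning = vapply(records, `[[`, "", "reasoning"),
    stringsAsFactors = FALSE)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(drug = "character", target = "character",
                                       reasoning = "character"))
  lapply(seq_len(nrow(df)), function(i) {
    structure(list(drug = df$drug[i], target = df$target[i],
                   ai_score = df$ai_score[i], kg_score = df$kg_score[i],
                   search_score = df$search_score[i],
                   final_score = df$final_score[i],
                   reasoning = df$reasoning[i]),
              class = "prediction_record")
  })
}

#' Read a pairs CSV (`drug,target` header)
#'
#' @param path CSV path.
#' @return data frame with `drug` and `target` columns.
#' @export
read_pairs_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("drug", "target") %in% names(df)))
    dg_parse_error("pairs file needs columns drug,target")
  df
}
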