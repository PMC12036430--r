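# Typed condition helpers. Every error the package raises carries a subclass of
# "dtifuse_error" so callers (and the orchestrator's failure policy) can branch
# on condition class rather than on message text.

dg_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "dtifuse_error"), call = call))
}

dg_format_error  <- function(msg) dg_error(msg, "dtifuse_format_error")
dg_parse_error   <- function(msg) dg_error(msg, "dtifuse_parse_error")
dg_config_error  <- function(msg) dg_error(msg, "dtifuse_config_error")
dg_backend_error <- function(msg) dg_error(msg, "dtifuse_backend_error")
dg_input_error   <- function(msg) dg_error(msg, "dtifuse_input_error")
dg_contract_error <- function(msg) dg_error(msg, "dtifuse_contract_error")
dg_join_error    <- function(msg) dg_error(msg, "dtifuse_join_error")
dg_size_error    <- function(msg) dg_error(msg, "dtifuse_size_error")
dg_spec_error    <- function(msg) dg_error(msg, "dtifuse_spec_error")

#' Normalize an entity identifier
#'
#' Drug and gene identifiers are matched case-insensitively after trimming
#' surrounding whitespace. No synonym resolution is attempted: a synonym map
#' is a user-supplied concern upstream of this package.
#'
#' @param x character vector of identifiers.
#' @return normalized character vector.
#' @export
normalize_id <- function(x) tolower(trimws(x))

# Deterministic, locale-independent ordering for character vectors.
dg_order <- function(...) order(..., method = "radix")

# Run code with the global RNG state preserved, seeding a local stream.
# All fixture generators funnel through this so they are pure functions of
# their seed and never perturb a caller's random sequence.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Polynomial rolling hash of a string onto [0, 1). Pure function of its input:
# used by the mock predictor so scores depend only on (seed, names), never on
# .Random.seed.
dg_hash01 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 0
  m <- 2147483647  # 2^31 - 1; 31 * m < 2^53 so doubles stay exact
  for (b in bytes) h <- (h * 31 + b) %% m
  # one extra mixing round to decorrelate near-identical strings
  for (b in rev(bytes)) h <- (h * 37 + b) %% m
  h / (m - 1)
}
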