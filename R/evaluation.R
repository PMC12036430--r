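#' Binary-classifier evaluation
#'
#' Metrics over prediction records joined to binary interaction labels:
#' confusion-matrix metrics at a score threshold (F1, precision, recall,
#' specificity) plus threshold-free AUROC (Mann-Whitney rank statistic, ties
#' get half credit) and AUPRC (step-wise integration of the precision-recall
#' curve, no interpolation). Conventions for empty denominators: precision
#' is 0 when nothing is predicted positive; F1 is 0 when precision + recall
#' is 0; AUROC and specificity are NA when only one class is present.
#'
#' @name evaluation
NULL

#' Read a labels CSV (`drug,target,label` header, labels 0/1)
#'
#' @param path CSV path.
#' @return data frame with `drug`, `target`, `label`.
#' @export
read_labels_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("drug", "target", "label") %in% names(df)))
    dg_parse_error("labels file needs columns drug,target,label")
  if (!all(df$label %in% c(0, 1)))
    dg_parse_error("labels must be 0 or 1")
  df
}

join_scores_labels <- function(records, labels) {
  if (is.data.frame(records)) {
    rdf <- records
  } else {
    rdf <- records_to_df(records)
  }
  key_r <- paste(normalize_id(rdf$drug), normalize_id(rdf$target), sep = "|")
  key_l <- paste(normalize_id(labels$drug), normalize_id(labels$target), sep = "|")
  if (anyDuplicated(key_l))
    dg_join_error("duplicate (drug,target) in labels")
  m <- match(key_r, key_l)
  if (anyNA(m)) {
    miss <- unique(paste(rdf$drug, rdf$target, sep = "-")[is.na(m)])
    dg_join_error(paste0("records without a matching label: ",
                         paste(utils::head(miss, 10), collapse = ", ")))
  }
  data.frame(score = rdf$final_score, label = labels$label[m])
}

auroc_rank <- function(scores, labels) {
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores)  # midranks give tied pairs half credit
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

auprc_step <- function(scores, labels) {
  n_pos <- sum(labels == 1)
  if (n_pos == 0) return(NA_real_)
  ord <- order(-scores)
  s <- scores[ord]; y <- labels[ord]
  # group ties: precision/recall evaluated only at distinct-score cut points
  cut <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[cut]
  fp <- cumsum(1 - y)[cut]
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  d_recall <- diff(c(0, recall))
  sum(d_recall * precision)
}

#' Compute the evaluation metric suite
#'
#' Joins records to labels by normalized (drug, target), binarizes the final
#' score at `threshold` (score >= threshold counts positive), and reports
#' F1, precision, recall, specificity, AUROC, AUPRC and the confusion matrix.
#'
#' @param records list of `prediction_record`s or a data frame with columns
#'   `drug,target,final_score`.
#' @param labels data frame with columns `drug,target,label` (labels 0/1).
#' @param threshold classification threshold (default 0.5).
#' @return a `metrics_report` list.
#' @export
compute_metrics <- function(records, labels, threshold = 0.5) {
  dat <- join_scores_labels(records, labels)
  if (any(!is.finite(dat$score)))
    dg_input_error("records contain missing final scores")
  pred <- as.integer(dat$score >= threshold)
  tp <- sum(pred == 1 & dat$label == 1)
  fp <- sum(pred == 1 & dat$label == 0)
  tn <- sum(pred == 0 & dat$label == 0)
  fn <- sum(pred == 0 & dat$label == 1)
  n_pos <- tp + fn; n_neg <- tn + fp
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (n_pos > 0) tp / n_pos else NA_real_
  specificity <- if (n_neg > 0) tn / n_neg else NA_real_
  f1 <- if (!is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(list(f1 = f1, precision = precision, recall = recall,
                 specificity = specificity,
                 auroc = auroc_rank(dat$score, dat$label),
                 auprc = auprc_step(dat$score, dat$label),
                 threshold = threshold, n_pos = n_pos, n_neg = n_neg,
                 confusion = c(tp = tp, fp = fp, tn = tn, fn = fn)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> threshold %.3g; %d positive, %d negative\n",
              x$threshold, x$n_pos, x$n_neg))
  for (m in c("f1", "precision", "recall", "specificity", "auroc", "auprc"))
    cat(sprintf("  %-12s %s\n", m,
                if (is.na(x[[m]])) "undefined" else sprintf("%.3f", x[[m]])))
  cat(sprintf("  confusion    tp=%d fp=%d tn=%d fn=%d\n",
              x$confusion["tp"], x$confusion["fp"], x$confusion["tn"],
              x$confusion["fn"]))
  invisible(x)
}

#' Repeated-subset evaluation
#'
#' Draws `n_subsets` seeded random subsets of `subset_size` labeled pairs
#' (without replacement within each subset), computes the metric suite on
#' each, and reports the per-metric mean and standard deviation -- the
#' mean (+/- SD) presentation used for repeated evaluation runs.
#'
#' @inheritParams compute_metrics
#' @param n_subsets number of independent subsets (default 5).
#' @param subset_size pairs per subset (default 50).
#' @param seed RNG seed for the subset draws.
#' @return a `subset_eval` object: per-metric `mean` and `sd`, plus the
#'   per-subset `metrics_report`s.
#' @export
repeated_subset_eval <- function(records, labels, n_subsets = 5,
                                 subset_size = 50, seed = 0,
                                 threshold = 0.5) {
  if (is.data.frame(records)) rdf <- records else rdf <- records_to_df(records)
  if (subset_size > nrow(rdf))
    dg_size_error(sprintf("subset_size %d exceeds available pairs (%d)",
                          subset_size, nrow(rdf)))
  reports <- with_local_seed(seed, lapply(seq_len(n_subsets), function(i) {
    idx <- sample.int(nrow(rdf), subset_size)
    compute_metrics(rdf[idx, , drop = FALSE], labels, threshold = threshold)
  }))
  metrics <- c("f1", "precision", "recall", "specificity", "auroc", "auprc")
  vals <- sapply(metrics, function(m) vapply(reports, `[[`, 0, m))
  vals <- matrix(vals, nrow = n_subsets,
                 dimnames = list(NULL, metrics))
  structure(list(mean = colMeans(vals),
                 sd = apply(vals, 2, function(v)
                   if (length(v) > 1) stats::sd(v) else 0),
                 reports = reports, n_subsets = n_subsets,
                 subset_size = subset_size, seed = seed),
            class = "subset_eval")
}

#' @export
print.subset_eval <- function(x, ...) {
  cat(sprintf("<subset_eval> %d subsets of %d pairs (seed %d)\n",
              x$n_subsets, x$subset_size, x$seed))
  for (m in names(x$mean))
    cat(sprintf("  %-12s %.3f (+/-%.3f)\n", m, x$mean[[m]], x$sd[[m]]))
  invisible(x)
}
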