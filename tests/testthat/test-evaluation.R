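score_df <- function(drugs, scores) {
  data.frame(drug = drugs, target = paste0("T_", drugs),
             final_score = scores, stringsAsFactors = FALSE)
}
label_df <- function(drugs, labels) {
  data.frame(drug = drugs, target = paste0("T_", drugs), label = labels,
             stringsAsFactors = FALSE)
}

test_that("confusion-matrix metrics match hand-computed toy cases", {
  # each case: scores, labels, threshold, expected (tp,fp,tn,fn,prec,rec,spec,f1)
  cases <- list(
    list(s = c(.9, .8, .1, .2), y = c(1, 1, 0, 0), th = .5,
         e = c(2, 0, 2, 0, 1, 1, 1, 1)),
    list(s = c(.9, .4, .6, .2), y = c(1, 1, 0, 0), th = .5,
         e = c(1, 1, 1, 1, .5, .5, .5, .5)),
    list(s = c(.9, .9, .9, .9), y = c(1, 0, 1, 0), th = .5,
         e = c(2, 2, 0, 0, .5, 1, 0, 2/3)),
    list(s = c(.1, .1, .1, .1), y = c(1, 0, 1, 0), th = .5,
         e = c(0, 0, 2, 2, 0, 0, 1, 0)),
    list(s = c(.5, .4, .5, .4), y = c(1, 1, 0, 0), th = .5,  # >= at threshold
         e = c(1, 1, 1, 1, .5, .5, .5, .5)),
    list(s = c(.8, .7, .6, .3, .2), y = c(1, 0, 1, 1, 0), th = .5,
         e = c(2, 1, 1, 1, 2/3, 2/3, .5, 2/3)),
    list(s = c(.8, .7, .6, .3, .2), y = c(1, 0, 1, 1, 0), th = .65,
         e = c(1, 1, 1, 2, .5, 1/3, .5, .4)),
    list(s = c(.9, .8, .7, .1), y = c(0, 0, 0, 1), th = .5,
         e = c(0, 3, 0, 1, 0, 0, 0, 0)),
    list(s = c(.6, .2), y = c(1, 0), th = .5,
         e = c(1, 0, 1, 0, 1, 1, 1, 1)),
    list(s = c(.2, .6), y = c(1, 0), th = .5,
         e = c(0, 1, 0, 1, 0, 0, 0, 0)))
  for (k in seq_along(cases)) {
    cs <- cases[[k]]
    ids <- sprintf("c%d_%d", k, seq_along(cs$s))
    m <- compute_metrics(score_df(ids, cs$s), label_df(ids, cs$y),
                         threshold = cs$th)
    expect_equal(unname(m$confusion[c("tp", "fp", "tn", "fn")]), cs$e[1:4],
                 info = paste("case", k))
    expect_equal(c(m$precision, m$recall, m$specificity, m$f1), cs$e[5:8],
                 info = paste("case", k))
  }
})

test_that("perfect separation yields all metrics 1.0", {
  ids <- sprintf("p%d", 1:8)
  m <- compute_metrics(score_df(ids, c(rep(.9, 4), rep(.1, 4))),
                       label_df(ids, c(rep(1, 4), rep(0, 4))))
  for (metric in c("f1", "precision", "recall", "specificity",
                   "auroc", "auprc"))
    expect_equal(m[[metric]], 1.0, info = metric)
})

test_that("an indiscriminate all-positive predictor shows its failure mode", {
  ids <- sprintf("q%d", 1:6)
  m <- compute_metrics(score_df(ids, rep(1.0, 6)),
                       label_df(ids, c(1, 0, 1, 0, 1, 0)))
  expect_equal(m$recall, 1.0)
  expect_equal(m$specificity, 0.0)
  expect_lt(m$precision, 1.0)
})

test_that("AUROC equals the O(n^2) concordant-pair oracle", {
  for (seed in 1:40) {
    set.seed(seed)
    n <- sample(6:30, 1)
    scores <- round(stats::runif(n), sample(c(1, 2, 6), 1))  # induce ties
    labels <- stats::rbinom(n, 1, 0.4)
    if (all(labels == 1)) labels[1] <- 0
    if (all(labels == 0)) labels[1] <- 1
    ids <- sprintf("s%d_%d", seed, seq_len(n))
    m <- compute_metrics(score_df(ids, scores), label_df(ids, labels))
    expect_equal(m$auroc, oracle_auroc(scores, labels))
  }
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  set.seed(99)
  scores <- stats::runif(25); labels <- stats::rbinom(25, 1, 0.5)
  labels[1:2] <- c(0, 1)
  ids <- sprintf("m%d", 1:25)
  a1 <- compute_metrics(score_df(ids, scores), label_df(ids, labels))$auroc
  a2 <- compute_metrics(score_df(ids, plogis(5 * scores - 1)),
                        label_df(ids, labels))$auroc
  expect_equal(a1, a2)
})

test_that("AUPRC follows step-wise precision-recall integration", {
  ids <- sprintf("a%d", 1:4)
  # descending scores .9 .8 .7 .6, labels 1 0 1 0:
  # steps at recall .5 (prec 1) and recall 1 (prec 2/3)
  m <- compute_metrics(score_df(ids, c(.9, .8, .7, .6)),
                       label_df(ids, c(1, 0, 1, 0)))
  expect_equal(m$auprc, 0.5 * 1 + 0.5 * (2 / 3))
  # tied scores collapse to one cut point
  m2 <- compute_metrics(score_df(ids, c(.9, .9, .9, .9)),
                        label_df(ids, c(1, 0, 1, 0)))
  expect_equal(m2$auprc, 0.5)
})

test_that("cross-check against an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  scores <- stats::runif(60); labels <- stats::rbinom(60, 1, 0.35)
  labels[1:2] <- c(0, 1)
  ids <- sprintf("r%d", 1:60)
  m <- compute_metrics(score_df(ids, scores), label_df(ids, labels))
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(m$auroc, ref)
})

test_that("threshold sweeps move recall down and specificity up", {
  set.seed(12)
  scores <- stats::runif(40); labels <- stats::rbinom(40, 1, 0.5)
  labels[1:2] <- c(0, 1)
  ids <- sprintf("t%d", 1:40)
  th <- seq(0, 1, by = 0.1)
  ms <- lapply(th, function(x)
    compute_metrics(score_df(ids, scores), label_df(ids, labels), threshold = x))
  rec <- vapply(ms, `[[`, 0, "recall")
  spec <- vapply(ms, `[[`, 0, "specificity")
  expect_true(all(diff(rec) <= 0))
  expect_true(all(diff(spec) >= 0))
})

test_that("degenerate label sets are flagged, not silently scored", {
  ids <- c("u1", "u2")
  m <- compute_metrics(score_df(ids, c(.6, .4)), label_df(ids, c(1, 1)))
  expect_true(is.na(m$auroc))
  expect_true(is.na(m$specificity))
  expect_error(
    compute_metrics(score_df(c("u1", "zz"), c(.5, .5)),
                    label_df(ids, c(1, 0))),
    "zz", class = "dtifuse_join_error")
})

test_that("repeated-subset evaluation is seeded and self-consistent", {
  set.seed(20)
  n <- 120
  ids <- sprintf("e%d", 1:n)
  scores <- stats::runif(n)
  labels <- as.integer(scores + stats::rnorm(n, 0, .3) > .5)
  rdf <- score_df(ids, scores); ldf <- label_df(ids, labels)

  one <- repeated_subset_eval(rdf, ldf, n_subsets = 1, subset_size = 50, seed = 3)
  expect_true(all(one$sd == 0))

  a <- repeated_subset_eval(rdf, ldf, n_subsets = 4, subset_size = 40, seed = 3)
  b <- repeated_subset_eval(rdf, ldf, n_subsets = 4, subset_size = 40, seed = 3)
  expect_identical(a$mean, b$mean)
  expect_identical(a$sd, b$sd)

  per <- vapply(a$reports, `[[`, 0, "f1")
  expect_gte(a$mean[["f1"]], min(per)); expect_lte(a$mean[["f1"]], max(per))

  expect_error(repeated_subset_eval(rdf, ldf, subset_size = 500),
               class = "dtifuse_size_error")
})
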