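# Independent literal-formula oracle for the confusion-based metrics,
# written directly from the defining equations.
oracle_metrics <- function(tp, fp, tn, fn) {
  n <- tp + fp + tn + fn
  tpr <- if (tp + fn > 0) tp / (tp + fn) else 0
  tnr <- if (tn + fp > 0) tn / (tn + fp) else 0
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(accuracy = (tp + tn) / n, recall = rec, precision = prec,
       mcc = mcc, bacc = (tpr + tnr) / 2, f1 = f1,
       specificity = if (tn + fp > 0) tn / (tn + fp) else 0)
}

test_that("confusion counts are exact", {
  cc <- confusion(c("positive", "positive", "negative", "negative"),
                  c("positive", "negative", "positive", "negative"))
  expect_identical(c(cc$TP, cc$FN, cc$FP, cc$TN), c(1L, 1L, 1L, 1L))
  y <- c(rep("positive", 12), rep("negative", 8))
  p <- y
  expect_identical(confusion(y, p)$FP + confusion(y, p)$FN, 0L)
  expect_error(confusion("positive", c("positive", "negative")),
               "input error")
})

test_that("counts match an exhaustive tally oracle on random tables", {
  set.seed(101)
  for (i in 1:20) {
    y <- sample(c("positive", "negative"), 50, replace = TRUE)
    p <- sample(c("positive", "negative"), 50, replace = TRUE)
    cc <- confusion(y, p)
    tally <- table(truth = y, pred = p)
    expect_identical(cc$TP, sum(y == "positive" & p == "positive"))
    expect_identical(cc$TP + cc$FP + cc$TN + cc$FN, 50L)
    expect_identical(as.integer(sum(tally)), 50L)
  }
})

test_that("every metric matches the literal-formula oracle to 1e-12", {
  set.seed(202)
  for (i in 1:1000) {
    tp <- sample(0:200, 1); fp <- sample(0:200, 1)
    tn <- sample(0:200, 1); fn <- sample(0:200, 1)
    if (tp + fp + tn + fn == 0) next
    cc <- structure(list(TP = tp, FP = fp, TN = tn, FN = fn),
                    class = "confusion_counts")
    m <- suppressWarnings(compute_metrics(cc))
    o <- oracle_metrics(tp, fp, tn, fn)
    expect_lt(abs(m$accuracy - o$accuracy), 1e-12)
    expect_lt(abs(m$recall_rate - o$recall), 1e-12)
    expect_lt(abs(m$precision - o$precision), 1e-12)
    expect_lt(abs(m$mcc - o$mcc), 1e-12)
    expect_lt(abs(m$bacc - o$bacc), 1e-12)
    expect_lt(abs(m$f1 - o$f1), 1e-12)
    expect_lt(abs(m$specificity - o$specificity), 1e-12)
  }
})

test_that("perfect and worked confusion examples evaluate exactly", {
  perfect <- structure(list(TP = 10L, FP = 0L, TN = 10L, FN = 0L),
                       class = "confusion_counts")
  m <- compute_metrics(perfect)
  expect_identical(unname(unlist(m[c("accuracy", "mcc", "f1", "bacc",
                                     "specificity")])),
                   rep(1, 5))
  worked <- structure(list(TP = 6L, FP = 1L, TN = 3L, FN = 2L),
                      class = "confusion_counts")
  w <- compute_metrics(worked)
  expect_equal(w$accuracy, 0.75)
  expect_equal(w$recall_rate, 0.75)
  expect_equal(w$precision, 6 / 7)
  expect_equal(w$specificity, 0.75)
})

test_that("AUROC equals the exhaustive pairwise-comparison oracle", {
  pairwise_auc <- function(y, s) {
    pos <- which(y == "positive"); neg <- which(y == "negative")
    tot <- 0
    for (i in pos) for (j in neg) {
      tot <- tot + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
    }
    tot / (length(pos) * length(neg))
  }
  set.seed(303)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    y <- sample(c("positive", "negative"), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- runif(n)
    expect_lt(abs(auroc_rank(y, s) - pairwise_auc(y, s)), 1e-9)
    # with heavy ties, midranks must still agree with the pairwise oracle
    st <- sample(c(0.2, 0.5, 0.8), n, replace = TRUE)
    expect_lt(abs(auroc_rank(y, st) - pairwise_auc(y, st)), 1e-9)
  }
})

test_that("ranking metric limits behave", {
  y <- c(rep("positive", 5), rep("negative", 5))
  expect_equal(auroc_rank(y, c(rep(1, 5), rep(0, 5))), 1)
  expect_equal(auroc_rank(y, rep(0.5, 10)), 0.5)
  expect_equal(auprc_step(y, c(rep(1, 5), rep(0, 5))), 1)
  # all-equal scores: AP equals prevalence under step interpolation
  expect_equal(auprc_step(y, rep(0.5, 10)), 0.5)
  expect_error(compute_metrics(
    structure(list(TP = 1L, FP = 1L, TN = 1L, FN = 1L),
              class = "confusion_counts"),
    scores = c(0.1, 0.2)), "y_true")
})
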