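test_that("confusion counts partition the samples exhaustively", {
  y <- c(1, 1, -1, -1, 1)
  expect_identical(confusionCounts(y, y),
                   list(tp = 3L, tn = 2L, fp = 0L, fn = 0L))
  expect_identical(confusionCounts(y, -y),
                   list(tp = 0L, tn = 0L, fp = 2L, fn = 3L))
  set.seed(3)
  for (rep in 1:5) {
    yt <- sample(c(-1, 1), 200, replace = TRUE)
    yp <- sample(c(-1, 1), 200, replace = TRUE)
    cc <- confusionCounts(yt, yp)
    expect_identical(cc, lapply(oracleConfusion(yt, yp), as.integer))
    expect_identical(cc$tp + cc$tn + cc$fp + cc$fn, 200L)
  }
  expect_error(confusionCounts(y, y[-1]), class = "dtiValidationError")
})

test_that("threshold metrics reproduce their printed formulas", {
  m <- classificationMetrics(list(tp = 25, tn = 25, fp = 25, fn = 25))
  expect_equal(m$mcc, 0); expect_equal(m$f1, 0.5)
  expect_equal(m$sensitivity, 0.5); expect_equal(m$specificity, 0.5)

  p <- classificationMetrics(list(tp = 10, tn = 20, fp = 0, fn = 0))
  expect_true(all(unlist(p[c("sensitivity", "precision", "specificity",
                             "f1", "mcc")]) == 1))
  expect_equal(p$fpr, 0)

  h <- classificationMetrics(list(tp = 3, fp = 1, fn = 2, tn = 4))
  expect_equal(h$sensitivity, 0.6)
  expect_equal(h$precision, 0.75)
  expect_equal(h$specificity, 0.8)
  expect_equal(h$fpr, 1 - h$specificity)
  expect_equal(h$f1, 6 / 9, tolerance = 1e-12)
  expect_equal(h$mcc, 10 / sqrt(600), tolerance = 1e-12)
  expect_true(h$mcc >= -1 && h$mcc <= 1)
  expect_equal(h$f1,
               2 * h$precision * h$sensitivity /
                 (h$precision + h$sensitivity), tolerance = 1e-12)

  # degenerate denominators return 0 with a warning
  expect_warning(z <- classificationMetrics(list(tp = 0, tn = 5, fp = 0,
                                                 fn = 5)),
                 "degenerate")
  expect_equal(z$precision, 0)
  expect_equal(z$mcc, 0)
})

test_that("ROC handles perfect, random and tied rankings and matches the U statistic", {
  y <- c(rep(1, 4), rep(-1, 6))
  perfect <- rocCurve(y, c(9:6, 5:0) / 10)
  expect_equal(perfect$auc, 1)
  tied <- rocCurve(y, rep(0.3, 10))
  expect_equal(tied$auc, 0.5)
  set.seed(5)
  for (rep in 1:30) {
    n <- sample(8:20, 1)
    yt <- c(1, -1, sample(c(-1, 1), n - 2, replace = TRUE))
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)    # many ties
    expect_equal(rocCurve(yt, sc)$auc, oracleAuROC(yt, sc),
                 tolerance = 1e-12)
  }
  expect_error(rocCurve(rep(1, 5), runif(5)), class = "dtiValidationError")
})

test_that("ROC/auROC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  for (rep in 1:10) {
    yt <- c(1, -1, sample(c(-1, 1), 48, replace = TRUE))
    sc <- round(runif(50), 2)
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = factor(yt, levels = c(-1, 1)), predictor = sc,
      quiet = TRUE, direction = "<")))
    expect_equal(rocCurve(yt, sc)$auc, ref, tolerance = 1e-10)
  }
})

test_that("PR curve uses step-wise integration and baselines at prevalence", {
  y <- c(rep(1, 3), rep(-1, 7))
  perfect <- prCurve(y, 10:1)
  expect_equal(perfect$auc, 1)
  flat <- prCurve(y, rep(0.2, 10))
  expect_equal(flat$auc, 0.3)          # all-equal scores -> prevalence
  set.seed(7)
  for (rep in 1:30) {
    n <- sample(8:20, 1)
    yt <- c(1, sample(c(-1, 1), n - 1, replace = TRUE))
    sc <- sample(seq(0, 1, 0.125), n, replace = TRUE)
    expect_equal(prCurve(yt, sc)$auc, oracleAuPR(yt, sc),
                 tolerance = 1e-12)
  }
  expect_error(prCurve(rep(-1, 4), runif(4)), class = "dtiValidationError")
})

test_that("curve areas are invariant under strictly monotone score transforms", {
  set.seed(8)
  for (rep in 1:20) {
    yt <- c(1, -1, sample(c(-1, 1), 28, replace = TRUE))
    sc <- runif(30)
    for (f in list(function(s) 2 * s - 1, function(s) exp(3 * s),
                   function(s) atan(s))) {
      expect_equal(rocCurve(yt, f(sc))$auc, rocCurve(yt, sc)$auc,
                   tolerance = 1e-12)
      expect_equal(prCurve(yt, f(sc))$auc, prCurve(yt, sc)$auc,
                   tolerance = 1e-12)
    }
  }
})

test_that("cross-validation stratifies folds and never balances test rows", {
  set.seed(9)
  n <- 150
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- c(rep(1, 30), rep(-1, 120))
  seen <- new.env(); seen$rows <- list()
  recorder <- function(Xtr, ytr) {
    seen$rows[[length(seen$rows) + 1L]] <- rownames(Xtr)
    out <- randomUndersample(Xtr, ytr, samplerConfig("rus", seed = 1))
    out
  }
  rownames(X) <- paste0("r", seq_len(n))
  cv <- crossValidate(X, y, sampler = recorder, nRounds = 3, folds = 5,
                      repeats = 2, seed = 4)
  expect_identical(nrow(cv$perFold), 10L)
  # stratification: each fold holds 6 positives and 24 negatives
  for (r in 1:2) {
    fid <- cv$folds[[r]]
    for (f in 1:5) {
      expect_identical(sum(y == 1 & fid == f), 6L)
      expect_identical(sum(y == -1 & fid == f), 24L)
    }
  }
  # the sampler never saw a test row of its own fold
  i <- 0
  for (r in 1:2) for (f in 1:5) {
    i <- i + 1
    testRows <- paste0("r", which(cv$folds[[r]] == f))
    expect_length(intersect(seen$rows[[i]], testRows), 0L)
  }
  # summary means equal the mean of per-fold values
  expect_equal(unname(cv$summary[["auROC"]]), mean(cv$perFold$auROC))
})

test_that("cross-validation is deterministic under its master seed", {
  set.seed(10)
  X <- matrix(rnorm(80 * 3), 80, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- rep(c(1, -1), each = 40)
  a <- crossValidate(X, y, nRounds = 3, folds = 4, repeats = 2, seed = 99)
  b <- crossValidate(X, y, nRounds = 3, folds = 4, repeats = 2, seed = 99)
  expect_identical(a$perFold, b$perFold)
  expect_error(crossValidate(X[1:6, ], c(1, 1, 1, -1, -1, -1),
                             folds = 5, repeats = 1),
               "fewer than", class = "dtiValidationError")
})

test_that("candidate ranking sorts by score with lexicographic tie-breaks", {
  pairs <- data.frame(drugId = c("d2", "d1", "d3"),
                      targetId = c("t1", "t2", "t3"))
  top <- rankNewInteractions(pairs, c(0.1, 0.9, 0.5), topN = 2)
  expect_identical(top$drugId, c("d1", "d3"))
  expect_equal(top$score[1], 0.9)

  tiedPairs <- data.frame(drugId = c("d2", "d1", "d1"),
                          targetId = c("t1", "t9", "t2"))
  tied <- rankNewInteractions(tiedPairs, rep(0.5, 3), topN = 3)
  expect_identical(paste(tied$drugId, tied$targetId),
                   c("d1 t2", "d1 t9", "d2 t1"))

  set.seed(11)
  big <- data.frame(drugId = sprintf("d%03d", sample(100)),
                    targetId = sprintf("t%03d", sample(100)))
  sc <- runif(100)
  all <- rankNewInteractions(big, sc, topN = 100)
  expect_identical(all$score, sort(sc, decreasing = TRUE))
  expect_warning(rankNewInteractions(big, sc, topN = 150), "returning all")
})
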