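# linearly separable toy problem
separableToy <- function(n = 40, seed = 1) {
  set.seed(seed)
  X <- cbind(x1 = c(runif(n / 2, -2, -0.5), runif(n / 2, 0.5, 2)),
             x2 = runif(n, -1, 1))
  list(X = X, y = rep(c(-1, 1), each = n / 2))
}

test_that("AdaBoost drives training error to zero on separable data and obeys its bound", {
  d <- separableToy()
  m <- adaBoost(d$X, d$y, weakLearnerSpec(maxDepth = 1), nRounds = 20)
  trainErr <- mean(predictLabel(m, d$X) != d$y)
  expect_equal(trainErr, 0)
  bound <- prod(2 * sqrt(stageErrors(m) * (1 - stageErrors(m))))
  expect_gte(bound, trainErr)
})

test_that("stage weights follow the closed form alpha = 0.5 log((1-eps)/eps)", {
  # craft a learner with a fixed hypothesis that errs on exactly 1 of 4
  # uniformly weighted samples: eps_1 = 0.25, alpha_1 = 0.5 log 3
  X <- matrix(1:4, ncol = 1, dimnames = list(NULL, "x"))
  y <- c(1, 1, 1, -1)
  fixed <- list(fit = function(X, y, w) "h",
                predict = function(model, X) rep(1, nrow(X)))
  m <- adaBoost(X, y, nRounds = 1, learner = fixed)
  expect_equal(stageErrors(m), 0.25)
  expect_equal(stageWeights(m), 0.5 * log(3), tolerance = 1e-12)
})

test_that("a chance-level weak learner on round 1 is an error, zero error stops with a capped stage", {
  X <- matrix(1:4, ncol = 1, dimnames = list(NULL, "x"))
  y <- c(1, -1, 1, -1)
  chance <- list(fit = function(X, y, w) "h",
                 predict = function(model, X) rep(1, nrow(X)))
  expect_error(adaBoost(X, y, nRounds = 5, learner = chance),
               "no better than", class = "dtiValidationError")

  perfect <- list(fit = function(X, y, w) "h",
                  predict = function(model, X)
                    ifelse(X[, 1] %% 2 == 1, 1, -1))
  m <- adaBoost(X, y, nRounds = 10, learner = perfect)
  expect_length(stageWeights(m), 1L)
  expect_equal(stageErrors(m), 0)
  expect_equal(stageWeights(m), 0.5 * log((1 - 1e-10) / 1e-10))
})

test_that("re-weighting makes the just-fit hypothesis worthless next round", {
  # defining AdaBoost property: weighted error of h_t under D_{t+1} is 1/2
  d <- separableToy(n = 60, seed = 3)
  # add label noise so rounds stay imperfect
  y <- d$y; y[c(3, 17, 44)] <- -y[c(3, 17, 44)]
  spec <- weakLearnerSpec(maxDepth = 1)
  learner <- giniTreeLearner(spec)
  n <- length(y)
  D <- rep(1 / n, n)
  for (t in 1:8) {
    h <- learner$fit(d$X, y, D)
    pred <- learner$predict(h, d$X)
    eps <- sum(D * (pred != y))
    if (eps <= 0 || eps >= 0.5) break
    alpha <- 0.5 * log((1 - eps) / eps)
    D <- D * exp(-alpha * y * pred)
    D <- D / sum(D)
    expect_equal(sum(D), 1, tolerance = 1e-12)
    expect_true(all(D >= 0))
    expect_equal(sum(D * (pred != y)), 0.5, tolerance = 1e-10)
  }
})

test_that("decision function is the alpha-weighted stage sum with +1 ties", {
  d <- separableToy(n = 30, seed = 5)
  y <- d$y; y[c(2, 29)] <- -y[c(2, 29)]
  m <- adaBoost(d$X, y, weakLearnerSpec(maxDepth = 1), nRounds = 6)
  g <- decisionFunction(m, d$X)
  # explicit per-stage summation oracle
  gOracle <- numeric(nrow(d$X))
  for (t in seq_along(m@stages))
    gOracle <- gOracle + stageWeights(m)[t] *
      m@learner$predict(m@stages[[t]], d$X)
  expect_equal(g, gOracle, tolerance = 1e-12)
  expect_identical(predictLabel(m, d$X), ifelse(g >= 0, 1, -1))
  expect_error(decisionFunction(m, d$X[, 1, drop = FALSE]),
               "missing model feature", class = "dtiValidationError")
  expect_error(decisionFunction(m, unname(d$X[, 1, drop = FALSE])),
               "mismatch", class = "dtiValidationError")
})

test_that("predictScore maps margins monotonically into [0,1]", {
  d <- separableToy(n = 30, seed = 6)
  y <- d$y; y[c(1, 15)] <- -y[c(1, 15)]
  m <- adaBoost(d$X, y, weakLearnerSpec(maxDepth = 1), nRounds = 8)
  g <- decisionFunction(m, d$X)
  s <- predictScore(m, d$X)
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(s, (g / sum(stageWeights(m)) + 1) / 2, tolerance = 1e-12)
  expect_equal(cor(s, g, method = "spearman"), 1)
  # unanimous agreement saturates the score
  onesided <- adaBoost(d$X, d$y, weakLearnerSpec(maxDepth = 1), nRounds = 3)
  sPos <- predictScore(onesided, d$X[d$y == 1, , drop = FALSE])
  expect_equal(max(sPos), 1)
})

test_that("the built-in Gini tree agrees with rpart on random stump problems", {
  spec <- weakLearnerSpec(maxDepth = 1, minSamplesSplit = 2,
                          minSamplesLeaf = 1)
  own <- giniTreeLearner(spec)
  ref <- rpartLearner(spec)
  set.seed(8)
  agree <- 0
  for (rep in 1:25) {
    n <- 40
    X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
    y <- ifelse(X[, 3] + 0.3 * rnorm(n) > 0, 1, -1)
    w <- rgamma(n, 2); w <- w / sum(w)
    pOwn <- own$predict(own$fit(X, y, w), X)
    pRef <- ref$predict(ref$fit(X, y, w), X)
    agree <- agree + mean(pOwn == pRef)
  }
  # identical split choices up to tie-breaking on a handful of cases
  expect_gte(agree / 25, 0.98)
})

test_that("fitting is reproducible and ensembles serialize losslessly", {
  d <- separableToy(n = 30, seed = 9)
  y <- d$y; y[4] <- -y[4]
  m1 <- adaBoost(d$X, y, weakLearnerSpec(maxDepth = 2), nRounds = 5, seed = 7)
  m2 <- adaBoost(d$X, y, weakLearnerSpec(maxDepth = 2), nRounds = 5, seed = 7)
  expect_identical(stageWeights(m1), stageWeights(m2))
  expect_identical(decisionFunction(m1, d$X), decisionFunction(m2, d$X))
  f <- withr::local_tempfile(fileext = ".rds")
  saveEnsemble(m1, f)
  m3 <- loadEnsemble(f)
  expect_identical(decisionFunction(m3, d$X), decisionFunction(m1, d$X))
})

test_that("named presets carry the printed tree controls", {
  p <- adaBoostPreset("enzymes", "rus")
  expect_identical(p$maxDepth, 100L)
  expect_identical(p$minSamplesSplit, 16L)
  expect_identical(p$minSamplesLeaf, 1L)
  p2 <- adaBoostPreset("nuclear_receptors", "cus")
  expect_identical(p2$maxDepth, 150L)
  expect_identical(p2$minSamplesSplit, 2L)
  expect_identical(p2$criterion, "gini")
})
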