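# independent oracle: same penalized objective optimized by BFGS
bfgs_logistic <- function(x, y, l2) {
  X1 <- cbind(1, x)
  obj <- function(beta) {
    eta <- drop(X1 %*% beta)
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) +
      l2 / 2 * sum(beta[-1]^2)
  }
  gr <- function(beta) {
    p <- plogis(drop(X1 %*% beta))
    drop(crossprod(X1, p - y)) + c(0, l2 * beta[-1])
  }
  optim(rep(0, ncol(X1)), obj, gr, method = "BFGS",
        control = list(maxit = 2000, reltol = 1e-15))$par
}

# brute-force pair-counting AUC, ties counted one half
pair_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

test_that("train/test split partitions deterministically", {
  sp <- splitTrainTest(100, 0.9, seed = 3)
  expect_length(sp$train, 90L)
  expect_length(sp$test, 10L)
  expect_equal(sort(c(sp$train, sp$test)), 1:100)
  expect_identical(splitTrainTest(100, 0.9, seed = 3), sp)
  expect_error(splitTrainTest(100, 1.2), "\\(0, 1\\)")
})

test_that("Newton fit solves the separable and degenerate cases", {
  x <- cbind(f1 = c(-2, -1.5, -1, 1, 1.5, 2), f2 = rnorm(6))
  y <- c(0, 0, 0, 1, 1, 1)
  m <- trainLogistic(x, y, l2 = 1)
  p <- predictProba(m, x)[, "derived"]
  expect_equal(as.numeric(p >= 0.5), y)
  expect_true(m@meta$converged)

  x0 <- matrix(0, 10, 2, dimnames = list(NULL, c("a", "b")))
  y0 <- c(rep(1, 7), rep(0, 3))
  m0 <- trainLogistic(x0, y0, l2 = 1)
  expect_equal(unname(modelWeights(m0)), c(0, 0))
  expect_equal(modelIntercept(m0), qlogis(0.7), tolerance = 1e-8)

  expect_error(trainLogistic(cbind(a = c(1, NA)), c(0, 1), 1),
               "non-finite")
})

test_that("Newton solution matches an independent optimizer to 1e-6", {
  withr::with_seed(42, {
    x <- matrix(rnorm(200 * 5), 200, 5,
                dimnames = list(NULL, paste0("f", 1:5)))
    y <- rbinom(200, 1, plogis(x %*% c(1, -2, 0.5, 0, 1)))
  })
  for (l2 in c(0.1, 1, 10)) {
    m <- trainLogistic(x, y, l2 = l2)
    ref <- bfgs_logistic(x, y, l2)
    expect_lt(max(abs(c(modelIntercept(m), modelWeights(m)) - ref)), 1e-6)
  }
})

test_that("predicted class probabilities are complementary and monotone", {
  m <- trainLogistic(matrix(0, 10, 1, dimnames = list(NULL, "f")),
                     rep(c(0, 1), 5), l2 = 1)
  pr <- predictProba(m, matrix(c(0, 1), 2, 1, dimnames = list(NULL, "f")))
  expect_equal(unname(pr[1, ]), c(0.5, 0.5))
  expect_lt(max(abs(rowSums(pr) - 1)), 1e-12)

  m2 <- new("TrainedModel", weights = c(f = 3), intercept = 0, l2 = 1,
            scaling = new("ScalingParams", sds = c(f = 1),
                          dropped = character()),
            specChecksum = NA_character_, meta = list())
  grid <- matrix(seq(-3, 3, 1), ncol = 1, dimnames = list(NULL, "f"))
  p <- predictProba(m2, grid)[, "derived"]
  expect_true(all(diff(p) > 0))
  expect_error(predictProba(m2, matrix(0, 1, 1,
                                       dimnames = list(NULL, "g"))),
               "missing")
})

test_that("rank-based AUC equals exhaustive pair counting, ties half", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.3), c(1, 0, 1)), 0.5)
  withr::with_seed(7, {
    for (i in 1:100) {
      n <- sample(5:40, 1)
      scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # forces ties
      labels <- c(0, 1, rbinom(n - 2, 1, 0.5))             # both classes
      expect_identical(rocAuc(scores, labels), pair_auc(scores, labels))
    }
  })
  withr::with_seed(8, {
    auc_null <- rocAuc(runif(2000), rbinom(2000, 1, 0.5))
  })
  expect_gt(auc_null, 0.45)
  expect_lt(auc_null, 0.55)
  expect_error(rocAuc(1:3, c(1, 1, 1)), "single class")
})

test_that("evaluation reports accuracy at 0.5 and AUC on held-out rows", {
  x <- matrix(c(-5, -4, 4, 5), 4, 1, dimnames = list(NULL, "f"))
  y <- c(0, 0, 1, 1)
  m <- trainLogistic(x, y, l2 = 0.01)
  ev <- evaluateModel(m, x, y)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$roc_auc, 1)
  expect_equal(sum(ev$confusion), 4)
})

test_that("L2 selection takes the argmax with ties toward more shrinkage", {
  inj <- c(`0.01` = 0.70, `0.1` = 0.74, `1` = 0.80, `10` = 0.78,
           `100` = 0.71)
  expect_equal(selectL2(inj), 1)
  expect_equal(selectL2(c(`10` = 0.8)), 10)
  expect_equal(selectL2(c(`0.1` = 0.75, `1` = 0.75, `10` = 0.7)), 1)
})

test_that("tuning runs repeated sub-sampling and is seed-stable", {
  withr::with_seed(13, {
    x <- matrix(rnorm(300 * 3), 300, 3,
                dimnames = list(NULL, paste0("f", 1:3)))
    y <- rbinom(300, 1, plogis(2 * x[, 1]))
  })
  cfg <- modelConfig(l2Candidates = c(0.1, 1, 10), repeats = 3, seed = 5)
  t1 <- tuneL2(x, y, cfg)
  t2 <- tuneL2(x, y, cfg)
  expect_identical(t1$mean_accuracy, t2$mean_accuracy)
  expect_true(t1$best_l2 %in% cfg$l2Candidates)
  expect_equal(dim(t1$accuracy), c(3L, 3L))
})

test_that("heavy regularization loses a strong sparse signal in tuning", {
  withr::with_seed(99, {
    x <- matrix(rnorm(400 * 4), 400, 4,
                dimnames = list(NULL, paste0("f", 1:4)))
    y <- rbinom(400, 1, plogis(4 * x[, 1]))
  })
  res <- tuneL2(x, y, modelConfig(l2Candidates = c(0.1, 1, 1000),
                                  repeats = 5, seed = 17))
  expect_lt(res$best_l2, 1000)
})

test_that("L2 shrinkage is monotone in the penalty", {
  withr::with_seed(3, {
    x <- matrix(rnorm(100 * 3), 100, 3,
                dimnames = list(NULL, paste0("f", 1:3)))
    y <- rbinom(100, 1, plogis(x[, 1] - x[, 2]))
  })
  norms <- vapply(c(0.01, 0.1, 1, 10, 100), function(l2)
    sqrt(sum(modelWeights(trainLogistic(x, y, l2))^2)), numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("feature weights rank by magnitude; planted signal ranks first", {
  m <- new("TrainedModel", weights = c(a = -3, b = 2, c = 0.1),
           intercept = 0, l2 = 1,
           scaling = new("ScalingParams", sds = c(a = 1, b = 1, c = 1),
                         dropped = character()),
           specChecksum = NA_character_, meta = list())
  rep1 <- featureWeightReport(m)
  expect_equal(rep1$feature, c("a", "b", "c"))
  expect_equal(nrow(featureWeightReport(m, topK = 10)), 3L)

  withr::with_seed(31, {
    x <- matrix(rnorm(500 * 5), 500, 5,
                dimnames = list(NULL, paste0("f", 1:5)))
    y <- rbinom(500, 1, plogis(3 * x[, 2]))
  })
  fit <- trainLogistic(x, y, l2 = 1)
  expect_equal(featureWeightReport(fit)$feature[1], "f2")
})
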