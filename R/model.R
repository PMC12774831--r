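#' Model configuration
#'
#' Defaults follow the training protocol: 90/10 outer split, L2 candidates
#' \{0.01, 0.1, 1, 10, 100\} tuned by 5-fold repeated random sub-sampling
#' (inner 90/10), Newton solver capped at 100 iterations.
#'
#' @param trainFraction outer training fraction
#' @param l2Candidates candidate ridge penalties
#' @param repeats number of random sub-sampling repeats
#' @param innerFraction inner training fraction
#' @param maxIter Newton iteration cap
#' @param seed integer seed driving every split
#' @return list of class "modelConfig"
#' @export
modelConfig <- function(trainFraction = 0.9,
                        l2Candidates = c(0.01, 0.1, 1.0, 10.0, 100.0),
                        repeats = 5L, innerFraction = 0.9,
                        maxIter = 100L, seed = 1L) {
  stopifnot(trainFraction > 0, trainFraction < 1,
            innerFraction > 0, innerFraction < 1,
            all(l2Candidates > 0), repeats >= 1L)
  structure(list(trainFraction = trainFraction, l2Candidates = l2Candidates,
                 repeats = repeats, innerFraction = innerFraction,
                 maxIter = maxIter, seed = seed), class = "modelConfig")
}

#' Random train/test partition
#'
#' @param n number of rows (or a FeatureMatrix / LabeledVariantSet)
#' @param fraction training fraction in (0, 1)
#' @param seed integer seed
#' @return list with integer index vectors \code{train} and \code{test}
#' @export
splitTrainTest <- function(n, fraction = 0.9, seed = 1L) {
  if (is(n, "FeatureMatrix")) n <- nrow(featureMatrix(n))
  if (is(n, "VariantSet")) n <- length(n)
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  if (n < 10L) stop("need at least 10 rows to split")
  ntrain <- round(n * fraction)
  train <- with_seed(seed, sort(sample(seq_len(n), ntrain)))
  list(train = train, test = setdiff(seq_len(n), train))
}

logistic_objective <- function(beta, X1, y, l2) {
  eta <- drop(X1 %*% beta)
  # log(1+exp(eta)) computed stably
  ll <- sum(ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30)))) - y * eta)
  ll + l2 / 2 * sum(beta[-1]^2)
}

#' Train the L2-regularized logistic regression by Newton/IRLS
#'
#' Minimizes the summed negative log-likelihood plus (l2/2)||w||^2 over the
#' feature weights, intercept unpenalized, with step-halving when a Newton
#' step fails to decrease the objective. Convergence is declared when the
#' gradient norm drops below 1e-8; otherwise iteration stops at
#' \code{maxIter} with \code{converged = FALSE} in the metadata.
#'
#' @param x scaled \linkS4class{FeatureMatrix} or numeric matrix
#' @param labels 0/1 vector (1 = derived)
#' @param l2 ridge penalty (on the summed NLL; see the methods vignette)
#' @param maxIter iteration cap
#' @param scaling optional \linkS4class{ScalingParams} to persist with the
#'   model
#' @param specChecksum optional feature-spec checksum to stamp
#' @return a \linkS4class{TrainedModel}
#' @export
trainLogistic <- function(x, labels, l2 = 1.0, maxIter = 100L,
                          scaling = NULL, specChecksum = NA_character_) {
  if (is(x, "FeatureMatrix")) {
    if (is.na(specChecksum)) specChecksum <- x@checksum
    x <- featureMatrix(x)
  }
  if (!all(is.finite(x))) stop("non-finite values in feature matrix")
  y <- as.numeric(labels)
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  if (nrow(x) != length(y)) stop("row/label length mismatch")
  n <- nrow(x); p <- ncol(x)
  X1 <- cbind(`(Intercept)` = 1, x)
  beta <- rep(0, p + 1L)
  pen <- c(0, rep(l2, p))
  obj <- logistic_objective(beta, X1, y, l2)
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    prob <- plogis(drop(X1 %*% beta))
    grad <- drop(crossprod(X1, prob - y)) + pen * beta
    if (sqrt(sum(grad^2)) < 1e-8) { converged <- TRUE; break }
    w <- pmax(prob * (1 - prob), 1e-10)
    H <- crossprod(X1 * w, X1)
    diag(H) <- diag(H) + pen
    step <- tryCatch(solve(H, grad), error = function(e)
      grad / max(diag(H)))
    # step halving: never accept an objective increase
    lam <- 1
    repeat {
      cand <- beta - lam * step
      cand_obj <- logistic_objective(cand, X1, y, l2)
      if (cand_obj <= obj || lam < 1e-8) break
      lam <- lam / 2
    }
    if (cand_obj > obj) break  # no descent direction left
    beta <- cand; obj <- cand_obj
    prob <- plogis(drop(X1 %*% beta))
    grad <- drop(crossprod(X1, prob - y)) + pen * beta
    if (sqrt(sum(grad^2)) < 1e-8) { converged <- TRUE; break }
  }
  if (is.null(scaling))
    scaling <- new("ScalingParams",
                   sds = setNames(rep(1, p), colnames(x) %||%
                                    paste0("f", seq_len(p))),
                   dropped = character())
  nm <- colnames(x) %||% paste0("f", seq_len(p))
  new("TrainedModel",
      weights = setNames(beta[-1], nm), intercept = unname(beta[1]),
      l2 = l2,
      scaling = scaling, specChecksum = specChecksum,
      meta = list(iterations = iter, converged = converged,
                  objective = obj, n = n))
}

#' Class probabilities from a trained model
#'
#' Returns per row P(derived) = sigmoid(w.x + b) and
#' P(simulated) = 1 - P(derived); each pair sums to 1 by construction.
#'
#' @param model a \linkS4class{TrainedModel}
#' @param x scaled \linkS4class{FeatureMatrix} or numeric matrix with the
#'   model's feature columns
#' @return numeric matrix with columns \code{derived} and \code{simulated}
#' @export
predictProba <- function(model, x) {
  if (is(x, "FeatureMatrix")) {
    if (!is.na(model@specChecksum) && !is.na(x@checksum) &&
        model@specChecksum != x@checksum)
      stop("feature-spec checksum mismatch between model and matrix")
    x <- featureMatrix(x)
  }
  nm <- names(model@weights)
  if (!is.null(colnames(x))) {
    if (!all(nm %in% colnames(x)))
      stop("matrix is missing model feature column(s): ",
           paste(setdiff(nm, colnames(x)), collapse = ", "))
    x <- x[, nm, drop = FALSE]
  } else if (ncol(x) != length(nm)) {
    stop("column count mismatch with model features")
  }
  p <- plogis(drop(x %*% model@weights) + model@intercept)
  cbind(derived = p, simulated = 1 - p)
}

#' Rank-based ROC-AUC with ties counted one half
#'
#' @param scores numeric scores (higher = more label-1-like)
#' @param labels 0/1 vector
#' @return AUC in [0, 1]
#' @export
rocAuc <- function(scores, labels) {
  y <- as.numeric(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: test labels contain a single class")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a model on held-out rows
#'
#' Accuracy at the 0.5 probability threshold plus rank-based ROC-AUC on
#' P(derived).
#'
#' @inheritParams predictProba
#' @param labels held-out 0/1 labels
#' @return list with accuracy, roc_auc and a confusion matrix
#' @export
evaluateModel <- function(model, x, labels) {
  y <- as.numeric(labels)
  prob <- predictProba(model, x)[, "derived"]
  pred <- as.numeric(prob >= 0.5)
  conf <- table(factor(pred, levels = c(0, 1)),
                factor(y, levels = c(0, 1)), dnn = c("pred", "truth"))
  list(accuracy = mean(pred == y),
       roc_auc = rocAuc(prob, y),
       confusion = conf)
}

#' Select the L2 penalty from mean validation accuracies
#'
#' Argmax of the mean accuracy; ties break toward the larger (more
#' regularized) candidate.
#'
#' @param meanAccuracies named numeric vector (names = L2 values)
#' @return the selected L2 as numeric
#' @export
selectL2 <- function(meanAccuracies) {
  l2s <- as.numeric(names(meanAccuracies))
  best <- max(meanAccuracies)
  max(l2s[meanAccuracies >= best - 1e-12])
}

#' Tune the L2 penalty by repeated random sub-sampling
#'
#' The training rows are split \code{repeats} times into inner 90/10
#' train/validation subsets (the same splits for every candidate); for each
#' candidate a model is fit on the inner-train rows and its accuracy
#' measured on the inner-validation rows. The candidate with the highest
#' mean accuracy wins, ties toward the larger penalty. A non-converged fit
#' contributes its accuracy with a warning rather than being discarded.
#'
#' @param x scaled \linkS4class{FeatureMatrix} or matrix (training rows)
#' @param labels 0/1 labels
#' @param config a \code{\link{modelConfig}}
#' @return list with best_l2, mean_accuracy (named vector) and the
#'   per-split accuracy matrix
#' @export
tuneL2 <- function(x, labels, config = modelConfig()) {
  if (is(x, "FeatureMatrix")) x <- featureMatrix(x)
  if (length(config$l2Candidates) < 2L && length(config$l2Candidates) != 1L)
    stop("need at least one candidate")
  n <- nrow(x)
  splits <- lapply(seq_len(config$repeats), function(r)
    splitTrainTest(n, config$innerFraction,
                   seed = derive_seed(config$seed, paste0("tune", r))))
  acc <- matrix(NA_real_, nrow = config$repeats,
                ncol = length(config$l2Candidates),
                dimnames = list(NULL, as.character(config$l2Candidates)))
  for (j in seq_along(config$l2Candidates)) {
    for (r in seq_len(config$repeats)) {
      tr <- splits[[r]]$train; va <- splits[[r]]$test
      fit <- trainLogistic(x[tr, , drop = FALSE], labels[tr],
                           l2 = config$l2Candidates[j],
                           maxIter = config$maxIter)
      if (!isTRUE(fit@meta$converged))
        warning(sprintf("L2 = %g, split %d: Newton did not converge; ",
                        config$l2Candidates[j], r),
                "accuracy recorded anyway", call. = FALSE)
      prob <- predictProba(fit, x[va, , drop = FALSE])[, "derived"]
      acc[r, j] <- mean(as.numeric(prob >= 0.5) == labels[va])
    }
  }
  means <- colMeans(acc)
  list(best_l2 = selectL2(means), mean_accuracy = means, accuracy = acc)
}

#' Ranked feature-weight table
#'
#' Features sorted by absolute weight, sign retained. Weight sign stems
#' from the feature encoding and is not biologically interpretable.
#'
#' @param model a \linkS4class{TrainedModel}
#' @param topK number of rows (full list when larger than the feature
#'   count)
#' @return data.frame with columns feature, weight, abs_weight
#' @export
featureWeightReport <- function(model, topK = Inf) {
  w <- modelWeights(model)
  ord <- order(abs(w), decreasing = TRUE)
  out <- data.frame(feature = names(w)[ord], weight = unname(w[ord]),
                    abs_weight = abs(unname(w[ord])),
                    stringsAsFactors = FALSE)
  head(out, min(topK, nrow(out)))
}
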