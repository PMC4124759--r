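# Learners for the evaluation grid. AdaBoost (depth-1 stumps) is implemented
# here; the two margin learners wrap libsvm (e1071, RBF kernel) and the
# SMO-type solver in kernlab (linear kernel).

#' AdaBoost with decision stumps
#'
#' Classical discrete AdaBoost: at each round the single-feature threshold
#' stump (either polarity) with the lowest weighted error is added, example
#' weights are re-exponentiated, and prediction is the sign of the
#' alpha-weighted stump vote. Works on binary and on continuous
#' (weighted-IPR) features alike.
#'
#' @param X Numeric feature matrix.
#' @param y Binary labels (0/1).
#' @param n_rounds Boosting rounds (default 50).
#' @return An `adaboost_stumps` model.
#' @export
fit_adaboost <- function(X, y, n_rounds = 50) {
  X <- as.matrix(X)
  yy <- ifelse(as.integer(y) == 1L, 1, -1)
  n <- length(yy)
  w <- rep(1 / n, n)
  stumps <- vector("list", n_rounds)
  alphas <- numeric(n_rounds)
  used <- 0L
  for (round in seq_len(n_rounds)) {
    st <- best_stump(X, yy, w)
    if (st$err >= 0.5 - 1e-10) break
    err <- max(st$err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    used <- used + 1L
    stumps[[used]] <- st
    alphas[used] <- alpha
    pred <- stump_predict(st, X)
    w <- w * exp(-alpha * yy * pred)
    w <- w / sum(w)
    if (st$err < 1e-10) break  # perfect stump; voting is decided
  }
  structure(list(
    stumps = stumps[seq_len(used)],
    alphas = alphas[seq_len(used)],
    majority = if (sum(yy) >= 0) 1 else -1
  ), class = "adaboost_stumps")
}

# Best single-feature threshold stump under example weights w.
# For each feature, sorting once gives the weighted error of every cut via
# cumulative sums; both polarities are scanned (err and 1 - err).
best_stump <- function(X, yy, w) {
  best <- list(err = Inf)
  w_neg_total <- sum(w[yy == -1])
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    o <- order(x)
    xo <- x[o]
    # cut after sorted position k: left half is x <= threshold
    cpos <- cumsum(w[o] * (yy[o] == 1))
    cneg <- cumsum(w[o] * (yy[o] == -1))
    valid <- which(xo[-length(xo)] < xo[-1])   # cuts between distinct values
    ks <- c(0L, valid)
    # rule A (polarity +1): predict +1 when x > threshold
    errA <- c(w_neg_total, cpos[valid] + (w_neg_total - cneg[valid]))
    errB <- 1 - errA                            # flipped polarity
    kA <- which.min(errA)
    kB <- which.min(errB)
    for (cand in list(c(errA[kA], ks[kA], 1), c(errB[kB], ks[kB], -1))) {
      if (cand[1] < best$err) {
        k <- cand[2]
        thr <- if (k == 0) xo[1] - 1 else (xo[k] + xo[k + 1]) / 2
        best <- list(err = cand[1], feature = j, threshold = thr,
                     polarity = cand[3])
      }
    }
  }
  best
}

stump_predict <- function(st, X) {
  st$polarity * ifelse(X[, st$feature] > st$threshold, 1, -1)
}

#' @export
predict.adaboost_stumps <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (length(object$alphas) == 0) {
    return(rep(as.integer(object$majority == 1), nrow(X)))
  }
  score <- numeric(nrow(X))
  for (k in seq_along(object$stumps)) {
    score <- score + object$alphas[k] * stump_predict(object$stumps[[k]], X)
  }
  as.integer(score >= 0)
}

# Unified fit/predict over the three grid learners. y is 0/1.
#
# The margin learners (RBF SVM, linear SMO) are fitted on per-column
# standardised features (training-fold mean/sd; zero-variance columns left
# untouched): the weighted-IPR encoding produces values whose scale shrinks
# with group size, and kernel machines at fixed C and gamma are not
# scale-invariant. AdaBoost stumps are threshold-based and unaffected.
fit_classifier <- function(learner, X, y, params = list()) {
  X <- as.matrix(X)
  if (ncol(X) == 0 || length(unique(y)) < 2) {
    maj <- structure(list(majority = as.integer(mean(y) >= 0.5)),
                     class = "majority_classifier")
    return(structure(list(model = maj, scaler = NULL),
                     class = "ipr2go_classifier"))
  }
  scaler <- NULL
  if (learner %in% c("svm", "smo")) {
    scaler <- list(mu = colMeans(X), sd = apply(X, 2, stats::sd))
    scaler$sd[!is.finite(scaler$sd) | scaler$sd < 1e-12] <- 1
    X <- scale_cols(X, scaler)
  }
  model <- switch(learner,
    adaboost = fit_adaboost(X, y, n_rounds = params$n_rounds %||% 50),
    svm = e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "radial",
                     cost = params$cost %||% 1, scale = FALSE),
    smo = kernlab::ksvm(X, factor(y, levels = c(0, 1)),
                        kernel = kernlab::vanilladot(),
                        C = params$cost %||% 1, scaled = FALSE),
    abort(sprintf("unknown learner '%s'", learner))
  )
  structure(list(model = model, scaler = scaler),
            class = "ipr2go_classifier")
}

scale_cols <- function(X, scaler) {
  sweep(sweep(X, 2, scaler$mu, "-"), 2, scaler$sd, "/")
}

predict_classifier <- function(fit, X) {
  X <- as.matrix(X)
  if (!is.null(fit$scaler)) X <- scale_cols(X, fit$scaler)
  model <- fit$model
  if (inherits(model, "majority_classifier")) {
    rep(model$majority, nrow(X))
  } else if (inherits(model, "adaboost_stumps")) {
    predict(model, X)
  } else if (inherits(model, "ksvm")) {
    as.integer(as.character(kernlab::predict(model, X)))
  } else {
    as.integer(as.character(predict(model, X)))
  }
}
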