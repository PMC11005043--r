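#' @include AllClasses.R model-bench.R
NULL

#' Permutation feature importance
#'
#' Importance of feature j = mean over repeats of
#' \code{metric(baseline) - metric(X with column j permuted)} for score-type
#' metrics (R2); for error-type metrics (RMSE, MAE) the sign is flipped so
#' larger remains more important.  Deterministic under \code{seed}; a
#' constant column has importance exactly 0 (permutation is a no-op).
#'
#' @param predictFun function(X) returning predictions (a fitted model bound
#'   into a closure), or a list with \code{learner} and \code{fit}.
#' @param X,y evaluation data.
#' @param metric \code{"r2"}, \code{"rmse"} or \code{"mae"}.
#' @param nRepeats permutations per feature (default 5).
#' @param seed integer seed.
#' @return data.frame (feature, importance, sd) sorted by importance.
#' @export
permutationImportance <- function(predictFun, X, y, metric = "r2",
                                  nRepeats = 5L, seed = 1L) {
  if (!metric %in% c("r2", "rmse", "mae")) stop("unknown metric: ", metric)
  if (is.list(predictFun) && !is.function(predictFun)) {
    lr <- predictFun$learner; ft <- predictFun$fit
    predictFun <- function(Z) lr$predict(ft, Z)
  }
  scoreOf <- function(pred) {
    m <- regressionMetrics(y, pred)
    switch(metric, r2 = m$r2, rmse = -m$rmse, mae = -m$mae)
  }
  base <- scoreOf(predictFun(X))
  p <- ncol(X)
  imp <- withSeed(seed, {
    vapply(seq_len(p), function(j) {
      if (length(unique(X[, j])) == 1L) return(c(0, 0))
      drops <- vapply(seq_len(nRepeats), function(r) {
        Z <- X
        Z[, j] <- X[sample(nrow(X)), j]
        base - scoreOf(predictFun(Z))
      }, 0)
      c(mean(drops), stats::sd(drops))
    }, numeric(2L))
  })
  out <- data.frame(feature = colnames(X) %||% paste0("f", seq_len(p)),
                    importance = imp[1L, ], sd = imp[2L, ],
                    stringsAsFactors = FALSE)
  out[order(-out$importance), ]
}

#' Gain and split-count rankings of a tree ensemble
#'
#' Extracts per-feature total gain and split counts from a fitted
#' gradient-boosted tree model; features the ensemble never used rank last
#' with zeros.
#'
#' @param fit a fitted \code{xgboost} booster.
#' @param featureNames all feature names (unused ones get zeros).
#' @return list with data.frames \code{gain} and \code{splits}, each sorted
#'   descending.
#' @export
treeImportances <- function(fit, featureNames) {
  if (!inherits(fit, "xgb.Booster")) stop("fit must be a fitted xgb.Booster")
  imp <- xgboost::xgb.importance(model = fit)
  gain <- structure(rep(0, length(featureNames)), names = featureNames)
  splits <- gain
  if (nrow(imp)) {
    gain[imp$Feature] <- imp$Gain
    splits[imp$Feature] <- imp$Frequency
  }
  list(gain = data.frame(feature = names(sort(gain, decreasing = TRUE)),
                         gain = sort(gain, decreasing = TRUE),
                         row.names = NULL, stringsAsFactors = FALSE),
       splits = data.frame(feature = names(sort(splits, decreasing = TRUE)),
                           splits = sort(splits, decreasing = TRUE),
                           row.names = NULL, stringsAsFactors = FALSE))
}

#' Exact Shapley values by coalition enumeration
#'
#' For models with at most \code{maxFeatures} features, computes exact
#' Shapley values with background-mean substitution: the value of a
#' coalition S is the mean prediction over background rows with the features
#' in S replaced by the instance's values.  Satisfies local accuracy: the
#' values sum to \code{f(instance) - mean(f(background))}.
#'
#' @param predictFun function(X) returning predictions.
#' @param instance single-row matrix (or numeric vector) to explain.
#' @param background background data matrix.
#' @param maxFeatures enumeration guard (default 12; beyond it, use the
#'   library-backed \code{\link{shapSummary}}).
#' @return named numeric vector of per-feature Shapley values.
#' @export
shapleyExactSmall <- function(predictFun, instance, background,
                              maxFeatures = 12L) {
  x <- if (is.matrix(instance)) instance[1L, ] else as.numeric(instance)
  B <- as.matrix(background)
  d <- ncol(B)
  if (d > maxFeatures)
    stop("more than ", maxFeatures,
         " features; use the library-backed SHAP path")
  nb <- nrow(B)
  ## coalition values: v[mask] = mean over background rows of f(x_S, z_-S)
  nMask <- 2^d
  bigX <- matrix(0, nMask * nb, d)
  for (mask in 0:(nMask - 1L)) {
    inS <- as.logical(bitwAnd(mask, bitwShiftL(1L, 0:(d - 1L))))
    Z <- B
    Z[, inS] <- matrix(x[inS], nb, sum(inS), byrow = TRUE)
    bigX[(mask * nb + 1L):((mask + 1L) * nb), ] <- Z
  }
  colnames(bigX) <- colnames(B)
  preds <- predictFun(bigX)
  v <- vapply(0:(nMask - 1L), function(mask)
    mean(preds[(mask * nb + 1L):((mask + 1L) * nb)]), 0)
  fact <- factorial(0:d)
  phi <- numeric(d)
  for (j in seq_len(d)) {
    bit <- bitwShiftL(1L, j - 1L)
    for (mask in 0:(nMask - 1L)) {
      if (bitwAnd(mask, bit) != 0L) next
      s <- sum(as.logical(bitwAnd(mask, bitwShiftL(1L, 0:(d - 1L)))))
      w <- fact[s + 1L] * fact[d - s] / fact[d + 1L]
      phi[j] <- phi[j] + w * (v[mask + bit + 1L] - v[mask + 1L])
    }
  }
  names(phi) <- colnames(B)
  phi
}

#' Label predictions by residual-tail thresholds
#'
#' Residuals \code{r = yhat - y} are thresholded at their empirical 5\% and
#' 95\% quantiles (linear interpolation, type 7): below the lower threshold
#' \code{poor_low}, above the upper \code{poor_high}, otherwise \code{ok}.
#'
#' @param yTrue,yPred equal-length vectors, n >= 20.
#' @param lowerQ,upperQ quantile levels (defaults 0.05 / 0.95).
#' @return list with \code{labels} (factor), \code{residuals},
#'   \code{lower}, \code{upper}.
#' @export
errorThresholdLabels <- function(yTrue, yPred, lowerQ = 0.05,
                                 upperQ = 0.95) {
  n <- length(yTrue)
  if (n < 20L || length(yPred) != n) stop("need equal lengths >= 20")
  r <- yPred - yTrue
  lo <- quantile(r, lowerQ, type = 7, names = FALSE)
  hi <- quantile(r, upperQ, type = 7, names = FALSE)
  lab <- ifelse(r < lo, "poor_low", ifelse(r > hi, "poor_high", "ok"))
  list(labels = factor(lab, c("poor_low", "ok", "poor_high")),
       residuals = r, lower = lo, upper = hi)
}

## Upper-tail hypergeometric probability P(X >= k) for X ~ Hyper(N, K, s),
## summed from log-gamma binomial coefficients.
hyperTailP <- function(k, s, K, N) {
  lchoose2 <- function(n, r) lgamma(n + 1) - lgamma(r + 1) - lgamma(n - r + 1)
  hi <- min(s, K)
  lo <- max(k, s - (N - K))
  if (lo > hi) return(if (k <= 0) 1 else 0)
  sum(exp(lchoose2(K, lo:hi) + lchoose2(N - K, s - (lo:hi)) -
            lchoose2(N, s)))
}

#' Hypergeometric error-enrichment test
#'
#' Tests whether flagged cases (e.g. variants with >= 5 co-occurring
#' mutations) are over-represented among the poor predictions: with
#' \code{s} poor predictions, \code{k} of them flagged, \code{K} flagged in
#' the population of \code{N}, the one-sided upper p-value is
#' \code{P(X >= k)} under Hypergeometric(N, K, s) and the enrichment fold is
#' \code{(k/s) / (K/N)}.
#'
#' @param labels factor from \code{\link{errorThresholdLabels}} (anything
#'   other than \code{"ok"} counts as poor), or a logical poor indicator.
#' @param flags logical flag per case.
#' @return list with \code{k}, \code{s}, \code{K}, \code{N}, \code{fold},
#'   \code{pValue}.  With s = 0 the p-value is 1 and the fold NaN.
#' @export
hypergeometricEnrichment <- function(labels, flags) {
  poor <- if (is.logical(labels)) labels else labels != "ok"
  if (length(poor) != length(flags)) stop("length mismatch")
  N <- length(poor); s <- sum(poor); K <- sum(flags)
  k <- sum(poor & flags)
  fold <- if (s > 0 && K > 0) (k / s) / (K / N) else NaN
  p <- if (s == 0) 1 else hyperTailP(k, s, K, N)
  list(k = k, s = s, K = K, N = N, fold = fold, pValue = p)
}

#' Flag variants by mutation count
#'
#' @param variants list of \linkS4class{VariantRecord}.
#' @param minMutations flag threshold (default 5).
#' @return logical vector: TRUE when a variant carries at least
#'   \code{minMutations} substitutions.
#' @export
mutationCountFlags <- function(variants, minMutations = 5L) {
  vapply(variants, function(v) nrow(v@mutations) >= minMutations, NA)
}

#' SHAP summary for a gradient-boosted tree model (library-backed)
#'
#' Per-instance per-feature SHAP attributions from the booster's TreeSHAP
#' implementation, the mean-|SHAP| feature ranking, and (optionally) the
#' interaction-strength ranking for one named feature.
#'
#' @param fit a fitted \code{xgb.Booster}.
#' @param X data matrix to explain.
#' @param interactionFeature optional feature name for which pairwise
#'   interaction strengths are ranked (uses SHAP interaction values; costly
#'   for large models).
#' @return list with \code{values} (n x p attribution matrix),
#'   \code{ranking} (data.frame feature / meanAbsShap), \code{baseValue},
#'   and optionally \code{interactions}.
#' @export
shapSummary <- function(fit, X, interactionFeature = NULL) {
  if (!inherits(fit, "xgb.Booster"))
    stop("SHAP path requires a tree model; use permutation importance")
  contrib <- predict(fit, X, predcontrib = TRUE)
  biasCol <- intersect(c("BIAS", "(Intercept)"), colnames(contrib))[1L]
  base <- contrib[, biasCol]
  vals <- contrib[, setdiff(colnames(contrib), biasCol), drop = FALSE]
  rank <- data.frame(feature = colnames(vals),
                     meanAbsShap = colMeans(abs(vals)),
                     row.names = NULL, stringsAsFactors = FALSE)
  rank <- rank[order(-rank$meanAbsShap), ]
  out <- list(values = vals, ranking = rank, baseValue = base)
  if (!is.null(interactionFeature)) {
    if (!interactionFeature %in% colnames(vals))
      stop("unknown feature: ", interactionFeature)
    inter <- predict(fit, X, predinteraction = TRUE)
    ## inter: n x (p+1) x (p+1); strength = mean |interaction| with others
    sl <- inter[, interactionFeature,
                setdiff(colnames(vals), interactionFeature), drop = FALSE]
    strength <- apply(abs(sl), 3L, mean)
    ord <- order(-strength)
    out$interactions <- data.frame(
      feature = dimnames(sl)[[3L]][ord], strength = strength[ord],
      row.names = NULL, stringsAsFactors = FALSE)
  }
  out
}
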