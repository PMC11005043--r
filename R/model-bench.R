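#' @include AllClasses.R dataset-assembly.R
#' @importFrom stats aov TukeyHSD glm lm predict qnorm ppoints rnorm sd
NULL

#' Regression metrics
#'
#' \code{RMSE = sqrt(mean((yhat - y)^2))},
#' \code{R2 = 1 - sum((yhat - y)^2) / sum((y - mean(y))^2)},
#' \code{MAE = mean(|yhat - y|)}.  A zero-variance truth makes R2 undefined
#' (returned as NaN with \code{r2Defined = FALSE}).
#'
#' @param yTrue,yPred equal-length numeric vectors.
#' @return list with \code{r2}, \code{rmse}, \code{mae}, \code{r2Defined}.
#' @export
regressionMetrics <- function(yTrue, yPred) {
  n <- length(yTrue)
  if (n == 0L || length(yPred) != n)
    stop("yTrue and yPred must have equal nonzero length")
  res <- yPred - yTrue
  sstot <- sum((yTrue - mean(yTrue))^2)
  defined <- sstot > 1e-300
  list(r2 = if (defined) 1 - sum(res^2) / sstot else NaN,
       rmse = sqrt(mean(res^2)), mae = mean(abs(res)),
       r2Defined = defined)
}

#' Response-distribution diagnostics
#'
#' Fisher-Pearson moment skewness and excess kurtosis, normal Q-Q points,
#' and domain checks for count/positive-response models: Poisson requires a
#' non-negative response (non-integer values are flagged), Gamma a strictly
#' positive one.
#'
#' @param y numeric response, length >= 8.
#' @return list with \code{skewness}, \code{kurtosis}, \code{qq}
#'   (data.frame of theoretical and sample quantiles), \code{poissonOk},
#'   \code{gammaOk}, \code{integerValued}.
#' @export
responseDistributionCheck <- function(y) {
  if (length(y) < 8L) stop("need n >= 8")
  list(skewness = momentSkewness(y), kurtosis = momentKurtosis(y),
       qq = data.frame(theoretical = qnorm(ppoints(length(y))),
                       sample = sort(y)),
       poissonOk = all(y >= 0),
       gammaOk = all(y > 0),
       integerValued = all(abs(y - round(y)) < 1e-8))
}

## ---- learner roster -----------------------------------------------------

uniformInt <- function(lo, hi) function() sample(lo:hi, 1L)
uniformReal <- function(lo, hi) function() stats::runif(1L, lo, hi)
logReal <- function(lo, hi) function() exp(stats::runif(1L, log(lo), log(hi)))

#' The default learner roster
#'
#' Library-backed regressors covering the linear, kernel, tree, ensemble,
#' neighbourless-neural and GLM families, each exposing \code{fit} /
#' \code{predict} closures, a \code{needs} domain requirement for the
#' response (\code{"none"}, \code{"nonnegative"} or \code{"positive"}) and,
#' where tuned, a random-search space.  The headline model is the
#' gradient-boosted tree ensemble (\code{"gbt"}).
#'
#' @param seed integer seed passed to stochastic learners.
#' @return named list of learner definitions.
#' @export
learnerRoster <- function(seed = 1L) {
  list(
    dummy_mean = list(
      family = "baseline", needs = "none",
      fit = function(X, y, params = list()) list(mu = mean(y)),
      predict = function(fit, X) rep(fit$mu, nrow(X))),
    linear = list(
      family = "linear", needs = "none",
      fit = function(X, y, params = list()) {
        f <- stats::lm.fit(cbind(1, X), y)
        cf <- f$coefficients; cf[is.na(cf)] <- 0
        list(coef = cf)
      },
      predict = function(fit, X) as.numeric(cbind(1, X) %*% fit$coef)),
    ridge = list(
      family = "linear", needs = "none",
      fit = function(X, y, params = list(lambda = 1)) {
        glmnet::glmnet(X, y, alpha = 0, lambda = params$lambda %||% 1)
      },
      predict = function(fit, X) as.numeric(predict(fit, X))),
    lasso = list(
      family = "linear", needs = "none",
      fit = function(X, y, params = list(lambda = 0.01)) {
        glmnet::glmnet(X, y, alpha = 1, lambda = params$lambda %||% 0.01)
      },
      predict = function(fit, X) as.numeric(predict(fit, X))),
    svm_radial = list(
      family = "kernel", needs = "none",
      fit = function(X, y, params = list())
        e1071::svm(X, y, kernel = "radial",
                   cost = params$cost %||% 1,
                   gamma = params$gamma %||% (1 / ncol(X))),
      predict = function(fit, X) as.numeric(predict(fit, X))),
    cart = list(
      family = "tree", needs = "none",
      fit = function(X, y, params = list()) {
        df <- as.data.frame(X); names(df) <- paste0("f", seq_len(ncol(X)))
        df$.y <- y
        rpart::rpart(.y ~ ., df,
                     control = rpart::rpart.control(
                       cp = params$cp %||% 0.01,
                       minsplit = params$minsplit %||% 20))
      },
      predict = function(fit, X) {
        df <- as.data.frame(X); names(df) <- paste0("f", seq_len(ncol(X)))
        as.numeric(predict(fit, df))
      }),
    random_forest = list(
      family = "ensemble", needs = "none",
      fit = function(X, y, params = list()) {
        df <- as.data.frame(X); names(df) <- paste0("f", seq_len(ncol(X)))
        df$.y <- y
        ranger::ranger(.y ~ ., df,
                       num.trees = params$num.trees %||% 300,
                       mtry = params$mtry %||% max(1L,
                                                   floor(ncol(X) / 3)),
                       seed = seed, num.threads = 1L)
      },
      predict = function(fit, X) {
        df <- as.data.frame(X); names(df) <- paste0("f", seq_len(ncol(X)))
        predict(fit, df, num.threads = 1L)$predictions
      }),
    gbt = list(
      family = "ensemble", needs = "none",
      fit = function(X, y, params = list()) {
        p <- params
        dm <- xgboost::xgb.DMatrix(X, label = y, nthread = 1L)
        xgboost::xgb.train(
          data = dm, nrounds = p$nrounds %||% 150L, verbose = 0,
          params = list(max_depth = p$max_depth %||% 4L,
                        eta = p$eta %||% 0.1,
                        subsample = p$subsample %||% 1,
                        colsample_bytree = p$colsample_bytree %||% 1,
                        min_child_weight = p$min_child_weight %||% 1,
                        nthread = 1L, seed = seed,
                        objective = "reg:squarederror"))
      },
      predict = function(fit, X) as.numeric(predict(fit, X)),
      searchSpace = list(nrounds = uniformInt(50L, 300L),
                         max_depth = uniformInt(2L, 6L),
                         eta = logReal(0.02, 0.3),
                         subsample = uniformReal(0.6, 1),
                         colsample_bytree = uniformReal(0.5, 1),
                         min_child_weight = uniformInt(1L, 10L))),
    mlp = list(
      family = "neural", needs = "none",
      fit = function(X, y, params = list()) {
        withSeed(seed, nnet::nnet(X, y, size = params$size %||% 5L,
                                  linout = TRUE, trace = FALSE,
                                  decay = params$decay %||% 0.01,
                                  maxit = params$maxit %||% 200L,
                                  MaxNWts = 100000L))
      },
      predict = function(fit, X) as.numeric(predict(fit, X))),
    poisson_glm = list(
      family = "glm", needs = "nonnegative",
      fit = function(X, y, params = list()) {
        df <- as.data.frame(X); names(df) <- paste0("f", seq_len(ncol(X)))
        df$.y <- y
        suppressWarnings(glm(.y ~ ., df, family = stats::poisson()))
      },
      predict = function(fit, X) {
        df <- as.data.frame(X); names(df) <- paste0("f", seq_len(ncol(X)))
        as.numeric(predict(fit, df, type = "response"))
      }),
    gamma_glm = list(
      family = "glm", needs = "positive",
      fit = function(X, y, params = list()) {
        df <- as.data.frame(X); names(df) <- paste0("f", seq_len(ncol(X)))
        df$.y <- y
        suppressWarnings(glm(.y ~ ., df, family = stats::Gamma(link = "log")))
      },
      predict = function(fit, X) {
        df <- as.data.frame(X); names(df) <- paste0("f", seq_len(ncol(X)))
        as.numeric(predict(fit, df, type = "response"))
      }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Screen a learner roster with default parameters
#'
#' Fits every roster entry on the training set with its defaults, scores it
#' on the test set, and excludes models whose test R2 is negative (they fit
#' worse than a horizontal line) or whose response-domain requirement the
#' response violates (distribution mismatch).  Survivors are ranked by R2
#' (descending), ties by RMSE then fit time.  A learner whose fit fails is
#' recorded as excluded, never aborts the screen.
#'
#' @param XTrain,yTrain,XTest,yTest split data (matrices / vectors).
#' @param roster learner roster (default \code{\link{learnerRoster}}).
#' @return data.frame with one row per learner: metrics, seconds,
#'   \code{excluded} and \code{reason} (\code{negative_r2},
#'   \code{distribution_mismatch}, \code{fit_error} or \code{none}),
#'   ranked with survivors first.
#' @export
screenModels <- function(XTrain, yTrain, XTest, yTest,
                         roster = learnerRoster()) {
  if (!length(roster)) stop("empty roster")
  dist <- responseDistributionCheck(yTrain)
  rows <- lapply(names(roster), function(nm) {
    lr <- roster[[nm]]
    out <- data.frame(model = nm, r2 = NA_real_, rmse = NA_real_,
                      mae = NA_real_, seconds = NA_real_, excluded = TRUE,
                      reason = "none", stringsAsFactors = FALSE)
    if ((identical(lr$needs, "nonnegative") && !dist$poissonOk) ||
        (identical(lr$needs, "positive") && !dist$gammaOk)) {
      out$reason <- "distribution_mismatch"
      return(out)
    }
    fit <- tryCatch({
      tm <- system.time(f <- lr$fit(XTrain, yTrain))
      list(f = f, s = unname(tm["elapsed"]))
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      out$reason <- "fit_error"
      return(out)
    }
    pred <- tryCatch(lr$predict(fit$f, XTest), error = function(e) e)
    if (inherits(pred, "error") || !all(is.finite(pred))) {
      out$reason <- "fit_error"
      return(out)
    }
    m <- regressionMetrics(yTest, pred)
    out$r2 <- m$r2; out$rmse <- m$rmse; out$mae <- m$mae
    out$seconds <- fit$s
    if (is.finite(m$r2) && m$r2 < 0) {
      out$reason <- "negative_r2"
    } else {
      out$excluded <- FALSE
    }
    out
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$excluded, -ifelse(is.na(res$r2), -Inf, res$r2),
                   res$rmse, res$seconds), ]
  rownames(res) <- NULL
  res
}

#' Random hyperparameter search with k-fold CV
#'
#' Draws \code{nIter} random parameter sets from the learner's search space
#' and scores each by the mean negative MAE over \code{folds}-fold CV on the
#' training set; the best-scoring draw wins.  Deterministic under
#' \code{seed}; invalid parameter draws are skipped and logged.
#'
#' @param learner a roster entry with a \code{searchSpace}.
#' @param X,y training data.
#' @param nIter number of random draws (default 20).
#' @param folds CV folds (default 5).
#' @param seed integer seed.
#' @param searchSpace optional space overriding the learner's own.
#' @return list with \code{best} (parameter list), \code{score} (mean
#'   negative MAE), and \code{trace} data.frame.
#' @export
tuneRandomSearch <- function(learner, X, y, nIter = 20L, folds = 5L,
                             seed = 1L, searchSpace = NULL) {
  space <- searchSpace %||% learner$searchSpace
  if (is.null(space) || !length(space)) stop("empty search space")
  n <- nrow(X)
  withSeed(seed, {
    foldId <- sample(rep(seq_len(folds), length.out = n))
    draws <- lapply(seq_len(nIter), function(i)
      lapply(space, function(s) if (is.function(s)) s()
             else if (length(s) == 1L) s else sample(s, 1L)))
    scores <- vapply(draws, function(p) {
      maes <- tryCatch(vapply(seq_len(folds), function(f) {
        tr <- foldId != f
        fit <- learner$fit(X[tr, , drop = FALSE], y[tr], params = p)
        pred <- learner$predict(fit, X[!tr, , drop = FALSE])
        mean(abs(pred - y[!tr]))
      }, 0), error = function(e) NA_real_)
      if (anyNA(maes)) NA_real_ else -mean(maes)
    }, 0)
    if (all(is.na(scores))) stop("all hyperparameter draws failed")
    best <- which.max(scores)
    list(best = draws[[best]], score = scores[best],
         trace = data.frame(iter = seq_len(nIter), negMae = scores))
  })
}

#' Bootstrap comparison of feature-block datasets
#'
#' For each dataset: per iteration, the training rows are resampled with
#' replacement (same size), the model is refit with that dataset's tuned
#' hyperparameters, and R2/RMSE/MAE are recorded on the fixed test set.
#' A failed fit is retried on the next seed substream (up to 3 times).
#'
#' @param datasets named list of \linkS4class{FeatureTable}s (e.g. from
#'   \code{\link{blockSubsets}}), all sharing the same variants.
#' @param params named list (per dataset) of tuned parameter lists.
#' @param split shared train/test split from \code{\link{trainTestSplit}}.
#' @param learner roster entry to fit (default the gradient-boosted tree).
#' @param nBoot bootstrap iterations (default 500).
#' @param seed integer seed.
#' @return named list of nBoot x 3 matrices (columns r2, rmse, mae).
#' @export
bootstrapCompare <- function(datasets, params, split,
                             learner = learnerRoster()$gbt, nBoot = 500L,
                             seed = 1L) {
  stopifnot(length(datasets) >= 1L)
  out <- lapply(seq_along(datasets), function(d) {
    tab <- datasets[[d]]
    X <- featureMatrix(tab); y <- responseFCA(tab)
    sc <- minmaxScale(X, fitRows = split$train)
    Xs <- sc$scaled
    Xtr <- Xs[split$train, , drop = FALSE]; ytr <- y[split$train]
    Xte <- Xs[split$test, , drop = FALSE]; yte <- y[split$test]
    p <- params[[d]] %||% list()
    m <- matrix(NA_real_, nBoot, 3L,
                dimnames = list(NULL, c("r2", "rmse", "mae")))
    for (b in seq_len(nBoot)) {
      for (attempt in 0:2) {
        idx <- withSeed(childSeed(childSeed(seed, d), b * 4L + attempt),
                        sample(nrow(Xtr), nrow(Xtr), replace = TRUE))
        fit <- tryCatch(
          learner$fit(Xtr[idx, , drop = FALSE], ytr[idx], params = p),
          error = function(e) NULL)
        if (!is.null(fit)) {
          met <- regressionMetrics(yte, learner$predict(fit, Xte))
          m[b, ] <- c(met$r2, met$rmse, met$mae)
          break
        }
      }
    }
    if (anyNA(m)) stop("bootstrap iteration failed repeatedly")
    m
  })
  names(out) <- names(datasets)
  out
}

#' One-way ANOVA plus Tukey HSD across datasets
#'
#' Classical one-way ANOVA over equally sized groups followed by Tukey's
#' honestly-significant-difference pairwise comparisons (studentized range).
#'
#' @param groups named list of equal-length numeric vectors (e.g. bootstrap
#'   R2 distributions per dataset).
#' @param alpha family-wise significance level (default 0.05).
#' @return list with \code{anovaP} and \code{tukey} (data.frame: pair, diff,
#'   lwr, upr, pAdj, significant).
#' @export
anovaTukey <- function(groups, alpha = 0.05) {
  if (length(groups) < 2L) stop("need >= 2 groups")
  if (length(unique(lengths(groups))) != 1L)
    stop("groups must have equal sizes")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(y = unlist(groups),
                   g = factor(rep(names(groups), lengths(groups)),
                              levels = names(groups)))
  fit <- aov(y ~ g, df)
  p <- summary(fit)[[1]][["Pr(>F)"]][1L]
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$g
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      pAdj = tk[, "p adj"],
                      significant = tk[, "p adj"] < alpha,
                      row.names = NULL, stringsAsFactors = FALSE)
  list(anovaP = p, tukey = tukey)
}
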