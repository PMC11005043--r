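test_that("permutation importance isolates the informative feature", {
  set.seed(51)
  n <- 200L
  X <- cbind(x1 = runif(n), x2 = runif(n), const = rep(1, n))
  y <- 2 * X[, "x1"]
  ## oracle model: an exact function of feature 1 only
  predictFun <- function(Z) 2 * Z[, "x1"]
  pi <- permutationImportance(predictFun, X, y, metric = "r2",
                              nRepeats = 5L, seed = 1L)
  expect_equal(pi$feature[1], "x1")
  expect_gt(pi$importance[pi$feature == "x1"], 0.5)
  expect_equal(pi$importance[pi$feature == "x2"], 0, tolerance = 1e-10)
  ## constant columns have importance exactly 0
  expect_equal(pi$importance[pi$feature == "const"], 0)
  ## deterministic under seed
  pi2 <- permutationImportance(predictFun, X, y, nRepeats = 5L, seed = 1L)
  expect_equal(pi, pi2)
  expect_error(permutationImportance(predictFun, X, y, metric = "auc"),
               "unknown metric")
})

test_that("duplicated features split importance", {
  set.seed(52)
  n <- 300L
  x <- runif(n)
  ## model averages the two identical copies
  Xdup <- cbind(a = x, b = x)
  predDup <- function(Z) (Z[, "a"] + Z[, "b"]) / 2
  y <- x
  impDup <- permutationImportance(predDup, Xdup, y, seed = 2L)
  Xsolo <- cbind(a = x, b = runif(n))
  predSolo <- function(Z) Z[, "a"]
  impSolo <- permutationImportance(predSolo, Xsolo, y, seed = 2L)
  soloA <- impSolo$importance[impSolo$feature == "a"]
  expect_lte(impDup$importance[impDup$feature == "a"], soloA)
  expect_lte(impDup$importance[impDup$feature == "b"], soloA)
})

fitStumpModel <- function(X, y, nrounds = 1L, seed = 1L) {
  dm <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  xgboost::xgb.train(data = dm, nrounds = nrounds, verbose = 0,
                     params = list(max_depth = 1L, eta = 1,
                                   base_score = 0.5, nthread = 1L,
                                   seed = seed,
                                   objective = "reg:squarederror"))
}

test_that("tree importances rank gain and split counts with zeros", {
  set.seed(53)
  n <- 200L
  X <- matrix(runif(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- ifelse(X[, 3] > 0.5, 2, -2)
  fit <- fitStumpModel(X, y)
  ti <- treeImportances(fit, colnames(X))
  expect_equal(nrow(ti$gain), 4L)
  expect_equal(nrow(ti$splits), 4L)
  expect_equal(ti$gain$feature[1], "f3")
  expect_equal(ti$splits$feature[1], "f3")
  expect_equal(sum(ti$gain$gain > 0), 1L)
  expect_equal(sum(ti$splits$splits > 0), 1L)
  expect_error(treeImportances(lm(y ~ X), colnames(X)), "xgb.Booster")
})

test_that("exact Shapley values satisfy the additive closed form", {
  set.seed(54)
  B <- matrix(runif(40), 20, 2, dimnames = list(NULL, c("x1", "x2")))
  f <- function(Z) Z[, 1] + 2 * Z[, 2]
  x <- c(x1 = 0.9, x2 = 0.1)
  phi <- shapleyExactSmall(f, x, B)
  ## additive model: phi_j = coefficient * (x_j - mean(background_j))
  expect_equal(phi[["x1"]], 0.9 - mean(B[, 1]), tolerance = 1e-10)
  expect_equal(phi[["x2"]], 2 * (0.1 - mean(B[, 2])), tolerance = 1e-10)
})

test_that("Shapley symmetry and local accuracy hold", {
  set.seed(55)
  B <- matrix(runif(60), 20, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  ## symmetry needs exchangeability in the model AND the background
  B[, "b"] <- B[, "a"]
  f <- function(Z) Z[, "a"] * Z[, "b"] + Z[, "a"] + Z[, "b"] + 3 * Z[, "c"]
  x <- c(a = 0.7, b = 0.7, c = 0.2)
  phi <- shapleyExactSmall(f, x, B)
  expect_equal(phi[["a"]], phi[["b"]], tolerance = 1e-10)
  ## local accuracy to 1e-10
  expect_equal(sum(phi),
               unname(f(matrix(x, 1, dimnames = list(NULL, names(x)))) -
                        mean(f(B))), tolerance = 1e-10)
  ## dimension guard
  B13 <- matrix(runif(26), 2, 13,
                dimnames = list(NULL, paste0("f", 1:13)))
  expect_error(shapleyExactSmall(f, rep(0, 13), B13), "12")
})

test_that("residual-tail labels follow type-7 quantile thresholds", {
  yTrue <- rep(0, 100)
  yPred <- 1:100   # residuals 1..100
  lab <- errorThresholdLabels(yTrue, yPred)
  lo <- quantile(1:100, 0.05, type = 7, names = FALSE)  # 5.95
  hi <- quantile(1:100, 0.95, type = 7, names = FALSE)  # 95.05
  expect_equal(sum(lab$labels == "poor_low"), sum(1:100 < lo))
  expect_equal(sum(lab$labels == "poor_high"), sum(1:100 > hi))
  expect_equal(sum(table(lab$labels)), 100)
  expect_equal(lab$lower, lo)
  expect_equal(lab$upper, hi)
  ## identical residuals: thresholds coincide, no poor labels
  same <- errorThresholdLabels(rep(0, 30), rep(1, 30))
  expect_equal(sum(same$labels != "ok"), 0L)
  expect_error(errorThresholdLabels(rep(0, 10), rep(0, 10)), ">= 20")
})

test_that("hypergeometric enrichment matches closed forms", {
  ## everything flagged: k = s, p = 1
  res <- hypergeometricEnrichment(c(rep(TRUE, 4), rep(FALSE, 6)),
                                  rep(TRUE, 10))
  expect_equal(res$k, res$s)
  expect_equal(res$pValue, 1)
  expect_equal(res$fold, 1)
  ## N=10, K=5, s=4, k=4: p = C(5,4) / C(10,4) = 5/210
  poor <- c(rep(TRUE, 4), rep(FALSE, 6))
  flags <- c(rep(TRUE, 4), TRUE, rep(FALSE, 5))
  res2 <- hypergeometricEnrichment(poor, flags)
  expect_equal(res2$pValue, 5 / 210, tolerance = 1e-12)
  expect_equal(res2$fold, (4 / 4) / (5 / 10))
  ## no poor predictions: p = 1, fold undefined
  res3 <- hypergeometricEnrichment(rep(FALSE, 10), flags)
  expect_equal(res3$pValue, 1)
  expect_true(is.nan(res3$fold))
})

test_that("the hypergeometric tail matches enumeration and phyper", {
  enumTail <- function(k, s, K, N) {
    ## exhaustive enumeration over all C(N, s) draws
    draws <- combn(N, s)
    mean(apply(draws, 2, function(d) sum(d <= K) >= k))
  }
  set.seed(56)
  for (i in 1:30) {
    N <- sample(4:12, 1)
    K <- sample(0:N, 1)
    s <- sample(1:N, 1)
    k <- sample(0:min(s, K), 1)
    poor <- seq_len(N) <= s          # arbitrary labelling with the counts
    got <- fcaflow:::hyperTailP(k, s, K, N)
    expect_equal(got, enumTail(k, s, K, N), tolerance = 1e-12)
    expect_equal(got, phyper(k - 1, K, N - K, s, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("mutation-count flags use the >= 5 co-occurrence rule", {
  tpl <- paste(rep("A", 200), collapse = "")
  mkv <- function(str) {
    mut <- parseMutations(str)
    new("VariantRecord", id = str, mutations = mut,
        sequence = applyMutations(tpl, mut), fca = 0)
  }
  vs <- list(mkv(""), mkv("A5G"),
             mkv("A5G/A10C/A15D/A20E/A25F"),
             mkv("A5G/A10C/A15D/A20E/A25F/A30H"))
  expect_equal(mutationCountFlags(vs), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(mutationCountFlags(vs, minMutations = 6L),
               c(FALSE, FALSE, FALSE, TRUE))
})

test_that("library SHAP agrees with the exact oracle on small models", {
  set.seed(57)
  n <- 400L
  X <- matrix(runif(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- ifelse(X[, 1] > 0.5, 1, -1) + 0.5 * ifelse(X[, 3] > 0.3, 1, -1)
  fit <- fitStumpModel(X, y, nrounds = 8L)
  sh <- shapSummary(fit, X[1:25, ])
  expect_equal(dim(sh$values), c(25L, 5L))
  predictFun <- function(Z) predict(fit, Z)
  for (i in 1:3) {
    phi <- shapleyExactSmall(predictFun, X[i, ], X)
    expect_equal(unname(sh$values[i, ]), unname(phi), tolerance = 1e-6)
  }
  ## constant model: all attributions zero
  cfit <- fitStumpModel(X, rep(2, n), nrounds = 3L)
  shc <- shapSummary(cfit, X[1:10, ])
  expect_equal(max(abs(shc$values)), 0, tolerance = 1e-10)
  ## stump on one feature: only that feature carries attribution
  y1 <- ifelse(X[, 2] > 0.6, 3, 0)
  fit1 <- fitStumpModel(X, y1, nrounds = 1L)
  sh1 <- shapSummary(fit1, X[1:10, ])
  nonzero <- colSums(abs(sh1$values)) > 1e-10
  expect_equal(names(which(nonzero)), "f2")
  expect_error(shapSummary(lm(y ~ X), X), "tree model")
})

test_that("SHAP interaction strengths rank a named feature's partners", {
  set.seed(58)
  n <- 300L
  X <- matrix(runif(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- 2 * (X[, 1] > 0.5) * (X[, 2] > 0.5) + 0.2 * X[, 4]
  dm <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  fit <- xgboost::xgb.train(data = dm, nrounds = 30L, verbose = 0,
                            params = list(max_depth = 2L, eta = 0.3,
                                          nthread = 1L, seed = 1L,
                                          objective = "reg:squarederror"))
  sh <- shapSummary(fit, X[1:50, ], interactionFeature = "f1")
  expect_equal(sh$interactions$feature[1], "f2")
  expect_error(shapSummary(fit, X[1:5, ], interactionFeature = "zzz"),
               "unknown feature")
})
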