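#' @include AllClasses.R io-formats.R
NULL

#' Construct a FeatureTable
#'
#' @param values variants x features numeric matrix.
#' @param ids variant ids (one per row of \code{values}).
#' @param block per-feature block tags (\code{SEQ}/\code{MD}/\code{POCKET}).
#' @param aggregation per-feature aggregation tags
#'   (\code{mean}/\code{std}/\code{na}).
#' @param featureNames feature names (default: column names of
#'   \code{values}).
#' @param fca response vector (default NA).
#' @return a \linkS4class{FeatureTable}.
#' @export
featureTable <- function(values, ids, block, aggregation = NULL,
                         featureNames = colnames(values),
                         fca = rep(NA_real_, length(ids))) {
  values <- as.matrix(values)
  if (is.null(aggregation))
    aggregation <- ifelse(grepl("_mean$", featureNames), "mean",
                          ifelse(grepl("_std$", featureNames), "std", "na"))
  if (anyDuplicated(featureNames))
    stop("duplicate feature name(s): ",
         paste(unique(featureNames[duplicated(featureNames)]),
               collapse = ", "))
  if (anyDuplicated(ids))
    stop("duplicate variant id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyNA(values)) stop("assembled feature values must not be missing")
  se <- SummarizedExperiment(
    assays = list(features = t(values)),
    rowData = DataFrame(block = block, aggregation = aggregation,
                        row.names = featureNames),
    colData = DataFrame(fca = as.numeric(fca), row.names = ids))
  new("FeatureTable", se)
}

#' Aggregate per-replicate feature values
#'
#' Mean over replicate values and the population SD (ddof = 0) over
#' replicate values, per feature.  With a single replicate the SD is 0.
#'
#' @param perReplicate replicates x features numeric matrix (consistent
#'   column names across replicates).
#' @return list with \code{mean} and \code{std} named vectors.
#' @export
aggregateReplicates <- function(perReplicate) {
  m <- as.matrix(perReplicate)
  if (nrow(m) < 1L) stop("need >= 1 replicate")
  list(mean = colMeans(m), std = apply(m, 2L, sdPop))
}

#' Assemble the full biodescriptor table
#'
#' Concatenates the sequence, MD and pocket blocks (column order SEQ, MD,
#' POCKET; 80 + 32 + 80 = 192 columns under the default featurization) and
#' attaches the response.  Blocks may be NULL to assemble partial tables.
#'
#' @param seqBlock,mdBlock,pocketBlock variants x features matrices with
#'   identical rownames (variant ids); NULL blocks are skipped.
#' @param fca response vector.
#' @return a \linkS4class{FeatureTable}.
#' @export
assembleFeatureTable <- function(seqBlock = NULL, mdBlock = NULL,
                                 pocketBlock = NULL, fca = NULL) {
  blocks <- list(SEQ = seqBlock, MD = mdBlock, POCKET = pocketBlock)
  blocks <- blocks[!vapply(blocks, is.null, NA)]
  if (!length(blocks)) stop("no blocks supplied")
  ids <- rownames(blocks[[1L]])
  if (is.null(ids)) stop("blocks must carry variant ids as rownames")
  for (b in names(blocks)) {
    off <- setdiff(rownames(blocks[[b]]), ids)
    if (!setequal(rownames(blocks[[b]]), ids))
      stop("variant ids differ across blocks (", b, "): ",
           paste(union(off, setdiff(ids, rownames(blocks[[b]]))),
                 collapse = ", "))
    blocks[[b]] <- as.matrix(blocks[[b]])[ids, , drop = FALSE]
  }
  values <- do.call(cbind, unname(blocks))
  tags <- rep(names(blocks), vapply(blocks, ncol, 1L))
  if (is.null(fca)) fca <- rep(NA_real_, length(ids))
  featureTable(values, ids = ids, block = tags, fca = fca)
}

#' Min-max rescaling with train-only fitting
#'
#' \code{x' = (x - min) / (max - min)} with the extrema taken from
#' \code{fitRows} only; constant columns map to 0; values outside the fitted
#' range scale beyond [0, 1] without clipping.
#'
#' @param values variants x features matrix (or
#'   \linkS4class{FeatureTable}).
#' @param fitRows row indices (or ids) used to fit the scaler; default all
#'   rows.
#' @return list with \code{scaled} matrix and scaler parameters \code{min},
#'   \code{range}.
#' @export
minmaxScale <- function(values, fitRows = NULL) {
  m <- if (is(values, "FeatureTable")) featureMatrix(values)
       else as.matrix(values)
  if (is.null(fitRows)) fitRows <- seq_len(nrow(m))
  if (!length(fitRows)) stop("fitRows must be non-empty")
  fit <- m[fitRows, , drop = FALSE]
  mins <- apply(fit, 2L, min)
  rng <- apply(fit, 2L, max) - mins
  scaled <- sweep(m, 2L, mins)
  const <- rng <= 0
  scaled[, !const] <- sweep(scaled[, !const, drop = FALSE], 2L,
                            rng[!const], `/`)
  scaled[, const] <- 0
  list(scaled = scaled, min = mins, range = rng)
}

#' Invert min-max scaling
#' @param scaled scaled matrix from \code{\link{minmaxScale}}.
#' @param scaler the scaler parameter list.
#' @return matrix on the original scale (constant columns return their
#'   fitted minimum).
#' @export
minmaxInverse <- function(scaled, scaler) {
  m <- as.matrix(scaled)
  rng <- ifelse(scaler$range > 0, scaler$range, 0)
  sweep(sweep(m, 2L, rng, `*`), 2L, scaler$min, `+`)
}

#' Random train/test split
#'
#' Unstratified, seed-controlled split with the train size floored
#' (\code{floor(trainFrac n)}), so 312 rows give 249 train / 63 test.
#'
#' @param n number of rows, or a \linkS4class{FeatureTable}.
#' @param trainFrac training fraction (default 0.8).
#' @param seed integer seed.
#' @return list with integer \code{train} and \code{test} indices.
#' @export
trainTestSplit <- function(n, trainFrac = 0.8, seed = 1L) {
  if (is(n, "FeatureTable")) n <- ncol(n)
  if (n < 5L) stop("need >= 5 rows to split")
  nTrain <- floor(trainFrac * n)
  withSeed(seed, {
    train <- sort(sample(n, nTrain))
    list(train = train, test = setdiff(seq_len(n), train))
  })
}

BLOCK_COMBINATIONS <- list(
  "Seq+MD+MDpocket" = c("SEQ", "MD", "POCKET"),
  "Seq+MD" = c("SEQ", "MD"),
  "MD+MDpocket" = c("MD", "POCKET"),
  "Seq+MDpocket" = c("SEQ", "POCKET"),
  "Seq" = "SEQ",
  "MD" = "MD",
  "MDpocket" = "POCKET")

#' The seven feature-block combinations
#'
#' Returns the seven canonical block subsets (Seq+MD+MDpocket, Seq+MD,
#' MD+MDpocket, Seq+MDpocket, Seq, MD, MDpocket), each preserving row order
#' and the response.
#'
#' @param table a \linkS4class{FeatureTable} containing all three blocks.
#' @return named list of seven \linkS4class{FeatureTable}s.
#' @export
blockSubsets <- function(table) {
  blocks <- featureBlocks(table)
  missing <- setdiff(c("SEQ", "MD", "POCKET"), unique(blocks))
  if (length(missing))
    stop("missing block(s): ", paste(missing, collapse = ", "))
  lapply(BLOCK_COMBINATIONS, function(keep)
    table[blocks %in% keep, ])
}
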