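#' @include AllClasses.R trajectory-features.R
#' @importFrom stats oneway.test pf hclust as.dist quantile
NULL

#' Split a trajectory into contiguous chunks
#'
#' Non-overlapping chunks of \code{chunkNs} nanoseconds in time order; a
#' trailing partial chunk is dropped.
#'
#' @param traj a \linkS4class{TrajectoryData}.
#' @param chunkNs chunk length in ns (default 10).
#' @return list of \linkS4class{TrajectoryData}.
#' @export
chunkTrajectory <- function(traj, chunkNs = 10) {
  framesPerChunk <- as.integer(round(chunkNs * 1000 / traj@dtPs))
  if (framesPerChunk < 1L) stop("chunk shorter than one frame")
  nf <- nFrames(traj)
  if (framesPerChunk > nf)
    stop("chunk (", framesPerChunk, " frames) longer than trajectory (",
         nf, " frames)")
  k <- nf %/% framesPerChunk
  lapply(seq_len(k), function(c) {
    idx <- ((c - 1L) * framesPerChunk + 1L):(c * framesPerChunk)
    TrajectoryData(traj@frames[idx, , , drop = FALSE], traj@dtPs,
                   traj@model)
  })
}

## Split a numeric series into chunks of equal frame count, dropping the
## trailing remainder.
chunkSeries <- function(x, framesPerChunk) {
  k <- length(x) %/% framesPerChunk
  if (k < 1L) stop("chunk longer than series")
  lapply(seq_len(k), function(c)
    x[((c - 1L) * framesPerChunk + 1L):(c * framesPerChunk)])
}

#' Classical one-way ANOVA
#'
#' Between/within decomposition with the p-value from the F distribution on
#' (k - 1, N - k) degrees of freedom.  When both the between- and
#' within-group variances vanish, F is defined as 0 with p = 1.
#'
#' @param groups list of >= 2 numeric vectors, each of length >= 2.
#' @return list with \code{F} and \code{p}.
#' @export
anovaOneway <- function(groups) {
  if (length(groups) < 2L) stop("need >= 2 groups")
  if (any(lengths(groups) < 2L)) stop("each group needs >= 2 values")
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  k <- length(groups); N <- length(x)
  gm <- mean(x)
  means <- vapply(groups, mean, 0)
  ssb <- sum(lengths(groups) * (means - gm)^2)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0))
  if (ssw < 1e-300) {
    if (ssb < 1e-300) return(list(F = 0, p = 1))
    return(list(F = Inf, p = 0))
  }
  F <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = F, p = pf(F, k - 1, N - k, lower.tail = FALSE))
}

#' Chunk-versus-first ANOVA p-value matrix
#'
#' For each variant, each 10 ns chunk beyond the first is compared with the
#' first chunk by one-way ANOVA of the per-frame RMSD values.  In the
#' default \code{"pooled"} mode frames are pooled across replicates per
#' chunk (groups = the two chunks); in \code{"nested"} mode the observations
#' are the per-replicate chunk means.
#'
#' @param rmsdSeriesList list (over variants) of lists (over replicates) of
#'   per-frame RMSD vectors.
#' @param chunkNs chunk length in ns.
#' @param dtPs frame spacing in ps.
#' @param mode \code{"pooled"} (default) or \code{"nested"}.
#' @param alpha significance level for the mask (default 0.05,
#'   uncorrected).
#' @return list with \code{p} ((nChunks - 1) x nVariants matrix),
#'   \code{significant} (logical mask at \code{alpha}) and \code{chunkNs}.
#' @export
chunkAnovaMatrix <- function(rmsdSeriesList, chunkNs = 10, dtPs = 100,
                             mode = c("pooled", "nested"), alpha = 0.05) {
  mode <- match.arg(mode)
  stopifnot(length(rmsdSeriesList) >= 1L)
  framesPerChunk <- as.integer(round(chunkNs * 1000 / dtPs))
  pcols <- lapply(rmsdSeriesList, function(reps) {
    if (length(reps) < 2L && mode == "nested")
      stop("nested mode needs >= 2 replicates per variant")
    chunked <- lapply(reps, chunkSeries, framesPerChunk = framesPerChunk)
    nch <- min(lengths(chunked))
    vapply(seq_len(nch)[-1L], function(c) {
      if (mode == "pooled") {
        g1 <- unlist(lapply(chunked, `[[`, 1L))
        gc <- unlist(lapply(chunked, `[[`, c))
      } else {
        g1 <- vapply(chunked, function(ch) mean(ch[[1L]]), 0)
        gc <- vapply(chunked, function(ch) mean(ch[[c]]), 0)
      }
      anovaOneway(list(g1, gc))$p
    }, 0)
  })
  nch <- unique(lengths(pcols))
  if (length(nch) != 1L)
    stop("variants yield differing chunk counts")
  p <- do.call(cbind, pcols)
  rownames(p) <- sprintf("chunk%d_vs_1", seq_len(nrow(p)) + 1L)
  colnames(p) <- names(rmsdSeriesList)
  list(p = p, significant = p < alpha, chunkNs = chunkNs, alpha = alpha)
}

#' Hausdorff distance between two conformational paths
#'
#' Treats two trajectories as sequences of conformations; the frame metric
#' is the pairwise superposed RMSD.  The directed distance from P to Q is
#' \code{max over p of min over q of RMSD(p, q)}, and the symmetric
#' Hausdorff distance is the larger of the two directions.
#'
#' @param pathP,pathQ F x N x 3 arrays (or \linkS4class{TrajectoryData})
#'   with the same atom count.
#' @return list with \code{deltaH}, \code{directedPQ}, \code{directedQP}.
#' @export
hausdorffDistance <- function(pathP, pathQ) {
  toArr <- function(x) if (is(x, "TrajectoryData")) frameArray(x) else x
  P <- toArr(pathP); Q <- toArr(pathQ)
  if (!length(P) || !length(Q)) stop("paths must be non-empty")
  if (dim(P)[2L] != dim(Q)[2L]) stop("atom count mismatch between paths")
  np <- dim(P)[1L]; nq <- dim(Q)[1L]
  D <- matrix(0, np, nq)
  for (i in seq_len(np)) {
    pi <- P[i, , , drop = TRUE]
    if (is.null(dim(pi))) pi <- matrix(pi, ncol = 3L)
    for (j in seq_len(nq)) {
      qj <- Q[j, , , drop = TRUE]
      if (is.null(dim(qj))) qj <- matrix(qj, ncol = 3L)
      D[i, j] <- kabschSuperpose(pi, qj)$rmsd
    }
  }
  dpq <- max(apply(D, 1L, min))
  dqp <- max(apply(D, 2L, min))
  list(deltaH = max(dpq, dqp), directedPQ = dpq, directedQP = dqp)
}

#' Pairwise Hausdorff matrix with Ward clustering
#'
#' All pairwise symmetric Hausdorff distances between paths, hierarchically
#' clustered with Ward linkage; the dendrogram leaf order is returned.
#'
#' @param chunks list of >= 2 paths (arrays or
#'   \linkS4class{TrajectoryData}).
#' @return list with \code{distance} (symmetric, zero diagonal),
#'   \code{hclust} and \code{order}.
#' @export
psaMatrix <- function(chunks) {
  n <- length(chunks)
  if (n < 2L) stop("need >= 2 paths")
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    D[i, j] <- D[j, i] <- hausdorffDistance(chunks[[i]],
                                            chunks[[j]])$deltaH
  hc <- hclust(as.dist(D), method = "ward.D2")
  list(distance = D, hclust = hc, order = hc$order)
}

#' Classify a Hausdorff distance
#'
#' Bands in \enc{Å}{Angstrom}: below 0.5 identical, above 3.0 highly
#' different, otherwise intermediate.
#'
#' @param deltaH non-negative Hausdorff distance(s).
#' @return character vector of \code{"identical"}, \code{"intermediate"} or
#'   \code{"highly_different"}.
#' @export
classifySimilarity <- function(deltaH) {
  if (any(deltaH < 0)) stop("deltaH must be non-negative")
  ifelse(deltaH < 0.5, "identical",
         ifelse(deltaH > 3.0, "highly_different", "intermediate"))
}

#' Shuffle retention test for replicate variability
#'
#' For each of \code{nFolds} folds, a random \code{keepFrac} subsample of
#' frames is drawn per replicate and the mean RMSD recorded; a one-way ANOVA
#' across replicates on the fold means then checks whether the
#' between-replicate differences survive averaging (retention declared at
#' p < 0.05).
#'
#' @param rmsdSeriesReps list of per-replicate RMSD vectors (>= 2
#'   replicates, >= 10 frames each).
#' @param nFolds number of folds (default 20).
#' @param keepFrac subsample fraction (default 0.8).
#' @param seed integer seed.
#' @return list with \code{foldMeans} (nFolds x replicates), \code{anovaP}
#'   and \code{retained}.
#' @export
retentionShuffleTest <- function(rmsdSeriesReps, nFolds = 20L,
                                 keepFrac = 0.8, seed = 1L) {
  if (length(rmsdSeriesReps) < 2L) stop("need >= 2 replicates")
  if (any(lengths(rmsdSeriesReps) < 10L))
    stop("each replicate needs >= 10 frames")
  lens <- lengths(rmsdSeriesReps)
  fm <- withSeed(seed, {
    t(vapply(seq_len(nFolds), function(f) {
      if (length(unique(lens)) == 1L) {
        ## paired subsampling: the same frame subset across replicates, so
        ## identical replicates give identical fold means
        idx <- sample(lens[1L], max(2L, floor(keepFrac * lens[1L])))
        vapply(rmsdSeriesReps, function(x) mean(x[idx]), 0)
      } else {
        vapply(rmsdSeriesReps, function(x)
          mean(sample(x, max(2L, floor(keepFrac * length(x))))), 0)
      }
    }, numeric(length(rmsdSeriesReps))))
  })
  av <- anovaOneway(lapply(seq_len(ncol(fm)), function(j) fm[, j]))
  list(foldMeans = fm, anovaP = av$p, retained = av$p < 0.05)
}

#' Minimum informative simulation length
#'
#' Given the chunk-versus-first p-value matrix, finds the largest horizon c
#' through which at least \code{agreementFrac} of variants show no
#' significant difference from the first chunk for every chunk 2..c.  When
#' that horizon spans the whole matrix the first chunk alone is informative
#' and its length is returned; when no horizon satisfies the criterion the
#' longest length is returned with a warning.
#'
#' @param pMatrix (nChunks - 1) x nVariants p-value matrix from
#'   \code{\link{chunkAnovaMatrix}}.
#' @param chunkNs chunk length in ns.
#' @param agreementFrac required fraction of agreeing variants (default
#'   0.8).
#' @param alpha significance level (default 0.05).
#' @return list with \code{chunkIndex} and \code{lengthNs}.
#' @export
chooseMinLength <- function(pMatrix, chunkNs = 10, agreementFrac = 0.8,
                            alpha = 0.05) {
  if (!length(pMatrix)) stop("empty p-value matrix")
  pMatrix <- as.matrix(pMatrix)
  nch <- nrow(pMatrix) + 1L
  ## fraction of variants with all chunks 2..c non-significant
  agree <- vapply(2:nch, function(c)
    mean(colSums(pMatrix[seq_len(c - 1L), , drop = FALSE] < alpha) == 0L), 0)
  ok <- which(agree >= agreementFrac)
  if (!length(ok)) {
    warning("no simulation length satisfies the agreement criterion; ",
            "returning the longest")
    return(list(chunkIndex = nch, lengthNs = nch * chunkNs))
  }
  cstar <- max(ok) + 1L
  if (cstar == nch)
    return(list(chunkIndex = 1L, lengthNs = chunkNs))
  list(chunkIndex = cstar, lengthNs = cstar * chunkNs)
}
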