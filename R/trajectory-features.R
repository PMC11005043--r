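#' @include AllClasses.R utils.R
NULL

ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                  S = 32.06, P = 30.974)

## Squared-distance matrix between two point sets (rows).
pdist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

#' Resolve an atom selection on a structure
#'
#' @param model a \linkS4class{StructureModel}.
#' @param kind \code{"heavy"} (all non-hydrogen protein atoms),
#'   \code{"backbone"} (N, CA, C, O) or \code{"calpha"}.
#' @param site optional \linkS4class{BindingSite}; when given, the selection
#'   is restricted to site residues.
#' @return integer atom indices (error when empty).
#' @export
atomSelection <- function(model, kind = c("heavy", "backbone", "calpha"),
                          site = NULL) {
  kind <- match.arg(kind)
  a <- atomData(model)
  keep <- !a$ligand & toupper(a$element) != "H"
  keep <- keep & switch(kind,
    heavy = TRUE,
    backbone = trimws(a$name) %in% c("N", "CA", "C", "O"),
    calpha = trimws(a$name) == "CA")
  if (!is.null(site)) keep <- keep & a$resid %in% site@residueIds
  idx <- which(keep)
  if (!length(idx)) stop("empty atom selection (", kind, ")")
  idx
}

#' Kabsch least-squares superposition
#'
#' Optimal rigid-body fit of \code{mobile} onto \code{reference}
#' (proper rotation, det = +1) minimizing the weighted RMSD.  The aligned
#' coordinates are \code{mobile \%*\% rotation + translation} (row-vector
#' convention).
#'
#' @param mobile,reference N x 3 matrices, N >= 3 non-collinear points.
#' @param weights optional non-negative per-atom weights.
#' @param resid optional per-atom residue ids; when given, per-residue RMSD
#'   after the fit is returned as well.
#' @return list with \code{rotation} (3 x 3), \code{translation} (length 3),
#'   \code{rmsd}, \code{aligned} (N x 3) and optionally
#'   \code{perResidueRmsd}.
#' @export
kabschSuperpose <- function(mobile, reference, weights = NULL, resid = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n < 3L || nrow(reference) != n)
    stop("need >= 3 paired points for superposition")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (any(w < 0) || sum(w) <= 0) stop("invalid weights")
  w <- w / sum(w)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  M <- sweep(mobile, 2L, cm); R <- sweep(reference, 2L, cr)
  H <- crossprod(M * w, R)
  s <- svd(H)
  if (s$d[2L] < 1e-10 * max(s$d[1L], 1))
    stop("degenerate (collinear) configuration")
  d <- sign(det(s$u) * det(s$v))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  aligned <- M %*% rot
  dev2 <- rowSums((aligned - R)^2)
  out <- list(rotation = rot, translation = as.numeric(cr - cm %*% rot),
              rmsd = sqrt(sum(w * dev2)),
              aligned = sweep(aligned, 2L, cr, `+`))
  if (!is.null(resid)) {
    pr <- tapply(dev2, resid, function(x) sqrt(mean(x)))
    out$perResidueRmsd <- pr[order(as.integer(names(pr)))]
  }
  out
}

#' Frame-wise RMSD series with respect to the initial structure
#'
#' Each frame is superposed (mass-unweighted, fit and measure on the same
#' selection) onto the reference structure; the post-fit RMSD in
#' \enc{Å}{Angstrom} is returned per frame.
#'
#' @param traj a \linkS4class{TrajectoryData}.
#' @param reference a \linkS4class{StructureModel} (typically the initial
#'   structure).
#' @param sel integer atom indices from \code{\link{atomSelection}}.
#' @return numeric vector, one RMSD per frame.
#' @export
rmsdSeries <- function(traj, reference, sel) {
  if (!length(sel)) stop("empty selection")
  ref <- atomCoords(reference)[sel, , drop = FALSE]
  n <- length(sel)
  if (n < 3L) stop("selection too small for superposition")
  Rc <- sweep(ref, 2L, colMeans(ref))
  rsq <- sum(Rc * Rc) / n
  fr <- frameArray(traj)
  ## post-fit RMSD from the Kabsch singular values without forming the
  ## aligned coordinates: rmsd^2 = <|M|^2> + <|R|^2> - 2 (d1 + d2 +/- d3)
  vapply(seq_len(nFrames(traj)), function(k) {
    x <- fr[k, sel, , drop = TRUE]
    Mc <- sweep(x, 2L, colMeans(x))
    H <- crossprod(Mc, Rc) / n
    s <- svd(H)
    d3 <- if (det(s$u) * det(s$v) < 0) -s$d[3L] else s$d[3L]
    r <- sqrt(max(0, sum(Mc * Mc) / n + rsq - 2 * (s$d[1L] + s$d[2L] + d3)))
    ## floating-point cancellation floor: identical conformations give
    ## residuals at sqrt(eps) scale, well below any physical RMSD
    if (r < 1e-5) r <- 0
    r
  }, 0)
}

#' Radius-of-gyration series
#'
#' Mass-weighted radius of gyration per frame:
#' \code{sqrt(sum(m_i |r_i - r_com|^2) / sum(m_i))} in \enc{Å}{Angstrom}.
#'
#' @inheritParams rmsdSeries
#' @return numeric vector, one RoG per frame.
#' @export
rogSeries <- function(traj, sel) {
  if (!length(sel)) stop("empty selection")
  el <- toupper(atomData(traj@model)$element[sel])
  m <- ELEMENT_MASS[el]
  m[is.na(m)] <- ELEMENT_MASS["C"]
  m <- m / sum(m)
  fr <- frameArray(traj)
  vapply(seq_len(nFrames(traj)), function(k) {
    x <- fr[k, sel, , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, ncol = 3L)
    com <- colSums(x * m)
    sqrt(sum(m * rowSums(sweep(x, 2L, com)^2)))
  }, 0)
}

#' Per-atom root-mean-square fluctuation
#'
#' RMSF about the time-mean position, by default after superposing every
#' frame onto the first frame on the selection (removing global rigid
#' motion).
#'
#' @inheritParams rmsdSeries
#' @param fit superpose frames onto the first frame before measuring
#'   (default TRUE).
#' @return numeric per-atom RMSF (\enc{Å}{Angstrom}), one per selected atom.
#' @export
rmsf <- function(traj, sel, fit = TRUE) {
  if (!length(sel)) stop("empty selection")
  if (nFrames(traj) < 2L) stop("RMSF requires >= 2 frames")
  fr <- frameArray(traj)
  xs <- lapply(seq_len(nFrames(traj)), function(k) {
    x <- fr[k, sel, , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, ncol = 3L)
    x
  })
  if (fit) {
    ref <- xs[[1L]]
    xs <- lapply(xs, function(x) kabschSuperpose(x, ref)$aligned)
  }
  arr <- simplify2array(xs)             # atoms x 3 x frames
  mu <- apply(arr, c(1L, 2L), mean)
  sqrt(rowMeans(apply(arr, 3L, function(x) rowSums((x - mu)^2))))
}

## ---- DSSP-style secondary structure -----------------------------------

## Backbone bookkeeping: indices of N, CA, C, O per residue (NA when absent).
backboneIndex <- function(model) {
  a <- atomData(model)
  prot <- which(!a$ligand)
  res <- sort(unique(a$resid[prot]))
  idx <- sapply(c("N", "CA", "C", "O"), function(nm)
    vapply(res, function(r) {
      i <- prot[a$resid[prot] == r & trimws(a$name[prot]) == nm]
      if (length(i)) i[1L] else NA_integer_
    }, 1L))
  if (length(res) == 1L) idx <- matrix(idx, nrow = 1L,
                                       dimnames = list(NULL, colnames(idx)))
  list(resid = res, idx = idx,
       resname = vapply(res, function(r)
         a$resname[prot[a$resid[prot] == r][1L]], ""))
}

## Kabsch-Sander hydrogen-bond energies and assignment on raw backbone
## coordinate matrices.  HB[i, j] is TRUE when the carbonyl of residue i
## accepts a hydrogen bond from the amide NH of residue j,
## E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN) kcal/mol, bond if
## E < -0.5.
dsspCore <- function(N, CA, C, O, isPro = rep(FALSE, nrow(N))) {
  n <- nrow(N)
  labels <- rep("C", n)
  if (n < 3L) return(labels)
  ## reconstructed amide H: N_j + unit(C_{j-1} - O_{j-1}); none for the
  ## N-terminal residue or proline
  H <- matrix(NA_real_, n, 3L)
  v <- C[-n, , drop = FALSE] - O[-n, , drop = FALSE]
  nv <- sqrt(.rowSums(v * v, n - 1L, 3L))
  ok <- nv > 1e-6 & !isPro[-1L]
  H[-1L, ][ok, ] <- N[-1L, , drop = FALSE][ok, ] + v[ok, , drop = FALSE] /
    nv[ok]
  hasH <- !is.na(H[, 1L])
  E <- cppHbondEnergy(C, O, N, H, CA, hasH)
  HB <- E < -0.5
  ## n-turn bonds CO(i) -> NH(i+3) / NH(i+4)
  turn3 <- c(HB[cbind(seq_len(n - 3L), seq_len(n - 3L) + 3L)],
             rep(FALSE, 3L))
  turn4 <- c(HB[cbind(seq_len(n - 4L), seq_len(n - 4L) + 4L)],
             rep(FALSE, 4L))
  ## bend: Calpha curvature over i-2, i, i+2 greater than 70 degrees
  if (n >= 5L) {
    u <- CA[3:(n - 2L), , drop = FALSE] - CA[seq_len(n - 4L), , drop = FALSE]
    w <- CA[5:n, , drop = FALSE] - CA[3:(n - 2L), , drop = FALSE]
    cosang <- .rowSums(u * w, n - 4L, 3L) /
      (sqrt(.rowSums(u * u, n - 4L, 3L)) *
         sqrt(.rowSums(w * w, n - 4L, 3L)))
    bend <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi > 70
    labels[(3:(n - 2L))[bend]] <- "S"
  }
  ## turns: residues bracketed by a 3- or 4-turn bond
  i3 <- which(turn3); i4 <- which(turn4)
  labels[unique(c(i3 + 1L, i3 + 2L, i4 + 1L, i4 + 2L, i4 + 3L))] <- "T"
  ## 3-10 helix: two consecutive 3-turns starting at i-1 and i
  g0 <- which(c(FALSE, turn3[-1L] & turn3[-length(turn3)]))
  if (length(g0)) labels[unique(c(g0, g0 + 1L, g0 + 2L))] <- "G"
  ## bridges (parallel / antiparallel), |i - j| > 2; candidate residue
  ## pairs are derived sparsely from the hydrogen-bond list
  hb <- which(HB, arr.ind = TRUE)
  if (nrow(hb)) {
    x <- hb[, 1L]; yv <- hb[, 2L]
    cand <- rbind(cbind(x + 1L, yv), cbind(yv - 1L, x),
                  cbind(yv, x + 1L), cbind(x, yv - 1L),
                  cbind(x, yv), cbind(yv, x),
                  cbind(x + 1L, yv - 1L), cbind(yv - 1L, x + 1L))
    ok <- cand[, 1L] >= 1L & cand[, 1L] <= n &
      cand[, 2L] >= 1L & cand[, 2L] <= n &
      abs(cand[, 1L] - cand[, 2L]) > 2L
    cand <- cand[ok, , drop = FALSE]
    cand <- cand[!duplicated((cand[, 1L] - 1L) * n + cand[, 2L]), ,
                 drop = FALSE]
    g <- function(i, j) {
      val <- rep(FALSE, length(i))
      inb <- i >= 1L & i <= n & j >= 1L & j <= n
      val[inb] <- HB[cbind(i[inb], j[inb])]
      val
    }
    if (nrow(cand)) {
      i <- cand[, 1L]; j <- cand[, 2L]
      isPar <- (g(i - 1L, j) & g(j, i + 1L)) | (g(j - 1L, i) & g(i, j + 1L))
      isAnti <- (g(i, j) & g(j, i)) | (g(i - 1L, j + 1L) & g(j - 1L, i + 1L))
      labels[unique(c(i[isPar], j[isPar]))] <- "E_para"
      labels[unique(c(i[isAnti], j[isAnti]))] <- "E_anti"
    }
  }
  ## alpha helix: two consecutive 4-turns (highest priority)
  h0 <- which(c(FALSE, turn4[-1L] & turn4[-length(turn4)]))
  if (length(h0))
    labels[unique(c(h0, h0 + 1L, h0 + 2L, h0 + 3L))] <- "H"
  labels
}

#' DSSP-style secondary-structure assignment
#'
#' Assigns per-residue labels from backbone hydrogen-bond patterns using the
#' Kabsch-Sander electrostatic energy
#' \code{E = 0.084 (1/rON + 1/rCH - 1/rOH - 1/rCN) 332} kcal/mol with a bond
#' declared below -0.5 kcal/mol.  Alpha (H) and 3-10 (G) helices come from
#' consecutive i -> i+4 / i -> i+3 turn bonds, parallel/antiparallel strand
#' labels (\code{E_para}/\code{E_anti}) from inter-strand bridge patterns,
#' turns (T) from isolated turn bonds, bends (S) from Calpha curvature above
#' 70 degrees, and everything else is coil (C).  Amide hydrogens are
#' reconstructed geometrically (1 \enc{Å}{Angstrom} from N along the
#' preceding carbonyl C=O direction); residues missing a backbone atom are
#' labelled C with a warning.
#'
#' @param model a \linkS4class{StructureModel} providing backbone atoms.
#' @param frame optional N x 3 coordinate matrix overriding the model's
#'   coordinates (e.g. one trajectory frame).
#' @return character vector of labels in
#'   \{H, G, E_para, E_anti, T, S, C\}, named by residue id.
#' @export
assignSecondaryStructure <- function(model, frame = NULL) {
  bb <- backboneIndex(model)
  xyz <- if (is.null(frame)) atomCoords(model) else as.matrix(frame)
  ok <- rowSums(is.na(bb$idx)) == 0L
  if (any(!ok))
    warning("residue(s) missing backbone atoms labelled C: ",
            paste(bb$resid[!ok], collapse = ", "))
  labels <- rep("C", length(bb$resid))
  if (sum(ok) >= 3L) {
    sub <- which(ok)
    labels[sub] <- dsspCore(xyz[bb$idx[sub, "N"], , drop = FALSE],
                            xyz[bb$idx[sub, "CA"], , drop = FALSE],
                            xyz[bb$idx[sub, "C"], , drop = FALSE],
                            xyz[bb$idx[sub, "O"], , drop = FALSE],
                            isPro = bb$resname[sub] == "PRO")
  }
  names(labels) <- bb$resid
  labels
}

SS_CLASSES <- c(h_alpha = "H", h_310 = "G", para_beta = "E_para",
                anti_beta = "E_anti", turn = "T", bend = "S", coil = "C",
                other = "")

ssFractionsOfLabels <- function(labels) {
  n <- length(labels)
  known <- vapply(SS_CLASSES[-8L], function(code) sum(labels == code) / n, 0)
  c(known, other = 1 - sum(known))
}

#' Secondary-structure fractions over a trajectory
#'
#' Per-frame fractions of residues in each of eight classes (alpha helix,
#' 3-10 helix, parallel/antiparallel sheet, turn, bend, coil, other); the
#' fractions form a probability vector each frame.
#'
#' @param traj a \linkS4class{TrajectoryData}.
#' @param bb precomputed backbone index (internal use).
#' @return list with \code{perFrame} (frames x 8 matrix), \code{mean},
#'   \code{std} (population SD over frames) and \code{nFrames}.
#' @export
ssFractions <- function(traj, bb = NULL) {
  if (is.null(bb)) bb <- backboneIndex(traj@model)
  ok <- rowSums(is.na(bb$idx)) == 0L
  if (sum(ok) < 3L) stop("too few complete residues for assignment")
  sub <- which(ok)
  fr <- frameArray(traj)
  per <- t(vapply(seq_len(nFrames(traj)), function(k) {
    xyz <- fr[k, , , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3L)
    lab <- rep("C", length(bb$resid))
    lab[sub] <- dsspCore(xyz[bb$idx[sub, "N"], , drop = FALSE],
                         xyz[bb$idx[sub, "CA"], , drop = FALSE],
                         xyz[bb$idx[sub, "C"], , drop = FALSE],
                         xyz[bb$idx[sub, "O"], , drop = FALSE],
                         isPro = bb$resname[sub] == "PRO")
    ssFractionsOfLabels(lab)
  }, numeric(8L)))
  list(perFrame = per, mean = colMeans(per), std = apply(per, 2L, sdPop),
       nFrames = nrow(per))
}

MD_SELECTION_GRID <- expand.grid(kind = c("heavy", "backbone", "calpha"),
                                 scope = c("whole", "site"),
                                 stringsAsFactors = FALSE)

## Per-replicate scalar summaries of the 12 geometry series (frame means)
## plus the 8 mean secondary-structure fractions.  Selections and the
## backbone index may be precomputed by the caller.
mdReplicateSummary <- function(traj, reference, site, sels = NULL,
                               bb = NULL) {
  vals <- numeric(0)
  for (g in seq_len(nrow(MD_SELECTION_GRID))) {
    kind <- MD_SELECTION_GRID$kind[g]
    scope <- MD_SELECTION_GRID$scope[g]
    sel <- if (is.null(sels)) {
      atomSelection(reference, kind,
                    site = if (scope == "site") site else NULL)
    } else sels[[g]]
    tag <- paste0(kind, "_", scope)
    vals[paste0("rmsd_", tag)] <- mean(rmsdSeries(traj, reference, sel))
    vals[paste0("rog_", tag)] <- mean(rogSeries(traj, sel))
  }
  ssm <- ssFractions(traj, bb = bb)$mean
  vals[paste0("ss_", names(ssm))] <- ssm
  vals
}

#' The 32-column MD feature block
#'
#' Twelve series (RMSD and RoG for heavy/backbone/Calpha selections over the
#' whole protein and the binding site) are reduced to their per-replicate
#' frame means, then aggregated across replicates into a mean and a
#' population SD (24 features); the eight mean secondary-structure fractions
#' complete the block (32 columns).
#'
#' @param trajectories list of replicate \linkS4class{TrajectoryData}.
#' @param reference the initial \linkS4class{StructureModel}.
#' @param site a \linkS4class{BindingSite}.
#' @return named numeric vector of length 32 with \code{"MD:"} prefixes.
#' @export
mdFeatureBlock <- function(trajectories, reference, site) {
  stopifnot(length(trajectories) >= 1L)
  sels <- lapply(seq_len(nrow(MD_SELECTION_GRID)), function(g)
    atomSelection(reference, MD_SELECTION_GRID$kind[g],
                  site = if (MD_SELECTION_GRID$scope[g] == "site") site
                         else NULL))
  bb <- backboneIndex(reference)
  per <- t(vapply(trajectories, mdReplicateSummary, reference = reference,
                  site = site, sels = sels, bb = bb,
                  FUN.VALUE = numeric(20L)))
  geo <- per[, 1:12, drop = FALSE]
  agg <- aggregateReplicates(geo)
  ss <- colMeans(per[, 13:20, drop = FALSE])
  out <- c(as.numeric(rbind(agg$mean, agg$std)),
           ss)
  names(out) <- c(as.vector(rbind(paste0(colnames(geo), "_mean"),
                                  paste0(colnames(geo), "_std"))),
                  paste0(colnames(per)[13:20], "_mean"))
  names(out) <- paste0("MD:", names(out))
  out
}
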