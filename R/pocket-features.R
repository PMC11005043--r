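#' @include AllClasses.R utils.R trajectory-features.R aa-data.R
NULL

## Van der Waals radii for SASA (Bondi).
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

#' Define the binding site on the template
#'
#' Residues with any heavy atom within \code{cutoff} \enc{Å}{Angstrom}
#' (inclusive boundary) of any ligand heavy atom.  The site is derived from
#' the template only and held fixed across frames.
#'
#' @param template a \linkS4class{StructureModel} with >= 1 ligand-flagged
#'   atom.
#' @param cutoff distance cutoff, default 3.5 \enc{Å}{Angstrom}.
#' @return a \linkS4class{BindingSite}.
#' @export
defineBindingSite <- function(template, cutoff = 3.5) {
  a <- atomData(template)
  lig <- which(a$ligand & toupper(a$element) != "H")
  if (!length(lig)) stop("template has no ligand atoms")
  prot <- which(!a$ligand & toupper(a$element) != "H")
  d <- pdist2(atomCoords(template)[prot, , drop = FALSE],
              atomCoords(template)[lig, , drop = FALSE])
  hit <- apply(d, 1L, min) <= cutoff
  res <- sort(unique(a$resid[prot[hit]]))
  if (!length(res))
    stop("no residue within ", cutoff,
         " A of the ligand; try a larger cutoff")
  new("BindingSite", residueIds = as.integer(res),
      atomIndices = prot[a$resid[prot] %in% res], cutoff = cutoff)
}

## Deterministic near-uniform points on the unit sphere (golden spiral).
spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom SASA by sphere-point sampling: each atom's solvent sphere
#' (radius + probe) is sampled at \code{nPoints} near-uniform points and the
#' fraction not buried inside any neighbour's solvent sphere is converted to
#' an area.
#'
#' @param coords N x 3 coordinates (\enc{Å}{Angstrom}).
#' @param radii per-atom van der Waals radii (> 0).
#' @param probe probe radius, default 1.4 \enc{Å}{Angstrom}.
#' @param nPoints sphere sample points per atom (default 960).
#' @return per-atom areas in \enc{Å}{Angstrom}^2.
#' @export
shrakeRupleySasa <- function(coords, radii, probe = 1.4, nPoints = 960L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (any(radii <= 0)) stop("radii must be positive")
  R <- radii + probe
  pts <- spherePoints(nPoints)
  ## all sphere points of all atoms at once; a point is buried when it lies
  ## inside any other atom's solvent sphere
  big <- coords[rep(seq_len(n), each = nPoints), , drop = FALSE] +
    pts[rep(seq_len(nPoints), n), , drop = FALSE] *
      R[rep(seq_len(n), each = nPoints)]
  D <- pdist2(big, coords)
  inside <- D < matrix(R, nrow(D), n, byrow = TRUE)
  inside[cbind(seq_len(nrow(D)), rep(seq_len(n), each = nPoints))] <- FALSE
  buried <- rowSums(inside) > 0
  acc <- vapply(seq_len(n), function(i)
    sum(!buried[((i - 1L) * nPoints + 1L):(i * nPoints)]), 0)
  4 * pi * R^2 * acc / nPoints
}

## ---- small incremental 3D convex hull ---------------------------------
## Returns list(volume, facets); facets are vertex-index triples with
## outward normals. O(n^2) insertion, adequate for pocket-sized point sets.
convexHull3d <- function(P) {
  P <- as.matrix(P)
  n <- nrow(P)
  if (n < 4L) return(list(volume = 0, degenerate = TRUE))
  ## find 4 non-coplanar seed points
  i1 <- 1L
  i2 <- which.max(rowSums(sweep(P, 2L, P[i1, ])^2))
  e1 <- P[i2, ] - P[i1, ]
  cr <- t(apply(P, 1L, function(p) crossv(e1, p - P[i1, ])))
  i3 <- which.max(rowSums(cr^2))
  nrm <- crossv(e1, P[i3, ] - P[i1, ])
  h <- abs(as.numeric(P %*% nrm) - sum(nrm * P[i1, ]))
  i4 <- which.max(h)
  if (vnorm(e1) < 1e-9 || vnorm(crossv(e1, P[i3, ] - P[i1, ])) < 1e-9 ||
      h[i4] < 1e-9 * max(1, vnorm(e1)))
    return(list(volume = 0, degenerate = TRUE))
  centroid <- colMeans(P[c(i1, i2, i3, i4), ])
  ## facets as preallocated parallel arrays: vertex triples, outward
  ## normals, plane offsets (avoids repeated concatenation)
  cap <- 8L * n + 16L
  V <- matrix(0L, cap, 3L); Nm <- matrix(0, cap, 3L); Off <- numeric(cap)
  nf <- 0L
  addFacet <- function(a, b, c) {
    nn <- crossv(P[b, ] - P[a, ], P[c, ] - P[a, ])
    if (sum(nn * (centroid - P[a, ])) > 0) nn <- -nn
    nf <<- nf + 1L
    V[nf, ] <<- c(a, b, c); Nm[nf, ] <<- nn; Off[nf] <<- sum(nn * P[a, ])
  }
  addFacet(i1, i2, i3); addFacet(i1, i2, i4)
  addFacet(i1, i3, i4); addFacet(i2, i3, i4)
  eps <- 1e-9
  for (p in setdiff(seq_len(n), c(i1, i2, i3, i4))) {
    act <- seq_len(nf)
    vis <- as.numeric(Nm[act, , drop = FALSE] %*% P[p, ]) - Off[act] >
      eps * sqrt(.rowSums(Nm[act, , drop = FALSE]^2, nf, 3L))
    if (!any(vis)) next
    ## horizon = edges of visible facets occurring exactly once
    vv <- V[act[vis], , drop = FALSE]
    a1 <- c(vv[, 1L], vv[, 2L], vv[, 1L])
    a2 <- c(vv[, 2L], vv[, 3L], vv[, 3L])
    key <- pmin(a1, a2) * (n + 1) + pmax(a1, a2)
    once <- which(!(duplicated(key) | duplicated(key, fromLast = TRUE)))
    ## drop visible facets, cone new ones from the horizon to p
    keep <- act[!vis]
    k <- length(keep)
    V[seq_len(k), ] <- V[keep, , drop = FALSE]
    Nm[seq_len(k), ] <- Nm[keep, , drop = FALSE]
    Off[seq_len(k)] <- Off[keep]
    nf <- k
    for (e in once) addFacet(a1[e], a2[e], p)
  }
  V <- V[seq_len(nf), , drop = FALSE]
  Nm <- Nm[seq_len(nf), , drop = FALSE]
  Off <- Off[seq_len(nf)]
  inner <- colMeans(P[unique(as.integer(V)), , drop = FALSE])
  ## interior point + convex hull: each facet tetrahedron adds |det|/6
  vol <- 0
  for (f in seq_len(nf)) {
    a <- P[V[f, 1L], ]; b <- P[V[f, 2L], ]; c <- P[V[f, 3L], ]
    vol <- vol + abs(sum(crossv(b - a, c - a) * (a - inner))) / 6
  }
  list(volume = vol,
       facets = list(v = V, n = Nm, off = Off),
       degenerate = FALSE)
}

#' Pocket geometry for one frame
#'
#' \code{volume} is the convex-hull volume of the site's heavy atoms (a
#' deterministic stand-in for cavity volume), \code{length} the maximum
#' pairwise atom distance, and \code{depth} the mean distance of site atoms
#' to the hull surface.  All three are invariant under rigid transforms of
#' the frame.
#'
#' @param site a \linkS4class{BindingSite}.
#' @param frame N x 3 coordinates of the full structure.
#' @return named numeric: \code{volume} (\enc{Å}{Angstrom}^3), \code{length}
#'   and \code{depth} (\enc{Å}{Angstrom}).  Fewer than 4 non-coplanar atoms
#'   give volume 0 with a warning.
#' @export
pocketGeometry <- function(site, frame) {
  X <- as.matrix(frame)[site@atomIndices, , drop = FALSE]
  g <- cppPocketGeometry(X)
  if (isTRUE(g$degenerate)) {
    warning("fewer than 4 non-coplanar site atoms; volume set to 0")
    return(c(volume = 0, length = g$length, depth = 0))
  }
  c(volume = g$volume, length = g$length, depth = g$depth)
}

#' Pocket chemistry (sequence-determined)
#'
#' Kyte-Doolittle mean hydrophobicity and residue-class counts over the site
#' residues, with charges at pH 8 (D/E = -1, K/R = +1, His uncharged).
#'
#' @param site a \linkS4class{BindingSite}.
#' @param sequence the variant's amino-acid string.
#' @return list with \code{hydrophobicityMean}, counts \code{nPositive},
#'   \code{nNegative}, \code{nPolar}, \code{nApolar}, \code{netCharge},
#'   \code{nCharged} and per-residue \code{charges}.
#' @export
pocketChemistry <- function(site, sequence) {
  aa <- checkSequence(sequence)
  if (any(site@residueIds > length(aa)))
    stop("site residue beyond sequence bounds")
  res <- aa[site@residueIds]
  charges <- ifelse(res %in% AA_CLASSES$positive, 1,
                    ifelse(res %in% AA_CLASSES$negative, -1, 0))
  names(charges) <- site@residueIds
  list(hydrophobicityMean = mean(KYTE_DOOLITTLE[res]),
       nPositive = sum(res %in% AA_CLASSES$positive),
       nNegative = sum(res %in% AA_CLASSES$negative),
       nPolar = sum(res %in% AA_CLASSES$polar),
       nApolar = sum(res %in% AA_CLASSES$apolar),
       netCharge = sum(charges),
       nCharged = sum(charges != 0),
       charges = charges)
}

#' Per-residue pocket occupancy over a trajectory
#'
#' For each site residue, the fraction of frames in which its nearest heavy
#' atom stays within \code{cutoff} of the ligand-region centroid fixed from
#' the first frame.
#'
#' @param site a \linkS4class{BindingSite}.
#' @param traj a \linkS4class{TrajectoryData}.
#' @param cutoff retention distance; defaults to the site's definition
#'   cutoff plus the template's centroid slack (see Details).
#' @details The ligand-region centroid is computed from the ligand atoms of
#'   frame 1; the default cutoff is the template distance of the farthest
#'   site residue to that centroid plus 1 \enc{Å}{Angstrom}, so the frozen
#'   trajectory has occupancy exactly 1 for every site residue.
#' @return named numeric occupancy in [0, 1], one per site residue.
#' @export
pocketOccupancy <- function(site, traj, cutoff = NULL) {
  a <- atomData(traj@model)
  fr <- frameArray(traj)
  lig <- which(a$ligand & toupper(a$element) != "H")
  if (!length(lig)) stop("trajectory model has no ligand atoms")
  center <- colMeans(matrix(fr[1L, lig, ], ncol = 3L))
  siteAtoms <- which(!a$ligand & a$resid %in% site@residueIds &
                       toupper(a$element) != "H")
  grp <- match(a$resid[siteAtoms], site@residueIds)
  nf <- nFrames(traj)
  ## per frame: squared distance of every site atom to the fixed centre,
  ## reduced to a per-residue minimum
  dmin <- vapply(seq_len(nf), function(t) {
    x <- matrix(fr[t, siteAtoms, ], ncol = 3L)
    d2 <- (x[, 1L] - center[1L])^2 + (x[, 2L] - center[2L])^2 +
      (x[, 3L] - center[3L])^2
    sqrt(vapply(split(d2, grp), min, 0))
  }, numeric(length(site@residueIds)))
  if (is.null(dim(dmin))) dmin <- matrix(dmin, nrow = 1L)
  if (is.null(cutoff)) cutoff <- max(dmin[, 1L]) + 1
  occ <- rowMeans(dmin <= cutoff)
  names(occ) <- site@residueIds
  occ
}

#' Normalized B-factor of site residues
#'
#' \code{B_i = (8 pi^2 / 3) RMSF_i^2} from the Calpha RMSF over the
#' trajectory, z-scored across site residues.  A frozen trajectory (zero
#' variance) returns all zeros.
#'
#' @param site a \linkS4class{BindingSite}.
#' @param traj a \linkS4class{TrajectoryData} with >= 2 frames.
#' @return named numeric z-scores, one per site residue.
#' @export
normalizedBfactor <- function(site, traj) {
  a <- atomData(traj@model)
  ca <- vapply(site@residueIds, function(r) {
    i <- which(!a$ligand & a$resid == r & trimws(a$name) == "CA")
    if (length(i)) i[1L] else NA_integer_
  }, 1L)
  if (anyNA(ca)) stop("site residue without a Calpha atom")
  f <- rmsf(traj, atomSelection(traj@model, "calpha"), fit = TRUE)
  sel <- atomSelection(traj@model, "calpha")
  b <- (8 * pi^2 / 3) * f[match(ca, sel)]^2
  s <- sdPop(b)
  z <- if (s < 1e-12) rep(0, length(b)) else (b - mean(b)) / s
  names(z) <- site@residueIds
  z
}

#' The 80-column pocket feature block
#'
#' Ten columns of frame-summarized pocket scalars (volume, length, depth,
#' total site SASA, hydrophobicity; per-replicate frame means aggregated to
#' mean + SD across replicates), 32 columns of per-slot occupancy
#' (mean + SD across replicates for 16 canonical site-residue slots ordered
#' by residue id), 32 columns of per-slot normalized B-factor (mean + SD),
#' and 6 chemistry counts = 80 columns.  Sites smaller than the slot count
#' are zero-padded (larger ones truncated) with a warning.
#'
#' @param site a \linkS4class{BindingSite}.
#' @param trajectories list of replicate \linkS4class{TrajectoryData}.
#' @param sequence the variant's sequence.
#' @param slots number of canonical site-residue slots (default 16).
#' @param sasaPoints sphere points per atom for the SASA series (default
#'   192; the standalone \code{\link{shrakeRupleySasa}} default is 960).
#' @param warnSlots emit the pad/truncate warning (default TRUE).
#' @return named numeric vector of length 80 with \code{"POCKET:"} prefixes.
#' @export
pocketFeatureBlock <- function(site, trajectories, sequence, slots = 16L,
                               sasaPoints = 192L, warnSlots = TRUE) {
  stopifnot(length(trajectories) >= 1L)
  model <- trajectories[[1L]]@model
  a <- atomData(model)
  chem <- pocketChemistry(site, sequence)
  heavySite <- site@atomIndices
  radii <- VDW_RADII[toupper(a$element[heavySite])]
  radii[is.na(radii)] <- VDW_RADII["C"]
  ## fixed per-atom occluder lists from the template (3 A fluctuation
  ## margin), so the per-frame SASA avoids all-pairs work
  pts <- spherePoints(sasaPoints)
  tmplX <- atomCoords(model)[heavySite, , drop = FALSE]
  R <- radii + 1.4
  R2 <- R^2
  areaFactor <- 4 * pi * R2 / sasaPoints
  dT <- pdist2(tmplX, tmplX)
  nbList <- lapply(seq_along(heavySite), function(i)
    which(dT[i, ] < R[i] + R + 3 & seq_along(heavySite) != i))
  ptsScaled <- lapply(seq_along(heavySite), function(i) pts * R[i])
  siteSasa <- function(X)
    cppSiteSasa(X, nbList, ptsScaled, R2, areaFactor)
  perRep <- lapply(trajectories, function(tr) {
    fr <- frameArray(tr)
    geo <- t(vapply(seq_len(nFrames(tr)), function(t) {
      frame <- fr[t, , , drop = TRUE]
      g <- suppressWarnings(pocketGeometry(site, frame))
      sasa <- siteSasa(frame[heavySite, , drop = FALSE])
      c(g, sasa = sasa)
    }, numeric(4L)))
    list(scalars = c(colMeans(geo), hydrophobicity = chem$hydrophobicityMean),
         occ = pocketOccupancy(site, tr),
         bfac = normalizedBfactor(site, tr))
  })
  padSlots <- function(x) {
    if (length(x) == slots) return(x)
    if (length(x) > slots) return(x[seq_len(slots)])
    c(x, rep(0, slots - length(x)))
  }
  nres <- length(site@residueIds)
  if (nres != slots && warnSlots)
    warning("site has ", nres, " residues; ",
            if (nres < slots) "zero-padding" else "truncating",
            " to ", slots, " slots")
  scal <- do.call(rbind, lapply(perRep, `[[`, "scalars"))
  occ <- do.call(rbind, lapply(perRep, function(p) padSlots(p$occ)))
  bfac <- do.call(rbind, lapply(perRep, function(p) padSlots(p$bfac)))
  aggScal <- aggregateReplicates(scal)
  aggOcc <- aggregateReplicates(occ)
  aggBfac <- aggregateReplicates(bfac)
  slotNames <- sprintf("slot%02d", seq_len(slots))
  out <- c(as.numeric(rbind(aggScal$mean, aggScal$std)),
           as.numeric(rbind(aggOcc$mean, aggOcc$std)),
           as.numeric(rbind(aggBfac$mean, aggBfac$std)),
           n_positive = chem$nPositive, n_negative = chem$nNegative,
           n_polar = chem$nPolar, n_apolar = chem$nApolar,
           net_charge = chem$netCharge, n_charged = chem$nCharged)
  names(out) <- c(
    as.vector(rbind(paste0(colnames(scal), "_mean"),
                    paste0(colnames(scal), "_std"))),
    as.vector(rbind(paste0("occ_", slotNames, "_mean"),
                    paste0("occ_", slotNames, "_std"))),
    as.vector(rbind(paste0("bfac_", slotNames, "_mean"),
                    paste0("bfac_", slotNames, "_std"))),
    "n_positive", "n_negative", "n_polar", "n_apolar", "net_charge",
    "n_charged")
  names(out) <- paste0("POCKET:", names(out))
  out
}
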