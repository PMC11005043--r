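## Shared fixtures, built in code.

## A small rigid, non-collinear structure: 4 protein atoms in 2 residues
## plus one ligand atom.
tinyStructure <- function(ligandDist = 3.0) {
  StructureModel(
    name = c("CA", "CB", "CA", "CB", "C1"),
    element = c("C", "C", "C", "C", "C"),
    resid = c(1L, 1L, 2L, 2L, 3L),
    resname = c("ALA", "ALA", "GLY", "GLY", "LIG"),
    chain = "A",
    coords = rbind(c(0, 0, 0), c(1.5, 0, 0.2), c(3, 1, 0), c(4.5, 1, 0.3),
                   c(0, ligandDist, 0)),
    ligand = c(FALSE, FALSE, FALSE, FALSE, TRUE))
}

## Build a TrajectoryData from a list of coordinate matrices.
toyTrajectory <- function(frames, model, dtPs = 100) {
  arr <- array(0, c(length(frames), nrow(frames[[1]]), 3L))
  for (k in seq_along(frames)) arr[k, , ] <- frames[[k]]
  TrajectoryData(arr, dtPs, model)
}

## Rotation matrix about z by angle degrees.
rotZ <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

randomRotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  quatToRot(q)
}

quatToRot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

## Independent brute-force rigid-fit oracle: minimize RMSD over rotations
## parameterized by quaternions, multistart Nelder-Mead (no SVD involved).
bruteForceRmsd <- function(mobile, reference, nStarts = 25L) {
  Mc <- sweep(mobile, 2, colMeans(mobile))
  Rc <- sweep(reference, 2, colMeans(reference))
  obj <- function(q) {
    q <- q / sqrt(sum(q^2))
    sqrt(mean(rowSums((Mc %*% quatToRot(q) - Rc)^2)))
  }
  best <- Inf
  for (s in seq_len(nStarts)) {
    q0 <- rnorm(4)
    o <- optim(q0, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
    o <- optim(o$par, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
    if (o$value < best) best <- o$value
  }
  best
}

## Two ideal antiparallel beta strands with registered backbone H-bonds:
## strand 2 is strand 1 rotated 180 degrees about y (so its chain runs the
## opposite way) and offset across the sheet; the offsets give
## Kabsch-Sander energies below -0.5 kcal/mol for the registered pairs.
antiparallelSheet <- function(nRes = 6L, dy = 4.0, dx = -1.5) {
  s1 <- makeTemplate(nRes, sheetSpans = list(c(1, nRes)), seed = 42,
                     sequence = paste(rep("V", nRes), collapse = ""))
  a <- atomData(s1$model)
  prot <- !a$ligand
  x1 <- atomCoords(s1$model)[prot, ]
  x2 <- x1 %*% diag(c(-1, 1, -1))
  x2 <- sweep(x2, 2, colMeans(x2) - colMeans(x1) + c(-dx, dy, 0))
  n <- sum(prot)
  StructureModel(
    name = rep(a$name[prot], 2),
    element = rep(a$element[prot], 2),
    resid = c(a$resid[prot], a$resid[prot] + nRes + 4L),
    resname = rep(a$resname[prot], 2),
    chain = "A",
    coords = rbind(x1, x2),
    ligand = rep(FALSE, 2L * n))
}

## Cached synthetic recovery study (expensive; built once per test run).
.studyCache <- new.env(parent = emptyenv())

recoverySpec <- function(seed = 1L)
  synthSpec(nVariants = 300L, framesPerTraj = 21L, noiseSd = 0.5,
            seed = seed)

getRecoveryStudy <- function() {
  if (is.null(.studyCache$study)) {
    .studyCache$study <- suppressMessages(
      buildStudyFeatureTable(recoverySpec()))
  }
  .studyCache$study
}
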