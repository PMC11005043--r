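test_that("superposing a structure on itself gives identity and zero RMSD", {
  set.seed(3)
  X <- matrix(rnorm(15), 5, 3)
  fit <- kabschSuperpose(X, X)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-8)
})

test_that("a rotated and translated copy superposes to zero RMSD", {
  set.seed(4)
  X <- matrix(rnorm(24), 8, 3)
  Y <- X %*% rotZ(90) + matrix(c(5, -3, 2), 8, 3, byrow = TRUE)
  fit <- kabschSuperpose(Y, X)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  expect_equal(fit$aligned, X, tolerance = 1e-8)
})

test_that("Kabsch RMSD matches a brute-force rotational search", {
  ## 4-point cloud with one atom displaced after best fit of the rest,
  ## plus random instances
  set.seed(5)
  base <- matrix(rnorm(12), 4, 3)
  mob <- base
  mob[4, ] <- mob[4, ] + c(1, 0, 0)
  expect_equal(kabschSuperpose(mob, base)$rmsd,
               bruteForceRmsd(mob, base), tolerance = 1e-6)
  for (i in 1:5) {
    A <- matrix(rnorm(15), 5, 3)
    B <- matrix(rnorm(15), 5, 3)
    expect_equal(kabschSuperpose(A, B)$rmsd, bruteForceRmsd(A, B),
                 tolerance = 1e-6)
  }
})

test_that("degenerate configurations are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabschSuperpose(line, line), "degenerate")
  expect_error(kabschSuperpose(matrix(rnorm(6), 2, 3),
                               matrix(rnorm(6), 2, 3)), ">= 3")
})

test_that("per-residue RMSD is reported by residue", {
  set.seed(6)
  X <- matrix(rnorm(18), 6, 3)
  Y <- X
  Y[5:6, ] <- Y[5:6, ] + 0.3
  fit <- kabschSuperpose(Y, X, resid = c(1, 1, 2, 2, 3, 3))
  expect_length(fit$perResidueRmsd, 3L)
  expect_gt(fit$perResidueRmsd[["3"]], 0)
})

test_that("RMSD series is zero for frozen or translated trajectories", {
  m <- tinyStructure()
  base <- atomCoords(m)
  sel <- atomSelection(m, "heavy")
  frozen <- toyTrajectory(list(base, base, base), m)
  expect_equal(rmsdSeries(frozen, m, sel), rep(0, 3), tolerance = 1e-9)
  shifted <- toyTrajectory(list(base, base + matrix(c(3, 0, 0), nrow(base),
                                                    3, byrow = TRUE)), m)
  expect_equal(rmsdSeries(shifted, m, sel), rep(0, 2), tolerance = 1e-9)
})

test_that("a two-frame toy RMSD matches manual Kabsch arithmetic", {
  m <- tinyStructure()
  base <- atomCoords(m)
  moved <- base
  moved[2, ] <- moved[2, ] + c(0.6, 0, 0)
  tr <- toyTrajectory(list(base, moved), m)
  sel <- atomSelection(m, "heavy")
  manual <- kabschSuperpose(moved[sel, ], base[sel, ])$rmsd
  expect_equal(rmsdSeries(tr, m, sel)[2], manual, tolerance = 1e-9)
  expect_gt(manual, 0)
})

test_that("RMSD series is invariant to a global rigid transform", {
  m <- tinyStructure()
  base <- atomCoords(m)
  set.seed(9)
  frames <- lapply(1:4, function(k) base + matrix(rnorm(15, 0, 0.2), 5, 3))
  tr <- toyTrajectory(frames, m)
  R <- randomRotation()
  trR <- toyTrajectory(lapply(frames, function(f)
    f %*% R + matrix(c(2, 4, -1), 5, 3, byrow = TRUE)), m)
  sel <- atomSelection(m, "heavy")
  expect_equal(rmsdSeries(trR, m, sel), rmsdSeries(tr, m, sel),
               tolerance = 1e-8)
})

test_that("radius of gyration follows the mass-weighted formula", {
  ## two unit-mass-like atoms (same element) 2 A apart -> RoG 1 A
  m <- StructureModel(name = c("C1", "C2"), element = c("C", "C"),
                      resid = c(1L, 1L), resname = "LIG", chain = "A",
                      coords = rbind(c(0, 0, 0), c(2, 0, 0)),
                      ligand = c(FALSE, FALSE))
  tr <- toyTrajectory(list(atomCoords(m)), m)
  expect_equal(rogSeries(tr, 1:2), 1.0)
  ## single atom
  expect_equal(rogSeries(tr, 1L), 0)
  ## random cloud equals direct evaluation with element masses
  m2 <- tinyStructure()
  set.seed(11)
  X <- matrix(rnorm(15, 0, 2), 5, 3)
  tr2 <- toyTrajectory(list(X), m2)
  sel <- atomSelection(m2, "heavy")
  masses <- rep(12.011, length(sel))
  com <- colSums(X[sel, ] * masses / sum(masses))
  direct <- sqrt(sum(masses / sum(masses) *
                       rowSums(sweep(X[sel, ], 2, com)^2)))
  expect_equal(rogSeries(tr2, sel), direct)
})

test_that("RMSF captures per-atom fluctuation and rigid-motion invariance", {
  m <- tinyStructure()
  base <- atomCoords(m)
  frozen <- toyTrajectory(list(base, base), m)
  expect_equal(rmsf(frozen, 1:5, fit = FALSE), rep(0, 5))
  expect_error(rmsf(toyTrajectory(list(base), m), 1:5), ">= 2 frames")
  ## one atom alternating +/- a along x: RMSF -> a (no fitting)
  a <- 0.8
  up <- base; up[5, 1] <- up[5, 1] + a
  dn <- base; dn[5, 1] <- dn[5, 1] - a
  tr <- toyTrajectory(rep(list(up, dn), 50), m)
  expect_equal(rmsf(tr, 1:5, fit = FALSE)[5], a, tolerance = 1e-9)
  ## global rigid motion is removed by the fit
  set.seed(12)
  frames <- lapply(1:6, function(k) base + matrix(rnorm(15, 0, 0.1), 5, 3))
  movedFrames <- lapply(seq_along(frames), function(k)
    frames[[k]] %*% rotZ(10 * k) + matrix(c(k, 0, 0), 5, 3, byrow = TRUE))
  expect_equal(rmsf(toyTrajectory(movedFrames, m), 1:5, fit = TRUE),
               rmsf(toyTrajectory(frames, m), 1:5, fit = TRUE),
               tolerance = 1e-6)
})

test_that("an ideal alpha helix is labelled H with bondable energies", {
  tpl <- makeTemplate(20, helixSpans = list(c(1, 20)), seed = 3)
  lab <- assignSecondaryStructure(tpl$model)
  expect_true(all(lab[3:17] == "H"))
  ## verify the i -> i+4 Kabsch-Sander energy by the stated formula
  a <- atomData(tpl$model)
  xyz <- atomCoords(tpl$model)
  get <- function(nm, r) xyz[which(!a$ligand & a$resid == r &
                                     trimws(a$name) == nm), ]
  i <- 8L; j <- i + 4L
  Cp <- get("C", j - 1L); Op <- get("O", j - 1L)
  H <- get("N", j) + (Cp - Op) / sqrt(sum((Cp - Op)^2))
  rON <- sqrt(sum((get("O", i) - get("N", j))^2))
  rCH <- sqrt(sum((get("C", i) - H)^2))
  rOH <- sqrt(sum((get("O", i) - H)^2))
  rCN <- sqrt(sum((get("C", i) - get("N", j))^2))
  E <- 0.084 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN) * 332
  expect_lt(E, -0.5)
})

test_that("a four-residue chain cannot contain alpha-helix labels", {
  tpl <- makeTemplate(4, helixSpans = list(c(1, 4)), seed = 3)
  expect_false(any(assignSecondaryStructure(tpl$model) == "H"))
})

test_that("registered antiparallel strands get E_anti labels", {
  lab <- suppressWarnings(assignSecondaryStructure(antiparallelSheet()))
  expect_gte(sum(lab == "E_anti"), 4L)
})

test_that("residues missing backbone atoms fall back to coil", {
  m <- tinyStructure()   # CA/CB only, no N/C/O
  expect_warning(lab <- assignSecondaryStructure(m), "missing backbone")
  expect_true(all(lab == "C"))
})

test_that("secondary-structure fractions form a probability vector", {
  tpl <- defaultTemplate(5L)
  spec <- synthSpec(nVariants = 1L, framesPerTraj = 5L, seed = 5L)
  v <- makeVariantLibrary(spec, tpl$sequence)[[1]]
  tr <- simulateReplicates(v, tpl$model, spec)[[1]]
  fr <- ssFractions(tr)
  expect_equal(unname(rowSums(fr$perFrame)), rep(1, 5), tolerance = 1e-12)
  expect_true(all(fr$perFrame >= 0))
  ## the static ideal template: h_alpha fraction = helix interior / length
  lab <- assignSecondaryStructure(tpl$model)
  frozen <- toyTrajectory(list(atomCoords(tpl$model)), tpl$model)
  expect_equal(ssFractions(frozen)$mean[["h_alpha"]],
               mean(lab == "H"))
})

test_that("an isolated extended chain is all coil", {
  ## a single extended strand has no hydrogen-bond partners and no bends
  tpl <- makeTemplate(8, sheetSpans = list(c(1, 8)), seed = 19)
  frozen <- toyTrajectory(list(atomCoords(tpl$model)), tpl$model)
  fr <- ssFractions(frozen)$mean
  expect_equal(unname(fr[["coil"]]), 1, tolerance = 1e-12)
  expect_equal(sum(fr), 1, tolerance = 1e-12)
})

test_that("helix content decreases with perturbation amplitude", {
  tpl <- makeTemplate(24, helixSpans = list(c(1, 24)), seed = 3)
  base <- atomCoords(tpl$model)
  set.seed(31)
  amps <- runif(200, 0, 1.2)
  hfrac <- vapply(amps, function(a) {
    lab <- assignSecondaryStructure(
      tpl$model, frame = base + matrix(rnorm(length(base), 0, a),
                                       nrow(base), 3))
    mean(lab == "H")
  }, 0)
  expect_lt(cor(amps, hfrac, method = "spearman"), 0)
})

test_that("the MD feature block has 32 replicate-order-invariant columns", {
  tpl <- defaultTemplate(2L)
  site <- defineBindingSite(tpl$model)
  spec <- synthSpec(nVariants = 1L, framesPerTraj = 6L, replicates = 3L,
                    seed = 2L)
  v <- makeVariantLibrary(spec, tpl$sequence)[[1]]
  trajs <- simulateReplicates(v, tpl$model, spec)
  blk <- mdFeatureBlock(trajs, tpl$model, site)
  expect_length(blk, 32L)
  expect_true(all(startsWith(names(blk), "MD:")))
  expect_equal(mdFeatureBlock(rev(trajs), tpl$model, site), blk)
  ## frozen replicates: all RMSD features and stds vanish
  frozen <- lapply(1:2, function(k)
    toyTrajectory(list(atomCoords(tpl$model), atomCoords(tpl$model)),
                  tpl$model))
  fblk <- mdFeatureBlock(frozen, tpl$model, site)
  expect_equal(unname(fblk[grepl("rmsd", names(fblk))]), rep(0, 12),
               tolerance = 1e-9)
  expect_equal(unname(fblk[grepl("_std$", names(fblk)) &
                             grepl("rog", names(fblk))]),
               rep(0, 6), tolerance = 1e-12)
})
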