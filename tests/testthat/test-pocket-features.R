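test_that("binding-site definition uses an inclusive 3.5 A cutoff", {
  ## ligand exactly 3.5 A from residue 1's nearest atom -> included
  expect_true(1L %in% defineBindingSite(tinyStructure(3.5))@residueIds)
  ## at 3.0 A included; residue 2 (3.9 A away) always excluded
  s <- defineBindingSite(tinyStructure(3.0))
  expect_true(1L %in% s@residueIds)
  expect_false(2L %in% s@residueIds)
  ## at 3.6 A nothing is in range -> empty-site error advising a larger
  ## cutoff; same for a ligand far from everything
  expect_error(defineBindingSite(tinyStructure(3.6)), "larger cutoff")
  expect_error(defineBindingSite(tinyStructure(50)), "larger cutoff")
  ## no ligand at all
  noLig <- StructureModel(name = "CA", element = "C", resid = 1L,
                          resname = "ALA", chain = "A",
                          coords = matrix(0, 1, 3), ligand = FALSE)
  expect_error(defineBindingSite(noLig), "no ligand")
})

test_that("single-sphere SASA matches the closed form within 1%", {
  a <- shrakeRupleySasa(matrix(0, 1, 3), radii = 1.7)
  expect_equal(a, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)
  ## two far-apart atoms: no occlusion
  b <- shrakeRupleySasa(rbind(c(0, 0, 0), c(100, 0, 0)), radii = c(1.7, 1.5))
  expect_equal(b[1], 4 * pi * 3.1^2, tolerance = 0.01)
  expect_equal(b[2], 4 * pi * 2.9^2, tolerance = 0.01)
  expect_error(shrakeRupleySasa(matrix(0, 1, 3), radii = -1), "positive")
})

test_that("two-sphere SASA matches a Monte-Carlo oracle within 2%", {
  mcSasa <- function(coords, radii, probe = 1.4, n = 1e6, seed = 99) {
    set.seed(seed)
    R <- radii + probe
    vapply(seq_len(nrow(coords)), function(i) {
      u <- matrix(rnorm(3 * n), n, 3)
      u <- u / sqrt(rowSums(u^2))
      p <- sweep(u * R[i], 2, coords[i, ], `+`)
      other <- setdiff(seq_len(nrow(coords)), i)
      free <- rep(TRUE, n)
      for (j in other)
        free <- free & sqrt(rowSums(sweep(p, 2, coords[j, ])^2)) >= R[j]
      4 * pi * R[i]^2 * mean(free)
    }, 0)
  }
  set.seed(14)
  for (k in 1:5) {
    d <- runif(1, 1.0, 5.5)
    coords <- rbind(c(0, 0, 0), c(d, 0, 0))
    radii <- runif(2, 1.2, 2.0)
    got <- shrakeRupleySasa(coords, radii)
    want <- mcSasa(coords, radii, n = 2e5)
    expect_equal(got, want, tolerance = 0.02)
  }
})

test_that("pocket geometry reproduces closed-form volumes", {
  site <- new("BindingSite", residueIds = 1L, atomIndices = 1:4,
              cutoff = 3.5)
  tetra <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
                 c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  g <- pocketGeometry(site, tetra)
  expect_equal(g[["volume"]], 1 / (6 * sqrt(2)), tolerance = 1e-10)
  expect_equal(g[["length"]], 1, tolerance = 1e-10)
  ## collinear points: zero volume with a warning, length = span
  line <- cbind(c(0, 1, 2, 5), 0, 0)
  expect_warning(gl <- pocketGeometry(site, line), "volume")
  expect_equal(gl[["volume"]], 0)
  expect_equal(gl[["length"]], 5)
})

test_that("pocket geometry is invariant under rigid transforms", {
  set.seed(15)
  X <- matrix(rnorm(30, sd = 3), 10, 3)
  site <- new("BindingSite", residueIds = 1L, atomIndices = 1:10,
              cutoff = 3.5)
  g1 <- pocketGeometry(site, X)
  R <- randomRotation()
  g2 <- pocketGeometry(site, X %*% R +
                         matrix(c(4, -2, 7), 10, 3, byrow = TRUE))
  expect_equal(g2, g1, tolerance = 1e-8)
})

test_that("pocket chemistry classifies residues at pH 8", {
  site <- new("BindingSite", residueIds = c(1L, 2L), atomIndices = 1:2,
              cutoff = 3.5)
  ## site of only Ile/Leu: apolar, hydrophobicity = mean KD value
  ch <- pocketChemistry(site, "ILAAAA")
  expect_equal(ch$nPolar, 0L)
  expect_equal(ch$nApolar, 2L)
  expect_equal(ch$hydrophobicityMean, mean(c(4.5, 3.8)))
  ## "DK" site: one positive, one negative, net zero; His uncharged
  ch2 <- pocketChemistry(site, "DKAAAA")
  expect_equal(ch2$nPositive, 1L)
  expect_equal(ch2$nNegative, 1L)
  expect_equal(ch2$netCharge, 0)
  ch3 <- pocketChemistry(site, "HHAAAA")
  expect_equal(ch3$netCharge, 0)
  expect_equal(ch3$nPolar, 2L)
})

test_that("pocket occupancy is 1 for frozen trajectories and in [0,1]", {
  tpl <- defaultTemplate(2L)
  site <- defineBindingSite(tpl$model)
  frozen <- toyTrajectory(list(atomCoords(tpl$model),
                               atomCoords(tpl$model)), tpl$model)
  occ <- pocketOccupancy(site, frozen)
  expect_equal(unname(occ), rep(1, length(site@residueIds)))
  ## drive one site residue 10 A away in half the frames -> occupancy 0.5
  a <- atomData(tpl$model)
  res <- site@residueIds[1]
  moved <- atomCoords(tpl$model)
  moved[a$resid == res & !a$ligand, ] <-
    moved[a$resid == res & !a$ligand, ] + 10
  tr <- toyTrajectory(list(atomCoords(tpl$model), moved,
                           atomCoords(tpl$model), moved), tpl$model)
  occ2 <- pocketOccupancy(site, tr)
  expect_equal(unname(occ2[as.character(res)]), 0.5)
  expect_true(all(occ2 >= 0 & occ2 <= 1))
})

test_that("normalized B-factors are z-scores of (8pi^2/3) RMSF^2", {
  tpl <- defaultTemplate(2L)
  site <- defineBindingSite(tpl$model)
  base <- atomCoords(tpl$model)
  ## frozen: degenerate, all zeros
  frozen <- toyTrajectory(list(base, base), tpl$model)
  expect_equal(unname(normalizedBfactor(site, frozen)),
               rep(0, length(site@residueIds)))
  ## one residue fluctuating twice as much gets the largest z-score
  a <- atomData(tpl$model)
  hot <- site@residueIds[2]
  set.seed(16)
  frames <- lapply(1:30, function(k) {
    f <- base + matrix(rnorm(length(base), 0, 0.05), nrow(base), 3)
    sel <- a$resid == hot & !a$ligand
    f[sel, ] <- base[sel, ] + matrix(rnorm(sum(sel) * 3, 0, 0.6),
                                     sum(sel), 3)
    f
  })
  z <- normalizedBfactor(site, toyTrajectory(frames, tpl$model))
  expect_equal(names(which.max(z)), as.character(hot))
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sqrt(mean((z - mean(z))^2)), 1, tolerance = 1e-10)
})

test_that("the pocket block is 80 columns and 112 with the MD block", {
  tpl <- defaultTemplate(2L)
  site <- defineBindingSite(tpl$model)
  spec <- synthSpec(nVariants = 1L, framesPerTraj = 5L, replicates = 2L,
                    seed = 3L)
  v <- makeVariantLibrary(spec, tpl$sequence)[[1]]
  trajs <- simulateReplicates(v, tpl$model, spec)
  pk <- suppressWarnings(pocketFeatureBlock(site, trajs, v@sequence))
  expect_length(pk, 80L)
  expect_true(all(startsWith(names(pk), "POCKET:")))
  md <- mdFeatureBlock(trajs, tpl$model, site)
  expect_length(c(md, pk), 112L)
  ## frozen trajectory: every replicate-std column is zero
  frozen <- lapply(1:2, function(k)
    toyTrajectory(list(atomCoords(tpl$model), atomCoords(tpl$model)),
                  tpl$model))
  pkf <- suppressWarnings(pocketFeatureBlock(site, frozen, v@sequence))
  stds <- pkf[grepl("_std$", names(pkf))]
  expect_equal(unname(stds), rep(0, length(stds)), tolerance = 1e-12)
})

test_that("sites are padded or truncated to the slot count with a warning", {
  tpl <- defaultTemplate(2L)
  site <- defineBindingSite(tpl$model)
  spec <- synthSpec(nVariants = 1L, framesPerTraj = 4L, replicates = 1L,
                    seed = 3L)
  v <- makeVariantLibrary(spec, tpl$sequence)[[1]]
  trajs <- simulateReplicates(v, tpl$model, spec)
  if (length(site@residueIds) != 16L)
    expect_warning(pocketFeatureBlock(site, trajs, v@sequence), "slots")
  pk <- pocketFeatureBlock(site, trajs, v@sequence, slots = 30L,
                           warnSlots = FALSE)
  ## widths grow with the slot count: 10 + 4*slots + 6
  expect_length(pk, 10L + 4L * 30L + 6L)
})

test_that("the C++ hull agrees with the independent R implementation", {
  set.seed(17)
  for (k in 1:10) {
    X <- matrix(rnorm(sample(8:60, 1) * 3, sd = 4), ncol = 3)
    rhull <- fcaflow:::convexHull3d(X)
    chull <- fcaflow:::cppPocketGeometry(X)
    expect_equal(chull$volume, rhull$volume,
                 tolerance = 1e-9)
  }
})
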