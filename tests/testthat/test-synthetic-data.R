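test_that("template construction is seeded and validates spans", {
  t5 <- makeTemplate(5, seed = 1L)
  expect_s4_class(t5$model, "StructureModel")
  expect_equal(nchar(t5$sequence), 5L)
  ## 4 backbone atoms per residue plus ligand atoms
  expect_gte(nAtoms(t5$model), 4L * 5L + 1L)
  expect_true(validObject(t5$model))
  ## same seed, identical coordinates; different seed differs
  expect_equal(atomCoords(makeTemplate(5, seed = 1L)$model),
               atomCoords(t5$model))
  expect_false(identical(atomCoords(makeTemplate(5, seed = 2L)$model),
                         atomCoords(t5$model)))
  expect_error(makeTemplate(10, helixSpans = list(c(1, 6)),
                            turnSpans = list(c(5, 8))), "overlap")
  expect_error(makeTemplate(10, helixSpans = list(c(1, 12))), "span")
})

test_that("helix spans are assigned as helix by the package's own DSSP", {
  tpl <- makeTemplate(16, helixSpans = list(c(1, 16)), seed = 4L)
  lab <- assignSecondaryStructure(tpl$model)
  interior <- lab[3:13]
  expect_true(all(interior == "H"))
})

test_that("the template ligand creates a non-empty binding site", {
  tpl <- defaultTemplate(1L)
  site <- defineBindingSite(tpl$model)
  expect_gte(length(site@residueIds), 3L)
  ## ligand anchored near its designated contacts
  expect_true(any(tpl$ligandContacts %in% site@residueIds))
})

test_that("variant libraries stay on hot positions and include variant 0", {
  spec <- synthSpec(nVariants = 40L, seed = 9L)
  tpl <- defaultTemplate(9L)
  lib <- makeVariantLibrary(spec, tpl$sequence)
  expect_length(lib, 40L)
  expect_equal(lib[[1]]@id, "v000")
  expect_equal(nrow(lib[[1]]@mutations), 0L)
  counts <- vapply(lib, function(v) nrow(v@mutations), 1L)
  expect_true(all(counts <= spec@maxMutations))
  pos <- unlist(lapply(lib, function(v) v@mutations$pos))
  expect_true(all(pos %in% spec@hotPositions))
  ## fraction of positions ever mutated bounded by the hot fraction
  occ <- mutationSiteOccurrence(lib)
  expect_lte(occ$fractionMutated, 30 / 101)
  ## determinism
  lib2 <- makeVariantLibrary(spec, tpl$sequence)
  expect_equal(vapply(lib2, function(v) v@sequence, ""),
               vapply(lib, function(v) v@sequence, ""))
  ## zero mutations: all sequences equal the template
  spec0 <- synthSpec(nVariants = 5L, maxMutations = 0L, seed = 1L)
  lib0 <- makeVariantLibrary(spec0, tpl$sequence)
  expect_true(all(vapply(lib0, function(v) v@sequence, "") ==
                    tpl$sequence))
  ## hot position beyond the sequence errors
  specBad <- synthSpec(nVariants = 3L, hotPositions = c(5L, 999L))
  expect_error(makeVariantLibrary(specBad, tpl$sequence), "beyond")
})

test_that("zero flexibility freezes the trajectory", {
  tpl <- defaultTemplate(1L)
  spec <- synthSpec(nVariants = 1L, framesPerTraj = 4L, replicates = 2L,
                    flexibilityBase = 0, seed = 1L)
  v <- makeVariantLibrary(spec, tpl$sequence)[[1]]
  trs <- simulateReplicates(v, tpl$model, spec)
  for (tr in trs) {
    for (k in 1:4)
      expect_equal(frameArray(tr)[k, , ], atomCoords(tpl$model))
  }
  sel <- atomSelection(tpl$model, "calpha")
  expect_equal(rmsdSeries(trs[[1]], tpl$model, sel), rep(0, 4),
               tolerance = 1e-12)
})

test_that("replicates share atoms but differ by seed stream", {
  tpl <- defaultTemplate(1L)
  spec <- synthSpec(nVariants = 1L, framesPerTraj = 5L, replicates = 3L,
                    seed = 2L)
  v <- makeVariantLibrary(spec, tpl$sequence)[[1]]
  trs <- simulateReplicates(v, tpl$model, spec)
  expect_length(trs, 3L)
  expect_equal(unique(vapply(trs, nAtoms, 1L)), nAtoms(tpl$model))
  expect_false(identical(frameArray(trs[[1]]), frameArray(trs[[2]])))
  ## bit-identical on rerun with the same spec
  trs2 <- simulateReplicates(v, tpl$model, spec)
  expect_identical(frameArray(trs[[1]]), frameArray(trs2[[1]]))
  expect_error(simulateReplicates(v, tpl$model,
                                  synthSpec(nVariants = 1L,
                                            framesPerTraj = 1L)),
               ">= 2")
})

test_that("the fluctuation generator matches its closed-form RMSF", {
  ## one free atom with amplitude a and rho = 0: stationary RMSF = a sqrt(3)
  tpl <- makeTemplate(5, seed = 6L)
  a <- 0.5
  amp <- rep(0, nAtoms(tpl$model))
  amp[2] <- a
  spec <- synthSpec(nVariants = 1L, framesPerTraj = 10000L,
                    replicates = 1L, rho = 0, seed = 3L)
  v <- makeVariantLibrary(synthSpec(nVariants = 1L, seed = 3L,
                                    hotPositions = 2L),
                          tpl$sequence)[[1]]
  tr <- simulateReplicates(v, tpl$model, spec, amplitudeOverride = amp)[[1]]
  f <- rmsf(tr, seq_len(nAtoms(tpl$model)), fit = FALSE)
  expect_equal(f[2], a * sqrt(3), tolerance = 0.05)
  expect_equal(max(f[-2]), 0, tolerance = 1e-12)
})

test_that("mutated and loop positions fluctuate more than helix core", {
  tpl <- defaultTemplate(1L)
  spec <- synthSpec(nVariants = 8L, framesPerTraj = 60L, replicates = 1L,
                    seed = 4L)
  lib <- makeVariantLibrary(spec, tpl$sequence)
  mutated <- Find(function(v) nrow(v@mutations) >= 2, lib)
  expect_false(is.null(mutated))
  tr <- simulateReplicates(mutated, tpl$model, spec)[[1]]
  f <- rmsf(tr, seq_len(nAtoms(tpl$model)), fit = FALSE)
  a <- atomData(tpl$model)
  mutRes <- mutated@mutations$pos
  helixCore <- setdiff(10:26, c(mutRes - 1, mutRes, mutRes + 1))
  fMut <- mean(f[a$resid %in% mutRes & !a$ligand])
  fCore <- mean(f[a$resid %in% helixCore & !a$ligand])
  expect_gt(fMut, fCore)
})

test_that("planted responses are linear in standardized features", {
  set.seed(61)
  m <- cbind("MD:ss_h_alpha_mean" = runif(50),
             "MD:ss_turn_mean" = runif(50),
             "SEQ:gravy" = rnorm(50))
  ## noiseless single-coefficient response is perfectly rank-correlated
  spec1 <- synthSpec(nVariants = 50L, noiseSd = 0,
                     effectCoefs = c("MD:ss_h_alpha_mean" = 1), seed = 5L)
  r1 <- plantResponse(m, spec1)
  expect_equal(cor(r1$fca, m[, 1], method = "spearman"), 1)
  expect_equal(r1$fca, r1$linear)
  ## all-zero coefficients: pure noise with the requested SD
  spec0 <- synthSpec(nVariants = 50L, noiseSd = 0.5,
                     effectCoefs = c("MD:ss_h_alpha_mean" = 0), seed = 5L)
  r0 <- plantResponse(m, spec0)
  expect_equal(r0$linear, rep(0, 50))
  expect_gt(sd(r0$fca), 0.3)
  ## missing column names the offender
  specBad <- synthSpec(effectCoefs = c("MD:nope" = 1))
  expect_error(plantResponse(m, specBad), "MD:nope")
  ## determinism under the spec seed
  expect_equal(plantResponse(m, spec1)$fca, r1$fca)
})

test_that("spec validation rejects impossible study conditions", {
  expect_error(synthSpec(nVariants = 0L), "nVariants")
  expect_error(synthSpec(noiseSd = -1), "noiseSd")
  expect_error(synthSpec(rho = 1), "rho")
  expect_error(synthSpec(replicates = 0L), "replicates")
})

test_that("study export writes the declared plain-text artefacts", {
  dir <- withr::local_tempdir()
  spec <- synthSpec(nVariants = 3L, framesPerTraj = 4L, replicates = 1L,
                    seed = 12L)
  st <- suppressMessages(buildStudyFeatureTable(spec))
  exportStudy(st, dir)
  expect_true(file.exists(file.path(dir, "template.pdb")))
  expect_true(file.exists(file.path(dir, "variants.fasta")))
  expect_true(file.exists(file.path(dir, "variants.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))
  ft <- readFeatureTable(file.path(dir, "features.csv"))
  expect_equal(dim(ft), dim(st$table))
  seqs <- readFasta(file.path(dir, "variants.fasta"))
  expect_length(seqs, 3L)
  expect_equal(unname(seqs[1]), st$variants[[1]]@sequence)
})
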