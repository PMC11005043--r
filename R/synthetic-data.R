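#' @include AllClasses.R utils.R sequence-layer.R trajectory-features.R
NULL

#' Construct a SynthSpec
#'
#' Study conditions for the synthetic generator.  Defaults emulate the
#' experimental library the pipeline targets: a 101-residue template, 30
#' hot-spot positions (29.7\% of positions ever mutable), variants carrying
#' 0--9 co-occurring substitutions with a truncated-Poisson count of mean
#' 3.4 (about a quarter of variants at five or more mutations, mean pairwise
#' identity above 90\%), five replicate trajectories of 101 frames (10 ns at
#' 100 ps spacing), and a planted response
#' \code{FCA = +1 z(h_alpha) - 1 z(turn) + noise} with SD 0.5.
#'
#' @param nVariants library size including the unmutated template (variant 0).
#' @param hotPositions 1-based mutable positions; the default 30 positions
#'   sit in the template's helix and turn regions.
#' @param maxMutations,meanMutations truncated-Poisson mutation count.
#' @param replicates,framesPerTraj,dtPs trajectory geometry.
#' @param flexibilityBase baseline per-coordinate fluctuation SD
#'   (\enc{Å}{Angstrom}).
#' @param rho AR(1) mean-reversion coefficient in [0, 1).
#' @param mutationScale,loopScale amplitude multipliers at mutated positions
#'   and in loop regions.
#' @param effectCoefs named planted-response weights on feature columns.
#' @param noiseSd response noise SD.
#' @param seed integer seed; identical specs give bit-identical output.
#' @return a \linkS4class{SynthSpec}.
#' @export
synthSpec <- function(nVariants = 312L,
                      hotPositions = defaultHotPositions(),
                      maxMutations = 9L, meanMutations = 3.4,
                      replicates = 5L, framesPerTraj = 101L, dtPs = 100,
                      flexibilityBase = 0.15, rho = 0.9,
                      mutationScale = 3, loopScale = 1.5,
                      effectCoefs = c("MD:ss_h_alpha_mean" = 1,
                                      "MD:ss_turn_mean" = -1),
                      noiseSd = 0.5, seed = 1L) {
  new("SynthSpec", nVariants = as.integer(nVariants),
      hotPositions = as.integer(hotPositions),
      maxMutations = as.integer(maxMutations),
      meanMutations = as.numeric(meanMutations),
      replicates = as.integer(replicates),
      framesPerTraj = as.integer(framesPerTraj), dtPs = as.numeric(dtPs),
      flexibilityBase = as.numeric(flexibilityBase), rho = as.numeric(rho),
      mutationScale = as.numeric(mutationScale),
      loopScale = as.numeric(loopScale),
      effectCoefs = effectCoefs, noiseSd = as.numeric(noiseSd),
      seed = as.integer(seed))
}

#' Default hot-spot positions of the synthetic template
#'
#' Thirty 1-based positions over the 101-residue default template: 18 inside
#' its two helices and 12 inside its beta-turn segments, so that mutations
#' perturb helix and turn content semi-independently.
#' @return integer vector of length 30.
#' @export
defaultHotPositions <- function() {
  as.integer(c(10, 12, 14, 16, 18, 20, 22, 24, 26,
               46, 48, 50, 52, 54, 56, 58, 60, 62,
               33, 34, 39, 40, 69, 70, 75, 76, 82, 83, 89, 90))
}

## Ideal backbone internal geometry (lengths in Angstrom, angles in deg).
BB_GEOM <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
                ang_ca_c_o = 120.8)

spanMatrix <- function(spans) {
  if (!length(spans)) return(matrix(0L, 0L, 2L))
  m <- do.call(rbind, lapply(spans, function(s) as.integer(s[1:2])))
  m
}

inSpans <- function(pos, spans) {
  m <- spanMatrix(spans)
  if (!nrow(m)) return(rep(FALSE, length(pos)))
  vapply(pos, function(p) any(p >= m[, 1L] & p <= m[, 2L]), NA)
}

#' Build an idealized template structure and sequence
#'
#' Constructs a backbone (N, CA, C, O per residue) from ideal internal
#' geometry: helix spans at (phi, psi) = (-57, -47), sheet spans at
#' (-119, 113), four-residue turn spans with type-I beta-turn dihedrals, and
#' randomized coil dihedrals elsewhere.  A small peptide-like ligand
#' (residue \code{"LIG"}) is placed within 3.5 \enc{Å}{Angstrom} of at least
#' three designated residues so that a non-empty binding site exists.
#'
#' @param length number of residues (>= 3).
#' @param helixSpans,sheetSpans,turnSpans lists of 1-based inclusive
#'   \code{c(start, end)} intervals within the chain; spans must not
#'   overlap.
#' @param seed integer seed (same seed, same coordinates).
#' @param ligandContacts residues the ligand is anchored to (default: three
#'   residues around the chain midpoint).
#' @param sequence optional fixed sequence; random (seeded) when NULL.
#' @return list with \code{model} (\linkS4class{StructureModel}),
#'   \code{sequence} and the span lists.
#' @export
makeTemplate <- function(length, helixSpans = list(), sheetSpans = list(),
                         turnSpans = list(), seed = 1L,
                         ligandContacts = NULL, sequence = NULL) {
  stopifnot(length >= 3L)
  all_spans <- rbind(spanMatrix(helixSpans), spanMatrix(sheetSpans),
                     spanMatrix(turnSpans))
  if (nrow(all_spans)) {
    if (any(all_spans < 1L) || any(all_spans > length) ||
        any(all_spans[, 1L] > all_spans[, 2L]))
      stop("span outside [1, length]")
    covered <- unlist(apply(all_spans, 1L, function(s) s[1L]:s[2L],
                            simplify = FALSE))
    if (anyDuplicated(covered)) stop("overlapping spans")
  }
  withSeed(seed, {
    pos <- seq_len(length)
    phi <- runif(length, -150, -60)      # coil
    psi <- runif(length, 60, 170)
    hel <- inSpans(pos, helixSpans)
    phi[hel] <- -57; psi[hel] <- -47
    sht <- inSpans(pos, sheetSpans)
    phi[sht] <- -119; psi[sht] <- 113
    for (s in turnSpans) {               # type-I beta turn at s[1]..s[1]+3
      i <- s[1L]
      if (i + 2L <= length) {
        phi[i + 1L] <- -60; psi[i + 1L] <- -30
        phi[i + 2L] <- -90; psi[i + 2L] <- 0
      }
    }
    if (is.null(sequence)) {
      ## proline avoided: it carries no amide H for hydrogen bonding
      sequence <- paste(sample(setdiff(AA_LETTERS, "P"), length,
                               replace = TRUE), collapse = "")
    }
    aa <- checkSequence(sequence)
    if (length(aa) != length) stop("sequence length mismatch")
    ## NeRF chain build
    N <- CA <- C <- O <- matrix(0, length, 3L)
    N[1L, ] <- c(0, 0, 0)
    CA[1L, ] <- c(BB_GEOM$n_ca, 0, 0)
    C[1L, ] <- placeAtom(c(-1, 1, 0), N[1L, ], CA[1L, ], BB_GEOM$ca_c,
                         BB_GEOM$ang_n_ca_c, phi[1L])
    for (i in seq_len(length)) {
      if (i > 1L) {
        N[i, ] <- placeAtom(N[i - 1L, ], CA[i - 1L, ], C[i - 1L, ],
                            BB_GEOM$c_n, BB_GEOM$ang_ca_c_n, psi[i - 1L])
        CA[i, ] <- placeAtom(CA[i - 1L, ], C[i - 1L, ], N[i, ],
                             BB_GEOM$n_ca, BB_GEOM$ang_c_n_ca, 180)
        C[i, ] <- placeAtom(C[i - 1L, ], N[i, ], CA[i, ],
                            BB_GEOM$ca_c, BB_GEOM$ang_n_ca_c, phi[i])
      }
      psi_eff <- if (i < length) psi[i] else 180
      O[i, ] <- placeAtom(N[i, ], CA[i, ], C[i, ], BB_GEOM$c_o,
                          BB_GEOM$ang_ca_c_o, psi_eff + 180)
    }
    if (is.null(ligandContacts)) {
      mid <- floor(length / 2)
      ligandContacts <- unique(pmin(pmax(c(mid - 4L, mid, mid + 4L), 1L),
                                    length))
    }
    centroid <- colMeans(CA)
    lig <- t(vapply(ligandContacts, function(r) {
      CA[r, ] + 3.0 * unitv(CA[r, ] - centroid)
    }, numeric(3L)))
    ## two linker atoms between consecutive anchors keep the ligand compact
    if (nrow(lig) >= 2L) {
      mids <- (lig[-nrow(lig), , drop = FALSE] +
                 lig[-1L, , drop = FALSE]) / 2
      lig <- rbind(lig, mids)
    }
    nl <- nrow(lig)
    model <- StructureModel(
      name = c(rep(c("N", "CA", "C", "O"), length), paste0("C", seq_len(nl))),
      element = c(rep(c("N", "C", "C", "O"), length), rep("C", nl)),
      resid = c(rep(pos, each = 4L), rep(length + 1L, nl)),
      resname = c(rep(AA_THREE[aa], each = 4L), rep("LIG", nl)),
      chain = c(rep("A", 4L * length), rep("A", nl)),
      coords = {
        prot <- matrix(0, 4L * length, 3L)
        prot[seq(1L, by = 4L, length.out = length), ] <- N
        prot[seq(2L, by = 4L, length.out = length), ] <- CA
        prot[seq(3L, by = 4L, length.out = length), ] <- C
        prot[seq(4L, by = 4L, length.out = length), ] <- O
        rbind(prot, lig)
      },
      ligand = c(rep(FALSE, 4L * length), rep(TRUE, nl)))
    list(model = model, sequence = sequence, helixSpans = helixSpans,
         sheetSpans = sheetSpans, turnSpans = turnSpans,
         ligandContacts = ligandContacts)
  })
}

#' The default 101-residue study template
#'
#' Two alpha helices (residues 8--28 and 44--64) and six type-I beta-turn
#' segments in the loops, with the ligand anchored near the middle of the
#' second helix.  Built deterministically from \code{seed}.
#'
#' @param seed integer seed.
#' @return as \code{\link{makeTemplate}}.
#' @export
defaultTemplate <- function(seed = 1L) {
  makeTemplate(101L,
               helixSpans = list(c(8, 28), c(44, 64)),
               turnSpans = list(c(32, 35), c(38, 41), c(68, 71),
                                c(74, 77), c(81, 84), c(88, 91)),
               seed = seed,
               ligandContacts = c(48L, 52L, 56L, 60L))
}

## Truncated-Poisson mutation count in 0..maxMutations.
rMutationCount <- function(n, mean, maxMutations) {
  k <- stats::rpois(n, mean)
  while (any(k > maxMutations))
    k[k > maxMutations] <- stats::rpois(sum(k > maxMutations), mean)
  k
}

#' Generate an epPCR-like variant library
#'
#' Draws, for each variant, a truncated-Poisson number of substitutions at
#' the hot-spot positions only (mutation strings in \code{"S38T"} form); the
#' unmutated template is always included as variant 0.
#'
#' @param spec a \linkS4class{SynthSpec}.
#' @param templateSequence the template's amino-acid string.
#' @return list of \linkS4class{VariantRecord} (FCA initialized to 0; see
#'   \code{\link{plantResponse}}).
#' @export
makeVariantLibrary <- function(spec, templateSequence) {
  aa <- checkSequence(templateSequence)
  if (!length(spec@hotPositions)) stop("hotPositions must be non-empty")
  if (any(spec@hotPositions > length(aa)))
    stop("hot position beyond sequence length")
  withSeed(childSeed(spec@seed, 1L), {
    n <- spec@nVariants
    counts <- c(0L, rMutationCount(n - 1L, spec@meanMutations,
                                   min(spec@maxMutations,
                                       length(spec@hotPositions))))
    lapply(seq_len(n), function(i) {
      k <- counts[i]
      muts <- if (k == 0L)
        data.frame(ref = character(), pos = integer(), alt = character(),
                   stringsAsFactors = FALSE)
      else {
        p <- sort(sample(spec@hotPositions, k))
        data.frame(ref = aa[p], pos = p,
                   alt = vapply(aa[p], function(r)
                     sample(setdiff(AA_LETTERS, c(r, "P")), 1L), ""),
                   stringsAsFactors = FALSE)
      }
      new("VariantRecord", id = sprintf("v%03d", i - 1L), mutations = muts,
          sequence = applyMutations(templateSequence, muts),
          activityA = NA_real_, activityB = NA_real_, fca = 0)
    })
  })
}

#' Simulate replicate toy trajectories for one variant
#'
#' Each frame is the template plus a stationary mean-reverting Gaussian
#' deviation, updated per coordinate as
#' \code{d[t+1] = rho d[t] + eta}, \code{eta ~ N(0, a^2 (1 - rho^2))}, so
#' the stationary per-coordinate SD equals the per-atom amplitude \code{a}.
#' The amplitude is \code{flexibilityBase}, multiplied by \code{loopScale}
#' in loop regions (template residues assigned coil/bend) and by
#' \code{mutationScale} at mutated positions (plus/minus one residue).
#' Replicates differ only by their seed streams.
#'
#' @param variant a \linkS4class{VariantRecord}.
#' @param template the template \linkS4class{StructureModel}.
#' @param spec a \linkS4class{SynthSpec}.
#' @param seed base seed for this variant (default derived from the spec).
#' @param amplitudeOverride optional per-atom amplitude vector replacing the
#'   construction above (used for generator-statistics checks).
#' @return list of \code{spec@replicates} \linkS4class{TrajectoryData}.
#' @export
simulateReplicates <- function(variant, template, spec,
                               seed = childSeed(spec@seed, 2L),
                               amplitudeOverride = NULL) {
  if (spec@framesPerTraj < 2L) stop("framesPerTraj must be >= 2")
  a <- atomData(template)
  n <- nAtoms(template)
  if (is.null(amplitudeOverride)) {
    amp <- rep(spec@flexibilityBase, n)
    labels <- suppressWarnings(assignSecondaryStructure(template))
    loopRes <- as.integer(names(labels)[labels %in% c("C", "S")])
    amp[a$resid %in% loopRes & !a$ligand] <-
      spec@flexibilityBase * spec@loopScale
    if (nrow(variant@mutations)) {
      mutRes <- unique(unlist(lapply(variant@mutations$pos,
                                     function(p) (p - 1L):(p + 1L))))
      amp[a$resid %in% mutRes & !a$ligand] <-
        spec@flexibilityBase * spec@mutationScale
    }
  } else {
    stopifnot(length(amplitudeOverride) == n)
    amp <- amplitudeOverride
  }
  base <- atomCoords(template)
  F <- spec@framesPerTraj
  rho <- spec@rho
  innov <- amp * sqrt(1 - rho^2)
  lapply(seq_len(spec@replicates), function(r) {
    withSeed(childSeed(seed, r), {
      frames <- array(0, c(F, n, 3L))
      dev <- matrix(stats::rnorm(n * 3L, 0, amp), n, 3L)
      for (t in seq_len(F)) {
        frames[t, , ] <- base + dev
        dev <- dev * rho + matrix(stats::rnorm(n * 3L, 0, innov), n, 3L)
      }
      TrajectoryData(frames, spec@dtPs, template)
    })
  })
}

#' Plant a linear FCA response on observed features
#'
#' \code{FCA_i = sum_j coef_j z(feature_ij) + eps_i} with
#' \code{eps ~ N(0, noiseSd^2)} and per-column standardization \code{z};
#' the ground-truth coefficients are returned alongside the response so
#' recovery experiments can check them.
#'
#' @param features a \linkS4class{FeatureTable} or a variants x features
#'   numeric matrix with named columns.
#' @param spec a \linkS4class{SynthSpec} (uses \code{effectCoefs},
#'   \code{noiseSd}, \code{seed}).
#' @return list with \code{fca}, \code{coefficients}, \code{linear} (the
#'   noise-free part) and \code{noiseSd}.
#' @export
plantResponse <- function(features, spec) {
  m <- if (is(features, "FeatureTable")) featureMatrix(features)
       else as.matrix(features)
  coefs <- spec@effectCoefs
  missing <- setdiff(names(coefs), colnames(m))
  if (length(missing))
    stop("feature column(s) not present: ", paste(missing, collapse = ", "))
  z <- vapply(names(coefs), function(j) {
    x <- m[, j]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) rep(0, nrow(m)) else (x - mean(x)) / s
  }, numeric(nrow(m)))
  linear <- as.numeric(z %*% coefs)
  eps <- withSeed(childSeed(spec@seed, 777L),
                  stats::rnorm(nrow(m), 0, spec@noiseSd))
  list(fca = linear + eps, coefficients = coefs, linear = linear,
       noiseSd = spec@noiseSd)
}
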