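#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' StructureModel: a single protein conformation
#'
#' Holds per-atom metadata and Cartesian coordinates (\enc{Å}{Angstrom}) for
#' one structure: the reference geometry used for superposition, binding-site
#' definition and as the template of synthetic trajectories.  Residue ids are
#' 1-based and preserved exactly as read from file; they are never
#' renumbered by I/O.
#'
#' @slot atoms data.frame with columns \code{name}, \code{element},
#'   \code{resid} (1-based integer), \code{resname} (3-letter code),
#'   \code{chain} and logical \code{ligand}.
#' @slot coords numeric N x 3 matrix of coordinates in \enc{Å}{Angstrom}.
#'
#' @export
setClass("StructureModel",
  representation(atoms = "data.frame", coords = "matrix"),
  validity = function(object) {
    msg <- character()
    need <- c("name", "element", "resid", "resname", "chain", "ligand")
    if (!all(need %in% names(object@atoms)))
      msg <- c(msg, paste("atoms must have columns:",
                          paste(need, collapse = ", ")))
    else {
      n <- nrow(object@atoms)
      if (nrow(object@coords) != n || ncol(object@coords) != 3L)
        msg <- c(msg, "coords must be an N x 3 matrix matching atoms")
      if (!all(is.finite(object@coords)))
        msg <- c(msg, "coords must be finite")
      ## residue ids non-decreasing within each chain (protein atoms)
      for (ch in unique(object@atoms$chain)) {
        ri <- object@atoms$resid[object@atoms$chain == ch &
                                   !object@atoms$ligand]
        if (length(ri) > 1L && any(diff(ri) < 0))
          msg <- c(msg, sprintf("residue ids decrease within chain '%s'", ch))
      }
    }
    if (length(msg)) msg else TRUE
  })

#' TrajectoryData: one replicate trajectory of one variant
#'
#' An ordered series of conformations of the same atom set as a reference
#' \linkS4class{StructureModel}, with the frame spacing in picoseconds taken
#' from configuration (neither supported on-disk format carries reliable
#' time metadata).
#'
#' @slot frames numeric array F x N x 3 (\enc{Å}{Angstrom}).
#' @slot dtPs frame spacing in ps, > 0.
#' @slot model the reference \linkS4class{StructureModel} supplying atom
#'   metadata.
#'
#' @export
setClass("TrajectoryData",
  representation(frames = "array", dtPs = "numeric", model = "StructureModel"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@frames)
    if (length(d) != 3L || d[3L] != 3L)
      msg <- c(msg, "frames must be an F x N x 3 array")
    else {
      if (d[1L] < 1L) msg <- c(msg, "at least one frame required")
      if (d[2L] != nrow(object@model@atoms))
        msg <- c(msg, "frame atom count differs from the reference structure")
    }
    if (length(object@dtPs) != 1L || !is.finite(object@dtPs) ||
        object@dtPs <= 0)
      msg <- c(msg, "dtPs must be a positive scalar")
    if (length(msg)) msg else TRUE
  })

#' VariantRecord: one library member
#'
#' A variant's mutation list (in \code{"S38T"} notation, 1-based positions),
#' full amino-acid sequence and the activity pair / fold-change-in-activity
#' (FCA) response.
#'
#' @slot id variant identifier.
#' @slot mutations data.frame with columns \code{ref}, \code{pos},
#'   \code{alt}.
#' @slot sequence amino-acid string (standard 20-letter alphabet).
#' @slot activityA activity without pre-incubation heating (>= 0; NA when
#'   only FCA is known).
#' @slot activityB activity with pre-incubation heating.
#' @slot fca fold change in activities (finite).
#'
#' @export
setClass("VariantRecord",
  representation(id = "character", mutations = "data.frame",
                 sequence = "character", activityA = "numeric",
                 activityB = "numeric", fca = "numeric"),
  prototype(activityA = NA_real_, activityB = NA_real_, fca = 0),
  validity = function(object) {
    msg <- character()
    if (!all(c("ref", "pos", "alt") %in% names(object@mutations)))
      msg <- c(msg, "mutations needs columns ref, pos, alt")
    if (length(object@fca) != 1L || !is.finite(object@fca))
      msg <- c(msg, "fca must be a finite scalar")
    if (nrow(object@mutations)) {
      p <- object@mutations$pos
      bad <- p < 1L | p > nchar(object@sequence)
      if (any(bad)) msg <- c(msg, "mutation position outside sequence")
      else {
        found <- substring(object@sequence, p, p)
        if (!all(found == object@mutations$alt))
          msg <- c(msg, "sequence inconsistent with mutation list")
      }
    }
    if (length(msg)) msg else TRUE
  })

#' BindingSite: the fixed binding-site definition
#'
#' Residues of the template with any heavy atom within \code{cutoff}
#' \enc{Å}{Angstrom} (inclusive) of any ligand heavy atom.  Defined once on
#' the template and held fixed across all frames and variants.
#'
#' @slot residueIds 1-based residue ids of site residues (sorted).
#' @slot atomIndices indices (into the template atom table) of the site's
#'   protein heavy atoms.
#' @slot cutoff distance cutoff in \enc{Å}{Angstrom} (default 3.5).
#'
#' @export
setClass("BindingSite",
  representation(residueIds = "integer", atomIndices = "integer",
                 cutoff = "numeric"),
  validity = function(object) {
    if (length(object@residueIds) < 1L) "binding site is empty" else TRUE
  })

#' SynthSpec: synthetic study conditions
#'
#' Parameters of the synthetic variant library, replicate toy trajectories
#' and planted FCA response.  The defaults are the study conditions the
#' pipeline is exercised under: a 101-residue template with 30 hot-spot
#' positions (so 29.7\% of positions can ever be mutated), 0--9 co-occurring
#' substitutions per variant, five replicate trajectories per variant, and a
#' planted response \code{+1 z(h_alpha) - 1 z(turn)} with noise SD 0.5.
#'
#' @slot nVariants number of variants (template included as variant 0).
#' @slot hotPositions 1-based mutable positions.
#' @slot maxMutations maximum substitutions per variant (default 9).
#' @slot meanMutations mean of the truncated-Poisson mutation count
#'   (default 3.4, which puts roughly a quarter of variants at >= 5
#'   mutations).
#' @slot replicates replicate trajectories per variant (default 5).
#' @slot framesPerTraj frames per trajectory (default 101; a config switch
#'   to 1001 reproduces the full per-trajectory series length).
#' @slot dtPs frame spacing, ps (default 100, i.e. 10 ns per 101 frames).
#' @slot flexibilityBase baseline per-coordinate fluctuation amplitude,
#'   \enc{Å}{Angstrom}.
#' @slot rho AR(1) mean-reversion coefficient in (0, 1); 0 gives white
#'   fluctuations.
#' @slot mutationScale amplitude multiplier at mutated positions.
#' @slot loopScale amplitude multiplier in loop regions.
#' @slot effectCoefs named numeric: planted response weights on feature
#'   columns.
#' @slot noiseSd response noise SD.
#' @slot seed integer seed; identical specs give bit-identical output.
#'
#' @export
setClass("SynthSpec",
  representation(nVariants = "integer", hotPositions = "integer",
                 maxMutations = "integer", meanMutations = "numeric",
                 replicates = "integer", framesPerTraj = "integer",
                 dtPs = "numeric", flexibilityBase = "numeric",
                 rho = "numeric", mutationScale = "numeric",
                 loopScale = "numeric", effectCoefs = "numeric",
                 noiseSd = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nVariants < 1L) msg <- c(msg, "nVariants must be >= 1")
    if (object@maxMutations < 0L) msg <- c(msg, "maxMutations must be >= 0")
    if (object@replicates < 1L) msg <- c(msg, "replicates must be >= 1")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (object@rho < 0 || object@rho >= 1)
      msg <- c(msg, "rho must lie in [0, 1)")
    if (length(msg)) msg else TRUE
  })

#' FeatureTable: variants x biodescriptors with block tags
#'
#' A \linkS4class{SummarizedExperiment} with biodescriptors as rows and
#' variants as columns.  \code{rowData} carries the feature block
#' (\code{SEQ}, \code{MD} or \code{POCKET}) and the replicate-aggregation
#' tag (\code{mean}, \code{std} or \code{na}); \code{colData} carries the
#' FCA response.  Under the default featurization the block widths are
#' SEQ = 80, MD = 32 and POCKET = 80 (192 features in total).
#'
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- character()
    rd <- rowData(object)
    if (!all(c("block", "aggregation") %in% names(rd)))
      msg <- c(msg, "rowData needs 'block' and 'aggregation' columns")
    else {
      if (!all(rd$block %in% c("SEQ", "MD", "POCKET")))
        msg <- c(msg, "block must be SEQ, MD or POCKET")
      if (!all(rd$aggregation %in% c("mean", "std", "na")))
        msg <- c(msg, "aggregation must be mean, std or na")
    }
    if (anyDuplicated(rownames(object)))
      msg <- c(msg, "duplicate feature names")
    if (anyDuplicated(colnames(object)))
      msg <- c(msg, "duplicate variant ids")
    if (length(msg)) msg else TRUE
  })

#' RunConfig: validated run configuration
#'
#' A typed key-value configuration with defaults filled for unset keys and
#' unknown keys rejected (see \code{\link{loadConfig}}).
#'
#' @slot values named list of configuration values.
#' @export
setClass("RunConfig", representation(values = "list"))
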