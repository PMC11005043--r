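#' @include AllClasses.R
NULL

#' Coordinates of a structure
#' @param x a \linkS4class{StructureModel}.
#' @return numeric N x 3 matrix (\enc{Å}{Angstrom}).
#' @export
setGeneric("atomCoords", function(x) standardGeneric("atomCoords"))

#' Per-atom metadata table
#' @param x a \linkS4class{StructureModel}.
#' @return data.frame with name, element, resid, resname, chain, ligand.
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))

#' Number of atoms
#' @param x a \linkS4class{StructureModel} or \linkS4class{TrajectoryData}.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Number of frames in a trajectory
#' @param x a \linkS4class{TrajectoryData}.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Frame array of a trajectory
#' @param x a \linkS4class{TrajectoryData}.
#' @return numeric F x N x 3 array.
#' @export
setGeneric("frameArray", function(x) standardGeneric("frameArray"))

#' Variants-by-features matrix of a FeatureTable
#'
#' Returns the assay transposed to the modelling orientation (variants as
#' rows, named features as columns).
#' @param x a \linkS4class{FeatureTable}.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' FCA response vector of a FeatureTable
#' @param x a \linkS4class{FeatureTable}.
#' @export
setGeneric("responseFCA", function(x) standardGeneric("responseFCA"))

#' Feature block tags of a FeatureTable
#' @param x a \linkS4class{FeatureTable}.
#' @return character vector (SEQ/MD/POCKET), one per feature.
#' @export
setGeneric("featureBlocks", function(x) standardGeneric("featureBlocks"))

setMethod("atomCoords", "StructureModel", function(x) x@coords)
setMethod("atomData", "StructureModel", function(x) x@atoms)
setMethod("nAtoms", "StructureModel", function(x) nrow(x@atoms))
setMethod("nAtoms", "TrajectoryData", function(x) dim(x@frames)[2L])
setMethod("nFrames", "TrajectoryData", function(x) dim(x@frames)[1L])
setMethod("frameArray", "TrajectoryData", function(x) x@frames)

setMethod("featureMatrix", "FeatureTable", function(x) {
  m <- t(assay(x))
  storage.mode(m) <- "double"
  m
})
setMethod("responseFCA", "FeatureTable", function(x) {
  fca <- colData(x)$fca
  names(fca) <- colnames(x)
  fca
})
setMethod("featureBlocks", "FeatureTable", function(x) {
  b <- as.character(rowData(x)$block)
  names(b) <- rownames(x)
  b
})

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  cat(sprintf("StructureModel: %d atoms, %d residues, %d ligand atom(s)\n",
              nrow(a), length(unique(a$resid[!a$ligand])), sum(a$ligand)))
})

setMethod("show", "TrajectoryData", function(object) {
  cat(sprintf("TrajectoryData: %d frames x %d atoms, dt = %g ps (%g ns total)\n",
              nFrames(object), nAtoms(object), object@dtPs,
              (nFrames(object) - 1L) * object@dtPs / 1000))
})

setMethod("show", "VariantRecord", function(object) {
  m <- object@mutations
  mut <- if (nrow(m)) paste0(m$ref, m$pos, m$alt, collapse = "/")
         else "(template)"
  cat(sprintf("VariantRecord %s: %s, FCA = %.3g\n", object@id, mut,
              object@fca))
})

setMethod("show", "BindingSite", function(object) {
  cat(sprintf("BindingSite: %d residues within %.1f A of the ligand (%s)\n",
              length(object@residueIds), object@cutoff,
              paste(object@residueIds, collapse = ", ")))
})

setMethod("show", "FeatureTable", function(object) {
  b <- table(factor(rowData(object)$block, c("SEQ", "MD", "POCKET")))
  cat(sprintf(
    "FeatureTable: %d variants x %d features (SEQ %d | MD %d | POCKET %d)\n",
    ncol(object), nrow(object), b["SEQ"], b["MD"], b["POCKET"]))
})

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig:\n")
  v <- object@values
  for (k in names(v))
    cat(sprintf("  %s = %s\n", k, paste(format(v[[k]]), collapse = ", ")))
})
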