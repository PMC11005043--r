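#' @include synthetic-data.R sequence-layer.R trajectory-features.R
#' @include pocket-features.R dataset-assembly.R
NULL

#' Sequence feature block for a variant library
#'
#' @param variants list of \linkS4class{VariantRecord}.
#' @return variants x 80 matrix (rownames = variant ids).
#' @export
buildSequenceBlock <- function(variants) {
  m <- t(vapply(variants, function(v) seqFeatureBlock(v@sequence),
                numeric(80L)))
  rownames(m) <- vapply(variants, function(v) v@id, "")
  m
}

#' Generate and featurize a synthetic study
#'
#' Runs the full synthetic pipeline: builds the template, draws the variant
#' library, simulates replicate trajectories per variant, computes the
#' sequence (80), MD (32) and pocket (80) feature blocks, assembles the
#' 192-column table and plants the FCA response on the observed features.
#'
#' @param spec a \linkS4class{SynthSpec}.
#' @param template optional template list from \code{\link{makeTemplate}}
#'   (default \code{defaultTemplate(spec@seed)}).
#' @param sasaPoints sphere points per atom for the pocket SASA series
#'   (default 96; the per-atom sampling error of a few percent averages out
#'   over frames and replicates).
#' @param verbose print progress every 50 variants.
#' @return list with \code{table} (\linkS4class{FeatureTable} with planted
#'   FCA), \code{variants}, \code{truth} (from \code{\link{plantResponse}}),
#'   \code{site}, \code{template}.
#' @export
buildStudyFeatureTable <- function(spec, template = NULL, sasaPoints = 96L,
                                   verbose = FALSE) {
  if (is.null(template)) template <- defaultTemplate(spec@seed)
  site <- defineBindingSite(template$model)
  variants <- makeVariantLibrary(spec, template$sequence)
  slots <- 16L
  if (length(site@residueIds) != slots)
    message("binding site has ", length(site@residueIds),
            " residues; pocket occupancy/B-factor use ", slots, " slots")
  mdRows <- matrix(NA_real_, length(variants), 32L)
  pkRows <- matrix(NA_real_, length(variants), 80L)
  for (i in seq_along(variants)) {
    trajs <- simulateReplicates(variants[[i]], template$model, spec,
                                seed = childSeed(spec@seed, 1000L + i))
    md <- mdFeatureBlock(trajs, template$model, site)
    pk <- pocketFeatureBlock(site, trajs, variants[[i]]@sequence,
                             slots = slots, sasaPoints = sasaPoints,
                             warnSlots = FALSE)
    if (i == 1L) {
      colnames(mdRows) <- names(md)
      colnames(pkRows) <- names(pk)
    }
    mdRows[i, ] <- md
    pkRows[i, ] <- pk
    if (verbose && i %% 50L == 0L)
      message("featurized ", i, "/", length(variants), " variants")
  }
  ids <- vapply(variants, function(v) v@id, "")
  rownames(mdRows) <- rownames(pkRows) <- ids
  seqBlock <- buildSequenceBlock(variants)
  table0 <- assembleFeatureTable(seqBlock, mdRows, pkRows)
  truth <- plantResponse(table0, spec)
  variants <- lapply(seq_along(variants), function(i) {
    v <- variants[[i]]; v@fca <- truth$fca[i]; v
  })
  table <- featureTable(featureMatrix(table0), ids = ids,
                        block = featureBlocks(table0), fca = truth$fca)
  list(table = table, variants = variants, truth = truth, site = site,
       template = template)
}

#' Read sequences from FASTA
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
readFasta <- function(path) {
  s <- Biostrings::readAAStringSet(path)
  structure(as.character(s), names = names(s))
}

#' Write sequences to FASTA
#' @param sequences named character vector.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}

#' Export a synthetic study to disk
#'
#' Writes the template (PDB), variant sequences (FASTA), the variant table
#' with mutation strings and planted FCA (CSV), the ground-truth response
#' coefficients (CSV) and the assembled feature table (CSV).
#'
#' @param study result of \code{\link{buildStudyFeatureTable}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
exportStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeStructure(study$template$model, file.path(dir, "template.pdb"))
  seqs <- vapply(study$variants, function(v) v@sequence, "")
  names(seqs) <- vapply(study$variants, function(v) v@id, "")
  writeFasta(seqs, file.path(dir, "variants.fasta"))
  vdf <- data.frame(
    id = names(seqs),
    mutations = vapply(study$variants, function(v) {
      m <- v@mutations
      if (nrow(m)) paste0(m$ref, m$pos, m$alt, collapse = "/") else ""
    }, ""),
    fca = vapply(study$variants, function(v) v@fca, 0))
  write.csv(vdf, file.path(dir, "variants.csv"), row.names = FALSE)
  write.csv(data.frame(feature = names(study$truth$coefficients),
                       coefficient = study$truth$coefficients,
                       row.names = NULL),
            file.path(dir, "ground_truth.csv"), row.names = FALSE)
  writeFeatureTable(study$table, file.path(dir, "features.csv"))
  invisible(dir)
}
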