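#' @include AllClasses.R
#' @importFrom utils read.csv write.csv
NULL

#' Construct a StructureModel
#'
#' @param name,element,resname,chain per-atom character vectors.
#' @param resid per-atom 1-based residue ids (integer).
#' @param coords numeric N x 3 coordinate matrix (\enc{Å}{Angstrom}).
#' @param ligand per-atom logical ligand flag (default all FALSE).
#' @return a \linkS4class{StructureModel}.
#' @export
StructureModel <- function(name, element, resid, resname, chain, coords,
                           ligand = rep(FALSE, length(name))) {
  atoms <- data.frame(name = as.character(name),
                      element = as.character(element),
                      resid = as.integer(resid),
                      resname = as.character(resname),
                      chain = as.character(chain),
                      ligand = as.logical(ligand),
                      stringsAsFactors = FALSE)
  coords <- as.matrix(coords)
  dimnames(coords) <- NULL
  new("StructureModel", atoms = atoms, coords = coords)
}

#' Construct a TrajectoryData
#'
#' @param frames numeric F x N x 3 array of coordinates.
#' @param dtPs frame spacing in picoseconds.
#' @param model reference \linkS4class{StructureModel}.
#' @return a \linkS4class{TrajectoryData}.
#' @export
TrajectoryData <- function(frames, dtPs, model) {
  new("TrajectoryData", frames = frames, dtPs = as.numeric(dtPs),
      model = model)
}

## Pre-scan a PDB file and error (naming the line) on malformed coordinate
## fields in ATOM/HETATM records.
validatePdbLines <- function(lines, path) {
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec))
    stop("no ATOM/HETATM records in '", path, "'")
  for (i in which(rec)) {
    xyz <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                         substr(lines[i], 39, 46),
                                         substr(lines[i], 47, 54))))
    if (any(is.na(xyz)))
      stop("malformed coordinate field in '", path, "' at line ", i)
  }
  invisible(TRUE)
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records; 1-based residue ids are preserved exactly as
#' in the file.  HETATM atoms whose residue name equals \code{ligandResname}
#' are flagged as ligand atoms.
#'
#' @param path PDB file path.
#' @param ligandResname 3-letter residue name marking the ligand
#'   (default \code{"LIG"}).
#' @param dialect on-disk format; only \code{"pdb"} is supported.
#' @return a \linkS4class{StructureModel}.
#' @export
readStructure <- function(path, ligandResname = "LIG", dialect = "pdb") {
  dialect <- match.arg(dialect, "pdb")
  if (!file.exists(path)) stop("file not found: ", path)
  validatePdbLines(readLines(path), path)
  p <- bio3d::read.pdb(path, verbose = FALSE)
  a <- p$atom
  StructureModel(name = a$elety,
                 element = ifelse(is.na(a$elesy) | a$elesy == "",
                                  substr(trimws(a$elety), 1, 1), a$elesy),
                 resid = a$resno, resname = a$resid, chain = a$chain,
                 coords = cbind(a$x, a$y, a$z),
                 ligand = a$type == "HETATM" & a$resid == ligandResname)
}

#' Write a StructureModel to a PDB file
#'
#' Coordinates are written at the PDB-standard 3-decimal precision, so a
#' write/read round trip reproduces coordinates to 1e-3 \enc{Å}{Angstrom}.
#'
#' @param x a \linkS4class{StructureModel}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeStructure <- function(x, path) {
  a <- atomData(x)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(atomCoords(x))),
                   type = ifelse(a$ligand, "HETATM", "ATOM"),
                   resno = a$resid, resid = a$resname, chain = a$chain,
                   elety = a$name, elesy = a$element)
  invisible(path)
}

readXyzTrajectory <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) <= length(lines)]
  frames <- list(); elements <- NULL
  i <- 1L; f <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L)
      stop("malformed XYZ atom-count line at line ", i, " in '", path, "'")
    f <- f + 1L
    if (i + 1L + n > length(lines))
      stop("truncated XYZ frame ", f, " in '", path, "'")
    body <- lines[(i + 2L):(i + 1L + n)]
    tok <- strsplit(trimws(body), "[[:space:]]+")
    el <- vapply(tok, `[`, "", 1L)
    xyz <- t(vapply(tok, function(t) {
      v <- suppressWarnings(as.numeric(t[2:4]))
      if (any(is.na(v))) stop("malformed coordinate in XYZ frame ", f,
                              " of '", path, "'")
      v
    }, numeric(3)))
    if (is.null(elements)) elements <- el
    else if (length(el) != length(elements))
      stop("frame ", f, " has ", length(el), " atoms; expected ",
           length(elements))
    frames[[f]] <- xyz
    i <- i + 2L + n
  }
  if (!length(frames)) stop("no frames in '", path, "'")
  arr <- array(0, c(length(frames), length(elements), 3L))
  for (k in seq_along(frames)) arr[k, , ] <- frames[[k]]
  list(frames = arr, elements = elements)
}

#' Read a trajectory (multi-model PDB or XYZ)
#'
#' Frame order is preserved; neither format carries reliable time metadata,
#' so the frame spacing \code{dtPs} is supplied by the caller / run
#' configuration.
#'
#' @param path trajectory file.
#' @param dialect \code{"pdb"} (MODEL/ENDMDL blocks) or \code{"xyz"}.
#' @param dtPs frame spacing in ps.
#' @param model reference \linkS4class{StructureModel}; required for
#'   \code{"xyz"} (which carries no residue metadata), optional for
#'   \code{"pdb"} (rebuilt from the first model when absent).
#' @param ligandResname ligand residue name for PDB input.
#' @return a \linkS4class{TrajectoryData}.
#' @export
readTrajectory <- function(path, dialect = c("pdb", "xyz"), dtPs = 100,
                           model = NULL, ligandResname = "LIG") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "xyz") {
    parsed <- readXyzTrajectory(path)
    if (is.null(model))
      stop("a reference StructureModel is required for XYZ input")
    if (dim(parsed$frames)[2L] != nAtoms(model))
      stop("XYZ atom count (", dim(parsed$frames)[2L],
           ") differs from the reference structure (", nAtoms(model), ")")
    return(TrajectoryData(parsed$frames, dtPs, model))
  }
  lines <- readLines(path)
  validatePdbLines(lines, path)
  ## per-model atom-count check with frame index in the message
  starts <- grep("^MODEL", lines)
  if (length(starts) > 1L) {
    ends <- grep("^ENDMDL", lines)
    counts <- vapply(seq_along(starts), function(k)
      sum(grepl("^(ATOM  |HETATM)", lines[starts[k]:ends[k]])), 1L)
    if (length(unique(counts)) > 1L)
      stop("frame ", which(counts != counts[1L])[1L],
           " has a differing atom count (", counts[counts != counts[1L]][1L],
           " vs ", counts[1L], ")")
  }
  p <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  nf <- nrow(p$xyz)
  na <- ncol(p$xyz) / 3L
  if (is.null(model)) {
    a <- p$atom
    model <- StructureModel(name = a$elety,
                            element = ifelse(is.na(a$elesy) | a$elesy == "",
                                             substr(trimws(a$elety), 1, 1),
                                             a$elesy),
                            resid = a$resno, resname = a$resid,
                            chain = a$chain,
                            coords = matrix(p$xyz[1L, ], ncol = 3L,
                                            byrow = TRUE),
                            ligand = a$type == "HETATM" &
                              a$resid == ligandResname)
  }
  if (na != nAtoms(model))
    stop("trajectory atom count (", na,
         ") differs from the reference structure (", nAtoms(model), ")")
  arr <- array(0, c(nf, na, 3L))
  for (k in seq_len(nf)) arr[k, , ] <- matrix(p$xyz[k, ], ncol = 3L,
                                              byrow = TRUE)
  TrajectoryData(arr, dtPs, model)
}

#' Write a trajectory to disk
#'
#' @param x a \linkS4class{TrajectoryData}.
#' @param path output file.
#' @param dialect \code{"pdb"} (multi-model) or \code{"xyz"}; coordinates
#'   are written at 3-decimal precision in both.
#' @return \code{path}, invisibly.
#' @export
writeTrajectory <- function(x, path, dialect = c("pdb", "xyz")) {
  dialect <- match.arg(dialect)
  a <- atomData(x@model)
  fr <- frameArray(x)
  if (dialect == "pdb") {
    xyz <- t(apply(fr, 1L, function(m) as.numeric(t(m))))
    bio3d::write.pdb(file = path, xyz = xyz,
                     type = ifelse(a$ligand, "HETATM", "ATOM"),
                     resno = a$resid, resid = a$resname, chain = a$chain,
                     elety = a$name, elesy = a$element)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    for (k in seq_len(nFrames(x))) {
      writeLines(c(as.character(nAtoms(x)), sprintf("frame %d", k)), con)
      writeLines(sprintf("%s %.3f %.3f %.3f", a$element,
                         fr[k, , 1L], fr[k, , 2L], fr[k, , 3L]), con)
    }
  }
  invisible(path)
}

## Header convention "BLOCK:name" with aggregation encoded in a trailing
## "_mean" / "_std" on the feature name.
parseFeatureHeader <- function(h) {
  parts <- regmatches(h, regexec("^(SEQ|MD|POCKET):(.+)$", h))
  block <- vapply(parts, function(p) if (length(p)) p[2L] else NA_character_,
                  "")
  if (anyNA(block))
    stop("feature header without a BLOCK: prefix: ",
         paste(h[is.na(block)], collapse = ", "))
  agg <- ifelse(grepl("_mean$", h), "mean",
                ifelse(grepl("_std$", h), "std", "na"))
  data.frame(block = block, aggregation = agg, stringsAsFactors = FALSE)
}

#' Read a feature table from CSV
#'
#' Expects a header row whose first column is the variant id, an optional
#' \code{fca} response column, and feature columns tagged by the
#' \code{"BLOCK:name"} convention (e.g. \code{"MD:rmsd_ca_whole_mean"});
#' the aggregation tag is recovered from a trailing \code{_mean}/\code{_std}.
#'
#' @param path CSV file path.
#' @return a \linkS4class{FeatureTable}.
#' @export
readFeatureTable <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate variant ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  fca <- if ("fca" %in% names(df)) as.numeric(df$fca)
         else rep(NA_real_, length(ids))
  feat <- df[, setdiff(names(df), c(names(df)[1L], "fca")), drop = FALSE]
  tags <- parseFeatureHeader(names(feat))
  featureTable(values = as.matrix(feat), ids = ids,
               block = tags$block, aggregation = tags$aggregation,
               featureNames = names(feat), fca = fca)
}

#' Write a feature table to CSV
#'
#' @param x a \linkS4class{FeatureTable}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeFeatureTable <- function(x, path) {
  m <- featureMatrix(x)
  df <- data.frame(variant_id = colnames(x),
                   fca = as.numeric(responseFCA(x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(m, check.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

configSchema <- function() {
  list(
    seed = list(default = 1L, type = "integer"),
    chunk_ns = list(default = 10, type = "numeric"),
    replicates = list(default = 5L, type = "integer"),
    frames_per_traj = list(default = 101L, type = "integer"),
    dt_ps = list(default = 100, type = "numeric"),
    train_frac = list(default = 0.8, type = "numeric"),
    bootstrap = list(default = 500L, type = "integer"),
    cv_folds = list(default = 5L, type = "integer"),
    lower_threshold = list(default = 0.05, type = "numeric"),
    upper_threshold = list(default = 0.95, type = "numeric"),
    mutation_count_cut = list(default = 5L, type = "integer"),
    alpha = list(default = 0.05, type = "numeric"),
    ligand_resname = list(default = "LIG", type = "character"),
    binding_site_cutoff = list(default = 3.5, type = "numeric"),
    site_slots = list(default = 16L, type = "integer"),
    retention_folds = list(default = 20L, type = "integer"),
    retention_keep_frac = list(default = 0.8, type = "numeric"),
    fca_sign = list(default = "b_minus_a", type = "character"))
}

#' Load (and validate) a run configuration
#'
#' Reads a JSON document, fills defaults for all unset keys (10 ns chunks,
#' 5 replicates, 80/20 split, 500 bootstrap iterations, 5 CV folds, 5\%/95\%
#' residual thresholds, mutation-count cut >= 5, ...), rejects unknown keys
#' and type-mismatched values.
#'
#' @param path JSON file path, or \code{NULL} for the all-defaults config.
#' @return a \linkS4class{RunConfig}.
#' @export
loadConfig <- function(path = NULL) {
  schema <- configSchema()
  vals <- lapply(schema, `[[`, "default")
  if (!is.null(path)) {
    user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    if (length(user)) {
      unknown <- setdiff(names(user), names(schema))
      if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
      for (k in names(user)) {
        v <- user[[k]]
        want <- schema[[k]]$type
        ok <- switch(want,
                     integer = is.numeric(v) && length(v) == 1L &&
                       isTRUE(all.equal(v, round(v))),
                     numeric = is.numeric(v) && length(v) == 1L,
                     character = is.character(v) && length(v) == 1L)
        if (!isTRUE(ok))
          stop("config key '", k, "' must be of type ", want)
        vals[[k]] <- if (want == "integer") as.integer(v) else v
      }
    }
  }
  new("RunConfig", values = vals)
}

#' Get one configuration value
#' @param config a \linkS4class{RunConfig}.
#' @param key configuration key name.
#' @return the value stored under \code{key}.
#' @export
configValue <- function(config, key) {
  if (!key %in% names(config@values)) stop("unknown config key: ", key)
  config@values[[key]]
}
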