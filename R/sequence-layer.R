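#' @include AllClasses.R aa-data.R
NULL

checkSequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L ||
      nchar(sequence) < 1L)
    stop("sequence must be a non-empty string")
  aa <- strsplit(sequence, "")[[1L]]
  bad <- setdiff(unique(aa), AA_LETTERS)
  if (length(bad))
    stop("non-standard residue(s): ", paste(bad, collapse = ", "))
  aa
}

#' Parse a mutation specification string
#'
#' Parses "/"-separated tokens such as \code{"S38T/L74F/M100K/S127T"} into a
#' table of (reference residue, 1-based position, substituted residue).
#' Token order is preserved; duplicate positions, identical ref/alt residues
#' and malformed tokens are rejected.
#'
#' @param specString mutation string, or \code{""} for the template.
#' @return data.frame with columns \code{ref}, \code{pos}, \code{alt}.
#' @examples
#' parseMutations("S38T/L74F")
#' @export
parseMutations <- function(specString) {
  stopifnot(is.character(specString), length(specString) == 1L)
  empty <- data.frame(ref = character(), pos = integer(),
                      alt = character(), stringsAsFactors = FALSE)
  if (!nzchar(specString)) return(empty)
  tokens <- strsplit(specString, "/", fixed = TRUE)[[1L]]
  ok <- grepl("^[A-Z][0-9]+[A-Z]$", tokens)
  if (any(!ok))
    stop("malformed mutation token: ", paste(tokens[!ok], collapse = ", "))
  ref <- substr(tokens, 1L, 1L)
  alt <- substring(tokens, nchar(tokens))
  pos <- as.integer(gsub("[A-Z]", "", tokens))
  bad <- !(ref %in% AA_LETTERS) | !(alt %in% AA_LETTERS)
  if (any(bad))
    stop("non-standard residue in token: ",
         paste(tokens[bad], collapse = ", "))
  if (anyDuplicated(pos))
    stop("duplicate mutated position in token: ",
         paste(tokens[duplicated(pos)], collapse = ", "))
  same <- ref == alt
  if (any(same))
    stop("reference equals substitution in token: ",
         paste(tokens[same], collapse = ", "))
  data.frame(ref = ref, pos = pos, alt = alt, stringsAsFactors = FALSE)
}

#' Apply a mutation list to a template sequence
#'
#' @param templateSequence amino-acid string.
#' @param mutations data.frame from \code{\link{parseMutations}}.
#' @return the mutated sequence; it differs from the template exactly at the
#'   mutated positions.
#' @export
applyMutations <- function(templateSequence, mutations) {
  aa <- checkSequence(templateSequence)
  if (!nrow(mutations)) return(templateSequence)
  if (any(mutations$pos > length(aa)))
    stop("mutation position beyond sequence length")
  found <- aa[mutations$pos]
  bad <- found != mutations$ref
  if (any(bad))
    stop(sprintf("reference mismatch at position %d: expected %s, found %s",
                 mutations$pos[bad][1L], mutations$ref[bad][1L],
                 found[bad][1L]))
  aa[mutations$pos] <- mutations$alt
  paste(aa, collapse = "")
}

#' Pairwise percent-identity matrix of a variant library
#'
#' Percent identity = 100 x (matching positions) / length over equal-length
#' sequences (no alignment is attempted).  Diagonal entries are 100.
#'
#' @param variants list of \linkS4class{VariantRecord}, or a character
#'   vector of sequences.
#' @return symmetric numeric matrix of percent identities.
#' @export
identityMatrix <- function(variants) {
  seqs <- if (is.character(variants)) variants
          else vapply(variants, function(v) v@sequence, "")
  n <- length(seqs)
  len <- unique(nchar(seqs))
  if (length(len) != 1L)
    stop("sequences differ in length; identity requires equal lengths")
  m <- do.call(rbind, strsplit(seqs, ""))
  out <- matrix(100, n, n)
  for (i in seq_len(n - 1L)) {
    eq <- sweep(m[(i + 1L):n, , drop = FALSE], 2L, m[i, ], `==`)
    idty <- 100 * rowMeans(eq)
    out[i, (i + 1L):n] <- idty
    out[(i + 1L):n, i] <- idty
  }
  ids <- if (is.character(variants)) NULL
         else vapply(variants, function(v) v@id, "")
  dimnames(out) <- list(ids, ids)
  out
}

#' Normalized mutation occurrence per site
#'
#' Counts, for every position, how many variants carry a mutation there,
#' normalized by the maximum count; also reports the fraction of positions
#' mutated at least once.
#'
#' @param variants list of \linkS4class{VariantRecord}.
#' @return list with \code{occurrence} (named numeric in [0,1]) and
#'   \code{fractionMutated}.
#' @export
mutationSiteOccurrence <- function(variants) {
  stopifnot(length(variants) >= 1L)
  len <- nchar(variants[[1L]]@sequence)
  pos <- unlist(lapply(variants, function(v) v@mutations$pos))
  if (!length(pos))
    return(list(occurrence = numeric(0), fractionMutated = 0))
  counts <- table(pos)
  occ <- as.numeric(counts) / max(counts)
  names(occ) <- names(counts)
  list(occurrence = occ, fractionMutated = length(counts) / len)
}

#' Fold change in activities (FCA)
#'
#' The per-setting fold activity is the ratio of the variant's activity to
#' the template's; FCA is the difference between the two settings' folds.
#' The default sign convention is (with pre-heat) minus (without pre-heat);
#' it is configurable because only "the difference" between settings is
#' defined by the assay.
#'
#' @param activityA,activityB variant activity without / with
#'   pre-incubation heating (>= 0).
#' @param templateA,templateB the template's activities (> 0).
#' @param sign \code{"b_minus_a"} (default) or \code{"a_minus_b"}.
#' @return FCA (numeric, vectorized over variants).
#' @examples
#' computeFCA(2, 6, 2, 2)  # fold_a = 1, fold_b = 3 -> FCA = 2
#' @export
computeFCA <- function(activityA, activityB, templateA, templateB,
                       sign = c("b_minus_a", "a_minus_b")) {
  sign <- match.arg(sign)
  stopifneg(activityA, "activityA"); stopifneg(activityB, "activityB")
  if (any(templateA <= 0) || any(templateB <= 0))
    stop("template activities must be > 0")
  foldA <- activityA / templateA
  foldB <- activityB / templateB
  if (sign == "b_minus_a") foldB - foldA else foldA - foldB
}

#' The 66 scale-based sequence descriptors
#'
#' For each of the ten canonical per-residue scale families (see
#' \code{\link{scaleDescriptorFamilies}}) every dimension is averaged over
#' the residues of the sequence, giving 66 composition-based descriptors.
#' These are permutation-invariant in residue order by construction.
#'
#' @param sequence amino-acid string (standard 20-letter alphabet; no
#'   imputation for non-standard residues).
#' @return named numeric vector of length 66.
#' @export
computeScaleDescriptors <- function(sequence) {
  aa <- checkSequence(sequence)
  fam <- scaleDescriptorFamilies()
  out <- unlist(lapply(fam, function(m) colMeans(m[aa, , drop = FALSE])))
  names(out) <- unlist(lapply(fam, colnames))
  out
}

#' Net charge at a given pH
#'
#' Henderson-Hasselbalch net charge using the EMBOSS pKa set, including
#' peptide termini.
#'
#' @param sequence amino-acid string.
#' @param pH pH value (default 8.0, the assay pH).
#' @return net charge (elementary charges).
#' @export
netCharge <- function(sequence, pH = 8.0) {
  aa <- checkSequence(sequence)
  counts <- table(factor(aa, AA_LETTERS))
  pos <- PKA_EMBOSS$positive
  neg <- PKA_EMBOSS$negative
  q <- 1 / (1 + 10^(pH - pos["Nterm"])) -
       1 / (1 + 10^(neg["Cterm"] - pH))
  for (r in setdiff(names(pos), "Nterm"))
    q <- q + counts[r] * 1 / (1 + 10^(pH - pos[r]))
  for (r in setdiff(names(neg), "Cterm"))
    q <- q - counts[r] * 1 / (1 + 10^(neg[r] - pH))
  as.numeric(q)
}

#' Isoelectric point by bisection
#'
#' Solves \code{netCharge(sequence, pH) = 0} by bisection on pH in [0, 14]
#' to |charge| < 1e-4 (the net-charge function is monotone decreasing in
#' pH).
#'
#' @param sequence amino-acid string.
#' @return the isoelectric point (pH units).
#' @export
isoelectricPoint <- function(sequence) {
  lo <- 0; hi <- 14
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    q <- netCharge(sequence, mid)
    if (abs(q) < 1e-4) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' The 14 global sequence properties
#'
#' Composition-based global properties: length; average molecular weight
#' (residue masses plus one water); isoelectric point (bisection on the
#' Henderson-Hasselbalch net charge, EMBOSS pKa set); aromaticity (F+W+Y
#' fraction); charged-residue fraction at pH 8 (D,E,K,R); GRAVY
#' (Kyte-Doolittle mean); net charge at pH 8.0 (the assay pH); molar
#' extinction coefficient at 280 nm with reduced cysteines; mean Vihinen
#' flexibility; helix/turn/sheet propensity fractions (Chou-Fasman style
#' class memberships); aliphatic index (Ikai); and the Boman
#' protein-binding index.
#'
#' @param sequence amino-acid string.
#' @return named numeric vector of length 14.
#' @examples
#' computeGlobalProperties("GG")[["mw"]]  # 2 x 57.0519 + 18.0153
#' @export
computeGlobalProperties <- function(sequence) {
  aa <- checkSequence(sequence)
  n <- length(aa)
  counts <- table(factor(aa, AA_LETTERS))
  frac <- counts / n
  c(length = n,
    mw = sum(AA_MASS[aa]) + WATER_MASS,
    pi = isoelectricPoint(sequence),
    aromaticity = sum(frac[c("F", "W", "Y")]),
    charged_fraction = sum(frac[c("D", "E", "K", "R")]),
    gravy = mean(KYTE_DOOLITTLE[aa]),
    charge_ph8 = netCharge(sequence, 8.0),
    extinction_reduced = sum(counts["W"] * EXTINCTION["W"],
                             counts["Y"] * EXTINCTION["Y"]),
    flexibility = mean(FLEXIBILITY[aa]),
    helix_fraction = sum(frac[SS_PROPENSITY_CLASSES$helix]),
    turn_fraction = sum(frac[SS_PROPENSITY_CLASSES$turn]),
    sheet_fraction = sum(frac[SS_PROPENSITY_CLASSES$sheet]),
    aliphatic_index = 100 * (frac[["A"]] + 2.9 * frac[["V"]] +
                               3.9 * (frac[["I"]] + frac[["L"]])),
    boman = -mean(BOMAN_SCALE[aa]))
}

#' The 80-column sequence feature block
#'
#' Concatenates the 66 scale descriptors and the 14 global properties, with
#' \code{"SEQ:"} feature names ready for table assembly.
#'
#' @param sequence amino-acid string.
#' @return named numeric vector of length 80.
#' @export
seqFeatureBlock <- function(sequence) {
  v <- c(computeScaleDescriptors(sequence),
         computeGlobalProperties(sequence))
  names(v) <- paste0("SEQ:", names(v))
  v
}
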