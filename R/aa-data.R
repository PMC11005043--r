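## Amino-acid constants and published per-residue descriptor scales.
##
## All tables use the row order A R N D C Q E G H I L K M F P S T W Y V.
## Scale families (66 dimensions in total, see scaleDescriptorFamilies):
##   BLOSUM indices (10)  Georgiev, J Comput Biol 2009 (BLOSUM-derived VARIMAX)
##   Cruciani (3)         Cruciani et al., J Chemom 2004
##   FASGAI (6)           Liang & Li, J Mol Graph Model 2007
##   Kidera (10)          Kidera et al., J Protein Chem 1985
##   MS-WHIM (3)          Zaliani & Gancia, J Chem Inf Comput Sci 1999
##   ProtFP (8)           van Westen et al., J Cheminform 2013
##   ST-scales (8)        Yang et al., Amino Acids 2010
##   T-scales (5)         Tian et al., J Mol Struct 2007
##   VHSE (8)             Mei et al., Biopolymers 2005
##   zScales (5)          Sandberg et al., J Med Chem 1998

AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA_THREE <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
              Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
              L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
              S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

AA_ONE <- structure(names(AA_THREE), names = AA_THREE)

## Average residue masses (Da); a peptide's molecular weight is the sum of
## residue masses plus one water (18.0153 Da).
AA_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
             C = 103.1388, Q = 128.1307, E = 129.1155, G = 57.0519,
             H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
             M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
             T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.0153

## EMBOSS pKa set used for net charge and isoelectric point.
PKA_EMBOSS <- list(
  positive = c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5),
  negative = c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1))

## Kyte-Doolittle hydropathy (GRAVY and pocket hydrophobicity).
KYTE_DOOLITTLE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

## Vihinen normalized flexibility (mean over residues = mean flexibility).
FLEXIBILITY <- c(A = 0.984, R = 1.008, N = 1.048, D = 1.068, C = 0.906,
                 Q = 1.037, E = 1.094, G = 1.031, H = 0.950, I = 0.927,
                 L = 0.935, K = 1.102, M = 0.952, F = 0.915, P = 1.049,
                 S = 1.046, T = 0.997, W = 0.904, Y = 0.929, V = 0.931)

## Free energies of transfer (kcal/mol) underlying the Boman protein-binding
## index (Radzicka & Wolfenden values as used by Boman, J Intern Med 2003);
## the index is minus their mean over residues.
BOMAN_SCALE <- c(A = -1.81, R = 14.92, N = 6.64, D = 8.72, C = -1.28,
                 Q = 5.54, E = 6.81, G = -0.94, H = 4.66, I = -4.92,
                 L = -4.92, K = 5.55, M = -2.35, F = -2.98, P = 0.00,
                 S = 3.40, T = 2.57, W = -2.33, Y = -0.14, V = -4.04)

## Molar extinction at 280 nm, reduced cysteines (Gill & von Hippel).
EXTINCTION <- c(W = 5500, Y = 1490)

## Chou-Fasman style class memberships for helix/turn/sheet fractions.
SS_PROPENSITY_CLASSES <- list(
  helix = c("V", "I", "Y", "F", "W", "L"),
  turn  = c("N", "P", "G", "S"),
  sheet = c("E", "M", "A", "L"))

## Residue chemistry classes at pH 8 (His treated as uncharged, pKa ~ 6).
AA_CLASSES <- list(
  positive = c("K", "R"),
  negative = c("D", "E"),
  polar    = c("S", "T", "N", "Q", "Y", "C", "H"),
  apolar   = c("A", "V", "L", "I", "M", "F", "W", "P", "G"))

aaScaleMatrix <- function(values, k, prefix) {
  m <- matrix(values, nrow = 20, ncol = k, byrow = TRUE,
              dimnames = list(AA_LETTERS, paste0(prefix, seq_len(k))))
  m
}

## 10 VARIMAX components of BLOSUM-derived physicochemical space.
SCALE_BLOSUM <- aaScaleMatrix(c(
  0.57, -0.25, 1.11, 0.17, 0.49, -0.26, -0.07, 0.05, 0.33, 0.36,
  -2.80, 1.40, -0.68, 0.48, -0.06, 0.46, 0.19, -0.64, 0.06, 0.67,
  -1.62, -0.27, -0.49, 0.38, 0.06, 0.43, -0.15, 0.17, 0.51, -0.29,
  -2.15, -0.70, -1.00, 0.33, 0.38, 0.35, 0.21, 0.34, 0.23, -0.37,
  1.41, 0.17, 0.89, -0.48, 0.37, -0.01, 0.24, -0.22, -0.11, 0.14,
  -1.45, 0.53, -0.71, 0.42, 0.09, 0.36, 0.12, -0.12, 0.24, -0.13,
  -2.16, 0.06, -1.11, 0.43, 0.30, 0.36, 0.15, 0.24, 0.24, -0.30,
  -0.77, -1.06, 0.66, 0.31, 0.33, 0.34, 0.54, 0.30, -0.39, 0.27,
  -0.39, 0.54, -0.32, -0.01, 0.14, 0.12, -0.69, 0.40, 0.25, 0.33,
  2.63, 0.26, 0.21, -0.41, 0.10, -0.42, -0.09, -0.20, -0.27, -0.06,
  2.11, 0.44, 0.04, -0.40, 0.08, -0.38, -0.15, -0.14, -0.24, 0.05,
  -2.10, 0.79, -0.52, 0.50, -0.08, 0.42, 0.17, -0.31, -0.03, 0.37,
  1.54, 0.59, 0.23, -0.32, 0.11, -0.27, -0.12, -0.08, -0.22, 0.09,
  2.02, 0.93, 0.38, -0.48, -0.06, -0.38, -0.12, 0.02, -0.06, -0.02,
  -1.39, -0.85, -0.04, 0.09, 0.41, 0.15, 0.27, -0.79, -0.31, -0.23,
  -1.03, -0.68, 0.13, 0.34, 0.16, 0.39, 0.17, 0.09, 0.11, -0.04,
  -0.42, -0.43, 0.34, 0.16, 0.12, 0.17, 0.00, -0.05, 0.08, -0.02,
  1.89, 1.53, 0.52, -0.45, -0.25, -0.30, -0.17, 0.26, -0.17, -0.29,
  1.21, 1.22, 0.16, -0.39, -0.04, -0.28, -0.21, 0.31, 0.00, -0.11,
  2.42, -0.02, 0.42, -0.45, 0.16, -0.45, -0.07, -0.18, -0.23, -0.03),
  10, "blosum")

## Cruciani principal properties: PP1 polarity, PP2 hydrophobicity,
## PP3 hydrogen-bonding capacity.
SCALE_CRUCIANI <- aaScaleMatrix(c(
  -0.96, -0.76, 0.31,
  0.80, 0.63, 0.99,
  0.82, -0.57, 0.02,
  1.00, -0.89, -1.00,
  -0.55, -0.47, 0.19,
  0.75, -0.40, 0.13,
  0.91, -0.81, -0.92,
  -0.88, -1.00, 0.49,
  0.67, 0.49, 0.36,
  -0.94, 0.05, -0.18,
  -0.90, 0.03, -0.24,
  0.60, 0.10, 1.00,
  -0.82, 0.03, -0.08,
  -0.85, 0.48, -0.58,
  -0.81, -0.44, -0.18,
  0.41, -0.97, 0.40,
  0.40, -0.64, 0.37,
  -0.59, 1.00, -0.48,
  -0.38, 0.82, -0.04,
  -0.96, -0.19, -0.22),
  3, "cruciani_pp")

## FASGAI vectors: F1 hydrophobicity, F2 alpha/turn propensity, F3 bulk,
## F4 composition, F5 local flexibility, F6 electronic properties.
SCALE_FASGAI <- aaScaleMatrix(c(
  -0.30, -0.44, -0.64, -0.49, -0.23, 0.26,
  0.94, 0.73, 0.54, 1.08, 0.33, -0.49,
  0.58, -0.34, -0.28, 0.24, 1.05, 0.28,
  0.78, -0.78, -0.40, 0.10, 0.84, -1.38,
  -0.36, 0.04, -0.38, -0.29, -0.38, 2.52,
  0.52, 0.36, 0.07, 0.55, 0.23, -0.20,
  0.71, -0.33, 0.02, 0.31, 0.30, -1.47,
  0.00, -1.32, -1.30, -0.84, 1.35, 0.40,
  0.38, 0.50, 0.19, 0.28, -0.18, 0.79,
  -1.14, 0.62, 0.18, -0.50, -0.73, -0.29,
  -1.01, 0.56, 0.22, -0.39, -0.62, -0.46,
  0.85, 0.53, 0.26, 1.13, 0.45, -0.65,
  -0.83, 0.68, 0.26, -0.19, -0.56, 0.24,
  -1.03, 0.51, 0.71, -0.38, -0.59, 0.24,
  0.34, -1.72, -0.35, -0.30, 0.77, -0.21,
  0.24, -0.69, -0.67, -0.22, 0.48, 0.26,
  0.10, -0.40, -0.37, -0.21, 0.10, 0.16,
  -0.83, 0.78, 1.83, -0.14, -0.48, 0.34,
  -0.49, 0.52, 1.18, -0.13, -0.22, 0.49,
  -0.77, 0.22, -0.29, -0.51, -0.56, -0.08),
  6, "fasgai_f")

## Kidera factors KF1-KF10.
SCALE_KIDERA <- aaScaleMatrix(c(
  -1.56, -1.67, -0.97, -0.27, -0.93, -0.78, -0.20, -0.08, 0.21, -0.48,
  0.22, 1.27, 1.37, 1.87, -1.70, 0.46, 0.92, -0.39, 0.23, 0.93,
  1.14, -0.07, -0.12, 0.81, 0.18, 0.37, -0.09, 1.23, 1.10, -1.73,
  0.58, -0.22, -1.58, 0.81, -0.92, 0.15, -1.52, 0.47, 0.76, 0.70,
  0.12, -0.89, 0.45, -1.05, -0.71, 2.41, 1.52, -0.69, 1.13, 1.10,
  -0.47, 0.24, 0.07, 1.10, 1.10, 0.59, 0.84, -0.71, -0.03, -2.33,
  -1.45, 0.19, -1.61, 1.17, -1.31, 0.40, 0.04, 0.38, -0.35, -0.12,
  1.46, -1.96, -0.23, -0.16, 0.10, -0.11, 1.32, 2.36, -1.66, 0.46,
  -0.41, 0.52, -0.28, 0.28, 1.61, 1.01, -1.85, 0.47, 1.13, 1.63,
  -0.73, -0.16, 1.79, -0.77, -0.54, 0.03, -0.83, 0.51, 0.66, -1.78,
  -1.04, 0.00, -0.24, -1.10, -0.55, -2.05, 0.96, -0.76, 0.45, 0.93,
  -0.34, 0.82, -0.23, 1.70, 1.54, -1.62, 1.15, -0.08, -0.48, 0.60,
  -1.40, 0.18, -0.42, -0.73, 2.00, 1.52, 0.26, 0.11, -1.27, 0.27,
  -0.21, 0.98, -0.36, -1.43, 0.22, -0.81, 0.67, 1.10, 1.71, -0.44,
  2.06, -0.33, -1.15, -0.75, 0.88, -0.45, 0.30, -2.30, 0.74, -0.28,
  0.81, -1.08, 0.16, 0.42, -0.21, -0.43, -1.89, -1.15, -0.97, -0.23,
  0.26, -0.70, 1.21, 0.63, -0.10, 0.21, 0.24, -1.15, -0.56, 0.19,
  0.30, 2.10, -0.72, -1.57, -1.16, 0.57, -0.48, -0.40, -2.30, -0.60,
  1.38, 1.48, 0.80, -0.56, 0.00, -0.68, -0.31, 1.03, -0.05, 0.53,
  -0.74, -0.71, 2.04, -0.40, 0.50, -0.81, -1.07, 0.06, -0.46, 0.65),
  10, "kidera_kf")

## MS-WHIM statistical scores.
SCALE_MSWHIM <- aaScaleMatrix(c(
  -0.73, 0.20, -0.62,
  -0.22, 0.27, 1.00,
  0.14, 0.20, -0.66,
  0.11, -1.00, -0.96,
  -0.66, 0.26, -0.27,
  0.30, 1.00, -0.30,
  0.24, -0.39, -0.04,
  -0.31, -0.28, -0.75,
  0.84, 0.67, -0.78,
  -0.91, 0.83, -0.25,
  -0.74, 0.72, -0.16,
  -0.51, 0.08, 0.60,
  -0.70, 1.00, -0.32,
  0.76, 0.85, -0.34,
  -0.43, 0.73, -0.60,
  -0.80, 0.61, -1.00,
  -0.58, 0.85, -0.89,
  1.00, 0.98, -0.47,
  0.97, 0.66, -0.16,
  -1.00, 0.79, -0.58),
  3, "mswhim")

## ProtFP principal-component fingerprints.
SCALE_PROTFP <- aaScaleMatrix(c(
  -2.01, 0.77, -1.00, -0.22, -1.33, -0.45, 0.48, -0.61,
  3.17, 1.45, 1.12, -1.28, -0.18, -0.37, -0.63, 0.32,
  1.10, -1.43, 0.47, 0.16, 0.98, 0.33, 1.39, 0.30,
  1.47, -2.46, 0.49, -0.24, 0.01, 1.27, 0.12, -0.61,
  -1.34, -0.35, -0.65, 2.28, 1.39, -0.41, 0.33, 1.15,
  1.62, 0.08, 0.82, -0.38, 0.38, 0.26, 0.85, -0.38,
  1.89, -1.77, 0.89, -0.92, -0.53, 1.18, -0.23, -0.77,
  -0.93, -2.04, -2.30, -1.45, 0.84, -0.69, -0.88, -0.17,
  1.73, 1.07, -0.51, 0.61, 1.06, -0.56, -1.06, -0.79,
  -2.30, 1.13, 1.22, 0.86, -0.68, 0.17, 0.15, 0.48,
  -2.25, 0.79, 0.98, 0.34, -0.44, -0.50, -0.41, 0.16,
  2.55, 1.16, 0.83, -0.92, 0.30, -0.61, -0.11, 1.29,
  -1.78, 1.12, 0.60, 0.47, 1.02, 1.10, -0.25, -0.49,
  -2.46, 1.47, 0.34, -0.67, 0.76, -0.26, 0.55, -0.31,
  0.50, -2.45, 0.14, 1.53, -1.47, -0.76, 0.90, 0.82,
  0.04, -1.27, -0.50, 0.13, 0.64, 0.28, 0.16, -0.31,
  -0.35, -0.64, 0.13, 0.35, 0.24, 0.57, 0.62, 0.13,
  -1.12, 2.69, -0.80, -1.33, 0.51, 0.73, 0.52, 0.52,
  -0.77, 2.26, -0.75, -0.69, -0.77, -0.02, -0.38, -0.70,
  -2.19, 0.42, 0.48, 1.27, -0.73, -0.51, -0.12, -0.03),
  8, "protfp")

## ST-scales (topological/structural PCA scores).
SCALE_ST <- aaScaleMatrix(c(
  -1.55, -0.79, -0.63, 0.24, -0.46, -2.23, 0.28, 1.22,
  1.70, 1.45, 0.13, -1.35, 0.48, 0.91, 0.08, -0.07,
  0.35, -0.77, 0.61, 0.26, 1.11, 0.37, 1.05, -0.31,
  0.45, -1.41, 0.57, -0.39, 0.52, 0.85, 0.04, -0.36,
  -1.03, -0.55, -0.10, 1.81, 0.67, 0.41, -1.01, 0.43,
  0.69, 0.05, 0.72, -0.34, 0.69, 0.43, 0.16, -0.23,
  0.81, -1.06, 0.96, -0.86, 0.25, 1.04, -0.37, -0.26,
  -1.92, -1.53, -1.12, -0.99, 0.61, -0.59, -0.35, 0.49,
  0.55, 0.91, 0.05, 0.23, 0.86, -0.33, -0.98, -0.70,
  -1.23, 0.67, 0.60, 0.83, -0.70, 0.32, 0.26, 0.17,
  -1.28, 0.55, 0.43, 0.46, -0.56, -0.41, -0.46, 0.08,
  1.30, 1.01, 0.30, -1.07, 0.35, -0.47, 0.06, 0.98,
  -0.97, 0.69, 0.47, 0.44, 0.79, 0.61, -0.31, -0.51,
  -1.21, 1.02, 0.26, -0.48, 0.55, -0.16, 0.68, -0.20,
  -0.23, -1.66, 0.24, 1.15, -1.07, -0.68, 0.72, 0.70,
  -0.54, -0.94, -0.31, 0.18, 0.65, 0.25, 0.30, -0.22,
  -0.65, -0.55, -0.03, 0.34, 0.30, 0.51, 0.64, 0.22,
  -0.57, 1.92, -0.52, -1.07, 0.43, 0.62, 0.50, 0.45,
  -0.45, 1.61, -0.44, -0.56, -0.54, 0.03, -0.33, -0.56,
  -1.33, 0.31, 0.37, 0.89, -0.66, -0.40, -0.10, -0.05),
  8, "st")

## T-scales (topological descriptors PCA).
SCALE_T <- aaScaleMatrix(c(
  -9.11, -1.63, 0.63, 1.04, 2.26,
  0.23, 3.89, -1.16, -0.39, -0.06,
  -4.62, 0.66, 1.16, -0.22, 0.93,
  -4.65, 0.75, 1.39, -0.40, 1.05,
  -7.35, -0.86, -0.33, 0.80, 0.98,
  -3.00, 1.72, 0.28, -0.39, 0.33,
  -3.03, 1.82, 0.51, -0.58, 0.43,
  -10.61, -1.21, -0.12, 0.75, 3.25,
  -1.01, -1.31, 0.01, -1.81, -0.21,
  -4.25, -0.28, -0.15, 1.40, -0.21,
  -4.38, 0.28, -0.49, 1.45, 0.02,
  -2.59, 2.34, -1.69, 0.41, -0.21,
  -4.08, 0.98, -2.34, 1.64, -0.79,
  0.49, -0.94, -0.63, -1.27, -0.44,
  -5.11, -3.54, -0.53, -0.36, -0.29,
  -7.44, -0.65, 0.68, -0.17, 1.58,
  -5.97, -0.62, 1.11, 0.31, 0.95,
  5.73, -2.67, -0.07, -1.96, -0.54,
  2.08, -0.47, 0.07, -1.67, -0.35,
  -5.87, -0.94, 0.28, 1.10, 0.48),
  5, "t")

## VHSE: principal components of hydrophobic (1-2), steric (3-4) and
## electronic (5-8) properties.
SCALE_VHSE <- aaScaleMatrix(c(
  0.15, -1.11, -1.35, -0.92, 0.02, -0.91, 0.36, -0.48,
  -1.47, 1.45, 1.24, 1.27, 1.55, 1.47, 1.30, 0.83,
  -0.99, 0.00, -0.37, 0.69, -0.55, 0.85, 0.73, -0.80,
  -1.15, 0.67, -0.41, -0.01, -2.68, 1.31, 0.03, 0.56,
  0.18, -1.67, -0.46, -0.21, 0.00, 1.20, -1.61, -0.19,
  -0.96, 0.12, 0.18, 0.16, 0.09, 0.42, -0.20, -0.41,
  -1.18, 0.40, 0.10, 0.36, -2.16, -0.17, 0.91, 0.02,
  -0.20, -1.53, -2.63, 2.28, -0.53, -1.18, 2.01, -1.34,
  -0.43, -0.25, 0.37, 0.19, 0.51, 1.28, 0.93, 0.65,
  1.27, -0.14, 0.30, -1.80, 0.30, -1.61, -0.16, -0.13,
  1.36, 0.07, 0.26, -0.80, 0.22, -1.37, 0.08, -0.62,
  -1.17, 0.70, 0.70, 0.80, 1.64, 0.67, 1.63, 0.13,
  1.01, -0.53, 0.43, 0.00, 0.23, 0.10, -0.86, -0.68,
  1.52, 0.61, 0.96, -0.16, 0.25, 0.28, -1.33, -0.20,
  0.22, -0.17, -0.50, 0.05, -0.01, -1.34, -0.19, 3.56,
  -0.67, -0.86, -1.07, -0.41, -0.32, 0.27, -0.64, 0.11,
  -0.34, -0.51, -0.55, -1.06, -0.06, -0.01, -0.79, 0.39,
  1.50, 2.06, 1.79, 0.75, 0.75, -0.13, -1.01, -0.85,
  0.61, 1.60, 1.17, 0.73, 0.53, 0.25, -0.96, -0.52,
  0.76, -0.92, -0.17, -1.91, 0.22, -1.40, -0.24, -0.03),
  8, "vhse")

## zScales: z1 lipophilicity, z2 steric bulk/polarizability,
## z3 polarity/charge, z4-z5 electronegativity/electrophilicity.
SCALE_Z <- aaScaleMatrix(c(
  0.24, -2.32, 0.60, -0.14, 1.30,
  3.52, 2.50, -3.50, 1.99, -0.17,
  3.05, 1.62, 1.04, -1.15, 1.61,
  3.98, 0.93, 1.93, -2.46, 0.75,
  0.84, -1.67, 3.71, 0.18, -2.65,
  1.75, 0.50, -1.44, -1.34, 0.66,
  3.11, 0.26, -0.11, -3.04, -0.25,
  2.05, -4.06, 0.36, -0.82, -0.38,
  2.47, 1.95, 0.26, 3.90, 0.09,
  -3.89, -1.73, -1.71, -0.84, 0.26,
  -4.28, -1.30, -1.49, -0.72, 0.84,
  2.29, 0.89, -2.49, 1.49, 0.31,
  -2.85, -0.22, 0.47, 1.94, -0.98,
  -4.22, 1.94, 1.06, 0.54, -0.62,
  -1.66, 0.27, 1.84, 0.70, 2.00,
  2.39, -1.07, 1.15, -1.39, 0.67,
  0.75, -2.18, -1.12, -1.46, -0.40,
  -4.36, 3.94, 0.59, 3.44, -1.59,
  -2.54, 2.44, 0.43, 0.04, -1.47,
  -2.59, -2.64, -1.54, -0.85, -0.02),
  5, "zscale_z")

#' Per-residue descriptor scale families
#'
#' The ten canonical scale families whose dimensions sum to 66: BLOSUM
#' indices (10), Cruciani properties (3), FASGAI vectors (6), Kidera
#' factors (10), MS-WHIM (3), ProtFP (8), ST-scales (8), T-scales (5),
#' VHSE (8) and zScales (5).  Each element is a 20 x k matrix with
#' one-letter amino-acid rownames.
#'
#' @return named list of numeric matrices.
#' @examples
#' sum(vapply(scaleDescriptorFamilies(), ncol, 1L)) # 66
#' @export
scaleDescriptorFamilies <- function() {
  list(blosum = SCALE_BLOSUM, cruciani = SCALE_CRUCIANI,
       fasgai = SCALE_FASGAI, kidera = SCALE_KIDERA,
       mswhim = SCALE_MSWHIM, protfp = SCALE_PROTFP,
       st = SCALE_ST, t = SCALE_T, vhse = SCALE_VHSE, z = SCALE_Z)
}
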