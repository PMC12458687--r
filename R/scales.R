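# Residue-level scales and element tables used by the descriptors.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

# Monera et al. hydrophobicity (pH 7, normalized to Gly = 0).
MONERA <- c(ALA = 41, ARG = -14, ASN = -28, ASP = -55, CYS = 49, GLN = -10,
            GLU = -31, GLY = 0, HIS = 8, ILE = 99, LEU = 97, LYS = -23,
            MET = 74, PHE = 100, PRO = -46, SER = -5, THR = 13, TRP = 97,
            TYR = 63, VAL = 76)

# Kyte-Doolittle hydropathy.
KYTE_DOOLITTLE <- c(ALA = 1.8, ARG = -4.5, ASN = -3.5, ASP = -3.5,
                    CYS = 2.5, GLN = -3.5, GLU = -3.5, GLY = -0.4,
                    HIS = -3.2, ILE = 4.5, LEU = 3.8, LYS = -3.9,
                    MET = 1.9, PHE = 2.8, PRO = -1.6, SER = -0.8,
                    THR = -0.7, TRP = -0.9, TYR = -1.3, VAL = 4.2)

# Residue volumes (Zamyatnin), cubic Angstrom.
RESIDUE_VOLUME <- c(ALA = 88.6, ARG = 173.4, ASN = 114.1, ASP = 111.1,
                    CYS = 108.5, GLN = 143.8, GLU = 138.4, GLY = 60.1,
                    HIS = 153.2, ILE = 166.7, LEU = 166.7, LYS = 168.6,
                    MET = 162.9, PHE = 189.9, PRO = 112.7, SER = 89.0,
                    THR = 116.1, TRP = 227.8, TYR = 193.6, VAL = 140.0)

# Grantham polarity.
GRANTHAM_POLARITY <- c(ALA = 8.1, ARG = 10.5, ASN = 11.6, ASP = 13.0,
                       CYS = 5.5, GLN = 10.5, GLU = 12.3, GLY = 9.0,
                       HIS = 10.4, ILE = 5.2, LEU = 4.9, LYS = 11.3,
                       MET = 5.7, PHE = 5.2, PRO = 8.0, SER = 9.2,
                       THR = 8.6, TRP = 5.4, TYR = 6.2, VAL = 5.9)

# Formal side-chain charge at pH 7.
RESIDUE_CHARGE <- c(ALA = 0, ARG = 1, ASN = 0, ASP = -1, CYS = 0, GLN = 0,
                    GLU = -1, GLY = 0, HIS = 0, ILE = 0, LEU = 0, LYS = 1,
                    MET = 0, PHE = 0, PRO = 0, SER = 0, THR = 0, TRP = 0,
                    TYR = 0, VAL = 0)

# van der Waals radii per element, Angstrom.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, F = 1.47,
               CL = 1.75, BR = 1.85, I = 1.98, FE = 2.00, ZN = 1.39,
               MG = 1.73, SE = 1.90, CO = 2.00)

#' Residue scale set for the scale-based descriptors
#'
#' Bundles the four residue-level maps behind hydrophobicity_score,
#' volume_score, polarity_score and charge_score. All 20 standard residues
#' are present in every map.
#'
#' @param hydrophobicity "monera" (default) or "kd" (Kyte-Doolittle).
#' @return Named list with elements hydrophobicity, volume, polarity,
#'   charge, each a named numeric vector over the 20 standard residues.
#' @export
defaultResidueScales <- function(hydrophobicity = c("monera", "kd")) {
  hydrophobicity <- match.arg(hydrophobicity)
  scales <- list(
    hydrophobicity = if (hydrophobicity == "monera") MONERA
                     else KYTE_DOOLITTLE,
    volume = RESIDUE_VOLUME,
    polarity = GRANTHAM_POLARITY,
    charge = RESIDUE_CHARGE)
  stopifnot(vapply(scales, function(s) all(AA3 %in% names(s)), TRUE))
  scales
}

#' van der Waals radius lookup
#'
#' @param element element symbols.
#' @return Radii in Angstrom; unknown elements raise an error naming the
#'   element.
#' @export
vdwRadius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  if (anyNA(r))
    stop("missing vdW radius for element(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "))
  unname(r)
}
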