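# Residue-level chemistry tables: codes, charges at pH 7.4, masses,
# hydrophobicity, van der Waals radii and reference accessibilities.

.aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
          E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
          M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
          Y = "TYR", V = "VAL")
.aa1 <- structure(names(.aa3), names = .aa3)

## average residue masses (Da, residue = amino acid minus water)
.residue_mass <- c(
  ALA =  71.0788, ARG = 156.1875, ASN = 114.1038, ASP = 115.0886,
  CYS = 103.1388, GLN = 128.1307, GLU = 129.1155, GLY =  57.0519,
  HIS = 137.1411, ILE = 113.1594, LEU = 113.1594, LYS = 128.1741,
  MET = 131.1926, PHE = 147.1766, PRO =  97.1167, SER =  87.0782,
  THR = 101.1051, TRP = 186.2132, TYR = 163.1760, VAL =  99.1326)

## residues counted as hydrophobic in the longitudinal profiles
.hydrophobic_set <- c("ALA", "GLY", "ILE", "LEU", "MET", "PHE", "PRO", "VAL")

## Bondi van der Waals radii (A) for heavy elements met in protein structures
.vdw_radius <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                 SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

## Tien et al. (2013) theoretical maximum SASA (A^2) of residue X in an
## extended Gly-X-Gly tripeptide; reference for relative solvent accessibility
.max_sasa <- c(
  ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
  GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
  LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
  SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)

## ion species recognized as bound hetero ions, with charge and mass
.ion_table <- data.frame(
  resid   = c("CA", "MG", "ZN", "NA", "K", "CL"),
  element = c("CA", "MG", "ZN", "NA", "K", "CL"),
  charge  = c(2, 2, 2, 1, 1, -1),
  mass    = c(40.078, 24.305, 65.38, 22.990, 39.098, 35.45),
  stringsAsFactors = FALSE)

#' Default residue charge rules at pH 7.4
#'
#' Aspartate and glutamate are fully deprotonated (-1), lysine and arginine
#' fully protonated (+1), histidine (and every other residue type, including
#' cysteine and tyrosine) neutral. Free N- and C-termini carry +1 and -1;
#' the C-terminal charge of a chain whose C-terminal residues are unresolved
#' in the structure is set to zero (that terminus is not physically present
#' in the modeled fragment). Bound calcium ions carry +2.
#'
#' @return An object of class `charge_rules`: list with `residue` (named
#'   numeric vector over 3-letter codes), `n_terminal`, `c_terminal`, and
#'   `ions` (named numeric vector).
#' @export
#' @examples
#' rules <- default_charge_rules()
#' rules$residue[c("ASP", "LYS", "HIS")]
default_charge_rules <- function() {
  res <- structure(numeric(length(.aa3)), names = unname(.aa3))
  res[c("ASP", "GLU")] <- -1
  res[c("LYS", "ARG")] <- +1
  x <- list(
    residue = res,
    n_terminal = +1,
    c_terminal = -1,
    ions = structure(.ion_table$charge, names = .ion_table$resid)
  )
  class(x) <- "charge_rules"
  x
}

#' Hydrophobic residue set
#'
#' Three-letter codes of the residues counted as hydrophobic in the
#' longitudinal hydrophobicity profiles (Ala, Gly, Ile, Leu, Met, Phe, Pro,
#' Val).
#'
#' @return Character vector of 3-letter codes.
#' @export
hydrophobic_residues <- function() .hydrophobic_set

## translate a 1-letter sequence to 3-letter codes, with position-aware errors
.seq_to_codes <- function(sequence) {
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!letters1 %in% names(.aa3))
  if (length(bad))
    stop(sprintf("invalid amino-acid letter '%s' at position %d",
                 letters1[bad[1]], bad[1]))
  unname(.aa3[letters1])
}
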