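# Amino-acid reference data used by the coarse-graining rules and the
# synthetic structure generator. Side-chain atom lists include CB (placement);
# note that for coarse-graining CB is counted to the *backbone* centroid.

AA_CODES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
              "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
              "TYR", "VAL")

# side-chain heavy atoms (name = element), CB included
AA_SIDECHAIN <- list(
  ALA = c(CB = "C"),
  ARG = c(CB = "C", CG = "C", CD = "C", NE = "N", CZ = "C", NH1 = "N", NH2 = "N"),
  ASN = c(CB = "C", CG = "C", OD1 = "O", ND2 = "N"),
  ASP = c(CB = "C", CG = "C", OD1 = "O", OD2 = "O"),
  CYS = c(CB = "C", SG = "S"),
  GLN = c(CB = "C", CG = "C", CD = "C", OE1 = "O", NE2 = "N"),
  GLU = c(CB = "C", CG = "C", CD = "C", OE1 = "O", OE2 = "O"),
  GLY = character(0),
  HIS = c(CB = "C", CG = "C", ND1 = "N", CD2 = "C", CE1 = "C", NE2 = "N"),
  ILE = c(CB = "C", CG1 = "C", CG2 = "C", CD1 = "C"),
  LEU = c(CB = "C", CG = "C", CD1 = "C", CD2 = "C"),
  LYS = c(CB = "C", CG = "C", CD = "C", CE = "C", NZ = "N"),
  MET = c(CB = "C", CG = "C", SD = "S", CE = "C"),
  PHE = c(CB = "C", CG = "C", CD1 = "C", CD2 = "C", CE1 = "C", CE2 = "C", CZ = "C"),
  PRO = c(CB = "C", CG = "C", CD = "C"),
  SER = c(CB = "C", OG = "O"),
  THR = c(CB = "C", OG1 = "O", CG2 = "C"),
  TRP = c(CB = "C", CG = "C", CD1 = "C", CD2 = "C", NE1 = "N", CE2 = "C",
          CE3 = "C", CZ2 = "C", CZ3 = "C", CH2 = "C"),
  TYR = c(CB = "C", CG = "C", CD1 = "C", CD2 = "C", CE1 = "C", CE2 = "C",
          CZ = "C", OH = "O"),
  VAL = c(CB = "C", CG1 = "C", CG2 = "C")
)

#' Background amino-acid composition
#'
#' Approximate natural amino-acid frequencies (UniProt/Swiss-Prot scale),
#' used as the default composition of the synthetic structure generator.
#' With this composition an average residue carries about 8 heavy atoms.
#'
#' @return Named numeric vector over the 20 standard residues, summing to 1.
#' @export
aa_frequencies <- function() {
  f <- c(ALA = 8.3, ARG = 5.5, ASN = 4.1, ASP = 5.5, CYS = 1.4, GLN = 3.9,
         GLU = 6.7, GLY = 7.1, HIS = 2.3, ILE = 5.9, LEU = 9.7, LYS = 5.8,
         MET = 2.4, PHE = 3.9, PRO = 4.7, SER = 6.6, THR = 5.4, TRP = 1.1,
         TYR = 2.9, VAL = 6.9)
  f / sum(f)
}

# backbone atom names whose centroid defines the backbone bead; CB belongs
# here (it is excluded from the side-chain centroid), OXT is a heavy
# backbone atom on the terminal residue
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "CB", "OXT")
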