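# single packaged element tables; a documented simplification relative
# to probe-style per-atom typing
VDW_RADII <- c(H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
               P = 1.80, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
VDW_DEFAULT <- 1.70

COV_RADII <- c(H = 0.31, D = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05,
               P = 1.07, SE = 1.20, F = 0.57, CL = 1.02, BR = 1.20, I = 1.39)
COV_DEFAULT <- 1.30

vdw_radius <- function(element) {
  r <- VDW_RADII[element]
  r[is.na(r)] <- VDW_DEFAULT
  unname(r)
}

cov_radius <- function(element) {
  r <- COV_RADII[element]
  r[is.na(r)] <- COV_DEFAULT
  unname(r)
}

# ideal backbone internal coordinates (Engh-Huber-like values)
IDEAL_BB <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, ca_cb = 1.521,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8, ang_n_ca_cb = 110.4
)

# hydrogen counts and parent hybridisation per residue side chain;
# each entry: parent atom name -> c(n_H, type) with type sp3/sp2/methyl
# (methyl = sp3 with a single heavy neighbour, staggered placement)
H_TABLE <- list(
  ALA = list(CB = c(3, "methyl")),
  ARG = list(CB = c(2, "sp3"), CG = c(2, "sp3"), CD = c(2, "sp3"),
             NE = c(1, "sp2"), NH1 = c(2, "sp2"), NH2 = c(2, "sp2")),
  ASN = list(CB = c(2, "sp3"), ND2 = c(2, "sp2")),
  ASP = list(CB = c(2, "sp3")),
  CYS = list(CB = c(2, "sp3"), SG = c(1, "sp3")),
  GLN = list(CB = c(2, "sp3"), CG = c(2, "sp3"), NE2 = c(2, "sp2")),
  GLU = list(CB = c(2, "sp3"), CG = c(2, "sp3")),
  GLY = list(),
  HIS = list(CB = c(2, "sp3"), ND1 = c(1, "sp2"), CD2 = c(1, "sp2"),
             CE1 = c(1, "sp2")),
  ILE = list(CB = c(1, "sp3"), CG1 = c(2, "sp3"), CG2 = c(3, "methyl"),
             CD1 = c(3, "methyl")),
  LEU = list(CB = c(2, "sp3"), CG = c(1, "sp3"), CD1 = c(3, "methyl"),
             CD2 = c(3, "methyl")),
  LYS = list(CB = c(2, "sp3"), CG = c(2, "sp3"), CD = c(2, "sp3"),
             CE = c(2, "sp3"), NZ = c(3, "methyl")),
  MET = list(CB = c(2, "sp3"), CG = c(2, "sp3"), CE = c(3, "methyl")),
  PHE = list(CB = c(2, "sp3"), CD1 = c(1, "sp2"), CD2 = c(1, "sp2"),
             CE1 = c(1, "sp2"), CE2 = c(1, "sp2"), CZ = c(1, "sp2")),
  PRO = list(CB = c(2, "sp3"), CG = c(2, "sp3"), CD = c(2, "sp3")),
  SER = list(CB = c(2, "sp3"), OG = c(1, "sp3")),
  THR = list(CB = c(1, "sp3"), OG1 = c(1, "sp3"), CG2 = c(3, "methyl")),
  TRP = list(CB = c(2, "sp3"), CD1 = c(1, "sp2"), NE1 = c(1, "sp2"),
             CE3 = c(1, "sp2"), CZ2 = c(1, "sp2"), CZ3 = c(1, "sp2"),
             CH2 = c(1, "sp2")),
  TYR = list(CB = c(2, "sp3"), CD1 = c(1, "sp2"), CD2 = c(1, "sp2"),
             CE1 = c(1, "sp2"), CE2 = c(1, "sp2"), OH = c(1, "sp3")),
  VAL = list(CB = c(1, "sp3"), CG1 = c(3, "methyl"), CG2 = c(3, "methyl"))
)

H_BOND_LENGTH <- c(C = 1.09, N = 1.01, O = 0.96, S = 1.34)

# chi-angle atom quads per residue type
CHI1_ATOMS <- list(
  ARG = c("N", "CA", "CB", "CG"),  ASN = c("N", "CA", "CB", "CG"),
  ASP = c("N", "CA", "CB", "CG"),  CYS = c("N", "CA", "CB", "SG"),
  GLN = c("N", "CA", "CB", "CG"),  GLU = c("N", "CA", "CB", "CG"),
  HIS = c("N", "CA", "CB", "CG"),  ILE = c("N", "CA", "CB", "CG1"),
  LEU = c("N", "CA", "CB", "CG"),  LYS = c("N", "CA", "CB", "CG"),
  MET = c("N", "CA", "CB", "CG"),  PHE = c("N", "CA", "CB", "CG"),
  PRO = c("N", "CA", "CB", "CG"),  SER = c("N", "CA", "CB", "OG"),
  THR = c("N", "CA", "CB", "OG1"), TRP = c("N", "CA", "CB", "CG"),
  TYR = c("N", "CA", "CB", "CG"),  VAL = c("N", "CA", "CB", "CG1")
)

CHI2_ATOMS <- list(
  ARG = c("CA", "CB", "CG", "CD"),  ASN = c("CA", "CB", "CG", "OD1"),
  ASP = c("CA", "CB", "CG", "OD1"), GLN = c("CA", "CB", "CG", "CD"),
  GLU = c("CA", "CB", "CG", "CD"),  HIS = c("CA", "CB", "CG", "ND1"),
  ILE = c("CA", "CB", "CG1", "CD1"), LEU = c("CA", "CB", "CG", "CD1"),
  LYS = c("CA", "CB", "CG", "CD"),  MET = c("CA", "CB", "CG", "SD"),
  PHE = c("CA", "CB", "CG", "CD1"), PRO = c("CA", "CB", "CG", "CD"),
  TRP = c("CA", "CB", "CG", "CD1"), TYR = c("CA", "CB", "CG", "CD1")
)

# residue types whose chi2 rotates an sp2 (planar) group: broad modes
CHI2_SP2 <- c("ASN", "ASP", "HIS", "PHE", "TRP", "TYR")

# coarse rotamer mode lists: per type, matrix with columns chi1, chi2
# (NA when undefined), weight. Compiled from the canonical
# gauche-/trans/gauche+ preferences of high-resolution structures.
ROTAMER_MODES <- list(
  SER = rbind(c(-65, NA, .45), c(62, NA, .30), c(178, NA, .25)),
  CYS = rbind(c(-65, NA, .55), c(-178, NA, .25), c(62, NA, .20)),
  THR = rbind(c(62, NA, .45), c(-60, NA, .45), c(-175, NA, .10)),
  VAL = rbind(c(175, NA, .70), c(-60, NA, .20), c(63, NA, .10)),
  LEU = rbind(c(-65, 175, .60), c(-172, 65, .30), c(-85, 65, .05),
              c(65, 175, .05)),
  ILE = rbind(c(-65, 170, .60), c(-57, -60, .15), c(62, 170, .15),
              c(-177, 165, .10)),
  MET = rbind(c(-65, 180, .30), c(-65, -65, .25), c(-177, 180, .25),
              c(62, 180, .20)),
  LYS = rbind(c(-65, 180, .40), c(-177, 180, .35), c(62, 180, .25)),
  ARG = rbind(c(-65, 180, .40), c(-177, 180, .35), c(62, 180, .25)),
  GLN = rbind(c(-65, 180, .40), c(-177, 180, .35), c(62, 180, .25)),
  GLU = rbind(c(-65, 180, .40), c(-177, 180, .35), c(62, 180, .25)),
  ASN = rbind(c(-65, -20, .45), c(-177, 0, .30), c(62, 0, .25)),
  ASP = rbind(c(-70, -15, .45), c(-177, 0, .30), c(62, 0, .25)),
  HIS = rbind(c(-65, -75, .40), c(-177, 75, .35), c(62, -75, .25)),
  PHE = rbind(c(-65, 90, .45), c(-177, 80, .35), c(62, 90, .20)),
  TYR = rbind(c(-65, 90, .45), c(-177, 80, .35), c(62, 90, .20)),
  TRP = rbind(c(-65, 95, .40), c(-177, -105, .35), c(62, 90, .25)),
  PRO = rbind(c(30, NA, .50), c(-25, NA, .50))
)
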