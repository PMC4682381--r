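# Chemistry lookup tables: van der Waals radii, reference maximal ASA,
# residue polarity classes, donor/acceptor atoms, formal charges,
# atomic solvation parameters, and the pairwise atom-typing scheme.

#' Standard three-letter amino-acid codes
#'
#' The 20 standard residues that enter polarity statistics.
#' @return Character vector of 20 three-letter codes.
#' @export
standard_residues <- function() {
  c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
}

# Aliases for common modified residues, mapped to the parent standard residue.
.residue_aliases <- c(
  MSE = "MET", SEC = "CYS", CSO = "CYS", CME = "CYS", OCS = "CYS",
  SEP = "SER", TPO = "THR", PTR = "TYR", MLY = "LYS", KCX = "LYS",
  HYP = "PRO", PCA = "GLU", CGU = "GLU", FME = "MET", MLE = "LEU"
)

#' Map residue names to their standard parent
#'
#' Modified residues with a known parent (e.g. selenomethionine MSE) are
#' renamed to the parent three-letter code; anything else is returned as is.
#' @param resid character vector of residue names.
#' @return character vector of the same length.
#' @export
canonical_residue <- function(resid) {
  hit <- resid %in% names(.residue_aliases)
  resid[hit] <- unname(.residue_aliases[resid[hit]])
  resid
}

#' Van der Waals radius table
#'
#' Chothia-class protein radius set: aliphatic/carbonyl carbon 1.87 A,
#' aromatic carbon 1.76 A, nitrogen 1.65 A, oxygen 1.40 A, sulfur 1.85 A,
#' with element-level fallbacks for atoms outside the named set.
#'
#' @param carbonyl_c,aliphatic_c,aromatic_c,nitrogen,oxygen,sulfur radii in
#'   Angstrom, exposed so a different published compilation can be swapped in.
#' @return A list with components `by_class` (named radii), `aromatic`
#'   (residue -> aromatic carbon atom names) and `element` (fallback radii),
#'   of class `"ppi_radius_table"`.
#' @export
ppi_radius_table <- function(carbonyl_c = 1.76, aliphatic_c = 1.87,
                             aromatic_c = 1.76, nitrogen = 1.65,
                             oxygen = 1.40, sulfur = 1.85) {
  aromatic <- list(
    PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
    HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
    ARG = c("CZ")
  )
  structure(list(
    by_class = c(C_carbonyl = carbonyl_c, C_aliphatic = aliphatic_c,
                 C_aromatic = aromatic_c, N = nitrogen, O = oxygen,
                 S = sulfur),
    aromatic = aromatic,
    element = c(C = aliphatic_c, N = nitrogen, O = oxygen, S = sulfur,
                P = 1.90, H = 1.00, SE = sulfur, F = 1.47, CL = 1.75,
                BR = 1.85, I = 1.98)
  ), class = "ppi_radius_table")
}

#' Reference maximal accessible surface areas
#'
#' Theoretical maximum ASA per residue type (Gly-X-Gly extended context,
#' Tien et al. 2013 theoretical values), in square Angstrom. Used to turn an
#' absolute residue ASA into a relative accessibility.
#' @return Named numeric vector over the 20 standard residues.
#' @export
max_asa_reference <- function() {
  c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
    GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
    LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
    SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)
}

#' Residue polarity / charge classification scheme
#'
#' Polar residues are R, N, D, E, Q, H, K, S, T, Y; nonpolar residues are
#' A, C, G, I, L, M, F, P, V, W. The charged subset defaults to D, E, K, R;
#' histidine can be included as charged.
#'
#' @param charged_his logical; treat histidine as charged (default `FALSE`).
#' @return List with character-vector components `polar`, `nonpolar`,
#'   `charged` (three-letter codes), class `"ppi_class_scheme"`.
#' @export
residue_class_scheme <- function(charged_his = FALSE) {
  polar <- c("ARG", "ASN", "ASP", "GLU", "GLN", "HIS", "LYS", "SER",
             "THR", "TYR")
  nonpolar <- c("ALA", "CYS", "GLY", "ILE", "LEU", "MET", "PHE", "PRO",
                "VAL", "TRP")
  charged <- c("ASP", "GLU", "LYS", "ARG")
  if (charged_his) charged <- c(charged, "HIS")
  structure(list(polar = polar, nonpolar = nonpolar, charged = charged),
            class = "ppi_class_scheme")
}

# Side-chain hydrogen-bond donor and acceptor heavy atoms, plus backbone.
# Heavy-atom chemistry only: the donor is the electronegative atom carrying
# the (unseen) hydrogen.
.donor_atoms <- list(
  backbone = "N",
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), LYS = "NZ", SER = "OG", THR = "OG1",
  TRP = "NE1", TYR = "OH", CYS = "SG"
)
.acceptor_atoms <- list(
  backbone = c("O", "OXT"),
  ASN = "OD1", ASP = c("OD1", "OD2"), GLN = "OE1", GLU = c("OE1", "OE2"),
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH", MET = "SD"
)

#' Donor/acceptor and charged-atom table
#'
#' Heavy-atom hydrogen-bond donors and acceptors per residue type (backbone N
#' donates, backbone O/OXT accepts), and the formally charged side-chain
#' atoms used for salt-bridge detection: Asp OD1/OD2 and Glu OE1/OE2 plus the
#' C-terminal OXT as negative; Lys NZ and Arg NH1/NH2/NE (and His ND1/NE2
#' when histidine is treated as charged) as positive.
#'
#' @param charged_his logical; include histidine ring nitrogens as positive.
#' @return List with components `donors`, `acceptors`, `positive`, `negative`
#'   (each residue -> atom-name vectors; `backbone` applies to all residues).
#' @export
donor_acceptor_table <- function(charged_his = FALSE) {
  positive <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"))
  if (charged_his) positive$HIS <- c("ND1", "NE2")
  list(
    donors = .donor_atoms,
    acceptors = .acceptor_atoms,
    positive = positive,
    negative = list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
                    backbone = "OXT")
  )
}

#' Atomic solvation parameters
#'
#' Eisenberg-McLachlan-style atomic solvation parameters sigma in
#' kcal/(mol A^2) by atom class: carbon positive (burial of nonpolar area is
#' favourable, giving negative solvation free-energy gain), neutral N/O
#' slightly negative, charged oxygen and nitrogen strongly negative, sulfur
#' positive.
#' @return Named numeric vector with classes `C`, `N_O_neutral`, `O_charged`,
#'   `N_charged`, `S`.
#' @export
solvation_params <- function() {
  c(C = 0.016, N_O_neutral = -0.006, O_charged = -0.024,
    N_charged = -0.050, S = 0.021)
}

# Charged side-chain oxygens / nitrogens for solvation-class assignment.
.charged_oxygens <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.charged_nitrogens <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"))

#' Solvation class of an atom
#'
#' Maps (residue, atom, element) to the solvation-parameter class used by
#' [delta_iG()]. Unclassifiable atoms fall back to their element class.
#' @param resid,elety,elesy character vectors: residue name, atom name,
#'   element symbol.
#' @return Character vector of class labels matching [solvation_params()].
#' @export
solvation_class <- function(resid, elety, elesy) {
  n <- length(elety)
  cls <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    el <- toupper(elesy[i])
    at <- elety[i]
    rs <- resid[i]
    cls[i] <-
      if (el == "S" || el == "SE") "S"
      else if (el == "C") "C"
      else if (el == "O" && at %in% .charged_oxygens[[rs]]) "O_charged"
      else if (at == "OXT") "O_charged"
      else if (el == "N" && at %in% .charged_nitrogens[[rs]]) "N_charged"
      else if (el %in% c("N", "O")) "N_O_neutral"
      else NA_character_
  }
  cls
}

#' Pairwise-potential atom typing
#'
#' Collapses (residue, atom) pairs to a compact atom-type alphabet so that
#' distance-bin counts from small training sets stay populated: backbone
#' N/CA/C/O types, side-chain carbon (aliphatic vs aromatic), hydroxyl,
#' amide O/N, carboxylate O, positively charged N, ring N, and sulfur.
#' @param resid,elety,elesy character vectors (residue name, atom name,
#'   element symbol).
#' @return Character vector of atom-type labels.
#' @export
atom_type <- function(resid, elety, elesy) {
  n <- length(elety)
  out <- character(n)
  hydroxyl <- c(SER = "OG", THR = "OG1", TYR = "OH")
  amide_o <- list(ASN = "OD1", GLN = "OE1")
  amide_n <- list(ASN = "ND2", GLN = "NE2")
  ring_n <- list(HIS = c("ND1", "NE2"), TRP = "NE1")
  aro <- ppi_radius_table()$aromatic
  for (i in seq_len(n)) {
    rs <- resid[i]; at <- elety[i]; el <- toupper(elesy[i])
    out[i] <-
      if (at == "N") "N_bb"
      else if (at == "CA") "CA_bb"
      else if (at == "C") "C_bb"
      else if (at %in% c("O", "OXT")) "O_bb"
      else if (el == "S" || el == "SE") "S_sc"
      else if (!is.na(hydroxyl[rs]) && at == hydroxyl[rs]) "O_hydroxyl"
      else if (at %in% amide_o[[rs]]) "O_amide"
      else if (at %in% amide_n[[rs]]) "N_amide"
      else if (at %in% .charged_oxygens[[rs]]) "O_carboxylate"
      else if (at %in% .charged_nitrogens[[rs]]) "N_positive"
      else if (at %in% ring_n[[rs]]) "N_ring"
      else if (el == "C" && at %in% aro[[rs]]) "C_aromatic"
      else if (el == "C") "C_aliphatic"
      else if (el == "N") "N_amide"
      else if (el == "O") "O_amide"
      else paste0("X_", el)
  }
  out
}
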