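# Amino-acid dictionaries and fixed physico-chemical tables.

#' @keywords internal
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
         "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

#' @keywords internal
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

aa3_to_1 <- function(x) {
  out <- AA1[match(toupper(x), AA3)]
  out
}

aa1_to_3 <- function(x) {
  AA3[match(toupper(x), AA1)]
}

## Theoretical maximum accessible surface areas (A^2) per residue
## (Tien et al. 2013, theoretical column), used to turn STRIDE areas into
## relative solvent accessibility.
MAX_ASA <- c(A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
             Q = 225.0, E = 223.0, G = 104.0, H = 224.0, I = 197.0,
             L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
             S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0)

## Pseudo amino acid composition property scales (classic type-I tables):
## hydrophobicity (Tanford), hydrophilicity (Hopp-Woods), side-chain mass.
PSEAA_HYDROPHOBICITY <- c(A = 0.62, R = -2.53, N = -0.78, D = -0.90, C = 0.29,
                          Q = -0.85, E = -0.74, G = 0.48, H = -0.40, I = 1.38,
                          L = 1.06, K = -1.50, M = 0.64, F = 1.19, P = 0.12,
                          S = -0.18, T = -0.05, W = 0.81, Y = 0.26, V = 1.08)

PSEAA_HYDROPHILICITY <- c(A = -0.5, R = 3.0, N = 0.2, D = 3.0, C = -1.0,
                          Q = 0.2, E = 3.0, G = 0.0, H = -0.5, I = -1.8,
                          L = -1.8, K = 3.0, M = -1.3, F = -2.5, P = 0.0,
                          S = 0.3, T = -0.4, W = -3.4, Y = -2.3, V = -1.5)

PSEAA_SIDE_CHAIN_MASS <- c(A = 15.0, R = 101.0, N = 58.0, D = 59.0, C = 47.0,
                           Q = 72.0, E = 73.0, G = 1.0, H = 82.0, I = 57.0,
                           L = 57.0, K = 73.0, M = 75.0, F = 91.0, P = 42.0,
                           S = 31.0, T = 45.0, W = 130.0, Y = 107.0, V = 43.0)

## ---------------------------------------------------------------------------
## 40-type heavy-atom classification used by the atomic accessible-surface
## potential. Backbone atoms are shared across residues (glycine CA and
## proline N kept apart); side-chain atoms are grouped by chemical
## environment. The partition is deliberately explicit so another typing
## scheme can be swapped in behind `atom_type_40()`.

ATOM40_GROUPS <- list(
  N.bb        = paste0(setdiff(AA3, "PRO"), ":N"),
  N.pro       = "PRO:N",
  CA.bb       = paste0(setdiff(AA3, "GLY"), ":CA"),
  CA.gly      = "GLY:CA",
  C.bb        = paste0(AA3, ":C"),
  O.bb        = c(paste0(AA3, ":O"), paste0(AA3, ":OXT")),
  CB.aliph    = c("ALA:CB", "VAL:CB", "LEU:CB", "ILE:CB", "PRO:CB",
                  "MET:CB", "LYS:CB", "ARG:CB", "GLN:CB", "GLU:CB"),
  CB.polar    = c("SER:CB", "THR:CB", "CYS:CB", "ASN:CB", "ASP:CB"),
  CB.aro      = c("PHE:CB", "TYR:CB", "TRP:CB", "HIS:CB"),
  C.methyl    = c("VAL:CG1", "VAL:CG2", "LEU:CD1", "LEU:CD2", "ILE:CG2",
                  "ILE:CD1", "THR:CG2"),
  C.ch        = "LEU:CG",
  C.ch2       = c("GLN:CG", "GLU:CG", "ILE:CG1", "LYS:CG", "LYS:CD",
                  "ARG:CG", "PRO:CG"),
  C.ch2.n     = c("LYS:CE", "ARG:CD", "PRO:CD"),
  C.ch2.s     = "MET:CG",
  C.me.s      = "MET:CE",
  C.aro.phe   = c("PHE:CG", "PHE:CD1", "PHE:CD2", "PHE:CE1", "PHE:CE2"),
  C.phe.cz    = "PHE:CZ",
  C.aro.tyr   = c("TYR:CG", "TYR:CD1", "TYR:CD2", "TYR:CE1", "TYR:CE2"),
  C.tyr.cz    = "TYR:CZ",
  C.trp.cg    = c("TRP:CG", "TRP:CD1"),
  C.trp.fused = c("TRP:CD2", "TRP:CE2"),
  C.trp.benz  = c("TRP:CE3", "TRP:CZ2", "TRP:CZ3", "TRP:CH2"),
  C.his.cg    = c("HIS:CG", "HIS:CD2"),
  C.his.ce    = "HIS:CE1",
  C.carboxyl  = c("ASP:CG", "GLU:CD"),
  C.amide     = c("ASN:CG", "GLN:CD"),
  C.guanid    = "ARG:CZ",
  S.thiol     = "CYS:SG",
  S.thioether = "MET:SD",
  O.carboxyl  = c("ASP:OD1", "ASP:OD2", "GLU:OE1", "GLU:OE2"),
  O.amide     = c("ASN:OD1", "GLN:OE1"),
  O.hydroxyl  = c("SER:OG", "THR:OG1"),
  O.phenol    = "TYR:OH",
  N.amide     = c("ASN:ND2", "GLN:NE2"),
  N.lys       = "LYS:NZ",
  N.arg.ne    = "ARG:NE",
  N.arg.nh    = c("ARG:NH1", "ARG:NH2"),
  N.his.nd    = "HIS:ND1",
  N.his.ne    = "HIS:NE2",
  N.trp       = "TRP:NE1"
)

## flat lookup: "RES:ATOM" -> type name
ATOM40_LOOKUP <- local({
  keys <- unlist(ATOM40_GROUPS, use.names = FALSE)
  vals <- rep(names(ATOM40_GROUPS), vapply(ATOM40_GROUPS, length, 1L))
  stats::setNames(vals, keys)
})

#' Classify a heavy atom into one of 40 types
#'
#' Maps `(residue 3-letter code, PDB atom name)` to one of 40 chemically
#' grouped heavy-atom types: the four backbone atoms are shared across
#' residues (with glycine CA and proline N distinguished) and side-chain
#' atoms are grouped by chemical environment.
#'
#' @param resid character vector of 3-letter residue codes.
#' @param atom character vector of PDB atom names (e.g. `"CA"`, `"OD1"`).
#' @return Character vector of type names; `NA` for atoms outside the table
#'   (hydrogens, non-standard atoms).
#' @export
atom_type_40 <- function(resid, atom) {
  unname(ATOM40_LOOKUP[paste0(toupper(resid), ":", toupper(atom))])
}
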