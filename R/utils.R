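# Shared internal helpers: residue keys, residue-name dictionaries, rounding.

AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
         GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
         LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
         SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
         # modified residues mapped to their parent amino acid
         MSE = "M", SEC = "C", PYL = "K")

DNA_RES <- c("DA", "DC", "DG", "DT", "DI")
RNA_RES <- c("A", "C", "G", "U", "I")
WATER_RES <- c("HOH", "WAT", "DOD", "H2O")

# Phosphodiester backbone atoms of a nucleotide; C1' is assigned to the
# backbone (sugar) by the standard convention even though it bonds the base.
NA_BACKBONE_ATOMS <- c("P", "OP1", "OP2", "OP3", "O1P", "O2P", "O3P",
                       "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'",
                       "C1'", "O2'")

#' @keywords internal
res_key <- function(chain, resno, insert = "") {
  insert <- ifelse(is.na(insert) | insert == " ", "", insert)
  sprintf("%s:%s%s", chain, resno, insert)
}

round_half_up <- function(x) floor(x + 0.5)

aa_one <- function(resid) {
  out <- AA3[resid]
  unname(out)
}

molecule_class <- function(resid) {
  ifelse(resid %in% names(AA3), "protein",
         ifelse(resid %in% DNA_RES, "DNA",
                ifelse(resid %in% RNA_RES, "RNA", "other")))
}

# Element symbol inferred from a PDB atom name when the element column is
# empty: first alphabetic character, with two-letter elements recognised.
element_from_name <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  el <- substr(nm, 1, 1)
  el[substr(nm, 1, 2) == "SE"] <- "SE"
  el[substr(nm, 1, 2) == "FE"] <- "FE"
  el[substr(nm, 1, 2) == "ZN"] <- "ZN"
  el[substr(nm, 1, 2) == "MG"] <- "MG"
  el
}

# Van der Waals radii (A) used by the accessibility engine.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               H = 1.20, SE = 1.90, FE = 1.80, ZN = 1.39, MG = 1.73)
VDW_DEFAULT <- 1.80

vdw_radius <- function(element) {
  r <- VDW_RADII[element]
  r[is.na(r)] <- VDW_DEFAULT
  unname(r)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
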