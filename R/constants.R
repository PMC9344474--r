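# Shared vocabularies: atom categories, residue name mapping, conformer labels.

# Sugar-phosphate heavy-atom names. The category split is by covalent identity:
# C1' and O4' belong to the sugar even though they take part in minor-groove
# water bridges.
BACKBONE_ATOMS <- c("P", "OP1", "OP2", "OP3",
                    "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "C1'")

WATER_RESNAMES <- c("HOH", "WAT", "DOD")

#' Default residue-name to one-letter mapping
#'
#' Maps deoxyribonucleotide residue names (including a few common modified
#' bases) to their parent one-letter code. Residues absent from the mapping
#' break the chain at that point during step extraction; the table is
#' user-editable: pass a modified copy to the residue/step functions.
#'
#' @return named character vector, names are residue names, values one of
#'   A, C, G, T.
#' @export
nucleotide_mapping <- function() {
  c(DA = "A", DC = "C", DG = "G", DT = "T",
    A = "A", C = "C", G = "G", T = "T",
    `5CM` = "C", `5MC` = "C", C5M = "C",   # 5-methylcytosine variants
    BRU = "T", `5BU` = "T",                # 5-bromo-dU read as T analogue
    `8OG` = "G")                           # 8-oxoguanine
}

#' Dinucleotide conformer class vocabulary
#'
#' The fixed 97-symbol vocabulary of dinucleotide conformer (NtC) class
#' mnemonics: 96 geometrically defined classes plus the NANT fallback for
#' steps that cannot be classified. Classification itself is pluggable
#' (external assignment tables or a nearest-centroid approximation), so the
#' vocabulary is used for bookkeeping and validation only.
#'
#' @return character vector of length 97; the last element is "NANT".
#' @export
ntc_classes <- function() {
  c(sprintf("AA%02d", 0:13), "AAS1",
    sprintf("AB%02d", 1:5), "AB1S", "AB2S",
    sprintf("BA%02d", c(1, 5, 8, 9, 10, 13, 16, 17)),
    sprintf("BB%02d", c(0:5, 7, 8, 10:17, 20)), "BB1S", "BB2S", "BBS1",
    sprintf("IC%02d", 1:7),
    sprintf("OP%02d", 1:31), "OPS1", "OP1S",
    "ZZ01", "ZZ02", "ZZ1S", "ZZ2S", "ZZS1", "ZZS2",
    "NANT")
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
is_dna_residue <- function(residue_name, mapping = nucleotide_mapping()) {
  residue_name %in% names(mapping)
}
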