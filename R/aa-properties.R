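#' @keywords internal
"_PACKAGE"

## Canonical one-letter amino-acid alphabet used throughout the package.
AA_ONE <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA_THREE <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
              Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
              L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
              S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

#' Convert between one- and three-letter amino-acid codes
#'
#' @param x Character vector of residue codes, one- or three-letter, any case.
#' @return For `aa_one_letter()`, a vector of upper-case one-letter codes;
#'   unknown codes raise an error naming the offender.
#' @examples
#' aa_one_letter(c("Arg", "W", "gly"))
#' @export
aa_one_letter <- function(x) {
  x <- toupper(x)
  out <- ifelse(nchar(x) == 3, names(AA_THREE)[match(x, AA_THREE)], x)
  bad <- is.na(out) | !(out %in% AA_ONE)
  if (any(bad)) {
    stop("not a standard amino-acid code: ", paste(unique(x[bad]), collapse = ", "))
  }
  out
}

#' Physicochemical property truth table for the 20 amino acids
#'
#' The ten binary properties (small, polar, hydrophobic, tiny, charged,
#' negative, positive, aromatic, aliphatic, proline) follow the classic
#' Taylor Venn-diagram assignments used by the Zvelebil conservation
#' method. The table is committed as a fixed constant so that column
#' conservation scores are stable and testable.
#'
#' @return A 20 x 10 logical matrix; rownames are one-letter residue codes,
#'   colnames the property names.
#' @export
aa_property_table <- function() {
  props <- c("small", "polar", "hydrophobic", "tiny", "charged",
             "negative", "positive", "aromatic", "aliphatic", "proline")
  tab <- matrix(FALSE, nrow = 20, ncol = 10,
                dimnames = list(AA_ONE, props))
  set <- function(res, which) tab[res, which] <<- TRUE
  set("A", c("small", "tiny", "hydrophobic"))
  set("C", c("small", "hydrophobic"))
  set("D", c("small", "polar", "negative", "charged"))
  set("E", c("polar", "negative", "charged"))
  set("F", c("hydrophobic", "aromatic"))
  set("G", c("small", "tiny", "hydrophobic"))
  set("H", c("polar", "hydrophobic", "aromatic", "positive", "charged"))
  set("I", c("hydrophobic", "aliphatic"))
  set("K", c("polar", "hydrophobic", "positive", "charged"))
  set("L", c("hydrophobic", "aliphatic"))
  set("M", "hydrophobic")
  set("N", c("small", "polar"))
  set("P", c("small", "proline"))
  set("Q", "polar")
  set("R", c("polar", "positive", "charged"))
  set("S", c("small", "tiny", "polar"))
  set("T", c("small", "polar", "hydrophobic"))
  set("V", c("small", "hydrophobic", "aliphatic"))
  set("W", c("polar", "hydrophobic", "aromatic"))
  set("Y", c("polar", "hydrophobic", "aromatic"))
  tab
}
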