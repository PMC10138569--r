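#' @keywords internal
"_PACKAGE"

## Amino-acid lookup tables used across the package.

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
         Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
         L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
         S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

AA1 <- setNames(names(AA3), AA3)

## het codes recognised as ligands out of the box; the NRPE retinoid substrate
## has no standard het code, so pipelines register aliases (substrate_codes).
DEFAULT_HET_CODES <- c("ATP", "MG", "NRPE")

#' Convert between one- and three-letter amino-acid codes
#'
#' @param x character vector of codes.
#' @return character vector of converted codes; unknown codes give `NA`.
#' @examples
#' aa_three_to_one("GLY")
#' aa_one_to_three("W")
#' @export
aa_three_to_one <- function(x) unname(AA1[toupper(x)])

#' @rdname aa_three_to_one
#' @export
aa_one_to_three <- function(x) unname(AA3[toupper(x)])

## Number of side-chain chi dihedrals per amino acid.
CHI_COUNT <- c(A = 0, G = 0,
               S = 1, C = 1, T = 1, V = 1,
               L = 2, I = 2, P = 2, F = 2, Y = 2, W = 2, H = 2,
               D = 2, N = 2,
               M = 3, E = 3, Q = 3,
               K = 4, R = 4)

## Maximum (standard-state) ASA (A^2) of residue X in an extended Gly-X-Gly
## tripeptide (Miller et al. 1987); normalises ASA to RSA so that a fully
## extended, unoccluded residue scores RSA ~ 1.
MAX_ASA <- c(A = 113, R = 241, N = 158, D = 151, C = 140,
             E = 183, Q = 189, G = 85, H = 194, I = 182,
             L = 180, K = 211, M = 204, F = 218, P = 143,
             S = 122, T = 146, W = 259, Y = 229, V = 160)

## van der Waals radii (A).  Mg as 1.73; unknown elements fall back to 1.7
## with a warning at the call site.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               H = 1.20, MG = 1.73, F = 1.47, CL = 1.75, BR = 1.85,
               SE = 1.90, ZN = 1.39, FE = 1.40, `NA` = 2.27, K = 2.75)

DEFAULT_VDW_RADIUS <- 1.70

## Hydrophobicity classes for the buried-polarity-change rule: a buried
## position whose class changes between ref and alt is scored as a surface /
## packing alteration.  His is grouped as polar here (its charge state is
## context dependent); it is still treated as potentially charged by the
## salt-bridge detector.
HYDROPHOBICITY_CLASS <- c(A = "hydrophobic", V = "hydrophobic", L = "hydrophobic",
                          I = "hydrophobic", M = "hydrophobic", F = "hydrophobic",
                          W = "hydrophobic", C = "hydrophobic", G = "hydrophobic",
                          P = "hydrophobic",
                          S = "polar", T = "polar", N = "polar", Q = "polar",
                          Y = "polar", H = "polar",
                          D = "charged", E = "charged", K = "charged",
                          R = "charged")

## Side-chain atoms carrying formal charge, for salt-bridge detection.
## His is counted as potentially charged (protonatable imidazole N).
CHARGED_POSITIVE_ATOMS <- list(R = c("NE", "NH1", "NH2"),
                               K = "NZ",
                               H = c("ND1", "NE2"))
CHARGED_NEGATIVE_ATOMS <- list(D = c("OD1", "OD2"),
                               E = c("OE1", "OE2"))

vdw_radius <- function(element) {
  el <- toupper(element)
  r <- VDW_RADII[el]
  if (anyNA(r)) {
    bad <- unique(el[is.na(r)])
    warning("no van der Waals radius for element(s) ", paste(bad, collapse = ", "),
            "; using fallback ", DEFAULT_VDW_RADIUS, " A", call. = FALSE)
    r[is.na(r)] <- DEFAULT_VDW_RADIUS
  }
  unname(r)
}

is_standard_aa1 <- function(x) x %in% names(AA3)
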