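## Internal-coordinate side-chain templates (heavy atoms only; hydrogens are
## never built — all geometric criteria downstream are heavy-atom based).
## Each atom is placed by NeRF from three previously placed atoms with ideal
## bond length (A), bond angle (deg) and a torsion that is either a fixed
## value or a named chi ("chi1", "chi2+180", ...).  Bond lengths/angles follow
## standard Engh & Huber-style values.

sc_row <- function(name, a, b, c, bond, angle, tors)
  list(name = name, a = a, b = b, c = c, bond = bond, angle = angle, tors = tors)

## CB placement is common to all non-Gly residues: torsion N-C-CA-CB fixed at
## -122.6 deg gives the L-configuration (matches the observed improper in
## experimental structures).
CB_ROW <- sc_row("CB", "N", "C", "CA", 1.52, 110.4, "-122.6")

SIDECHAIN_TEMPLATES <- list(
  G = list(),
  A = list(CB_ROW),
  S = list(CB_ROW, sc_row("OG",  "N",  "CA", "CB", 1.42, 110.8, "chi1")),
  C = list(CB_ROW, sc_row("SG",  "N",  "CA", "CB", 1.81, 114.0, "chi1")),
  T = list(CB_ROW, sc_row("OG1", "N",  "CA", "CB", 1.43, 109.6, "chi1"),
           sc_row("CG2", "N",  "CA", "CB", 1.52, 110.5, "chi1+122")),
  V = list(CB_ROW, sc_row("CG1", "N",  "CA", "CB", 1.52, 110.5, "chi1"),
           sc_row("CG2", "N",  "CA", "CB", 1.52, 110.5, "chi1-122")),
  L = list(CB_ROW, sc_row("CG",  "N",  "CA", "CB", 1.53, 116.3, "chi1"),
           sc_row("CD1", "CA", "CB", "CG", 1.52, 110.5, "chi2"),
           sc_row("CD2", "CA", "CB", "CG", 1.52, 110.5, "chi2-122")),
  I = list(CB_ROW, sc_row("CG1", "N",  "CA", "CB", 1.53, 110.4, "chi1"),
           sc_row("CG2", "N",  "CA", "CB", 1.53, 110.5, "chi1+123"),
           sc_row("CD1", "CA", "CB", "CG1", 1.51, 113.8, "chi2")),
  P = list(CB_ROW, sc_row("CG",  "N",  "CA", "CB", 1.49, 104.5, "chi1"),
           sc_row("CD",  "CA", "CB", "CG", 1.51, 106.1, "chi2")),
  M = list(CB_ROW, sc_row("CG",  "N",  "CA", "CB", 1.52, 114.1, "chi1"),
           sc_row("SD",  "CA", "CB", "CG", 1.80, 112.7, "chi2"),
           sc_row("CE",  "CB", "CG", "SD", 1.79, 100.9, "chi3")),
  F = list(CB_ROW, sc_row("CG",  "N",  "CA", "CB", 1.50, 113.8, "chi1"),
           sc_row("CD1", "CA", "CB", "CG", 1.39, 120.8, "chi2"),
           sc_row("CD2", "CA", "CB", "CG", 1.39, 120.8, "chi2+180"),
           sc_row("CE1", "CB", "CG", "CD1", 1.39, 120.8, "180"),
           sc_row("CE2", "CB", "CG", "CD2", 1.39, 120.8, "180"),
           sc_row("CZ",  "CG", "CD1", "CE1", 1.39, 120.0, "0")),
  Y = list(CB_ROW, sc_row("CG",  "N",  "CA", "CB", 1.51, 113.9, "chi1"),
           sc_row("CD1", "CA", "CB", "CG", 1.39, 120.8, "chi2"),
           sc_row("CD2", "CA", "CB", "CG", 1.39, 120.8, "chi2+180"),
           sc_row("CE1", "CB", "CG", "CD1", 1.39, 121.1, "180"),
           sc_row("CE2", "CB", "CG", "CD2", 1.39, 121.1, "180"),
           sc_row("CZ",  "CG", "CD1", "CE1", 1.38, 119.5, "0"),
           sc_row("OH",  "CD1", "CE1", "CZ", 1.38, 119.9, "180")),
  W = list(CB_ROW, sc_row("CG",  "N",  "CA", "CB", 1.50, 113.6, "chi1"),
           sc_row("CD1", "CA", "CB", "CG", 1.37, 126.9, "chi2"),
           sc_row("CD2", "CA", "CB", "CG", 1.43, 126.7, "chi2+180"),
           sc_row("NE1", "CB", "CG", "CD1", 1.38, 110.2, "180"),
           sc_row("CE2", "CB", "CG", "CD2", 1.41, 107.2, "180"),
           sc_row("CE3", "CB", "CG", "CD2", 1.40, 133.9, "0"),
           sc_row("CZ2", "CG", "CD2", "CE2", 1.40, 122.4, "180"),
           sc_row("CZ3", "CG", "CD2", "CE3", 1.39, 118.6, "180"),
           sc_row("CH2", "CD2", "CE2", "CZ2", 1.37, 117.5, "0")),
  H = list(CB_ROW, sc_row("CG",  "N",  "CA", "CB", 1.49, 113.7, "chi1"),
           sc_row("ND1", "CA", "CB", "CG", 1.38, 122.7, "chi2"),
           sc_row("CD2", "CA", "CB", "CG", 1.35, 131.0, "chi2+180"),
           sc_row("CE1", "CB", "CG", "ND1", 1.32, 109.0, "180"),
           sc_row("NE2", "CB", "CG", "CD2", 1.37, 107.0, "180")),
  D = list(CB_ROW, sc_row("CG",  "N",  "CA", "CB", 1.52, 113.0, "chi1"),
           sc_row("OD1", "CA", "CB", "CG", 1.25, 119.0, "chi2"),
           sc_row("OD2", "CA", "CB", "CG", 1.25, 119.0, "chi2+180")),
  N = list(CB_ROW, sc_row("CG",  "N",  "CA", "CB", 1.52, 112.7, "chi1"),
           sc_row("OD1", "CA", "CB", "CG", 1.23, 120.8, "chi2"),
           sc_row("ND2", "CA", "CB", "CG", 1.33, 116.5, "chi2+180")),
  E = list(CB_ROW, sc_row("CG",  "N",  "CA", "CB", 1.52, 114.1, "chi1"),
           sc_row("CD",  "CA", "CB", "CG", 1.52, 112.6, "chi2"),
           sc_row("OE1", "CB", "CG", "CD", 1.25, 118.5, "chi3"),
           sc_row("OE2", "CB", "CG", "CD", 1.25, 118.5, "chi3+180")),
  Q = list(CB_ROW, sc_row("CG",  "N",  "CA", "CB", 1.52, 114.1, "chi1"),
           sc_row("CD",  "CA", "CB", "CG", 1.52, 112.6, "chi2"),
           sc_row("OE1", "CB", "CG", "CD", 1.23, 120.9, "chi3"),
           sc_row("NE2", "CB", "CG", "CD", 1.33, 116.4, "chi3+180")),
  K = list(CB_ROW, sc_row("CG",  "N",  "CA", "CB", 1.52, 114.1, "chi1"),
           sc_row("CD",  "CA", "CB", "CG", 1.52, 111.3, "chi2"),
           sc_row("CE",  "CB", "CG", "CD", 1.52, 111.3, "chi3"),
           sc_row("NZ",  "CG", "CD", "CE", 1.49, 111.9, "chi4")),
  R = list(CB_ROW, sc_row("CG",  "N",  "CA", "CB", 1.52, 114.1, "chi1"),
           sc_row("CD",  "CA", "CB", "CG", 1.52, 111.3, "chi2"),
           sc_row("NE",  "CB", "CG", "CD", 1.46, 112.0, "chi3"),
           sc_row("CZ",  "CG", "CD", "NE", 1.33, 124.2, "chi4"),
           sc_row("NH1", "CD", "NE", "CZ", 1.33, 120.0, "0"),
           sc_row("NH2", "CD", "NE", "CZ", 1.33, 120.0, "180"))
)

## Chi-defining atom quadruples, derived from the templates.
chi_atom_quads <- function(aa) {
  tpl <- SIDECHAIN_TEMPLATES[[aa]]
  quads <- list()
  for (row in tpl) {
    m <- regmatches(row$tors, regexec("^chi([0-9])$", row$tors))[[1]]
    if (length(m) == 2L)
      quads[[as.integer(m[2])]] <- c(row$a, row$b, row$c, row$name)
  }
  quads
}

eval_torsion <- function(tors, chis) {
  m <- regmatches(tors, regexec("^chi([0-9])([+-][0-9.]+)?$", tors))[[1]]
  if (length(m)) {
    k <- as.integer(m[2])
    off <- if (nzchar(m[3])) as.numeric(m[3]) else 0
    wrap180(chis[k] + off)
  } else {
    as.numeric(tors)
  }
}

#' Build a side chain from backbone coordinates and chi angles
#'
#' Rebuilds the heavy-atom side chain (including CB) of an amino acid on a
#' fixed backbone using an ideal internal-coordinate template at the supplied
#' chi dihedrals.  Glycine has no side chain; supplying chis for it (or a chi
#' count not matching the amino acid) is an error.
#'
#' @param backbone named list or 3-row matrix with `N`, `CA`, `C` coordinates.
#' @param aa one-letter amino-acid code.
#' @param chis numeric vector of chi dihedrals in degrees (length must equal
#'   the amino acid's chi count).
#' @return numeric matrix of side-chain coordinates, rownames = atom names;
#'   0-row matrix for glycine called with no chis.
#' @export
build_sidechain <- function(backbone, aa, chis = numeric()) {
  aa <- toupper(aa)
  if (!is_standard_aa1(aa)) stop("not a standard amino acid: ", aa)
  if (is.matrix(backbone)) {
    bb <- list(N = backbone["N", ], CA = backbone["CA", ], C = backbone["C", ])
  } else bb <- backbone
  for (nm in c("N", "CA", "C"))
    if (is.null(bb[[nm]]) || length(bb[[nm]]) != 3L)
      stop("backbone must provide 3D coordinates for N, CA and C")
  v1 <- bb$N - bb$CA; v2 <- bb$C - bb$CA
  if (vnorm(cross3(v1, v2)) < 1e-6)
    stop("backbone N/CA/C atoms are collinear; cannot orient a side chain")
  if (aa == "G") {
    if (length(chis))
      stop("glycine has no side chain; chi angles are not applicable")
    return(matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("x", "y", "z"))))
  }
  nchi <- CHI_COUNT[[aa]]
  if (length(chis) != nchi)
    stop(aa_one_to_three(aa), " takes ", nchi, " chi angle(s), got ", length(chis))
  placed <- bb
  tpl <- SIDECHAIN_TEMPLATES[[aa]]
  out <- matrix(NA_real_, nrow = length(tpl), ncol = 3,
                dimnames = list(vapply(tpl, `[[`, "", "name"), c("x", "y", "z")))
  for (row in tpl) {
    tors <- eval_torsion(row$tors, chis)
    xyz <- place_atom(placed[[row$a]], placed[[row$b]], placed[[row$c]],
                      row$bond, row$angle, tors)
    placed[[row$name]] <- xyz
    out[row$name, ] <- xyz
  }
  out
}

#' Measure the chi dihedrals of a placed residue
#'
#' @param coords named list or matrix (rownames = atom names) holding the
#'   residue's backbone and side-chain coordinates.
#' @param aa one-letter amino-acid code.
#' @return numeric vector of chi angles in degrees (length = chi count).
#' @export
measure_chis <- function(coords, aa) {
  aa <- toupper(aa)
  if (is.matrix(coords)) {
    nm <- rownames(coords)
    coords <- setNames(lapply(seq_len(nrow(coords)), function(i) coords[i, ]), nm)
  }
  quads <- chi_atom_quads(aa)
  vapply(quads, function(q) {
    if (any(!q %in% names(coords)))
      stop("missing atom(s) for chi measurement: ",
           paste(setdiff(q, names(coords)), collapse = ", "))
    dihedral_angle(coords[[q[1]]], coords[[q[2]]], coords[[q[3]]], coords[[q[4]]])
  }, numeric(1))
}

sidechain_atom_names <- function(aa)
  vapply(SIDECHAIN_TEMPLATES[[toupper(aa)]], `[[`, "", "name")

## Expected template bond lengths (parent-child), for validation/testing.
sidechain_bonds <- function(aa) {
  tpl <- SIDECHAIN_TEMPLATES[[toupper(aa)]]
  do.call(rbind, lapply(tpl, function(row)
    data.frame(from = row$c, to = row$name, length = row$bond,
               stringsAsFactors = FALSE)))
}
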