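# shared helpers for building tiny structures and comparing angles

angle_diff <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

# a minimal one-residue PDB text (alanine), written to a temp file
minimal_pdb <- function() {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 90.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00 90.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00 90.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00 90.00           O",
    "ATOM      5  CB  ALA A   1       1.988  -0.773  -1.199  1.00 90.00           C",
    "END"), path)
  path
}

# PDB with an ATP HETATM block appended to the alanine
pdb_with_atp <- function() {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 90.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00 90.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00 90.00           C",
    "HETATM    4  PG  ATP A 401       8.000   0.000   0.000  1.00 50.00           P",
    "HETATM    5  O1G ATP A 401       9.200   0.900   0.000  1.00 50.00           O",
    "HETATM    6  O2G ATP A 401       8.100  -1.500   0.200  1.00 50.00           O",
    "END"), path)
  path
}

# rigid-body transform of a whole structure (rotation about z + translation)
rigid_transform <- function(s, theta = 0.6, t = c(5, -3, 2)) {
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, t, "+")
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

coords_of <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

residue_coord_matrix <- function(s, resno) {
  m <- s$atoms[!s$atoms$het & s$atoms$resno == resno, ]
  x <- as.matrix(m[, c("x", "y", "z")])
  rownames(x) <- m$elety
  x
}
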