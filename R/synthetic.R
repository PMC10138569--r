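## Synthetic structure generators: every geometric feature the pipeline
## detects can be planted in a toy structure and recovered, which is how the
## geometry criteria are validated without any external model files.

make_atom_rows <- function(chain, resno, resid, elety, xyz, b = 100, het = FALSE,
                           insert = "") {
  xyz <- matrix(xyz, ncol = 3)
  data.frame(chain = chain, resno = resno, insert = insert, resid = resid,
             elety = elety,
             elesy = guess_element(elety, resid),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1, b = b, het = het,
             stringsAsFactors = FALSE)
}

## Rodrigues rotation aligning unit vector a onto unit vector b.
rotation_align <- function(a, b) {
  a <- unit(a); b <- unit(b)
  v <- cross3(a, b)
  c_ <- sum(a * b)
  if (vnorm(v) < 1e-12) {
    if (c_ > 0) return(diag(3))
    ## antiparallel: rotate pi about any axis orthogonal to a
    axis <- unit(cross3(a, if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
    K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                  -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + K + K %*% K * (1 - c_) / sum(v * v)
}

transform_rows <- function(rows, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(rows[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, t, "+")
  rows$x <- xyz[, 1]; rows$y <- xyz[, 2]; rows$z <- xyz[, 3]
  rows
}

## Build a peptide backbone (N, CA, C, O per residue) at the given phi/psi,
## with side chains from each residue's top-probability rotamer.
build_peptide <- function(seq, phi, psi, chain = "A", start_resno = 1L,
                          b = 100, with_sidechains = TRUE) {
  aa <- strsplit(toupper(seq), "")[[1]]
  n <- length(aa)
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  rows <- list()
  prevN <- prevCA <- prevC <- NULL
  for (i in seq_len(n)) {
    if (i == 1L) {
      N <- c(0, 0, 0)
      CA <- c(1.458, 0, 0)
      C <- place_atom(c(0, 0, 1), N, CA, 1.525, 111.2, 0)
    } else {
      N <- place_atom(prevN, prevCA, prevC, 1.329, 116.2, psi[i - 1L])
      CA <- place_atom(prevCA, prevC, N, 1.458, 121.7, 180)
      C <- place_atom(prevC, N, CA, 1.525, 111.2, phi[i])
    }
    O <- place_atom(N, CA, C, 1.231, 120.5, wrap180(psi[i] + 180))
    resno <- start_resno + i - 1L
    resid <- aa_one_to_three(aa[i])
    rows[[length(rows) + 1L]] <-
      make_atom_rows(chain, resno, resid, c("N", "CA", "C", "O"),
                     rbind(N, CA, C, O), b = b)
    if (with_sidechains && aa[i] != "G") {
      rot <- rotamers_for(aa[i])
      top <- order_rotamers(rot)[1]
      sc <- build_sidechain(list(N = N, CA = CA, C = C), aa[i],
                            rot$chis[[top]])
      if (nrow(sc))
        rows[[length(rows) + 1L]] <-
          make_atom_rows(chain, resno, resid, rownames(sc), sc, b = b)
    }
    prevN <- N; prevCA <- CA; prevC <- C
  }
  do.call(rbind, rows)
}

## One residue with its side chain at given chis, in a local frame.
build_residue <- function(aa, chis = NULL, resno = 1L, chain = "A", b = 100) {
  rows <- build_peptide(aa, phi = -139, psi = 135, chain = chain,
                        start_resno = resno, b = b, with_sidechains = FALSE)
  if (toupper(aa) != "G") {
    if (is.null(chis)) {
      rot <- rotamers_for(aa)
      chis <- rot$chis[[order_rotamers(rot)[1]]]
    }
    bb <- list(N = as.numeric(rows[rows$elety == "N", c("x", "y", "z")]),
               CA = as.numeric(rows[rows$elety == "CA", c("x", "y", "z")]),
               C = as.numeric(rows[rows$elety == "C", c("x", "y", "z")]))
    sc <- build_sidechain(bb, aa, chis)
    if (nrow(sc))
      rows <- rbind(rows, make_atom_rows(chain, resno,
                                         aa_one_to_three(aa), rownames(sc),
                                         sc, b = b))
  }
  rows
}

atom_xyz <- function(rows, elety) {
  as.numeric(rows[rows$elety == elety, c("x", "y", "z")][1, ])
}

## Place a partner residue so that its atom `atom_b` sits at `target` and
## points back along direction `dir` (the residue body extends beyond the
## contact atom, away from the first residue).
place_partner <- function(rows, atom_b, target, dir) {
  p_atom <- atom_xyz(rows, atom_b)
  p_ca <- atom_xyz(rows, "CA")
  R <- rotation_align(unit(p_ca - p_atom), unit(dir))
  rows <- transform_rows(rows, R = R)
  p_atom_new <- atom_xyz(rows, atom_b)
  transform_rows(rows, t = target - p_atom_new)
}

#' Build a toy structure with a planted feature
#'
#' Deterministic miniature structures, each constructed so that exactly the
#' intended geometric feature is present:
#' \describe{
#'   \item{helix}{ideal alpha helix (phi -57, psi -47), `n` residues of
#'     `sequence` (default poly-Ala).}
#'   \item{salt_bridge_pair}{Arg (residue 1) and Glu (residue 10) with the
#'     Arg NH1 to Glu OE1 distance planted at `distance` (default 3.9 A).}
#'   \item{disulfide_pair}{two Cys with SG-SG at `distance` (default 2.05 A).}
#'   \item{atp_pocket}{a Thr residue plus a synthetic ATP fragment: one
#'     phosphate oxygen at `distance` (default 2.9 A) from the Thr `contact_atom`
#'     (default OG1), and two further oxygens positioned along both proline
#'     rotamer directions so that a Thr->Pro substitution both loses the polar
#'     contact and clashes with the ligand in every rotamer.}
#'   \item{cage}{a central Gly enclosed by a carbon shell (radius 4 A around
#'     CA) so that every rotamer of any substitution clashes.}
#'   \item{gxg_tripeptide}{extended Gly-X-Gly (phi -139, psi 135) with
#'     `x = ` the central residue.}
#' }
#'
#' @param kind one of the fixture kinds above.
#' @param n helix length (helix kind).
#' @param sequence helix sequence; default poly-Ala of length `n`.
#' @param x central residue of the tripeptide.
#' @param distance planted contact distance (A), kind-specific default.
#' @param contact_atom Thr atom carrying the ligand contact (atp_pocket).
#' @return `protein_structure`.
#' @export
build_toy_structure <- function(kind = c("helix", "salt_bridge_pair",
                                         "disulfide_pair", "atp_pocket",
                                         "cage", "gxg_tripeptide"),
                                n = 12L, sequence = NULL, x = "A",
                                distance = NULL, contact_atom = "OG1") {
  kind <- match.arg(kind)
  atoms <- switch(
    kind,
    helix = {
      if (is.null(sequence)) sequence <- paste(rep("A", n), collapse = "")
      if (nchar(sequence) < 5L) stop("helix needs at least 5 residues")
      build_peptide(sequence, phi = -57, psi = -47)
    },
    gxg_tripeptide = {
      if (!is_standard_aa1(toupper(x))) stop("invalid central residue: ", x)
      build_peptide(paste0("G", toupper(x), "G"), phi = -139, psi = 135)
    },
    salt_bridge_pair = {
      if (is.null(distance)) distance <- 3.9
      arg <- build_residue("R", resno = 1L)
      glu <- build_residue("E", resno = 10L)
      nh1 <- atom_xyz(arg, "NH1"); cz <- atom_xyz(arg, "CZ")
      dir <- unit(nh1 - cz)
      glu <- place_partner(glu, "OE1", nh1 + distance * dir, dir)
      rbind(arg, glu)
    },
    disulfide_pair = {
      if (is.null(distance)) distance <- 2.05
      c1 <- build_residue("C", resno = 1L)
      c2 <- build_residue("C", resno = 10L)
      sg <- atom_xyz(c1, "SG"); cb <- atom_xyz(c1, "CB")
      dir <- unit(sg - cb)
      c2 <- place_partner(c2, "SG", sg + distance * dir, dir)
      rbind(c1, c2)
    },
    atp_pocket = {
      if (is.null(distance)) distance <- 2.9
      thr <- build_residue("T", resno = 5L)
      anchor <- atom_xyz(thr, contact_atom)
      ca <- atom_xyz(thr, "CA"); cb <- atom_xyz(thr, "CB")
      dir <- unit(anchor - if (contact_atom == "OG1") cb else ca)
      o3b <- anchor + distance * dir
      pb <- o3b + 1.6 * dir
      o1b <- pb + 1.5 * unit(dir + c(0.4, 0.4, 0))
      ## oxygens along both Pro-rotamer CG directions, 4 A out from CB,
      ## so that every Pro rotamer clashes after a T->P substitution
      bb <- list(N = atom_xyz(thr, "N"), CA = ca, C = atom_xyz(thr, "C"))
      pro_rot <- rotamers_for("P")
      cage_o <- t(vapply(pro_rot$chis, function(ch) {
        cg <- build_sidechain(bb, "P", ch)["CG", ]
        cb + 4.0 * unit(cg - cb)
      }, numeric(3)))
      atp <- make_atom_rows("A", 401L, "ATP",
                            c("O3B", "PB", "O1B", "O1A", "O2A"),
                            rbind(o3b, pb, o1b, cage_o), het = TRUE)
      rbind(thr, atp)
    },
    cage = {
      gly <- build_residue("G", resno = 5L)
      ca <- atom_xyz(gly, "CA")
      shell <- sweep(sphere_points(60L) * 4.0, 2, ca, "+")
      cage <- make_atom_rows("A", 501L, "CAG",
                             paste0("C", seq_len(nrow(shell))), shell,
                             het = TRUE)
      rbind(gly, cage)
    })
  rownames(atoms) <- NULL
  new_structure(atoms, source = "predicted")
}

#' Gaussian coordinate perturbation
#'
#' Adds i.i.d. Gaussian displacement (sd `sigma` per coordinate axis) to every
#' atom; deterministic for a given seed.
#'
#' @param s `protein_structure`.
#' @param sigma displacement standard deviation (A), >= 0.
#' @param seed integer seed.
#' @return perturbed `protein_structure`.
#' @export
perturb_coords <- function(s, sigma, seed = 1L) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(s)
  rng <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(rng)) assign(".Random.seed", rng, envir = globalenv()))
  set.seed(seed)
  n <- nrow(s$atoms)
  s$atoms$x <- s$atoms$x + stats::rnorm(n, 0, sigma)
  s$atoms$y <- s$atoms$y + stats::rnorm(n, 0, sigma)
  s$atoms$z <- s$atoms$z + stats::rnorm(n, 0, sigma)
  s
}

#' The packaged 30-variant ABCA4 reference cohort
#'
#' Returns the curated fixture of 30 ABCA4 missense variants (10 benign, 10
#' pathogenic, 10 of uncertain significance): HGVS identities, ddG values,
#' alignment scores, allele frequencies, per-tool predictor calls and encoded
#' structural findings.  The structural findings are an encoding of reported
#' model analyses, not geometry recomputed by this package (the underlying
#' predicted full-length models are not redistributable); see the fixture
#' metadata.
#'
#' @return list with `metadata` and `records` (list of 30 records).
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "abca4_cohort.json", package = "structvar",
                      mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = FALSE)
}

parse_partner <- function(p) {
  if (is.null(p) || is.na(p) || !nzchar(p))
    return(list(resno = NA_integer_, resid = NA_character_))
  if (toupper(p) %in% DEFAULT_HET_CODES || !grepl("^[A-Z][0-9]+$", p))
    return(list(resno = NA_integer_, resid = toupper(p)))
  list(resno = as.integer(sub("^[A-Z]", "", p)),
       resid = aa_one_to_three(substr(p, 1, 1)))
}

findings_to_contacts <- function(items) {
  if (is.null(items) || !length(items)) return(empty_contacts())
  do.call(rbind, lapply(items, function(it) {
    pp <- parse_partner(it$partner)
    data.frame(kind = it$kind, chain_a = "A", resno_a = NA_integer_,
               atom_a = NA_character_, chain_b = "A",
               resno_b = pp$resno, resid_b = pp$resid, atom_b = NA_character_,
               distance = NA_real_,
               domain_relation = if (!is.null(it$relation)) it$relation
               else if (it$kind == "ligand_polar") "ligand" else NA_character_,
               stringsAsFactors = FALSE)
  }))
}

#' Feature set encoded from a fixture record
#'
#' Converts a fixture record's `findings` block into the [feature_set()]
#' consumed by [structural_category()] (fixture-replay mode).
#'
#' @param record one element of `table1_fixture()$records`.
#' @return `feature_set`.
#' @export
fixture_feature_set <- function(record) {
  f <- record$findings
  if (is.null(f)) f <- list()
  flag <- function(nm) isTRUE(f[[nm]])
  wt_rsa <- mut_rsa <- NA_real_
  wt_buried <- mut_buried <- FALSE
  if (flag("buried_exposed_flip")) {
    wt_rsa <- 0.1; mut_rsa <- 0.5; wt_buried <- TRUE; mut_buried <- FALSE
  } else if (flag("buried_gly_replaced") || flag("buried_polarity_change")) {
    wt_rsa <- mut_rsa <- 0.1; wt_buried <- mut_buried <- TRUE
  }
  v <- if (!is.null(record$protein))
    tryCatch(parse_variant_label(record$protein), error = function(e) NULL)
  special <- if (flag("buried_gly_replaced")) "gly_replaced"
  else if (!is.null(v) && v$kind == "missense" && !is.na(v$alt_aa) &&
           v$alt_aa == "P") "pro_introduced"
  else if (!is.null(v) && v$kind == "missense" &&
           ("C" %in% c(v$ref_aa, v$alt_aa))) "cys_involved"
  else "none"
  feature_set(
    lost = findings_to_contacts(f$lost),
    gained = findings_to_contacts(f$gained),
    clash = list(pairs = empty_contacts(),
                 max_overlap = if (flag("all_rotamers_clash")) 0.4 else 0,
                 all_rotamers_clash = flag("all_rotamers_clash")),
    wt_surface = list(asa = NA_real_, rsa = wt_rsa, buried = wt_buried),
    mut_surface = list(asa = NA_real_, rsa = mut_rsa, buried = mut_buried),
    sequon_lost = flag("sequon_lost"),
    pro_in_helix = flag("pro_in_helix"),
    buried_polarity_change = flag("buried_polarity_change"),
    special_residue_change = special)
}
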