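## Rotamer handling: a compact backbone-independent library (shipped as a TSV
## resource) drives in-silico mutagenesis.  The environment is held rigid
## during placement (no repacking), mirroring interactive mutagenesis tools.

.structvar_env <- new.env(parent = emptyenv())

#' The embedded backbone-independent rotamer library
#'
#' A compact set of 1-5 rotamers per amino acid with chi angles (degrees) and
#' library probabilities, after published backbone-independent rotamer
#' libraries.  Probabilities per amino acid sum to at most 1.
#'
#' @return data.frame with columns `aa`, `chi1`..`chi4`, `probability`.
#' @export
rotamer_library <- function() {
  if (is.null(.structvar_env$rotlib)) {
    path <- system.file("extdata", "rotamers.tsv", package = "structvar",
                        mustWork = TRUE)
    .structvar_env$rotlib <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  .structvar_env$rotlib
}

rotamers_for <- function(aa) {
  lib <- rotamer_library()
  rows <- lib[lib$aa == toupper(aa), , drop = FALSE]
  if (nrow(rows) == 0L) stop("no rotamers for amino acid ", aa)
  nchi <- CHI_COUNT[[toupper(aa)]]
  chis <- lapply(seq_len(nrow(rows)), function(i)
    as.numeric(rows[i, paste0("chi", seq_len(nchi))]))
  if (nchi == 0L) chis <- rep(list(numeric()), nrow(rows))
  list(chis = chis, probability = rows$probability)
}

## Ordering: descending probability, ties broken by ascending chi1.
order_rotamers <- function(rot) {
  chi1 <- vapply(rot$chis, function(ch) if (length(ch)) ch[1] else 0, numeric(1))
  order(-rot$probability, chi1)
}

#' Enumerate rotamer placements of a substitution at a site
#'
#' Builds every library rotamer of the target amino acid on the fixed backbone
#' of the focus residue, counts each placement's severe steric clashes against
#' the rigid environment, and returns placements ordered by descending library
#' probability (ties by ascending chi1).
#'
#' @param s `protein_structure`.
#' @param pos author residue number of the focus residue.
#' @param alt_aa one-letter code of the replacement amino acid.
#' @param chain chain id; default first chain.
#' @param clash_overlap van der Waals overlap (A) counted as a severe clash.
#' @return list of placements; each has `aa`, `chis`, `probability`,
#'   `atoms` (side-chain coordinate matrix) and `clash_count`.  The attribute
#'   `all_rotamers_clash` is `TRUE` when every placement clashes.
#' @export
enumerate_rotamers <- function(s, pos, alt_aa, chain = NULL,
                               clash_overlap = 0.4) {
  alt_aa <- toupper(alt_aa)
  res <- residue_atoms(s, pos, chain)
  if (nrow(res) == 0L) stop("no residue numbered ", pos, " in structure")
  rot <- rotamers_for(alt_aa)
  ord <- order_rotamers(rot)
  placements <- lapply(ord, function(i) {
    cand <- replace_sidechain(s, pos, alt_aa, rot$chis[[i]], chain)
    rep_ <- detect_clashes(cand, pos, chain = chain, overlap_threshold = clash_overlap)
    list(aa = alt_aa, chis = rot$chis[[i]], probability = rot$probability[i],
         atoms = attr(cand, "new_sidechain"),
         clash_count = nrow(rep_$pairs))
  })
  attr(placements, "all_rotamers_clash") <-
    all(vapply(placements, function(p) p$clash_count > 0L, logical(1)))
  placements
}

## Swap the side chain of residue `pos` for `alt_aa` at the given chis.
## Backbone atoms (N, CA, C, O, OXT) are untouched; every other residue is
## bit-identical.  The new structure carries the rebuilt side-chain matrix in
## attribute "new_sidechain".
replace_sidechain <- function(s, pos, alt_aa, chis, chain = NULL) {
  res <- residue_atoms(s, pos, chain)
  if (nrow(res) == 0L) stop("no residue numbered ", pos, " in structure")
  the_chain <- res$chain[1]
  bb_names <- c("N", "CA", "C", "O", "OXT")
  get_xyz <- function(nm) {
    row <- res[res$elety == nm, ]
    if (nrow(row) == 0L) stop("focus residue lacks backbone atom ", nm)
    as.numeric(row[1, c("x", "y", "z")])
  }
  bb <- list(N = get_xyz("N"), CA = get_xyz("CA"), C = get_xyz("C"))
  sc <- build_sidechain(bb, alt_aa, chis)
  keep <- !(!s$atoms$het & s$atoms$chain == the_chain & s$atoms$resno == pos &
              !(s$atoms$elety %in% bb_names))
  atoms <- s$atoms[keep, , drop = FALSE]
  ## retag the backbone rows with the new residue identity
  sel <- !atoms$het & atoms$chain == the_chain & atoms$resno == pos
  atoms$resid[sel] <- aa_one_to_three(alt_aa)
  if (nrow(sc)) {
    b_val <- mean(res$b)
    ins <- res$insert[1]
    newrows <- data.frame(chain = the_chain, resno = pos, insert = ins,
                          resid = aa_one_to_three(alt_aa),
                          elety = rownames(sc),
                          elesy = substr(rownames(sc), 1, 1),
                          x = sc[, 1], y = sc[, 2], z = sc[, 3],
                          o = 1, b = b_val, het = FALSE,
                          stringsAsFactors = FALSE)
    ## keep atoms grouped by residue: insert after the residue's backbone rows
    last_bb <- max(which(sel))
    atoms <- rbind(atoms[seq_len(last_bb), , drop = FALSE], newrows,
                   if (last_bb < nrow(atoms))
                     atoms[seq(last_bb + 1L, nrow(atoms)), , drop = FALSE])
  }
  rownames(atoms) <- NULL
  out <- new_structure(atoms, source = s$source)
  attr(out, "new_sidechain") <- sc
  out
}

#' Apply a missense mutation to a structure
#'
#' Replaces the side chain at the variant position with the target amino acid,
#' leaving the backbone and every other residue untouched.  With
#' `placement = "best"` the rotamer with the lowest clash count is chosen
#' (ties resolved by higher library probability, then ascending chi1).
#'
#' @param s `protein_structure`.
#' @param v `variant_spec` (missense).
#' @param placement `"best"`, an integer index into [enumerate_rotamers()]
#'   order, or a placement object from that list.
#' @param chain chain id; default first chain.
#' @return mutated `protein_structure`; attributes `placement` (the rotamer
#'   used) and `all_rotamers_clash`.
#' @export
apply_mutation <- function(s, v, placement = "best", chain = NULL) {
  if (!inherits(v, "variant_spec")) stop("v must be a variant_spec")
  if (v$kind != "missense") stop("apply_mutation handles missense variants only")
  res <- residue_atoms(s, v$position, chain)
  if (nrow(res) == 0L) stop("no residue numbered ", v$position, " in structure")
  found <- aa_three_to_one(res$resid[1])
  if (is.na(found) || found != v$ref_aa)
    stop("reference mismatch at position ", v$position, ": structure has ",
         res$resid[1], " (", found, "), variant expects ", v$ref_aa)
  placements <- enumerate_rotamers(s, v$position, v$alt_aa, chain)
  pick <-
    if (identical(placement, "best")) {
      counts <- vapply(placements, `[[`, integer(1), "clash_count")
      probs <- vapply(placements, `[[`, numeric(1), "probability")
      chi1 <- vapply(placements, function(p)
        if (length(p$chis)) p$chis[1] else 0, numeric(1))
      placements[[order(counts, -probs, chi1)[1]]]
    } else if (is.numeric(placement)) {
      placements[[placement]]
    } else placement
  out <- replace_sidechain(s, v$position, v$alt_aa, pick$chis, chain)
  attr(out, "placement") <- pick
  attr(out, "all_rotamers_clash") <- attr(placements, "all_rotamers_clash")
  out
}
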