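#' Protein structure container
#'
#' A light S3 container for a protein model: one flat atom table plus a
#' provenance tag.  Residue numbering is 1-based author numbering (matching
#' UniProt protein coordinates for single-chain models) and is never
#' renumbered by any operation in the package, so variant positions stay
#' valid after trimming.  The B-factor column is reinterpreted as per-residue
#' pLDDT (0-100) when `source = "predicted"`.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `insert`, `resid`
#'   (three-letter residue / het code), `elety` (atom name), `elesy`
#'   (element symbol), `x`, `y`, `z`, `o` (occupancy), `b` (B-factor or
#'   pLDDT), `het` (logical: ligand/heteroatom record).
#' @param source provenance tag, `"experimental"` or `"predicted"`.
#' @return object of class `protein_structure`.
#' @export
new_structure <- function(atoms, source = c("experimental", "predicted")) {
  source <- match.arg(source)
  required <- c("chain", "resno", "insert", "resid", "elety", "elesy",
                "x", "y", "z", "o", "b", "het")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  atoms <- as.data.frame(atoms)[required]
  if (nrow(atoms) == 0L) stop("a structure needs at least one atom")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates in atom table")
  if (any(!nzchar(atoms$elesy) | is.na(atoms$elesy)))
    stop("empty element symbol in atom table")
  if (any(atoms$o < 0 | atoms$o > 1, na.rm = TRUE))
    stop("occupancy outside [0, 1]")
  prot <- atoms[!atoms$het, ]
  if (nrow(prot)) {
    key <- paste(prot$chain, prot$resno, prot$insert, prot$resid)
    per_res <- unique(prot[, c("chain", "resno", "insert", "resid")])
    dup <- duplicated(per_res[, c("chain", "resno", "insert")])
    if (any(dup))
      stop("duplicate residue number(s) within a chain: ",
           paste(unique(paste0(per_res$chain[dup], ":", per_res$resno[dup])),
                 collapse = ", "))
  }
  structure(list(atoms = atoms, source = source), class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  rt <- residue_table(x)
  cat("<protein_structure> ", sum(!rt$het), " residues, ",
      sum(rt$het), " het groups, ", nrow(x$atoms), " atoms, source: ",
      x$source, "\n", sep = "")
  invisible(x)
}

#' Residue-level summary of a structure
#'
#' @param s `protein_structure`.
#' @return data.frame with one row per residue: `chain`, `resno`, `insert`,
#'   `resid`, `aa` (one-letter code, `NA` for het groups), `het`.
#' @export
residue_table <- function(s) {
  a <- s$atoms
  key <- paste(a$chain, a$resno, a$insert, a$het)
  idx <- !duplicated(key)
  out <- a[idx, c("chain", "resno", "insert", "resid", "het")]
  out$aa <- aa_three_to_one(out$resid)
  rownames(out) <- NULL
  out[, c("chain", "resno", "insert", "resid", "aa", "het")]
}

#' One-letter sequence of a chain
#' @param s `protein_structure`.
#' @param chain chain identifier; default first chain.
#' @return named character vector of one-letter codes, names = residue numbers.
#' @export
chain_sequence <- function(s, chain = NULL) {
  rt <- residue_table(s)
  rt <- rt[!rt$het, ]
  if (is.null(chain)) chain <- rt$chain[1]
  rt <- rt[rt$chain == chain, ]
  rt <- rt[order(rt$resno), ]
  setNames(rt$aa, rt$resno)
}

residue_atoms <- function(s, resno, chain = NULL) {
  a <- s$atoms
  if (is.null(chain)) chain <- a$chain[!a$het][1]
  a[!a$het & a$chain == chain & a$resno == resno, , drop = FALSE]
}

ligand_atoms <- function(s) s$atoms[s$atoms$het, , drop = FALSE]

guess_element <- function(elety, resid) {
  resid <- rep_len(resid, length(elety))
  ifelse(toupper(resid) == "MG", "MG", {
    stripped <- gsub("^[0-9']+", "", elety)
    two <- toupper(substr(stripped, 1, 2))
    ifelse(two %in% c("MG", "FE", "ZN", "CL", "BR", "SE"),
           two, toupper(substr(stripped, 1, 1)))
  })
}

#' Read a structure from PDB or mmCIF
#'
#' ATOM records with standard residue codes become chain residues; HETATM
#' records and unrecognised residue codes are routed to ligands (het) with a
#' warning for unknown codes.  B-factors are preserved (pLDDT for predicted
#' models).
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by extension).
#' @param source provenance tag stored on the result.
#' @return `protein_structure`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           source = c("experimental", "predicted")) {
  format <- match.arg(format)
  source <- match.arg(source)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  raw <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE)
    else suppressWarnings(bio3d::read.cif(path, verbose = FALSE)),
    error = function(e) stop("cannot parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- raw$atom
  if (is.null(at) || nrow(at) == 0L)
    stop("cannot parse ", path, " as ", format, ": no atom records found")
  elesy <- at$elesy
  if (is.null(elesy)) elesy <- rep(NA_character_, nrow(at))
  need <- is.na(elesy) | !nzchar(trimws(elesy))
  elesy[need] <- guess_element(at$elety[need], at$resid[need])
  elesy <- trimws(toupper(elesy))
  chain <- at$chain
  chain[is.na(chain) | !nzchar(chain)] <- "A"
  insert <- at$insert
  if (is.null(insert)) insert <- rep("", nrow(at))
  insert[is.na(insert)] <- ""
  o <- at$o; o[is.na(o)] <- 1
  b <- at$b; b[is.na(b)] <- 0
  resid <- toupper(trimws(at$resid))
  het <- at$type == "HETATM" | !(resid %in% AA3)
  unknown <- het & at$type == "ATOM" & !(resid %in% AA3)
  if (any(unknown))
    warning("unknown residue code(s) routed to ligands: ",
            paste(unique(resid[unknown]), collapse = ", "), call. = FALSE)
  atoms <- data.frame(chain = chain, resno = at$resno, insert = insert,
                      resid = resid, elety = trimws(at$elety), elesy = elesy,
                      x = at$x, y = at$y, z = at$z, o = o, b = b, het = het,
                      stringsAsFactors = FALSE)
  new_structure(atoms, source = source)
}

#' Write a structure to PDB or mmCIF
#'
#' Output is re-readable by [read_structure()]; coordinates are written at the
#' fixed decimal precision of the format (3 decimals).
#'
#' @param s `protein_structure`.
#' @param path output file path.
#' @param format `"pdb"` or `"mmcif"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path, format = c("pdb", "mmcif")) {
  format <- match.arg(format)
  a <- s$atoms
  if (nrow(a) == 0L) stop("refusing to write a structure with no atoms")
  ok <- tryCatch({
    if (format == "pdb") {
      bio3d::write.pdb(file = path,
                       xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                       type = ifelse(a$het, "HETATM", "ATOM"),
                       resno = a$resno, resid = a$resid,
                       eleno = seq_len(nrow(a)), elety = a$elety,
                       chain = a$chain, insert = ifelse(nzchar(a$insert), a$insert, NA),
                       o = a$o, b = a$b, elesy = a$elesy)
    } else {
      write_mmcif(a, path)
    }
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ",
                              conditionMessage(e), call. = FALSE))
  invisible(path)
}

## Minimal mmCIF atom_site writer (coordinates at 3 decimals).
write_mmcif <- function(a, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("data_structvar", "#", "loop_",
               "_atom_site.group_PDB", "_atom_site.id",
               "_atom_site.type_symbol", "_atom_site.label_atom_id",
               "_atom_site.label_alt_id", "_atom_site.label_comp_id",
               "_atom_site.label_asym_id", "_atom_site.label_entity_id",
               "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
               "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
               "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
               "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
               "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
               "_atom_site.pdbx_PDB_model_num"), con)
  lines <- sprintf(
    "%-6s %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f %d %s %s %s 1",
    ifelse(a$het, "HETATM", "ATOM"), seq_len(nrow(a)), a$elesy, a$elety,
    a$resid, a$chain, a$resno,
    ifelse(nzchar(a$insert), a$insert, "?"),
    a$x, a$y, a$z, a$o, a$b, a$resno, a$resid, a$chain, a$elety)
  writeLines(lines, con)
  writeLines("#", con)
}

#' Remove residue ranges from a structure
#'
#' Residues whose author numbers fall inside any inclusive range are removed.
#' Remaining residues keep their original author numbers (numbering is never
#' compacted), so protein-coordinate variant positions remain valid.
#'
#' @param s `protein_structure`.
#' @param ranges list of inclusive `c(start, end)` pairs, or a two-column
#'   matrix.
#' @return trimmed `protein_structure`.
#' @export
trim_regions <- function(s, ranges) {
  if (is.matrix(ranges)) ranges <- asplit(ranges, 1)
  if (length(ranges) == 0L) return(s)
  for (r in ranges) {
    if (length(r) != 2L || any(!is.finite(r)))
      stop("each range must be a finite (start, end) pair")
    if (r[1] > r[2])
      stop("inverted range: (", r[1], ", ", r[2], ")")
  }
  prot_nums <- unique(s$atoms$resno[!s$atoms$het])
  drop <- logical(nrow(s$atoms))
  for (r in ranges) {
    wanted <- seq.int(r[1], r[2])
    absent <- setdiff(wanted, prot_nums)
    if (length(absent) == length(wanted))
      warning("range (", r[1], ", ", r[2], ") matches no residues", call. = FALSE)
    drop <- drop | (!s$atoms$het & s$atoms$resno >= r[1] & s$atoms$resno <= r[2])
  }
  atoms <- s$atoms[!drop, , drop = FALSE]
  rownames(atoms) <- NULL
  new_structure(atoms, source = s$source)
}

#' Per-residue model-confidence flags from pLDDT
#'
#' For predicted models the B-factor column carries pLDDT (0-100).  Residues
#' with pLDDT at or below the cutoff are flagged low-confidence (the
#' comparison is inclusive), and the mean over residues is returned.
#'
#' @param s `protein_structure` with `source = "predicted"`.
#' @param threshold pLDDT cutoff; default 50.
#' @return list with `per_residue` (data.frame: `chain`, `resno`, `plddt`,
#'   `low_confidence`) and `mean` (mean residue pLDDT).
#' @export
model_confidence <- function(s, threshold = 50) {
  if (s$source != "predicted")
    stop("pLDDT confidence flags apply to predicted models only; ",
         "this structure is tagged 'experimental'")
  a <- s$atoms[!s$atoms$het, ]
  key <- paste(a$chain, a$resno, a$insert)
  plddt <- tapply(a$b, key, mean)
  ukey <- unique(key)
  first <- a[!duplicated(key), c("chain", "resno")]
  per <- data.frame(chain = first$chain, resno = first$resno,
                    plddt = as.numeric(plddt[ukey]),
                    stringsAsFactors = FALSE)
  per <- per[order(per$chain, per$resno), ]
  per$low_confidence <- per$plddt <= threshold
  rownames(per) <- NULL
  list(per_residue = per, mean = mean(per$plddt))
}
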