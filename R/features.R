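#' Domain-range map
#'
#' Named inclusive residue ranges (a domain may span several segments, e.g. a
#' transmembrane domain interrupted by an exocytoplasmic domain).  Ranges must
#' not overlap.
#'
#' @param ranges named list; each element a `c(start, end)` pair or a list of
#'   such pairs.
#' @return object of class `domain_map`.
#' @export
domain_map <- function(ranges) {
  norm <- list()
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (is.matrix(r)) r <- asplit(r, 1)
    else if (!is.list(r)) r <- list(r)
    for (seg in r) {
      if (length(seg) != 2L || seg[1] > seg[2])
        stop("bad range for domain ", nm)
      norm[[length(norm) + 1L]] <- list(name = nm, start = seg[1], end = seg[2])
    }
  }
  segs <- do.call(rbind, lapply(norm, function(x)
    data.frame(name = x$name, start = x$start, end = x$end,
               stringsAsFactors = FALSE)))
  segs <- segs[order(segs$start), ]
  if (nrow(segs) > 1L && any(segs$start[-1] <= segs$end[-nrow(segs)]))
    stop("domain ranges overlap")
  structure(list(segments = segs), class = "domain_map")
}

#' Load a domain map from a JSON config
#'
#' The JSON maps domain names to `[start, end]` pairs (or lists of pairs) and
#' may carry a `substrate_codes` array of het aliases for the substrate.
#'
#' @param path JSON file; default the packaged approximate ABCA4 map.
#' @return `domain_map`; attribute `substrate_codes` if present in the file.
#' @export
read_domain_map <- function(path = system.file("extdata", "abca4_domains.json",
                                               package = "structvar",
                                               mustWork = TRUE)) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  subs <- cfg$substrate_codes
  cfg$substrate_codes <- NULL
  cfg$comment <- NULL
  dm <- domain_map(cfg)
  if (!is.null(subs)) attr(dm, "substrate_codes") <- toupper(subs)
  dm
}

#' @export
print.domain_map <- function(x, ...) {
  cat("<domain_map>\n")
  print(x$segments, row.names = FALSE)
  invisible(x)
}

domain_of <- function(d, resno) {
  segs <- d$segments
  hit <- which(segs$start <= resno & segs$end >= resno)
  if (length(hit)) segs$name[hit[1]] else NA_character_
}

#' Classify a contact by domain relation
#'
#' @param contact one-row contact data.frame (from [detect_contacts()]).
#' @param d `domain_map`.
#' @return one of `"intradomain"`, `"interdomain"`, `"interchain"`,
#'   `"ligand"`; `"unassigned"` (with a warning) when a partner falls outside
#'   every range.
#' @export
classify_contact_domain <- function(contact, d) {
  if (contact$kind == "ligand_polar" || isTRUE(contact$resid_b %in% DEFAULT_HET_CODES))
    return("ligand")
  if (contact$chain_a != contact$chain_b) return("interchain")
  da <- domain_of(d, contact$resno_a)
  db <- domain_of(d, contact$resno_b)
  if (is.na(da) || is.na(db)) {
    warning("residue ", contact$resno_a[is.na(da)][1], contact$resno_b[is.na(db)][1],
            " outside every domain range", call. = FALSE)
    return("unassigned")
  }
  if (da == db) "intradomain" else "interdomain"
}

#' Is a position the Asn of an N-X-S/T sequon?
#'
#' N-linked glycosylation requires the sequon N-X-S/T with X != P.
#'
#' @param sequence one-letter amino-acid string.
#' @param pos 1-based position tested as the sequon's Asn.
#' @return logical.
#' @export
sequon_scan <- function(sequence, pos) {
  n <- nchar(sequence)
  if (pos < 1L || pos > n - 2L)
    stop("pos must lie in [1, length - 2] for a sequon test")
  s1 <- substr(sequence, pos, pos)
  s2 <- substr(sequence, pos + 1L, pos + 1L)
  s3 <- substr(sequence, pos + 2L, pos + 2L)
  s1 == "N" && s2 != "P" && s3 %in% c("S", "T")
}

## Helix assignment when no annotation is available: residues i with backbone
## O(i)-N(i+4) distance <= 3.5 A for >= 4 consecutive i span a helix
## (residues i0 .. i1+4).
assign_helices <- function(s, chain = NULL, hbond_max = 3.5) {
  a <- s$atoms
  if (is.null(chain)) chain <- a$chain[!a$het][1]
  prot <- a[!a$het & a$chain == chain, ]
  resnos <- sort(unique(prot$resno))
  get_atom <- function(resno, name) {
    row <- prot[prot$resno == resno & prot$elety == name, ]
    if (nrow(row)) as.numeric(row[1, c("x", "y", "z")]) else NULL
  }
  hb <- logical(length(resnos))
  for (k in seq_along(resnos)) {
    o <- get_atom(resnos[k], "O")
    nn <- get_atom(resnos[k] + 4L, "N")
    hb[k] <- !is.null(o) && !is.null(nn) && sqrt(sum((o - nn)^2)) <= hbond_max
  }
  helix <- rep(FALSE, length(resnos))
  r <- rle(hb)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segments <- list()
  for (k in seq_along(r$values)) {
    if (r$values[k] && r$lengths[k] >= 4L) {
      i0 <- starts[k]; i1 <- min(ends[k] + 4L, length(resnos))
      helix[i0:i1] <- TRUE
      segments[[length(segments) + 1L]] <- c(resnos[i0], resnos[i1])
    }
  }
  list(resno = resnos, helix = helix, segments = segments)
}

#' Would substituting Pro fall in a helix interior?
#'
#' Proline lacks a backbone amide hydrogen and kinks alpha-helices; a Pro
#' introduced in the interior of a helix (beyond the first/last turn) is
#' treated as helix-disrupting.
#'
#' @param s `protein_structure` (wild type).
#' @param pos residue number of the substitution site.
#' @param alt_aa one-letter replacement amino acid.
#' @param chain chain id.
#' @return logical: `TRUE` iff `alt_aa == "P"` and `pos` lies at least one
#'   full turn (4 residues) from both helix ends.
#' @export
helix_proline_check <- function(s, pos, alt_aa, chain = NULL) {
  if (toupper(alt_aa) != "P") return(FALSE)
  hx <- assign_helices(s, chain)
  for (seg in hx$segments) {
    if (pos >= seg[1] + 4L && pos <= seg[2] - 4L) return(TRUE)
  }
  FALSE
}

#' Construct a feature set
#'
#' Container for the structural-impact features of one variant: lost/gained
#' contacts, the clash verdict, WT/mutant surface reports and the special
#' substitution flags.  This is the unit consumed by [structural_category()].
#'
#' @param lost,gained contact data.frames (see [detect_contacts()]).
#' @param clash `clash_report` (or a list with at least `all_rotamers_clash`).
#' @param wt_surface,mut_surface lists with `asa`, `rsa`, `buried`.
#' @param sequon_lost,pro_in_helix,buried_polarity_change logicals.
#' @param special_residue_change one of `"none"`, `"gly_replaced"`,
#'   `"pro_introduced"`, `"cys_involved"`.
#' @return object of class `feature_set`.
#' @export
feature_set <- function(lost = empty_contacts(), gained = empty_contacts(),
                        clash = list(pairs = empty_contacts(), max_overlap = 0,
                                     all_rotamers_clash = FALSE),
                        wt_surface = list(asa = NA_real_, rsa = NA_real_,
                                          buried = FALSE),
                        mut_surface = list(asa = NA_real_, rsa = NA_real_,
                                           buried = FALSE),
                        sequon_lost = FALSE, pro_in_helix = FALSE,
                        buried_polarity_change = FALSE,
                        special_residue_change = "none") {
  key <- function(df) if (nrow(df)) paste(df$kind, df$chain_b, df$resno_b) else character()
  if (length(intersect(key(lost), key(gained))))
    stop("a contact cannot be both lost and gained")
  special_residue_change <- match.arg(special_residue_change,
                                      c("none", "gly_replaced",
                                        "pro_introduced", "cys_involved"))
  structure(list(lost = lost, gained = gained, clash = clash,
                 wt_surface = wt_surface, mut_surface = mut_surface,
                 sequon_lost = sequon_lost, pro_in_helix = pro_in_helix,
                 buried_polarity_change = buried_polarity_change,
                 special_residue_change = special_residue_change),
            class = "feature_set")
}

empty_contacts <- function() {
  data.frame(kind = character(), chain_a = character(), resno_a = integer(),
             atom_a = character(), chain_b = character(), resno_b = integer(),
             resid_b = character(), atom_b = character(), distance = numeric(),
             domain_relation = character(), stringsAsFactors = FALSE)
}

#' @export
print.feature_set <- function(x, ...) {
  cat("<feature_set> lost:", nrow(x$lost), " gained:", nrow(x$gained),
      " all_rotamers_clash:", isTRUE(x$clash$all_rotamers_clash),
      "\n  flags: sequon_lost=", x$sequon_lost,
      " pro_in_helix=", x$pro_in_helix,
      " buried_polarity_change=", x$buried_polarity_change,
      " special=", x$special_residue_change, "\n", sep = "")
  invisible(x)
}

## contact identity for WT-vs-mutant diffing: kind + partner residue
contact_key <- function(df) {
  if (!nrow(df)) return(character())
  paste(df$kind, df$chain_b, df$resno_b, df$resid_b)
}

#' Structural-feature differences between WT and mutant models
#'
#' Compares the contacts, clash status and surface state of the variant site
#' between the wild-type and mutated structures (which must share backbone and
#' residue set; only the focus side chain may differ), and derives the special
#' substitution flags.  Passing `mut` identical to `wt` yields an empty
#' feature set.
#'
#' @param wt,mut `protein_structure`s.
#' @param v `variant_spec`; `wt` must carry `v$ref_aa` at `v$position`.
#' @param d optional `domain_map` for domain-relation annotation.
#' @param chain chain id.
#' @return `feature_set`.
#' @export
diff_features <- function(wt, mut, v, d = NULL, chain = NULL) {
  rt_wt <- residue_table(wt); rt_mut <- residue_table(mut)
  if (nrow(rt_wt) != nrow(rt_mut) ||
      !all(rt_wt$resno[!rt_wt$het] == rt_mut$resno[!rt_mut$het]))
    stop("WT and mutant structures have different residue sets")
  res_wt <- residue_atoms(wt, v$position, chain)
  if (nrow(res_wt) == 0L) stop("no residue ", v$position, " in WT structure")
  aa_wt <- aa_three_to_one(res_wt$resid[1])
  if (is.na(aa_wt) || aa_wt != v$ref_aa)
    stop("WT structure has ", res_wt$resid[1], " at ", v$position,
         ", variant expects ", v$ref_aa)
  res_mut <- residue_atoms(mut, v$position, chain)
  aa_mut <- aa_three_to_one(res_mut$resid[1])
  identical_models <- isTRUE(all.equal(wt$atoms[, c("x", "y", "z")],
                                       mut$atoms[, c("x", "y", "z")],
                                       tolerance = 1e-9)) && aa_mut == aa_wt
  if (identical_models) return(feature_set())

  cw <- detect_contacts(wt, v$position, chain = chain, domain_map = d)
  cm <- detect_contacts(mut, v$position, chain = chain, domain_map = d)
  lost <- cw[!contact_key(cw) %in% contact_key(cm), , drop = FALSE]
  gained <- cm[!contact_key(cm) %in% contact_key(cw), , drop = FALSE]
  lost <- lost[!duplicated(contact_key(lost)), , drop = FALSE]
  gained <- gained[!duplicated(contact_key(gained)), , drop = FALSE]

  placements <- enumerate_rotamers(wt, v$position, v$alt_aa, chain)
  clash <- detect_clashes(mut, v$position, chain = chain)
  clash$all_rotamers_clash <- attr(placements, "all_rotamers_clash")

  sa_wt <- solvent_accessibility(wt)
  sa_mut <- solvent_accessibility(mut)
  surf_wt <- residue_surface(sa_wt, v$position, chain)
  surf_mut <- residue_surface(sa_mut, v$position, chain)

  seq_wt <- paste(chain_sequence(wt, chain), collapse = "")
  offset <- min(as.integer(names(chain_sequence(wt, chain))))
  rel <- v$position - offset + 1L
  sequon_lost <- FALSE
  for (start_rel in (rel - 2L):rel) {
    if (start_rel < 1L || start_rel > nchar(seq_wt) - 2L) next
    if (sequon_scan(seq_wt, start_rel)) {
      seq_mut <- seq_wt
      substr(seq_mut, rel, rel) <- v$alt_aa
      if (!sequon_scan(seq_mut, start_rel)) sequon_lost <- TRUE
    }
  }

  special <- if (v$ref_aa == "G") "gly_replaced"
  else if (v$alt_aa == "P") "pro_introduced"
  else if (v$ref_aa == "C" || v$alt_aa == "C") "cys_involved"
  else "none"

  feature_set(
    lost = lost, gained = gained, clash = clash,
    wt_surface = surf_wt, mut_surface = surf_mut,
    sequon_lost = sequon_lost,
    pro_in_helix = helix_proline_check(wt, v$position, v$alt_aa, chain),
    buried_polarity_change = isTRUE(surf_wt$buried) &&
      HYDROPHOBICITY_CLASS[[v$ref_aa]] != HYDROPHOBICITY_CLASS[[v$alt_aa]],
    special_residue_change = special)
}
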