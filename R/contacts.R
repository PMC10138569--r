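## Clash and contact detection.  All criteria are heavy-atom, distance-based
## conventions (inputs carry no hydrogens):
##   severe clash     vdW overlap >= 0.4 A (1-2/1-3 pairs excluded, 1-4 pairs
##                    reported separately, never counted)
##   hydrogen bond    donor/acceptor heavy atoms (N/O/S) <= 3.5 A
##   salt bridge      charged side-chain N (Arg/Lys/His) to charged O
##                    (Asp/Glu) <= 4.0 A
##   disulfide        SG-SG in [1.8, 2.5] A
##   ligand polar     H-bond criterion against registered het groups
##                    (metal coordination to Mg included)

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

## Covalent bond inference.  Bonds are only inferred within a residue, between
## consecutive protein residues of a chain (peptide C-N), and between SG atoms
## at disulfide distance.  Distance cutoffs: 1.9 A generally, 2.5 A for S-S.
## This deliberately never bonds non-adjacent residues, so planted clashes are
## not mistaken for bonds.
infer_bonds <- function(atoms) {
  n <- nrow(atoms)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  out_i <- integer(0); out_j <- integer(0)
  rid <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$het)
  for (id in unique(rid)) {
    idx <- which(rid == id)
    if (length(idx) < 2L) next
    d <- as.matrix(stats::dist(xyz[idx, , drop = FALSE]))
    sel <- which(d > 0 & d < 1.9, arr.ind = TRUE)
    sel <- sel[sel[, 1] < sel[, 2], , drop = FALSE]
    out_i <- c(out_i, idx[sel[, 1]]); out_j <- c(out_j, idx[sel[, 2]])
  }
  ## peptide bonds: C(i) - N(i+1) within a chain
  prot <- which(!atoms$het)
  cs <- prot[atoms$elety[prot] == "C"]
  ns <- prot[atoms$elety[prot] == "N"]
  for (i in cs) {
    j <- ns[atoms$chain[ns] == atoms$chain[i] &
              atoms$resno[ns] == atoms$resno[i] + 1L]
    for (jj in j) {
      if (sqrt(sum((xyz[i, ] - xyz[jj, ])^2)) < 1.9) {
        out_i <- c(out_i, i); out_j <- c(out_j, jj)
      }
    }
  }
  ## disulfides are covalent: SG-SG within 2.5 A
  sgs <- which(atoms$elety == "SG")
  if (length(sgs) > 1L) {
    d <- as.matrix(stats::dist(xyz[sgs, , drop = FALSE]))
    sel <- which(d > 0 & d <= 2.5, arr.ind = TRUE)
    sel <- sel[sel[, 1] < sel[, 2], , drop = FALSE]
    out_i <- c(out_i, sgs[sel[, 1]]); out_j <- c(out_j, sgs[sel[, 2]])
  }
  cbind(out_i, out_j)
}

## adjacency list from a bond edge matrix
bond_adjacency <- function(bonds, n) {
  adj <- vector("list", n)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds[k, 1]; j <- bonds[k, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

## graph (bond-count) distance from atom i, capped at `max_depth`
bond_distances_from <- function(adj, i, max_depth = 3L) {
  dist <- rep(NA_integer_, length(adj))
  dist[i] <- 0L
  frontier <- i
  for (d in seq_len(max_depth)) {
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[is.na(dist[nxt])]
    if (!length(nxt)) break
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

#' Detect severe steric clashes of a residue's side chain
#'
#' For every non-bonded pair between the focus residue's side-chain atoms and
#' the environment, the van der Waals overlap `(r_i + r_j) - d` is computed.
#' Pairs at or above the overlap threshold are reported; 1-2 and 1-3 bonded
#' pairs are excluded and 1-4 pairs are listed separately without counting as
#' clashes.
#'
#' @param s `protein_structure`.
#' @param focus author residue number.
#' @param chain chain id; default first chain.
#' @param overlap_threshold overlap (A) counted as a severe clash.
#' @return list of class `clash_report`: `pairs` (data.frame of clashing
#'   pairs), `one_four` (1-4 pairs meeting the overlap), `max_overlap`,
#'   `all_rotamers_clash` (`NA` here; filled by rotamer enumeration).
#' @export
detect_clashes <- function(s, focus, chain = NULL, overlap_threshold = 0.4) {
  a <- s$atoms
  if (is.null(chain)) chain <- a$chain[!a$het][1]
  in_focus <- !a$het & a$chain == chain & a$resno == focus
  if (!any(in_focus)) stop("no residue numbered ", focus, " in chain ", chain)
  sc <- which(in_focus & !(a$elety %in% BACKBONE_ATOMS))
  env <- which(!in_focus)
  empty <- data.frame(chain_a = character(), resno_a = integer(),
                      atom_a = character(), chain_b = character(),
                      resno_b = integer(), resid_b = character(),
                      atom_b = character(), distance = numeric(),
                      overlap = numeric(), stringsAsFactors = FALSE)
  if (!length(sc) || !length(env))
    return(structure(list(pairs = empty, one_four = empty, max_overlap = 0,
                          all_rotamers_clash = NA), class = "clash_report"))
  xyz <- as.matrix(a[, c("x", "y", "z")])
  radii <- vdw_radius(a$elesy)
  bonds <- infer_bonds(a)
  adj <- bond_adjacency(bonds, nrow(a))
  rows <- list(); rows14 <- list()
  for (i in sc) {
    bd <- bond_distances_from(adj, i, max_depth = 3L)
    d <- sqrt((xyz[env, 1] - xyz[i, 1])^2 + (xyz[env, 2] - xyz[i, 2])^2 +
                (xyz[env, 3] - xyz[i, 3])^2)
    ov <- radii[i] + radii[env] - d
    hit <- which(ov >= overlap_threshold - 1e-9)   # boundary inclusive
    for (k in hit) {
      j <- env[k]
      gd <- bd[j]
      if (!is.na(gd) && gd <= 2L) next           # 1-2 / 1-3: bonded geometry
      row <- data.frame(chain_a = a$chain[i], resno_a = a$resno[i],
                        atom_a = a$elety[i], chain_b = a$chain[j],
                        resno_b = a$resno[j], resid_b = a$resid[j],
                        atom_b = a$elety[j], distance = d[k], overlap = ov[k],
                        stringsAsFactors = FALSE)
      if (!is.na(gd) && gd == 3L) rows14[[length(rows14) + 1L]] <- row
      else rows[[length(rows) + 1L]] <- row
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else empty
  one_four <- if (length(rows14)) do.call(rbind, rows14) else empty
  structure(list(pairs = pairs, one_four = one_four,
                 max_overlap = if (nrow(pairs)) max(pairs$overlap) else 0,
                 all_rotamers_clash = NA),
            class = "clash_report")
}

#' Detect polar contacts, salt bridges, disulfides and ligand contacts
#'
#' Distance-based contact detection between a focus residue (all heavy atoms,
#' backbone included) and its environment.
#'
#' @param s `protein_structure`.
#' @param focus author residue number.
#' @param kinds subset of `c("hbond", "saltbridge", "disulfide",
#'   "ligand_polar")`.
#' @param chain chain id; default first chain.
#' @param domain_map optional [domain_map()] used to annotate each contact's
#'   domain relation.
#' @param hbond_max,saltbridge_max,disulfide_range distance criteria (A).
#' @return data.frame of contacts: `kind`, partner identity columns,
#'   `distance`, `domain_relation`.
#' @export
detect_contacts <- function(s, focus,
                            kinds = c("hbond", "saltbridge", "disulfide",
                                      "ligand_polar"),
                            chain = NULL, domain_map = NULL,
                            hbond_max = 3.5, saltbridge_max = 4.0,
                            disulfide_range = c(1.8, 2.5)) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  a <- s$atoms
  if (is.null(chain)) chain <- a$chain[!a$het][1]
  in_focus <- !a$het & a$chain == chain & a$resno == focus
  if (!any(in_focus)) stop("no residue numbered ", focus, " in chain ", chain)
  focus_aa <- aa_three_to_one(a$resid[which(in_focus)[1]])
  xyz <- as.matrix(a[, c("x", "y", "z")])
  bonds <- infer_bonds(a)
  adj <- bond_adjacency(bonds, nrow(a))
  polar_el <- c("N", "O", "S")
  out <- list()
  add_contact <- function(kind, i, j, d) {
    rel <- if (a$het[j]) "ligand"
    else if (a$chain[i] != a$chain[j]) "interchain"
    else if (!is.null(domain_map)) {
      da <- domain_of(domain_map, a$resno[i]); db <- domain_of(domain_map, a$resno[j])
      if (is.na(da) || is.na(db)) "unassigned"
      else if (da == db) "intradomain" else "interdomain"
    } else NA_character_
    out[[length(out) + 1L]] <<- data.frame(
      kind = kind, chain_a = a$chain[i], resno_a = a$resno[i],
      atom_a = a$elety[i], chain_b = a$chain[j], resno_b = a$resno[j],
      resid_b = a$resid[j], atom_b = a$elety[j], distance = d,
      domain_relation = rel, stringsAsFactors = FALSE)
  }
  pair_scan <- function(iset, jset, dmin, dmax, kind, exclude_bonded = TRUE) {
    for (i in iset) {
      if (!length(jset)) next
      bd <- if (exclude_bonded) bond_distances_from(adj, i, 3L) else NULL
      d <- sqrt((xyz[jset, 1] - xyz[i, 1])^2 + (xyz[jset, 2] - xyz[i, 2])^2 +
                  (xyz[jset, 3] - xyz[i, 3])^2)
      hit <- which(d >= dmin & d <= dmax)
      for (k in hit) {
        j <- jset[k]
        if (exclude_bonded && !is.na(bd[j]) && bd[j] <= 3L) next
        add_contact(kind, i, j, d[k])
      }
    }
  }
  focus_idx <- which(in_focus)
  env_prot <- which(!in_focus & !a$het)
  env_het <- which(a$het)
  if ("hbond" %in% kinds) {
    iset <- focus_idx[a$elesy[focus_idx] %in% polar_el]
    jset <- env_prot[a$elesy[env_prot] %in% polar_el]
    pair_scan(iset, jset, 0, hbond_max, "hbond")
  }
  if ("saltbridge" %in% kinds) {
    pos_atoms <- CHARGED_POSITIVE_ATOMS[[focus_aa]]
    neg_atoms <- CHARGED_NEGATIVE_ATOMS[[focus_aa]]
    env_aa <- aa_three_to_one(a$resid[env_prot])
    charged_env <- function(tbl) {
      env_prot[vapply(seq_along(env_prot), function(k) {
        aa1 <- env_aa[k]
        !is.na(aa1) && a$elety[env_prot[k]] %in% tbl[[aa1]]
      }, logical(1))]
    }
    if (!is.null(pos_atoms)) {
      iset <- focus_idx[a$elety[focus_idx] %in% pos_atoms]
      pair_scan(iset, charged_env(CHARGED_NEGATIVE_ATOMS), 0, saltbridge_max,
                "saltbridge")
    }
    if (!is.null(neg_atoms)) {
      iset <- focus_idx[a$elety[focus_idx] %in% neg_atoms]
      pair_scan(iset, charged_env(CHARGED_POSITIVE_ATOMS), 0, saltbridge_max,
                "saltbridge")
    }
  }
  if ("disulfide" %in% kinds && focus_aa == "C") {
    iset <- focus_idx[a$elety[focus_idx] == "SG"]
    jset <- env_prot[a$elety[env_prot] == "SG"]
    pair_scan(iset, jset, disulfide_range[1], disulfide_range[2], "disulfide",
              exclude_bonded = FALSE)
  }
  if ("ligand_polar" %in% kinds && length(env_het)) {
    iset <- focus_idx[a$elesy[focus_idx] %in% polar_el]
    jset <- env_het[a$elesy[env_het] %in% c(polar_el, "MG")]
    pair_scan(iset, jset, 0, hbond_max, "ligand_polar")
  }
  if (!length(out))
    return(data.frame(kind = character(), chain_a = character(),
                      resno_a = integer(), atom_a = character(),
                      chain_b = character(), resno_b = integer(),
                      resid_b = character(), atom_b = character(),
                      distance = numeric(), domain_relation = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  ## a pair that qualifies as a salt bridge should not double as a plain hbond
  key <- paste(res$atom_a, res$chain_b, res$resno_b, res$atom_b)
  sb <- key[res$kind == "saltbridge"]
  res <- res[!(res$kind == "hbond" & key %in% sb), , drop = FALSE]
  rownames(res) <- NULL
  res
}
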