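## Numeric Shrake-Rupley solvent-accessible surface area.

## Near-uniform points on the unit sphere (golden-section spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent accessibility by Shrake-Rupley sampling
#'
#' Numeric ASA per atom (probe-expanded spheres, point sampling), summed per
#' residue; RSA normalises by the residue's theoretical maximum ASA in an
#' extended Gly-X-Gly tripeptide.  A residue is called buried when its RSA is
#' below `buried_cutoff`.  Het groups occlude but are not reported.
#'
#' @param s `protein_structure`.
#' @param probe probe radius in Angstrom (water = 1.4).
#' @param n_points sphere sample points per atom.
#' @param buried_cutoff RSA below which a residue is buried (default 0.25).
#' @return list with `per_residue` (data.frame: `chain`, `resno`, `aa`, `asa`,
#'   `rsa`, `buried`) and `per_atom` (numeric ASA vector along the atom
#'   table).
#' @export
solvent_accessibility <- function(s, probe = 1.4, n_points = 480,
                                  buried_cutoff = 0.25) {
  a <- s$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  radii <- vdw_radius(a$elesy)
  n <- nrow(a)
  pts <- sphere_points(n_points)
  asa <- numeric(n)
  rexp <- radii + probe
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (rexp + rexp[i])^2 & seq_len(n) != i)
    p <- pts * rexp[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      acc <- acc & dj2 > rexp[j]^2
    }
    asa[i] <- mean(acc) * 4 * pi * rexp[i]^2
  }
  prot <- !a$het
  key <- paste(a$chain, a$resno, a$insert)
  res_asa <- tapply(asa[prot], key[prot], sum)
  rt <- residue_table(s)
  rt <- rt[!rt$het, , drop = FALSE]
  rkey <- paste(rt$chain, rt$resno, rt$insert)
  per <- data.frame(chain = rt$chain, resno = rt$resno, aa = rt$aa,
                    asa = as.numeric(res_asa[rkey]), stringsAsFactors = FALSE)
  per$rsa <- per$asa / unname(MAX_ASA[per$aa])
  per$buried <- !is.na(per$rsa) & per$rsa < buried_cutoff
  list(per_residue = per, per_atom = asa)
}

residue_surface <- function(sa, resno, chain = NULL) {
  per <- sa$per_residue
  if (is.null(chain)) chain <- per$chain[1]
  row <- per[per$chain == chain & per$resno == resno, ]
  if (nrow(row) == 0L) return(NULL)
  list(asa = row$asa[1], rsa = row$rsa[1], buried = row$buried[1])
}
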