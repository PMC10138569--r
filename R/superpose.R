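#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of `Q` onto `P` with positional (identity)
#' correspondence: finds rotation `R` and translation `t` minimising
#' `sum |P_i - (R Q_i + t)|^2` by SVD of the covariance matrix, with the sign
#' correction that excludes reflections.
#'
#' @param P,Q n x 3 coordinate matrices (n >= 3), row i of `Q` corresponding
#'   to row i of `P`.
#' @return list of class `superposition`: `rotation` (3 x 3, det = +1),
#'   `translation` (3-vector), `rmsd` (A), `per_residue_distance`,
#'   `Q_aligned` (transformed `Q`).
#' @export
kabsch_superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q))) stop("coordinate sets differ in size")
  if (nrow(P) < 3L) stop("at least 3 points are required for superposition")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Qc, Pc)              # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)         # rotation applied as R %*% q
  Qr <- Qc %*% t(R)
  t_vec <- cp - as.numeric(R %*% cq)
  dists <- sqrt(rowSums((Pc - Qr)^2))
  structure(list(rotation = R, translation = t_vec,
                 rmsd = sqrt(mean(dists^2)),
                 per_residue_distance = dists,
                 Q_aligned = sweep(Qr, 2, cp, "+")),
            class = "superposition")
}

#' TM-score distance scale d0
#' @param L_target normalisation length (>= 22 so that d0 > 0).
#' @return d0 in Angstrom.
#' @export
tm_d0 <- function(L_target) {
  if (L_target < 22L)
    stop("d0 = 1.24 (L - 15)^(1/3) - 1.8 requires L_target >= 22")
  1.24 * (L_target - 15)^(1/3) - 1.8
}

tm_of_superposition <- function(P, Q, sup, d0, L_target) {
  Qa <- sweep(Q %*% t(sup$rotation), 2, sup$translation, "+")
  d <- sqrt(rowSums((P - Qa)^2))
  sum(1 / (1 + (d / d0)^2)) / L_target
}

## Iteratively refine a superposition on the subset of residues within d_cut,
## shrinking d_cut from d0 toward d0/2; returns the best TM over the path.
tm_refine <- function(P, Q, seed_idx, d0, L_target, max_iter = 20L) {
  best <- -Inf
  idx <- seed_idx
  d_cut <- d0
  for (it in seq_len(max_iter)) {
    if (length(idx) < 3L) break
    sup <- kabsch_superpose(P[idx, , drop = FALSE], Q[idx, , drop = FALSE])
    tm <- tm_of_superposition(P, Q, sup, d0, L_target)
    if (tm > best) best <- tm
    Qa <- sweep(Q %*% t(sup$rotation), 2, sup$translation, "+")
    d <- sqrt(rowSums((P - Qa)^2))
    new_idx <- which(d < d_cut)
    if (length(new_idx) < 3L) new_idx <- order(d)[1:4]
    if (identical(new_idx, idx) && d_cut <= d0 / 2 + 1e-12) break
    idx <- new_idx
    d_cut <- max(d0 / 2, d_cut * 0.9)
  }
  best
}

#' TM-score of two equal-length Calpha traces
#'
#' `TM = max over superpositions of (1/L_target) sum_i 1 / (1 + (d_i/d0)^2)`
#' with `d0 = 1.24 (L_target - 15)^(1/3) - 1.8`.  The maximisation uses the
#' standard iterative heuristic: superpositions are seeded from the full
#' residue set and from sliding fragments (lengths L, L/2, L/4), then
#' iteratively re-superposed on the residues closer than a distance cutoff
#' shrinking from d0 to d0/2 until the retained set is stable (at most 20
#' iterations).  The full-set Kabsch superposition is always among the seeds,
#' so the result is never below the single-superposition score.
#'
#' @param P,Q n x 3 Calpha coordinate matrices with identity correspondence.
#' @param L_target normalisation length; defaults to n.
#' @return list of class `alignment_scores`: `rmsd` (full-set Kabsch RMSD),
#'   `tm_score`, `L_target`, `d0`.
#' @export
tm_score <- function(P, Q, L_target = nrow(P)) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q))) stop("coordinate sets differ in size")
  n <- nrow(P)
  d0 <- tm_d0(L_target)
  full <- kabsch_superpose(P, Q)
  best <- tm_of_superposition(P, Q, full, d0, L_target)
  seeds <- list(seq_len(n))
  ## small instances get every sliding fragment (exact small-instance mode);
  ## larger ones the standard L, L/2, L/4 schedule with half-overlapping
  ## windows
  lens <- if (n <= 30L) seq(4L, n - 1L)
  else unique(pmax(4L, c(n %/% 2L, n %/% 4L)))
  for (frag in lens) {
    if (frag >= n) next
    stride <- if (n <= 30L) 1L else max(1L, frag %/% 2L)
    starts <- unique(c(seq(1L, n - frag + 1L, by = stride), n - frag + 1L))
    for (st in starts) seeds[[length(seeds) + 1L]] <- st:(st + frag - 1L)
  }
  for (idx in seeds) {
    tm <- tm_refine(P, Q, idx, d0, L_target)
    if (tm > best) best <- tm
  }
  structure(list(rmsd = full$rmsd, tm_score = best,
                 L_target = L_target, d0 = d0),
            class = "alignment_scores")
}

#' @export
print.alignment_scores <- function(x, ...) {
  cat(sprintf("<alignment_scores> rmsd = %.3f A, TM = %.4f (L = %d, d0 = %.3f)\n",
              x$rmsd, x$tm_score, x$L_target, x$d0))
  invisible(x)
}

ca_coords <- function(s, chain = NULL) {
  a <- s$atoms
  if (is.null(chain)) chain <- a$chain[!a$het][1]
  ca <- a[!a$het & a$chain == chain & a$elety == "CA", ]
  ca <- ca[order(ca$resno), ]
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- ca$resno
  m
}

#' Alignment scores between a WT and a variant model
#'
#' Calpha RMSD with identity correspondence and no outlier rejection, plus
#' TM-score normalised by the WT chain length.
#'
#' @param wt,var `protein_structure`s sharing the same residue set.
#' @param chain chain id.
#' @return `alignment_scores`.
#' @export
compare_models <- function(wt, var, chain = NULL) {
  P <- ca_coords(wt, chain)
  Q <- ca_coords(var, chain)
  if (nrow(P) != nrow(Q) || !all(rownames(P) == rownames(Q))) {
    missing <- c(setdiff(rownames(P), rownames(Q)),
                 setdiff(rownames(Q), rownames(P)))
    stop("residue sets differ between models",
         if (length(missing)) paste0(" (residues ",
                                     paste(utils::head(missing, 10), collapse = ", "),
                                     ")"))
  }
  tm_score(P, Q, L_target = nrow(P))
}
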