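#' Stability class from a ddG value
#'
#' Folding free-energy change classification (kcal/mol, positive =
#' destabilizing): neutral in `[-0.5, +0.5]` (boundaries inclusive),
#' stabilizing below `-0.5`, destabilizing above `+0.5`.
#'
#' @param ddg numeric ddG value(s), kcal/mol.
#' @param neutral_band inclusive neutral band, default `c(-0.5, 0.5)`.
#' @return character: `"stabilizing"`, `"neutral"` or `"destabilizing"`.
#' @export
classify_stability <- function(ddg, neutral_band = c(-0.5, 0.5)) {
  if (any(!is.finite(ddg)))
    stop("ddG must be finite (omit the value for non-missense/pLoF variants)")
  ifelse(ddg < neutral_band[1], "stabilizing",
         ifelse(ddg > neutral_band[2], "destabilizing", "neutral"))
}

#' Binarize a predictor score panel into per-tool calls
#'
#' A tool calls a variant pathogenic when: CADD PHRED >= 20; PolyPhen-2 is
#' possibly or probably damaging; REVEL >= 0.5; MutPred-2 >= 0.5.  A missing
#' score yields `"unavailable"` for that tool and is excluded from the
#' consensus denominator.
#'
#' @param cadd_phred CADD PHRED score (0-99) or `NA`.
#' @param polyphen `"benign"`, `"possibly_damaging"`, `"probably_damaging"`
#'   or `NA`.
#' @param revel REVEL score (0-1) or `NA`.
#' @param mutpred2 MutPred-2 score (0-1) or `NA`.
#' @return named character vector of per-tool calls
#'   (`"pathogenic"`/`"benign"`/`"unavailable"`).
#' @export
binarize_predictors <- function(cadd_phred = NA, polyphen = NA,
                                revel = NA, mutpred2 = NA) {
  bin <- function(x, test) {
    if (is.na(x)) "unavailable" else if (test(x)) "pathogenic" else "benign"
  }
  if (!is.na(polyphen))
    polyphen <- match.arg(polyphen, c("benign", "possibly_damaging",
                                      "probably_damaging"))
  c(cadd = bin(cadd_phred, function(x) x >= 20),
    polyphen = bin(polyphen, function(x)
      x %in% c("possibly_damaging", "probably_damaging")),
    revel = bin(revel, function(x) x >= 0.5),
    mutpred2 = bin(mutpred2, function(x) x >= 0.5))
}

#' Consensus over per-tool pathogenicity calls
#'
#' Majority rule over the available calls: `"pathogenic"` when at least 3 of
#' the 4 tools call pathogenic, `"benign"` when at least 3 call benign,
#' `"conflicting"` otherwise (including 2-vs-2).  With fewer than 3 available
#' calls the consensus is `"conflicting"` with a warning.
#'
#' @param calls character vector of per-tool calls (order immaterial).
#' @param quorum number of agreeing tools required, default 3.
#' @return `"pathogenic"`, `"benign"` or `"conflicting"`.
#' @export
consensus_call <- function(calls, quorum = 3L) {
  avail <- calls[calls %in% c("pathogenic", "benign")]
  if (length(avail) < quorum) {
    warning("fewer than ", quorum, " available predictor calls; ",
            "consensus is 'conflicting'", call. = FALSE)
    return("conflicting")
  }
  np <- sum(avail == "pathogenic")
  nb <- sum(avail == "benign")
  if (np >= quorum) "pathogenic" else if (nb >= quorum) "benign" else "conflicting"
}

#' Population-absence evidence (PM2)
#'
#' Moderate pathogenicity evidence requires absence from all consulted
#' population databases (gnomAD, ExAC, 1000 Genomes).
#'
#' @param gnomad_af,exac_af,kg_af allele frequencies; `NA` = absent.
#' @param other_db_presence optional logical: the variant is known present in
#'   at least one database without a recorded frequency.
#' @return logical.
#' @export
pm2_check <- function(gnomad_af = NA, exac_af = NA, kg_af = NA,
                      other_db_presence = NA) {
  if (isTRUE(other_db_presence)) return(FALSE)
  all(is.na(c(gnomad_af, exac_af, kg_af)))
}

#' Structural-impact category of a feature set
#'
#' Deleterious (`"Del"`) when any of: every rotamer clashes; a ligand-polar,
#' disulfide, interdomain or interchain contact is lost; a glycosylation
#' sequon is destroyed; a proline lands in a helix interior; a buried glycine
#' is replaced or a buried position changes hydrophobicity class; the site
#' flips between buried and exposed.  `"Mild"` when none of those hold but new
#' contacts are gained.  `"Neu"` otherwise.
#'
#' @param fs `feature_set`.
#' @return `"Neu"`, `"Mild"` or `"Del"`.
#' @export
structural_category <- function(fs) {
  stopifnot(inherits(fs, "feature_set"))
  lost <- fs$lost
  del <- isTRUE(fs$clash$all_rotamers_clash) ||
    any(lost$kind %in% c("ligand_polar", "disulfide")) ||
    any(lost$domain_relation %in% c("interdomain", "interchain"), na.rm = TRUE) ||
    isTRUE(fs$sequon_lost) ||
    isTRUE(fs$pro_in_helix) ||
    (fs$special_residue_change == "gly_replaced" && isTRUE(fs$wt_surface$buried)) ||
    isTRUE(fs$buried_polarity_change) ||
    (isTRUE(fs$wt_surface$buried) != isTRUE(fs$mut_surface$buried) &&
       !is.na(fs$wt_surface$rsa) && !is.na(fs$mut_surface$rsa))
  if (del) return("Del")
  if (nrow(fs$gained) > 0L) return("Mild")
  "Neu"
}

#' Assemble the ACMG computational-evidence bundle
#'
#' Combines the structural category, predictor consensus and
#' population-absence evidence into PP3/BP4/PM2 codes and a final call.
#' A predicted loss-of-function consequence (pLoF, e.g. splice-disruption
#' truncation) overrides the structural category and forces
#' `pathogenic_support`.  PP3 requires consensus pathogenic and a
#' deleterious (or pLoF) structure; BP4 requires consensus benign and a
#' structurally neutral site; the two are mutually exclusive by construction.
#' Disagreement between predictors and structure is reported as
#' `"conflicting"`.
#'
#' @param category `"Neu"`, `"Mild"` or `"Del"`.
#' @param collective `"pathogenic"`, `"benign"` or `"conflicting"`.
#' @param pm2 logical.
#' @param plof logical, predicted complete loss of function.
#' @param conservation_grade optional 1-9 conservation grade, carried as
#'   annotation only (it never enters the final call).
#' @return object of class `evidence_bundle`.
#' @export
assemble_evidence <- function(category, collective, pm2 = FALSE, plof = FALSE,
                              conservation_grade = NA_integer_) {
  category <- match.arg(category, c("Neu", "Mild", "Del"))
  collective <- match.arg(collective, c("pathogenic", "benign", "conflicting"))
  structural <- if (plof) "pLoF" else category
  pp3 <- collective == "pathogenic" && structural %in% c("Del", "pLoF")
  bp4 <- collective == "benign" && structural == "Neu"
  final_call <- if (pp3 || plof) "pathogenic_support"
  else if (bp4) "benign_support"
  else if ((collective == "benign" && structural == "Del") ||
           (collective == "pathogenic" && structural == "Neu") ||
           collective == "conflicting") "conflicting"
  else "uncertain"
  structure(list(structural_category = structural,
                 collective_prediction = collective,
                 pm2 = isTRUE(pm2), pp3 = pp3, bp4 = bp4,
                 final_call = final_call,
                 conservation_grade = conservation_grade),
            class = "evidence_bundle")
}

#' @export
print.evidence_bundle <- function(x, ...) {
  cat("<evidence_bundle> ", x$structural_category, " / ",
      x$collective_prediction,
      " | PM2:", x$pm2, " PP3:", x$pp3, " BP4:", x$bp4,
      " -> ", x$final_call, "\n", sep = "")
  invisible(x)
}

#' Cohort summary counts
#'
#' Deterministic grouped counts over a set of evaluated variant records:
#' stability classes, structural categories, collective predictions, PM2 and
#' final calls, per clinical group.
#'
#' @param records data.frame with columns `clinvar_group`, `stability_class`,
#'   `structural_category`, `collective_prediction`, `pm2`, `final_call`
#'   (missing columns are tolerated and skipped).
#' @return named list of contingency tables (plus `n` per group).
#' @export
summarize_cohort <- function(records) {
  groups <- c("benign", "pathogenic", "vus")
  fac <- function(col, levels) {
    if (!col %in% names(records)) return(NULL)
    table(group = factor(records$clinvar_group, levels = groups),
          value = factor(records[[col]], levels = levels))
  }
  list(
    n = table(factor(records$clinvar_group, levels = groups)),
    stability = fac("stability_class",
                    c("stabilizing", "neutral", "destabilizing")),
    category = fac("structural_category", c("Neu", "Mild", "Del", "pLoF")),
    collective = fac("collective_prediction",
                     c("pathogenic", "benign", "conflicting")),
    pm2 = fac("pm2", c(FALSE, TRUE)),
    final = fac("final_call", c("pathogenic_support", "benign_support",
                                "conflicting", "uncertain")))
}
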