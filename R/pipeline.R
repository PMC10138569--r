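#' Pipeline configuration
#'
#' All tunable thresholds of the pipeline, with the package defaults:
#' severe-clash overlap 0.4 A; H-bond heavy-atom distance 3.5 A; salt bridge
#' 4.0 A; disulfide SG-SG within [1.8, 2.5] A; buried below RSA 0.25; ddG
#' neutral band [-0.5, +0.5] kcal/mol; pLDDT low-confidence cutoff 50;
#' predictor consensus quorum 3 of 4.
#'
#' @param clash_overlap,hbond_max,saltbridge_max,disulfide_range distances, A.
#' @param rsa_buried RSA burial cutoff (fraction).
#' @param ddg_neutral inclusive neutral ddG band (kcal/mol).
#' @param plddt_cutoff pLDDT at or below which a residue is low-confidence.
#' @param consensus_quorum agreeing predictor tools required for a consensus.
#' @param substrate_codes het codes treated as the translocation substrate.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(clash_overlap = 0.4, hbond_max = 3.5,
                            saltbridge_max = 4.0,
                            disulfide_range = c(1.8, 2.5),
                            rsa_buried = 0.25, ddg_neutral = c(-0.5, 0.5),
                            plddt_cutoff = 50, consensus_quorum = 3L,
                            substrate_codes = "NRPE") {
  stopifnot(clash_overlap > 0, hbond_max > 0, saltbridge_max > 0,
            length(disulfide_range) == 2L, disulfide_range[1] > 0,
            disulfide_range[1] < disulfide_range[2],
            rsa_buried > 0, rsa_buried < 1,
            length(ddg_neutral) == 2L, ddg_neutral[1] < ddg_neutral[2],
            plddt_cutoff > 0, plddt_cutoff <= 100, consensus_quorum >= 1L)
  structure(list(clash_overlap = clash_overlap, hbond_max = hbond_max,
                 saltbridge_max = saltbridge_max,
                 disulfide_range = disulfide_range, rsa_buried = rsa_buried,
                 ddg_neutral = ddg_neutral, plddt_cutoff = plddt_cutoff,
                 consensus_quorum = as.integer(consensus_quorum),
                 substrate_codes = toupper(substrate_codes)),
            class = "pipeline_config")
}

na_if_null <- function(x) if (is.null(x)) NA else x

evaluate_record <- function(record, config) {
  v <- parse_variant_label(record$protein, na_if_null(record$cdna))
  plof <- isTRUE(record$plof)
  fs <- fixture_feature_set(record)
  category <- structural_category(fs)
  ddg <- na_if_null(record$ddg)
  stability <- if (is.na(ddg)) NA_character_
  else classify_stability(ddg, config$ddg_neutral)
  collective <- consensus_call(unlist(record$calls), config$consensus_quorum)
  pm2 <- pm2_check(gnomad_af = na_if_null(record$gnomad_af),
                   other_db_presence = isTRUE(record$other_db_presence))
  ev <- assemble_evidence(category, collective, pm2 = pm2, plof = plof)
  data.frame(
    protein = record$protein, cdna = na_if_null(record$cdna),
    clinvar_group = record$group,
    position = v$position,
    low_plddt = isTRUE(record$low_plddt),
    ddg = if (is.na(ddg)) NA_real_ else as.numeric(ddg),
    stability_class = stability,
    structural_category = ev$structural_category,
    collective_prediction = ev$collective_prediction,
    pm2 = ev$pm2, pp3 = ev$pp3, bp4 = ev$bp4,
    final_call = ev$final_call,
    rmsd = na_if_null(record$rmsd), tm = na_if_null(record$tm),
    n_lost = nrow(fs$lost), n_gained = nrow(fs$gained),
    all_rotamers_clash = isTRUE(fs$clash$all_rotamers_clash),
    stringsAsFactors = FALSE)
}

evaluate_computed <- function(label, wt, d, config, var_structure = NULL,
                              chain = NULL) {
  v <- parse_variant_label(label)
  mut <- if (is.null(var_structure)) apply_mutation(wt, v, chain = chain)
  else var_structure
  fs <- diff_features(wt, mut, v, d = d, chain = chain)
  category <- structural_category(fs)
  scores <- tryCatch(compare_models(wt, mut, chain = chain),
                     error = function(e) NULL)
  data.frame(
    protein = format_variant(v), cdna = na_if_null(v$cdna_label),
    clinvar_group = NA_character_, position = v$position,
    low_plddt = NA, ddg = NA_real_, stability_class = NA_character_,
    structural_category = category,
    collective_prediction = NA_character_,
    pm2 = NA, pp3 = NA, bp4 = NA, final_call = NA_character_,
    rmsd = if (is.null(scores)) NA_real_ else scores$rmsd,
    tm = if (is.null(scores)) NA_real_ else scores$tm_score,
    n_lost = nrow(fs$lost), n_gained = nrow(fs$gained),
    all_rotamers_clash = isTRUE(fs$clash$all_rotamers_clash),
    stringsAsFactors = FALSE)
}

#' Run the variant-impact pipeline
#'
#' Two modes.  In `"replay"` mode the structural findings of each cohort
#' record are already encoded (e.g. the packaged ABCA4 cohort from
#' [table1_fixture()]) and the pipeline applies the decision layer: stability
#' classification, predictor consensus, population-absence evidence, the
#' structural category and the ACMG computational-evidence codes.  In
#' `"compute"` mode the geometric features are computed from a WT structure by
#' in-silico mutagenesis and feature diffing; fields that need external inputs
#' (ddG, predictor scores, frequencies) are reported as unavailable (`NA`).
#'
#' @param records list of cohort records (replay mode).
#' @param wt WT `protein_structure` (compute mode).
#' @param variants character vector of HGVS protein labels (compute mode).
#' @param var_structures optional named list of pre-built variant structures,
#'   keyed by label (compute mode).
#' @param d optional `domain_map` (compute mode).
#' @param chain chain id (compute mode).
#' @param config `pipeline_config`.
#' @return object of class `pipeline_report`: list with `report` (one row per
#'   variant) and `summary` (grouped counts from [summarize_cohort()], replay
#'   mode only).
#' @export
run_pipeline <- function(records = NULL, wt = NULL, variants = NULL,
                         var_structures = NULL, d = NULL, chain = NULL,
                         config = pipeline_config()) {
  if (!is.null(records)) {
    rows <- lapply(records, evaluate_record, config = config)
  } else if (!is.null(wt) && !is.null(variants)) {
    rows <- lapply(variants, function(lab)
      evaluate_computed(lab, wt, d, config,
                        var_structure = var_structures[[lab]], chain = chain))
  } else if (is.null(wt) && is.null(variants) && is.null(records)) {
    rows <- list()
  } else {
    stop("provide `records` (replay mode) or `wt` + `variants` (compute mode)")
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    evaluate_record(list(protein = "p.A1V", group = "vus", calls = list(
      cadd = "benign", polyphen = "benign", revel = "benign",
      mutpred2 = "benign")), config)[0, ]
  rownames(report) <- NULL
  structure(list(report = report, summary = summarize_cohort(report)),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> ", nrow(x$report), " variants\n", sep = "")
  if (nrow(x$report)) {
    print(utils::head(x$report[, c("protein", "clinvar_group",
                                   "stability_class", "structural_category",
                                   "collective_prediction", "final_call")],
                      20), row.names = FALSE)
    if (nrow(x$report) > 20) cat("...\n")
  }
  invisible(x)
}

#' Write a pipeline report to TSV and/or JSON
#'
#' @param x `pipeline_report`.
#' @param tsv,json output paths (either may be `NULL`).
#' @return invisibly, the report data.frame.
#' @export
write_report <- function(x, tsv = NULL, json = NULL) {
  stopifnot(inherits(x, "pipeline_report"))
  if (!is.null(tsv))
    utils::write.table(x$report, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(x$report, json, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  invisible(x$report)
}
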