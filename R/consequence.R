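## Splice-consequence simulation: retention of the intron downstream of a
## broached donor site, translation to the first premature stop, and
## truncation accounting against a domain map.  The disruption of the donor
## itself is an input assertion (splice-site strength scoring is out of
## scope); full retention of the downstream intron is the modelled
## consequence, exon skipping is not modelled.

GENETIC_CODE_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

#' Translate a nucleotide sequence (standard genetic code)
#'
#' @param seq DNA string (A/C/G/T).
#' @param from 1-based start of the reading frame.
#' @return list: `protein` (one-letter string, stop excluded), `stopped`
#'   (logical: a stop codon was reached before the sequence ran out).
#' @export
translate_cds <- function(seq, from = 1L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n - from + 1L < 3L) stop("coding sequence shorter than one codon")
  aas <- character()
  i <- from
  stopped <- FALSE
  while (i + 2L <= n) {
    codon <- substr(seq, i, i + 2L)
    aa <- GENETIC_CODE_TABLE[[codon]]
    if (is.null(aa)) stop("unknown codon ", codon)
    if (aa == "*") { stopped <- TRUE; break }
    aas <- c(aas, aa)
    i <- i + 3L
  }
  list(protein = paste(aas, collapse = ""), stopped = stopped)
}

#' Transcript model (exons + introns)
#'
#' @param exons character vector of exon sequences, 5' to 3'.
#' @param introns character vector of intron sequences (length
#'   `length(exons) - 1`; `NA` marks an unavailable intron sequence).
#' @param cds_start_offset 1-based offset of the CDS start within the spliced
#'   cDNA.
#' @param id transcript identifier.
#' @return object of class `transcript_model`.
#' @export
transcript_model <- function(exons, introns = character(), cds_start_offset = 1L,
                             id = "toy") {
  exons <- toupper(exons); introns <- toupper(introns)
  if (length(introns) != max(0L, length(exons) - 1L))
    stop("need exactly length(exons) - 1 introns (use NA for missing sequence)")
  ok <- function(x) all(is.na(x) | grepl("^[ACGT]+$", x))
  if (!ok(exons) || !ok(introns))
    stop("sequences must be over the alphabet {A, C, G, T}")
  cdna_len <- sum(nchar(exons))
  if (cds_start_offset < 1L || cds_start_offset > cdna_len)
    stop("cds_start_offset outside the spliced cDNA")
  ends <- cumsum(nchar(exons))
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  structure(list(exons = exons, introns = introns,
                 exon_cdna_start = starts, exon_cdna_end = ends,
                 cds_start_offset = as.integer(cds_start_offset), id = id),
            class = "transcript_model")
}

apply_donor_variant <- function(exons, variant) {
  if (is.null(variant)) return(exons)
  i <- variant$exon_index
  ex <- exons[i]
  substr(ex, nchar(ex), nchar(ex)) <- toupper(variant$base)
  exons[i] <- ex
  exons
}

#' Simulate intron retention at a broached donor site
#'
#' Builds the mRNA produced when the intron downstream of `exon_index` is
#' retained: exons 1..i, the retained intron, then the remaining exons.  An
#' optional substitution at the donor's -1 position (the last nucleotide of
#' `exon_index`) is applied first.  With `exon_index = NULL` the normally
#' spliced mRNA is returned.
#'
#' @param t `transcript_model`.
#' @param exon_index exon whose downstream intron is retained, or `NULL`.
#' @param variant optional `list(exon_index =, base =)` substitution at that
#'   exon's last nucleotide.
#' @return mRNA sequence (character).
#' @export
simulate_intron_retention <- function(t, exon_index = NULL, variant = NULL) {
  exons <- apply_donor_variant(t$exons, variant)
  if (is.null(exon_index)) return(paste(exons, collapse = ""))
  if (exon_index < 1L || exon_index >= length(exons))
    stop("exon_index must have a downstream intron")
  intr <- t$introns[exon_index]
  if (is.na(intr))
    stop("intron ", exon_index, " sequence unavailable; supply it to model ",
         "retention")
  paste(c(exons[seq_len(exon_index)], intr,
          exons[seq(exon_index + 1L, length(exons))]), collapse = "")
}

#' Translate a mutant mRNA and account the truncation
#'
#' Translates `mut_mrna` from the CDS start, takes the longest common prefix
#' with the WT protein as the last preserved residue, reports the novel
#' residues up to the premature stop, and lists the domains lost downstream.
#'
#' @param wt_protein WT protein sequence (one-letter string).
#' @param mut_mrna mutant mRNA sequence.
#' @param cds_start_offset 1-based CDS start within `mut_mrna`.
#' @param d optional `domain_map`; domains entirely downstream of the stop are
#'   `lost_domains`, partially truncated ones `partial_domains`.
#' @return object of class `truncation_result`: `last_wt_aa`, `last_wt_pos`,
#'   `novel_aa`, `novel_count`, `stop_protein_position`, `non_stop`,
#'   `lost_domains`, `partial_domains`.
#' @export
translate_and_diff <- function(wt_protein, mut_mrna, cds_start_offset = 1L,
                               d = NULL) {
  tr <- translate_cds(mut_mrna, cds_start_offset)
  mut_protein <- tr$protein
  nwt <- nchar(wt_protein); nmut <- nchar(mut_protein)
  lcp <- 0L
  while (lcp < min(nwt, nmut) &&
         substr(wt_protein, lcp + 1L, lcp + 1L) ==
         substr(mut_protein, lcp + 1L, lcp + 1L)) lcp <- lcp + 1L
  novel <- if (nmut > lcp) substr(mut_protein, lcp + 1L, nmut) else ""
  novel_count <- nchar(novel)
  stop_pos <- lcp + novel_count + 1L
  lost <- character(); partial <- character()
  if (!is.null(d) && tr$stopped) {
    segs <- d$segments
    for (nm in unique(segs$name)) {
      dsegs <- segs[segs$name == nm, , drop = FALSE]
      if (all(dsegs$start >= stop_pos)) lost <- c(lost, nm)
      else if (any(dsegs$end >= stop_pos)) partial <- c(partial, nm)
    }
  }
  structure(list(
    last_wt_aa = if (lcp > 0L) substr(wt_protein, lcp, lcp) else NA_character_,
    last_wt_pos = lcp, novel_aa = novel, novel_count = novel_count,
    stop_protein_position = stop_pos, non_stop = !tr$stopped,
    lost_domains = lost, partial_domains = partial),
    class = "truncation_result")
}

#' @export
print.truncation_result <- function(x, ...) {
  if (x$non_stop) {
    cat("<truncation_result> no stop codon reached (non-stop)\n")
  } else {
    cat(sprintf("<truncation_result> p.%s%d fs: %d novel residue(s) '%s', stop at %d\n",
                x$last_wt_aa, x$last_wt_pos + 1L, x$novel_count, x$novel_aa,
                x$stop_protein_position))
    if (length(x$lost_domains))
      cat("  lost domains:", paste(x$lost_domains, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Deterministic toy transcript for splice-consequence testing
#'
#' Two exons and one intron built so that retention of the intron after a
#' donor -1 G>A substitution yields a configurable number of novel residues
#' after the junction phenylalanine before a premature stop -- a miniature of
#' a donor-site disruption causing p.(F)fs-type truncation.  With
#' `no_stop = TRUE` the retained intron contains no terminator and
#' translation runs off the transcript end ("non-stop" result).
#'
#' @param novel_count number of novel residues before the stop (>= 1).
#' @param no_stop construct the degenerate non-stop configuration instead.
#' @return list: `transcript` (`transcript_model`), `wt_protein`, `variant`
#'   (donor -1 substitution), `retained_exon` (exon index).
#' @export
toy_transcript <- function(novel_count = 3L, no_stop = FALSE) {
  if (!no_stop && novel_count < 1L)
    stop("a canonical GT donor after the substituted base always yields at ",
         "least one novel codon; novel_count must be >= 1")
  exon1 <- "ATGTTTG"                 # M F + donor -1 base G
  exon2 <- "GAGCCTGA"                # completes ...G|GA GCC TGA -> G A *
  body <- paste(rep("CGT", max(0L, novel_count - 1L)), collapse = "")
  intron <- if (no_stop) paste0("GT", "CGTCGT")
  else paste0("GT", body, "TAG", "CCCAG")
  t <- transcript_model(c(exon1, exon2), intron, cds_start_offset = 1L,
                        id = "toy-donor")
  wt <- translate_cds(simulate_intron_retention(t, NULL), 1L)
  list(transcript = t, wt_protein = wt$protein,
       variant = list(exon_index = 1L, base = "A"), retained_exon = 1L)
}
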