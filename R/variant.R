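#' Parse an HGVS protein (or paired c./p.) variant label
#'
#' Accepts missense substitution labels in one- or three-letter form
#' (`"p.V77M"`, `"p.Gly1862Ser"`), with or without the `p.` prefix, and
#' optionally a combined `"c.229G>A(p.V77M)"` form.  Frameshift and other
#' complex protein labels are parsed as non-missense with `kind` set
#' accordingly rather than rejected, so pipelines can route them (e.g. to
#' splice/truncation handling).
#'
#' @param label HGVS string.
#' @param cdna_label optional HGVS c. string stored alongside.
#' @return object of class `variant_spec`: list with `cdna_label`, `ref_aa`,
#'   `position`, `alt_aa`, `raw_protein_label`, `kind`
#'   (`"missense"` or `"non_missense"`).
#' @examples
#' parse_variant_label("p.V77M")
#' parse_variant_label("p.Gly1862Ser")
#' @export
parse_variant_label <- function(label, cdna_label = NA_character_) {
  stopifnot(is.character(label), length(label) == 1L)
  raw <- trimws(label)
  p <- raw
  ## combined "c.... (p....)" form
  m <- regmatches(raw, regexec("^(c\\.[^ ()]+)\\s*\\(\\s*(p\\.[^)]+)\\s*\\)$", raw))[[1]]
  if (length(m) == 3L) {
    if (is.na(cdna_label)) cdna_label <- m[2]
    p <- m[3]
  }
  p <- sub("^p\\.", "", p)
  p <- gsub("\\s", "", p)

  three <- regmatches(p, regexec("^([A-Za-z]{3})([0-9]+)([A-Za-z]{3})$", p))[[1]]
  one <- regmatches(p, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", p))[[1]]
  ref <- alt <- NA_character_; pos <- NA_integer_
  if (length(three) == 4L) {
    ref <- aa_three_to_one(three[2]); alt <- aa_three_to_one(three[4])
    pos <- as.integer(three[3])
    if (is.na(ref) || is.na(alt))
      stop("unknown three-letter amino-acid code in '", label, "'")
  } else if (length(one) == 4L) {
    ref <- toupper(one[2]); alt <- toupper(one[4]); pos <- as.integer(one[3])
    if (!is_standard_aa1(ref) || !is_standard_aa1(alt))
      stop("unknown one-letter amino-acid code in '", label, "'")
  } else if (grepl("fs|del|ins|dup|\\*|Ter|ext", p)) {
    return(structure(list(cdna_label = cdna_label, ref_aa = NA_character_,
                          position = suppressWarnings(
                            as.integer(sub("^[A-Za-z]{1,3}([0-9]+).*$", "\\1", p))),
                          alt_aa = NA_character_, raw_protein_label = raw,
                          kind = "non_missense"),
                     class = "variant_spec"))
  } else {
    stop("cannot parse variant label '", label, "' as an HGVS substitution")
  }
  if (pos < 1L) stop("variant position must be >= 1")
  if (ref == alt)
    stop("'", label, "' is not a substitution (reference and alternate ",
         "amino acid are both ", ref, ")")
  structure(list(cdna_label = cdna_label, ref_aa = ref, position = pos,
                 alt_aa = alt, raw_protein_label = raw, kind = "missense"),
            class = "variant_spec")
}

#' Canonical one-letter protein label of a variant
#' @param v `variant_spec`.
#' @return character, e.g. `"p.V77M"`.
#' @export
format_variant <- function(v) {
  if (v$kind != "missense") return(v$raw_protein_label)
  paste0("p.", v$ref_aa, v$position, v$alt_aa)
}

#' @export
print.variant_spec <- function(x, ...) {
  cat("<variant_spec> ", format_variant(x),
      if (!is.na(x$cdna_label)) paste0(" (", x$cdna_label, ")"),
      " [", x$kind, "]\n", sep = "")
  invisible(x)
}
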