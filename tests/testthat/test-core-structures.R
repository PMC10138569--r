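test_that("a minimal one-residue PDB parses into a single-chain structure", {
  s <- read_structure(minimal_pdb(), source = "predicted")
  rt <- residue_table(s)
  expect_equal(nrow(rt), 1L)
  expect_equal(rt$aa, "A")
  expect_equal(sum(rt$het), 0L)
  expect_equal(nrow(s$atoms), 5L)
})

test_that("PDB and mmCIF round trips preserve atoms, numbering and coordinates", {
  h <- build_toy_structure("helix", n = 8)
  for (fmt in c("pdb", "mmcif")) {
    path <- tempfile(fileext = if (fmt == "pdb") ".pdb" else ".cif")
    write_structure(h, path, fmt)
    h2 <- read_structure(path, source = "predicted")
    expect_equal(nrow(h2$atoms), nrow(h$atoms))
    expect_equal(h2$atoms$resno, h$atoms$resno)
    expect_equal(h2$atoms$elety, h$atoms$elety)
    expect_lt(max(abs(coords_of(h2) - coords_of(h))), 1e-3)
  }
})

test_that("HETATM blocks are routed to ligands with codes preserved", {
  s <- read_structure(pdb_with_atp())
  lig <- s$atoms[s$atoms$het, ]
  expect_equal(unique(lig$resid), "ATP")
  expect_equal(nrow(lig), 3L)
  expect_equal(sum(!s$atoms$het), 3L)
})

test_that("writing an empty structure errors and unparseable input names the format", {
  h <- build_toy_structure("helix", n = 5)
  h$atoms <- h$atoms[0, ]
  expect_error(write_structure(h, tempfile(), "pdb"), "no atoms")
  bad <- tempfile(fileext = ".pdb")
  writeLines("this is not a pdb file", bad)
  expect_error(suppressWarnings(read_structure(bad)), "pdb")
})

test_that("variant labels parse in one- and three-letter HGVS, rejecting identities", {
  v <- parse_variant_label("p.V77M")
  expect_equal(v$ref_aa, "V"); expect_equal(v$position, 77L)
  expect_equal(v$alt_aa, "M"); expect_equal(v$kind, "missense")

  v3 <- parse_variant_label("p.Gly1862Ser")
  expect_equal(v3$ref_aa, "G"); expect_equal(v3$position, 1862L)
  expect_equal(v3$alt_aa, "S")

  comb <- parse_variant_label("c.229G>A(p.V77M)")
  expect_equal(comb$cdna_label, "c.229G>A")
  expect_equal(comb$position, 77L)

  expect_error(parse_variant_label("p.V77V"), "not a substitution")
  expect_error(parse_variant_label("p.X77Z"), "cannot parse|unknown")

  fs <- parse_variant_label("p.G1862fs*4")
  expect_equal(fs$kind, "non_missense")
  expect_equal(fs$position, 1862L)
})

test_that("parse/format of variant labels round-trips", {
  set.seed(7)
  aas <- names(structvar:::AA3)
  for (i in 1:25) {
    ref <- sample(aas, 1); alt <- sample(setdiff(aas, ref), 1)
    pos <- sample(1:2273, 1)
    lab <- paste0("p.", ref, pos, alt)
    expect_equal(format_variant(parse_variant_label(lab)), lab)
    title <- function(x) paste0(substr(x, 1, 1), tolower(substr(x, 2, 3)))
    lab3 <- paste0("p.", title(structvar:::AA3[ref]), pos,
                   title(structvar:::AA3[alt]))
    expect_equal(format_variant(parse_variant_label(lab3)), lab)
  }
})

test_that("trimming removes ranges, keeps author numbering, and validates input", {
  n <- 2273L
  atoms <- data.frame(chain = "A", resno = seq_len(n), insert = "",
                      resid = "ALA", elety = "CA", elesy = "C",
                      x = seq_len(n) * 3.8, y = 0, z = 0, o = 1, b = 80,
                      het = FALSE)
  s <- new_structure(atoms, "predicted")
  ranges <- list(c(164, 208), c(862, 914), c(1164, 1203), c(1279, 1340),
                 c(2225, 2231), c(2256, 2273))
  trimmed <- trim_regions(s, ranges)
  expect_equal(nrow(residue_table(trimmed)), 2048L)
  # numbering is never compacted
  expect_true(all(c(163, 209, 861, 915) %in% trimmed$atoms$resno))
  expect_false(any(c(164, 208, 2273) %in% trimmed$atoms$resno))

  expect_identical(trim_regions(s, list()), s)
  expect_error(trim_regions(s, list(c(10, 5))), "inverted")
  expect_warning(trim_regions(s, list(c(5000, 5100))), "matches no residues")
})

test_that("model confidence flags pLDDT <= cutoff inclusively and needs a predicted model", {
  atoms <- do.call(rbind, lapply(1:3, function(i)
    data.frame(chain = "A", resno = i, insert = "", resid = "ALA",
               elety = "CA", elesy = "C", x = i * 3.8, y = 0, z = 0,
               o = 1, b = c(40, 60, 80)[i], het = FALSE)))
  s <- new_structure(atoms, "predicted")
  mc <- model_confidence(s, threshold = 50)
  expect_equal(mc$mean, 60)
  expect_equal(sum(mc$per_residue$low_confidence), 1L)

  s$atoms$b <- 100
  mc2 <- model_confidence(s)
  expect_equal(mc2$mean, 100)
  expect_equal(sum(mc2$per_residue$low_confidence), 0L)

  s$atoms$b <- 50      # boundary: exactly at the cutoff is flagged
  expect_equal(sum(model_confidence(s, 50)$per_residue$low_confidence), 3L)

  exp_s <- new_structure(atoms, "experimental")
  expect_error(model_confidence(exp_s), "predicted models only")
})
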