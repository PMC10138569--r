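test_that("Shrake-Rupley matches the analytic sphere and full occlusion", {
  iso <- new_structure(structvar:::make_atom_rows("A", 1, "GLY", "CA", c(0, 0, 0)),
                       "predicted")
  asa <- solvent_accessibility(iso)$per_atom[1]
  expect_equal(asa, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.02)

  # central atom enclosed by a tight shell of touching atoms
  shell <- structvar:::sphere_points(80) * 2.2
  atoms <- rbind(structvar:::make_atom_rows("A", 1, "GLY", "CA", c(0, 0, 0)),
                 structvar:::make_atom_rows("A", 900, "CAG",
                                            paste0("C", 1:80), shell,
                                            het = TRUE))
  occl <- new_structure(atoms, "predicted")
  expect_lt(solvent_accessibility(occl)$per_atom[1], 1)
})

test_that("extended Gly-X-Gly residues are near-maximally exposed", {
  for (x in c("A", "V", "W", "R", "D")) {
    g <- build_toy_structure("gxg_tripeptide", x = x)
    per <- solvent_accessibility(g)$per_residue
    expect_gt(per$rsa[2], 0.9)
    expect_lt(per$rsa[2], 1.1)
    expect_false(per$buried[2])
  }
})

test_that("doubling the sphere sampling changes atom ASA fractions by < 1%", {
  g <- build_toy_structure("gxg_tripeptide", x = "W")
  a1 <- solvent_accessibility(g, n_points = 480)$per_atom
  a2 <- solvent_accessibility(g, n_points = 960)$per_atom
  radii <- structvar:::vdw_radius(g$atoms$elesy) + 1.4
  frac_change <- abs(a1 - a2) / (4 * pi * radii^2)
  expect_lt(max(frac_change), 0.01)
})

test_that("clash detection applies the inclusive 0.4 A overlap and bonded exclusions", {
  ala <- structvar:::build_residue("A", resno = 1)
  cb <- as.numeric(ala[ala$elety == "CB", c("x", "y", "z")])
  mk <- function(d) {
    probe <- structvar:::make_atom_rows("A", 900, "LIG", "C1",
                                        cb + c(d, 0, 0), het = TRUE)
    new_structure(rbind(ala, probe), "predicted")
  }
  at_boundary <- detect_clashes(mk(3.0), 1)      # C-C vdW sum 3.4, overlap 0.4
  expect_equal(nrow(at_boundary$pairs), 1L)
  expect_equal(at_boundary$pairs$overlap, 0.4, tolerance = 1e-9)
  expect_equal(at_boundary$max_overlap, 0.4, tolerance = 1e-9)

  expect_equal(nrow(detect_clashes(mk(3.5), 1)$pairs), 0L)

  # covalently bonded CA-CB (1-2) never counts as a clash
  solo <- new_structure(ala, "predicted")
  expect_equal(nrow(detect_clashes(solo, 1)$pairs), 0L)
})

test_that("contact kinds fire at their planted distances", {
  sb <- build_toy_structure("salt_bridge_pair")
  hits <- detect_contacts(sb, 1, kinds = "saltbridge")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$distance, 3.9, tolerance = 1e-6)
  expect_equal(hits$atom_a, "NH1"); expect_equal(hits$atom_b, "OE1")
  # symmetric in pair order: scanning from the Glu side finds the same bridge
  hits_rev <- detect_contacts(sb, 10, kinds = "saltbridge")
  expect_equal(nrow(hits_rev), 1L)
  expect_equal(hits_rev$distance, hits$distance, tolerance = 1e-9)

  # beyond the 4.0 A bound nothing is reported
  far <- build_toy_structure("salt_bridge_pair", distance = 4.2)
  expect_equal(nrow(detect_contacts(far, 1, kinds = "saltbridge")), 0L)

  ds <- build_toy_structure("disulfide_pair")
  dh <- detect_contacts(ds, 1, kinds = "disulfide")
  expect_equal(nrow(dh), 1L)
  expect_equal(dh$distance, 2.05, tolerance = 1e-6)

  ap <- build_toy_structure("atp_pocket", contact_atom = "N")
  lh <- detect_contacts(ap, 5, kinds = "ligand_polar")
  expect_true(any(lh$atom_a == "N" & lh$resid_b == "ATP" &
                    abs(lh$distance - 2.9) < 1e-6))
})

test_that("contacts and clashes are invariant under rigid motion", {
  for (s in list(build_toy_structure("salt_bridge_pair"),
                 build_toy_structure("atp_pocket"))) {
    moved <- rigid_transform(s)
    focus <- s$atoms$resno[!s$atoms$het][1]
    c1 <- detect_contacts(s, focus)
    c2 <- detect_contacts(moved, focus)
    expect_equal(nrow(c1), nrow(c2))
    expect_equal(c1$distance, c2$distance, tolerance = 1e-9)
    k1 <- detect_clashes(s, focus); k2 <- detect_clashes(moved, focus)
    expect_equal(nrow(k1$pairs), nrow(k2$pairs))
    expect_equal(k1$max_overlap, k2$max_overlap, tolerance = 1e-9)
  }
})

test_that("sequon scanning follows the N-X-S/T (X != P) rule", {
  expect_true(sequon_scan("NAS", 1))
  expect_false(sequon_scan("NPS", 1))
  expect_true(sequon_scan("ANTTG", 2))
  expect_false(sequon_scan("NAA", 1))
  expect_error(sequon_scan("NAS", 2), "sequon")
  expect_error(sequon_scan("NAS", 0), "sequon")
})

test_that("helix-interior prolines are flagged, others are not", {
  h <- build_toy_structure("helix", n = 12)
  expect_true(helix_proline_check(h, 6, "P"))
  expect_false(helix_proline_check(h, 6, "L"))
  expect_false(helix_proline_check(h, 1, "P"))   # first turn
  expect_false(helix_proline_check(h, 12, "P"))  # last turn
  coil <- build_toy_structure("gxg_tripeptide", x = "A")
  expect_false(helix_proline_check(coil, 2, "P"))
})

test_that("contacts classify by domain membership", {
  dm <- read_domain_map()
  mk_contact <- function(ra, rb, resid_b = "ALA", kind = "hbond",
                         chain_b = "A") {
    data.frame(kind = kind, chain_a = "A", resno_a = ra, atom_a = "N",
               chain_b = chain_b, resno_b = rb, resid_b = resid_b,
               atom_b = "O", distance = 3.0,
               domain_relation = NA_character_)
  }
  expect_equal(classify_contact_domain(mk_contact(900, 2000), dm), "interdomain")
  expect_equal(classify_contact_domain(mk_contact(100, 200), dm), "intradomain")
  expect_equal(classify_contact_domain(mk_contact(900, 500, "ATP",
                                                  kind = "ligand_polar"), dm),
               "ligand")
  expect_equal(classify_contact_domain(mk_contact(900, 900, chain_b = "B"), dm),
               "interchain")
  expect_warning(out <- classify_contact_domain(mk_contact(900, 5000), dm),
                 "outside")
  expect_equal(out, "unassigned")
})

test_that("feature diffing is empty on identical models", {
  h <- build_toy_structure("helix", n = 8)
  fs <- diff_features(h, h, parse_variant_label("p.A4V"))
  expect_s3_class(fs, "feature_set")
  expect_equal(nrow(fs$lost), 0L)
  expect_equal(nrow(fs$gained), 0L)
  expect_false(fs$clash$all_rotamers_clash)
  expect_false(fs$sequon_lost); expect_false(fs$pro_in_helix)
  expect_equal(structural_category(fs), "Neu")

  # property: identity diff is empty across fixture kinds
  for (kind in c("salt_bridge_pair", "disulfide_pair", "gxg_tripeptide")) {
    s <- build_toy_structure(kind)
    pos <- s$atoms$resno[!s$atoms$het][1]
    ref <- residue_table(s)$aa[1]
    alt <- setdiff(c("V", "L"), ref)[1]
    fs_k <- diff_features(s, s, parse_variant_label(paste0("p.", ref, pos, alt)))
    expect_equal(nrow(fs_k$lost) + nrow(fs_k$gained), 0L)
  }
})

test_that("breaking a disulfide partner is reported as a lost disulfide", {
  ds <- build_toy_structure("disulfide_pair")
  v <- parse_variant_label("p.C1Y")
  mut <- apply_mutation(ds, v)
  fs <- diff_features(ds, mut, v)
  expect_true(any(fs$lost$kind == "disulfide"))
  expect_equal(fs$special_residue_change, "cys_involved")
  expect_equal(structural_category(fs), "Del")
})

test_that("mutating the ATP-contacting residue loses the ligand contact and clashes", {
  ap <- build_toy_structure("atp_pocket")
  v <- parse_variant_label("p.T5P")
  mut <- apply_mutation(ap, v)
  fs <- diff_features(ap, mut, v)
  expect_true(any(fs$lost$kind == "ligand_polar" & fs$lost$resid_b == "ATP"))
  expect_true(fs$clash$all_rotamers_clash)
  expect_true(any(fs$clash$pairs$resid_b == "ATP"))
  expect_equal(fs$special_residue_change, "pro_introduced")
  expect_equal(structural_category(fs), "Del")
})

test_that("mutating the sequon Asn of an N-X-T motif flags sequon loss", {
  g <- build_toy_structure("helix", n = 6, sequence = "ANATAA")
  v <- parse_variant_label("p.N2K")
  mut <- apply_mutation(g, v)
  fs <- diff_features(g, mut, v)
  expect_true(fs$sequon_lost)
  expect_equal(structural_category(fs), "Del")
})
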