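bb <- list(N = c(0, 0, 0), CA = c(1.458, 0, 0), C = c(2.009, 1.420, 0))

test_that("glycine has no side chain and chi counts are enforced", {
  expect_equal(nrow(build_sidechain(bb, "G")), 0L)
  expect_error(build_sidechain(bb, "G", 60), "no side chain")
  expect_error(build_sidechain(bb, "K", c(180, 180)), "chi angle")
  expect_error(build_sidechain(list(N = c(0, 0, 0), CA = c(1, 0, 0),
                                    C = c(2, 0, 0)), "A"), "collinear")
})

test_that("alanine gets a single CB at the template CA-CB distance", {
  sc <- build_sidechain(bb, "A")
  expect_equal(rownames(sc), "CB")
  expect_equal(unname(sqrt(sum((sc["CB", ] - bb$CA)^2))), 1.52, tolerance = 1e-9)
})

test_that("requested chi dihedrals are reproduced by measurement", {
  for (case in list(list(aa = "K", chis = c(180, 180, 180, 180)),
                    list(aa = "K", chis = c(-65, 170, -150, 60)),
                    list(aa = "R", chis = c(-60, 175, 65, 85)),
                    list(aa = "M", chis = c(-65, -65, -70)),
                    list(aa = "S", chis = 62))) {
    sc <- build_sidechain(bb, case$aa, case$chis)
    coords <- rbind(N = bb$N, CA = bb$CA, C = bb$C, sc)
    got <- measure_chis(coords, case$aa)
    expect_lt(max(angle_diff(got, case$chis)), 1e-4)
  }
})

test_that("every amino-acid template reproduces its ideal bond lengths", {
  for (aa in setdiff(names(structvar:::AA3), "G")) {
    nchi <- structvar:::CHI_COUNT[[aa]]
    sc <- build_sidechain(bb, aa, rep(-65, nchi))
    coords <- rbind(N = bb$N, CA = bb$CA, C = bb$C, sc)
    bonds <- structvar:::sidechain_bonds(aa)
    for (i in seq_len(nrow(bonds))) {
      d <- sqrt(sum((coords[bonds$from[i], ] - coords[bonds$to[i], ])^2))
      expect_lt(abs(d - bonds$length[i]), 1e-3)
    }
  }
})

test_that("rotamer enumeration is an ordered permutation of the library", {
  h <- build_toy_structure("helix", n = 8)
  lib <- rotamer_library()
  for (aa in c("A", "V", "L", "K", "R", "W")) {
    pl <- enumerate_rotamers(h, 4, aa)
    rows <- lib[lib$aa == aa, ]
    expect_equal(length(pl), nrow(rows))
    probs <- vapply(pl, `[[`, numeric(1), "probability")
    expect_equal(sort(probs, decreasing = TRUE), probs)
    expect_setequal(probs, rows$probability)
  }
  expect_equal(length(enumerate_rotamers(h, 4, "A")), 1L)
  expect_error(enumerate_rotamers(h, 99, "A"), "no residue")
})

test_that("rotamers in an open environment are clash-free; a tight cage traps them all", {
  h <- build_toy_structure("helix", n = 12)
  open_site <- enumerate_rotamers(h, 1, "V")    # helix terminus: open space
  expect_true(all(vapply(open_site, `[[`, integer(1), "clash_count") == 0L))
  expect_false(attr(open_site, "all_rotamers_clash"))

  cage <- build_toy_structure("cage")
  trapped <- enumerate_rotamers(cage, 5, "R")
  counts <- vapply(trapped, `[[`, integer(1), "clash_count")
  expect_true(all(counts > 0L))
  expect_true(attr(trapped, "all_rotamers_clash"))

  # brute-force oracle: min pair distance between any placement atom and the
  # cage is below the vdW sum minus the clash threshold
  cage_xyz <- as.matrix(cage$atoms[cage$atoms$het, c("x", "y", "z")])
  for (p in trapped) {
    dmin <- min(apply(p$atoms, 1, function(at)
      min(sqrt(rowSums(sweep(cage_xyz, 2, at)^2)))))
    expect_lt(dmin, 1.7 + 1.7 - 0.4)
  }
})

test_that("apply_mutation swaps only the side chain and checks the reference", {
  h <- build_toy_structure("helix", n = 12)
  v <- parse_variant_label("p.A6M")
  mut <- apply_mutation(h, v)
  # backbone of the mutated residue is untouched
  for (at in c("N", "CA", "C", "O")) {
    expect_equal(residue_coord_matrix(mut, 6)[at, ],
                 residue_coord_matrix(h, 6)[at, ])
  }
  # every other residue is bit-identical
  other_wt <- h$atoms[h$atoms$resno != 6, c("x", "y", "z")]
  other_mut <- mut$atoms[mut$atoms$resno != 6, c("x", "y", "z")]
  expect_equal(unname(as.matrix(other_mut)), unname(as.matrix(other_wt)))
  expect_equal(residue_table(mut)$aa[6], "M")

  expect_error(apply_mutation(h, parse_variant_label("p.V6M")),
               "reference mismatch")
})

test_that("'best' placement agrees with the enumeration argmin", {
  cage <- build_toy_structure("cage")
  v <- parse_variant_label("p.G5R")
  pl <- enumerate_rotamers(cage, 5, "R")
  counts <- vapply(pl, `[[`, integer(1), "clash_count")
  probs <- vapply(pl, `[[`, numeric(1), "probability")
  best_idx <- order(counts, -probs)[1]
  mut <- apply_mutation(cage, v, "best")
  expect_equal(attr(mut, "placement")$chis, pl[[best_idx]]$chis)
  expect_true(attr(mut, "all_rotamers_clash"))
})
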