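test_that("stability classes partition ddG with inclusive +/-0.5 boundaries", {
  expect_equal(classify_stability(-5.19), "stabilizing")
  expect_equal(classify_stability(0.48), "neutral")
  expect_equal(classify_stability(0.71), "destabilizing")
  expect_equal(classify_stability(0.15), "neutral")
  expect_equal(classify_stability(c(-0.5, 0.5)), c("neutral", "neutral"))
  expect_equal(classify_stability(-0.5000001), "stabilizing")
  expect_error(classify_stability(NaN), "finite")

  # totality: every value lands in exactly one class
  set.seed(2)
  vals <- c(runif(200, -100, 100), -0.5, 0.5, 0)
  cls <- classify_stability(vals)
  expect_true(all(cls %in% c("stabilizing", "neutral", "destabilizing")))
  expect_equal(cls[vals < -0.5], rep("stabilizing", sum(vals < -0.5)))
  expect_equal(cls[vals > 0.5], rep("destabilizing", sum(vals > 0.5)))
})

test_that("predictor binarization applies the tool thresholds", {
  calls <- binarize_predictors(25, "probably_damaging", 0.8, 0.3)
  expect_equal(sum(calls == "pathogenic"), 3L)
  expect_equal(unname(calls["mutpred2"]), "benign")

  expect_equal(sum(binarize_predictors(10, "benign", 0.1, 0.1) == "pathogenic"), 0L)
  expect_equal(unname(binarize_predictors(19.99, "benign", 0.5, 0.5)["revel"]),
               "pathogenic")   # boundary: score exactly 0.5 is pathogenic
  expect_equal(unname(binarize_predictors(20, "possibly_damaging", 0, 0)["cadd"]),
               "pathogenic")

  part <- binarize_predictors(NA, "benign", 0.6, NA)
  expect_equal(unname(part["cadd"]), "unavailable")
  expect_equal(unname(part["mutpred2"]), "unavailable")
})

test_that("consensus requires a 3-of-4 majority and is order-invariant", {
  expect_equal(consensus_call(c("pathogenic", "pathogenic", "pathogenic",
                                "benign")), "pathogenic")
  expect_equal(consensus_call(rep("benign", 4)), "benign")
  expect_equal(consensus_call(c("pathogenic", "benign", "pathogenic",
                                "benign")), "conflicting")
  set.seed(4)
  calls <- c("pathogenic", "pathogenic", "benign", "pathogenic")
  for (i in 1:5)
    expect_equal(consensus_call(sample(calls)), "pathogenic")
  expect_warning(out <- consensus_call(c("pathogenic", "unavailable",
                                         "unavailable", "unavailable")),
                 "fewer than")
  expect_equal(out, "conflicting")
})

test_that("PM2 requires absence from every population database", {
  expect_true(pm2_check())
  expect_false(pm2_check(gnomad_af = 2.03e-3))
  expect_false(pm2_check(exac_af = 1e-6))
  expect_false(pm2_check(other_db_presence = TRUE))
})

test_that("structural categories follow the deleterious/mild/neutral rules", {
  gained_sb <- feature_set(gained = data.frame(
    kind = "saltbridge", chain_a = "A", resno_a = 423, atom_a = "NH1",
    chain_b = "A", resno_b = 500, resid_b = "GLU", atom_b = "OE1",
    distance = 3.8, domain_relation = "intradomain"))
  expect_equal(structural_category(gained_sb), "Mild")

  clashing <- feature_set(clash = list(pairs = structvar:::empty_contacts(),
                                       max_overlap = 1,
                                       all_rotamers_clash = TRUE))
  expect_equal(structural_category(clashing), "Del")

  expect_equal(structural_category(feature_set()), "Neu")

  lost_inter <- feature_set(lost = data.frame(
    kind = "hbond", chain_a = "A", resno_a = 965, atom_a = "ND2",
    chain_b = "A", resno_b = 2100, resid_b = "GLY", atom_b = "O",
    distance = 3.1, domain_relation = "interdomain"))
  expect_equal(structural_category(lost_inter), "Del")

  sequon <- feature_set(sequon_lost = TRUE)
  expect_equal(structural_category(sequon), "Del")

  buried_gly <- feature_set(wt_surface = list(asa = 5, rsa = 0.05, buried = TRUE),
                            mut_surface = list(asa = 5, rsa = 0.05, buried = TRUE),
                            special_residue_change = "gly_replaced")
  expect_equal(structural_category(buried_gly), "Del")

  flip <- feature_set(wt_surface = list(asa = 10, rsa = 0.1, buried = TRUE),
                      mut_surface = list(asa = 80, rsa = 0.5, buried = FALSE))
  expect_equal(structural_category(flip), "Del")
})

test_that("evidence assembly sets PP3/BP4 correctly and pLoF dominates", {
  ev <- assemble_evidence("Del", "pathogenic", pm2 = TRUE)
  expect_true(ev$pp3); expect_false(ev$bp4); expect_true(ev$pm2)
  expect_equal(ev$final_call, "pathogenic_support")

  ev2 <- assemble_evidence("Del", "benign")
  expect_false(ev2$pp3); expect_false(ev2$bp4)
  expect_equal(ev2$final_call, "conflicting")

  ev3 <- assemble_evidence("Neu", "benign")
  expect_true(ev3$bp4)
  expect_equal(ev3$final_call, "benign_support")

  ev4 <- assemble_evidence("Neu", "benign", plof = TRUE)
  expect_equal(ev4$structural_category, "pLoF")
  expect_equal(ev4$final_call, "pathogenic_support")

  # exhaustive lattice: PP3 and BP4 are never both set; pLoF always forces
  # pathogenic support
  for (cat in c("Neu", "Mild", "Del"))
    for (col in c("pathogenic", "benign", "conflicting"))
      for (pm2 in c(TRUE, FALSE))
        for (plof in c(TRUE, FALSE)) {
          ev <- assemble_evidence(cat, col, pm2, plof)
          expect_false(ev$pp3 && ev$bp4)
          if (plof) expect_equal(ev$final_call, "pathogenic_support")
        }
})

test_that("cohort summaries count groups deterministically", {
  empty <- summarize_cohort(data.frame(clinvar_group = character(),
                                       stability_class = character(),
                                       structural_category = character(),
                                       collective_prediction = character(),
                                       pm2 = logical(),
                                       final_call = character()))
  expect_true(all(empty$n == 0))
  expect_true(all(empty$stability == 0))

  df <- data.frame(clinvar_group = c("benign", "benign", "vus"),
                   stability_class = c("neutral", "stabilizing", "neutral"),
                   structural_category = c("Neu", "Mild", "Del"),
                   collective_prediction = c("benign", "benign", "pathogenic"),
                   pm2 = c(FALSE, FALSE, TRUE),
                   final_call = c("benign_support", "uncertain",
                                  "pathogenic_support"))
  sm <- summarize_cohort(df)
  expect_equal(unname(sm$n["benign"]), 2L)
  expect_equal(sm$stability["benign", "neutral"], c(neutral = 1L),
               ignore_attr = TRUE)
  expect_equal(sm$pm2["vus", "TRUE"], c("TRUE" = 1L), ignore_attr = TRUE)
})
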