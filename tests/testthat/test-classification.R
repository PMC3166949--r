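test_that("the four-class map is total and matches every printed class pattern", {
  # all 8 rows of the class table: (ref, null, activated) -> class, both directions
  for (dir in c("INDUCTION", "REPRESSION")) {
    expect_identical(
      classify_pka_dependence(TRUE, "TOTAL", FALSE)$pka_class,
      "CLASS1_PKA_INDEPENDENT")
    expect_identical(
      classify_pka_dependence(TRUE, "NONE", TRUE)$pka_class,
      "CLASS2_PKA_ONLY")
    expect_identical(
      classify_pka_dependence(TRUE, "TOTAL", TRUE)$pka_class,
      "CLASS3_REDUNDANT")
    expect_identical(
      classify_pka_dependence(TRUE, "NONE", FALSE)$pka_class,
      "CLASS4_COOPERATIVE")
  }
  # partial responses without PKA belong to the cooperative class
  expect_identical(classify_pka_dependence(TRUE, "PARTIAL", FALSE)$pka_class,
                   "CLASS4_COOPERATIVE")
  expect_identical(classify_pka_dependence(TRUE, "PARTIAL", TRUE)$pka_class,
                   "CLASS2_PKA_ONLY")
  # unresponsive reference gates everything
  expect_identical(classify_pka_dependence(FALSE, "TOTAL", TRUE)$pka_class,
                   "NOT_GLUCOSE_REGULATED")
  # graceful degradation without activation data
  no_act_total <- classify_pka_dependence(TRUE, "TOTAL", NA)
  expect_identical(no_act_total$pka_class, "CLASS1_PKA_INDEPENDENT")
  expect_true(no_act_total$activation_data_absent)
  expect_identical(classify_pka_dependence(TRUE, "NONE", NA)$pka_class,
                   "UNRESOLVED")
  # the map is total over the full call grid
  for (strength in c("TOTAL", "PARTIAL", "NONE"))
    for (act in c(TRUE, FALSE, NA))
      expect_true(nzchar(classify_pka_dependence(TRUE, strength, act)$pka_class))
})

test_that("transience reproduces the reference-strain calls of both study tables", {
  expected_ind <- c(PDC1 = "SUSTAINED", PDC5 = "TRANSIENT", ALD5 = "TRANSIENT",
                    TMT1 = "TRANSIENT", YMC2 = "TRANSIENT", ATR1 = "TRANSIENT")
  tab <- study_table("induction_factors")
  ref <- tab[tab$strain == "REF_PKA_PLUS", ]
  for (i in seq_len(nrow(ref))) {
    expect_identical(
      classify_transience(ref$short_factor[i], ref$growth_factor[i], "INDUCTION"),
      unname(expected_ind[ref$gene[i]]), label = ref$gene[i])
  }
  expected_rep <- c(TPS1 = "TRANSIENT", TPS2 = "TRANSIENT",
                    `HXT6/7` = "SUSTAINED", GRX2 = "TRANSIENT",
                    PEP4 = "TRANSIENT")
  tab <- study_table("repression_factors")
  ref <- tab[tab$strain == "REF_PKA_PLUS", ]
  for (i in seq_len(nrow(ref))) {
    expect_identical(
      classify_transience(ref$short_factor[i], ref$growth_factor[i], "REPRESSION"),
      unname(expected_rep[ref$gene[i]]), label = ref$gene[i])
  }
  expect_identical(classify_transience(1, 1, "INDUCTION"), "NONE")
  expect_identical(classify_transience(1.2, 6, "INDUCTION"), "GROWTH_ONLY")
})

test_that("gluconeogenic PKA requirement matches the printed signal rows", {
  tab <- study_table("gluconeogenic_signals")
  call_of <- function(gene) {
    r <- tab[tab$gene == gene, ]
    pka_requirement_gluconeogenic(r$ref, r$msn, r$yak, fold = 2)
  }
  expect_identical(call_of("HXK1"), "PKA_REQUIRED")    # 459/77, 459/228 both >= 2
  expect_identical(call_of("HSP12"), "MSN_DEPENDENT")  # 3790/2436 < 2
  expect_identical(pka_requirement_gluconeogenic(100, 100, 100), "UNCHANGED")
  expect_identical(pka_requirement_gluconeogenic(100, 120, 30), "YAK_DEPENDENT")
  # invariant under common rescaling
  set.seed(31)
  for (k in c(0.01, 1, 37)) {
    expect_identical(call_of("GLC3"),
                     pka_requirement_gluconeogenic(390 * k, 96 * k, 425 * k))
  }
  expect_error(pka_requirement_gluconeogenic(-1, 2, 3), "non-negative")
})

test_that("suppressor comparison flags divergent genes in the right direction", {
  tab <- study_table("gluconeogenic_signals")
  dal3 <- tab[tab$gene == "DAL3", ]
  expect_identical(compare_suppressors(dal3$msn, dal3$yak), "HIGHER_IN_MSN")
  atf2 <- tab[tab$gene == "ATF2", ]
  expect_identical(compare_suppressors(atf2$msn, atf2$yak), "HIGHER_IN_YAK")
  expect_identical(compare_suppressors(100, 100), "SIMILAR")
  expect_identical(compare_suppressors(5 * 100, 5 * 40),
                   compare_suppressors(100, 40))
})

test_that("build_profiles recovers planted truth exactly on noiseless data", {
  cfg <- sim_config(n_genes = 120, replicate_cv = 0, array_scale_jitter = 0)
  sim <- generate_dataset(cfg, seed = 13)
  # noiseless, undistorted signals are already on a common scale; with this
  # few genes, rescaling tiny arrays would itself shift condition means
  noiseless <- expr_matrix(unclass(sim$matrix), scaled = TRUE)
  prof <- build_profiles(noiseless, sim$samples)
  labels <- truth_labels(sim$truth)
  expect_identical(prof$pka_class, labels$pka_class)
  responsive <- labels$pka_class != "NOT_GLUCOSE_REGULATED"
  expect_identical(prof$transience_ref[responsive],
                   labels$transience[responsive])
  expect_identical(prof$gluconeogenic, labels$gluconeogenic)
  # single planted class-1 induced gene with a pinned effect: factor exactly 10
  one <- sim_config(n_genes = 1, responsive_fraction = 0.9,
                    class_mix = c(CLASS1_PKA_INDEPENDENT = 1,
                                  CLASS2_PKA_ONLY = 0, CLASS3_REDUNDANT = 0,
                                  CLASS4_COOPERATIVE = 0),
                    induction_fraction = 1, transient_fraction = 0,
                    msn_dependent_fraction = 0,
                    effect_range = c(10, 10),
                    replicate_cv = 0, array_scale_jitter = 0)
  s1 <- generate_dataset(one, seed = 4)
  p1 <- build_profiles(expr_matrix(unclass(s1$matrix), scaled = TRUE),
                       s1$samples)
  expect_equal(p1$ref_factor, 10, tolerance = 1e-9)
  expect_equal(p1$msn_factor, 10, tolerance = 1e-9)
  expect_equal(p1$yak_factor, 10, tolerance = 1e-9)
})

test_that("profiles are invariant to gene order and fail without required conditions", {
  sim <- generate_dataset(sim_config(n_genes = 60, array_scale_jitter = 0),
                          seed = 17)
  prof <- build_profiles(sim$matrix, sim$samples)
  perm <- sample(nrow(sim$matrix))
  shuffled <- make_matrix(unclass(sim$matrix)[perm, ],
                          genes = rownames(sim$matrix)[perm],
                          samples = colnames(sim$matrix))
  prof2 <- build_profiles(shuffled, sim$samples)
  prof2 <- prof2[match(prof$gene, prof2$gene), ]
  expect_identical(prof$pka_class, prof2$pka_class)
  expect_equal(prof$ref_factor, prof2$ref_factor)
  # reference-only data cannot be classified
  keep <- sim$samples$strain == "REF_PKA_PLUS"
  expect_error(
    build_profiles(sim$matrix[, sim$samples$sample_id[keep]],
                   sim$samples[keep, ]),
    "PKA-null strain")
})

test_that("absent activation condition degrades classes instead of guessing", {
  cfg <- sim_config(n_genes = 200, with_activation = FALSE,
                    array_scale_jitter = 0, replicate_cv = 0)
  sim <- generate_dataset(cfg, seed = 23)
  prof <- build_profiles(expr_matrix(unclass(sim$matrix), scaled = TRUE),
                         sim$samples)
  truthcls <- truth_labels(sim$truth)$pka_class
  expect_false(any(prof$pka_class %in% c("CLASS2_PKA_ONLY", "CLASS3_REDUNDANT")))
  # planted class 1 and 3 genes collapse onto flagged class 1
  sel13 <- truthcls %in% c("CLASS1_PKA_INDEPENDENT", "CLASS3_REDUNDANT")
  expect_true(all(prof$pka_class[sel13] == "CLASS1_PKA_INDEPENDENT"))
  expect_true(all(prof$activation_data_absent[sel13]))
  # planted class 2 and 4 genes become UNRESOLVED
  sel24 <- truthcls %in% c("CLASS2_PKA_ONLY", "CLASS4_COOPERATIVE")
  expect_true(all(prof$pka_class[sel24] == "UNRESOLVED"))
})
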