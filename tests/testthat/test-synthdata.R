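test_that("generator configuration validates its probability inputs", {
  expect_s3_class(generator_config(), "ipv_generator_config")
  expect_error(generator_config(category_probs = c(NO_IPV = 0.5,
                                                   LI_PHY_ONLY = 0.6)),
               "named")
  bad <- generator_config()
  bad$category_probs["NO_IPV"] <- 2
  expect_error(validate_generator_config(bad), "summing to 1")
  expect_error(generator_config(p_both_missing = 1.2), "\\[0, 1\\]")
  expect_error(generator_config(freq_probs = c(never = 0.5, once = 0.5)),
               "non-never")
})

test_that("identical seeds give identical records; different seeds differ", {
  cfg <- generator_config(n_couples = 120)
  a <- generate_couples(cfg, seed = 9)
  b <- generate_couples(cfg, seed = 9)
  expect_identical(as.data.frame(a$records), as.data.frame(b$records))
  expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))
  c <- generate_couples(cfg, seed = 10)
  expect_false(identical(as.data.frame(a$records), as.data.frame(c$records)))
})

test_that("noiseless generation is classifier-consistent with latent truth", {
  cfg <- generator_config(n_couples = 400, p_one_missing = 0,
                          p_both_missing = 0)
  sim <- generate_couples(cfg, seed = 21)
  expect_equal(nrow(validate_fm(sim$records)), 0L)
  cls <- classify_couples(sim$records)
  m <- dplyr::inner_join(tidy(cls), sim$truth, by = "couple_id",
                         suffix = c("", "_true"))
  expect_equal(as.character(m$category), as.character(m$category_true))
  expect_equal(as.character(m$direction_psy), m$direction_psy_true)
  expect_equal(as.character(m$direction_phy_cs), m$direction_phy_cs_true)
  expect_equal(m$repeated_phy, m$repeated_phy_true)
  expect_equal(m$repeated_psy, m$repeated_psy_true)
})

test_that("observed category frequencies track the latent mixture", {
  n <- 20000
  cfg <- generator_config(n_couples = n, p_one_missing = 0,
                          p_both_missing = 0)
  cls <- classify_couples(generate_couples(cfg, seed = 5)$records)
  obs <- table(cls$category) / n
  for (cat in names(cfg$category_probs)) {
    p <- cfg$category_probs[[cat]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(obs[[cat]] - p), 3 * se + 1e-12)
  }
})

test_that("missingness rates land near their configured probabilities", {
  cfg <- generator_config()  # study-scale defaults
  sim <- generate_couples(cfg, seed = 13)
  nr <- count_reports(sim$records)
  n_both <- sum(nr$n_reports == 0)
  n_one <- sum(nr$n_reports == 1)
  expect_lt(abs(n_both - 55), 3 * sqrt(55 * (1 - 55 / 1781)) + 1)
  expect_lt(abs(n_one - 110), 3 * sqrt(110 * (1 - 110 / 1781)) + 1)
})

test_that("degradation is identity at perfect sensitivity and total at zero", {
  sim <- generate_couples(generator_config(n_couples = 150, p_one_missing = 0,
                                           p_both_missing = 0), seed = 2)
  same <- degrade_records(sim$records, sensitivity = 1, specificity = 1,
                          seed = 1)
  expect_identical(as.data.frame(same), as.data.frame(sim$records))
  gone <- degrade_records(sim$records, sensitivity = 0, seed = 1)
  expect_true(all(classify_couples(gone)$category == "NO_IPV"))
})

test_that("degraded records stay schema-valid and never invent impacts", {
  sim <- generate_couples(generator_config(n_couples = 300, p_one_missing = 0,
                                           p_both_missing = 0), seed = 3)
  deg <- degrade_records(sim$records, sensitivity = 0.6, specificity = 0.98,
                         seed = 4)
  expect_equal(nrow(validate_fm(deg)), 0L)
  # impacts only degraded off: every surviving impact token existed before
  inj_cols <- grep("^inj_", names(deg), value = TRUE)
  for (cl in inj_cols) {
    before <- strsplit(sim$records[[cl]], ";", fixed = TRUE)
    after <- strsplit(deg[[cl]], ";", fixed = TRUE)
    expect_true(all(mapply(function(a, b) all(a %in% b), after, before)))
  }
})

test_that("under-reporting biases prevalence down and the union rule recovers part of it", {
  cfg <- generator_config(n_couples = 3000, p_one_missing = 0,
                          p_both_missing = 0)
  sim <- generate_couples(cfg, seed = 8)
  deg <- degrade_records(sim$records, sensitivity = 0.7, seed = 9)
  true_pos <- mean(sim$truth$category != "NO_IPV")
  union_pos <- mean(classify_couples(deg)$category != "NO_IPV")
  # single-informant prevalence: blank the partner's report everywhere
  solo <- deg
  solo$missing[solo$role == "partner"] <- 1L
  solo <- as_fm_records(solo, drop_non_ipv_other = FALSE)
  solo_pos <- mean(classify_couples(solo)$category != "NO_IPV")
  expect_lt(union_pos, true_pos)       # under-reporting biases downward
  expect_gt(union_pos, solo_pos)       # two informants beat one
})
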