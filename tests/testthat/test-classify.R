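test_that("couple-level occurrence is the union with the maximum frequency", {
  # concordant reports count once at the couple level
  rec <- report_act(new_couples("a"), "a", "partner_to_woman",
                    "pushed_shoved", "three_to_five", by = "both")
  acts <- couple_acts(rec)
  expect_equal(nrow(acts), 1L)
  expect_equal(as.character(acts$frequency), "three_to_five")

  # union with an empty set: perpetrator-only report, victim missing
  rec2 <- report_act(new_couples("b"), "b", "woman_to_partner", "slapped",
                     "once", by = "perp")
  rec2 <- mark_missing(rec2, "b", "partner")
  acts2 <- couple_acts(rec2)
  expect_equal(acts2$act_id, "slapped")
  expect_equal(as.character(acts2$frequency), "once")

  # discordant frequencies resolve to the maximum
  rec3 <- report_act(new_couples("c"), "c", "woman_to_partner", "grabbed",
                     "twice", by = "vict")
  rec3 <- report_act(rec3, "c", "woman_to_partner", "grabbed", "six_plus",
                     by = "perp")
  expect_equal(as.character(couple_acts(rec3)$frequency), "six_plus")
})

test_that("physical severity applies the three clinical-significance clauses", {
  base <- report_act(new_couples("a"), "a", "partner_to_woman",
                     "pushed_shoved", "once")
  sev <- function(r) {
    s <- physical_severity(r)
    as.character(s$severity[s$direction == "partner_to_woman"])
  }
  expect_equal(sev(base), "LI")   # acts without impact stay low-impact

  withinj <- report_injury(base, "a", "partner_to_woman", "pushed_shoved",
                           "bruise_or_welt", "victim")
  expect_equal(sev(withinj), "CS")

  choke <- report_act(new_couples("a"), "a", "partner_to_woman", "choked",
                      "once")
  expect_equal(sev(choke), "CS")  # inherently dangerous act, no follow-up

  # fear for own safety only counts from the victim's report
  fear_vic <- report_injury(base, "a", "partner_to_woman", "pushed_shoved",
                            "feared_for_own_safety", "victim")
  expect_equal(sev(fear_vic), "CS")
  fear_perp <- report_injury(base, "a", "partner_to_woman", "pushed_shoved",
                             "feared_for_own_safety", "perpetrator")
  expect_equal(sev(fear_perp), "LI")

  # non-fear injury counts from either informant (union rule)
  inj_perp <- report_injury(base, "a", "partner_to_woman", "pushed_shoved",
                            "graze_or_wound", "perpetrator")
  expect_equal(sev(inj_perp), "CS")
})

test_that("the dangerous-act set is configurable", {
  kick <- report_act(new_couples("k"), "k", "woman_to_partner", "kicked",
                     "once")
  default_cls <- classify_couples(kick)
  expect_equal(as.character(default_cls$category), "LI_PHY_ONLY")
  custom <- fm_physical_acts(dangerous = c("choked", "hit_with_object",
                                           "kicked"))
  cls <- classify_couples(kick, physical = custom)
  expect_equal(as.character(cls$category), "CS_PHY_ONLY")
})

test_that("psychological CS needs an act plus an impact clause, victim-report only", {
  cs <- report_psych(new_couples("a"), "a", "pregnant_woman",
                     c(insulted = "twice"), screener = "stress", attrib = 1L)
  expect_true(psych_cs(cs)$psy_cs[cs$role == "pregnant_woman"])

  no_impact <- report_psych(new_couples("b"), "b", "pregnant_woman",
                            c(insulted = "twice"))
  expect_false(any(psych_cs(no_impact)$psy_cs))

  no_act <- set_cell(new_couples("c"), "c", "pregnant_woman", "psy_screen",
                     "depression")
  expect_false(any(psych_cs(no_act)$psy_cs))

  safety_only <- report_psych(new_couples("d"), "d", "partner",
                              c(stalked = "once"),
                              safety = "fear_harm_close_others")
  expect_true(psych_cs(safety_only)$psy_cs[safety_only$role == "partner"])

  interfere_only <- report_psych(new_couples("e"), "e", "partner",
                                 c(grilled = "six_plus"),
                                 interfere = "work;family_friends")
  expect_true(psych_cs(interfere_only)$psy_cs[interfere_only$role == "partner"])
})

test_that("couple categories follow the six mutually exclusive definitions", {
  li <- report_act(new_couples("a"), "a", "woman_to_partner", "grabbed", "once")
  expect_equal(as.character(classify_one(li)$category), "LI_PHY_ONLY")

  none <- new_couples("b")
  expect_equal(as.character(classify_one(none)$category), "NO_IPV")

  both <- report_act(new_couples("c"), "c", "partner_to_woman",
                     "pushed_shoved", "once")
  both <- report_injury(both, "c", "partner_to_woman", "pushed_shoved",
                        "bruise_or_welt", "victim")
  both <- report_psych(both, "c", "partner", c(put_down = "once"),
                       screener = "fear", attrib = 1L)
  cls <- classify_one(both)
  expect_equal(as.character(cls$category), "CS_PSY_AND_CS_PHY")
  expect_equal(as.character(cls$direction_phy_cs), "PARTNER_TO_WOMAN")
  expect_equal(as.character(cls$direction_psy), "WOMAN_TO_PARTNER")
})

test_that("direction labels are victim-consistent and bidirectional when both sides occur", {
  rec <- report_act(new_couples("a"), "a", "woman_to_partner", "slapped", "once")
  rec <- report_act(rec, "a", "partner_to_woman", "grabbed", "once")
  cls <- classify_one(rec)
  expect_equal(as.character(cls$direction_phy_li), "BIDIRECTIONAL")

  one_way <- report_act(new_couples("b"), "b", "woman_to_partner", "slapped",
                        "once")
  expect_equal(as.character(classify_one(one_way)$direction_phy_li),
               "WOMAN_TO_PARTNER")
})

test_that("repeated IPV uses minimum counts: more than one act per partner", {
  # one act at once by each partner: up to one act per partner, not repeated
  rec <- report_act(new_couples("a"), "a", "woman_to_partner", "slapped", "once")
  rec <- report_act(rec, "a", "partner_to_woman", "grabbed", "once")
  expect_false(classify_one(rec)$repeated_phy)

  # single act at twice: min_count(twice) = 2 >= 2
  rec2 <- report_act(new_couples("b"), "b", "woman_to_partner", "slapped",
                     "twice")
  expect_true(classify_one(rec2)$repeated_phy)

  # two distinct acts at once by the same perpetrator: 1 + 1 >= 2
  rec3 <- report_act(new_couples("c"), "c", "woman_to_partner", "slapped",
                     "once")
  rec3 <- report_act(rec3, "c", "woman_to_partner", "bitten", "once")
  expect_true(classify_one(rec3)$repeated_phy)

  # exhaustive over single-act frequencies: repeated iff min count >= 2
  for (f in setdiff(fm_frequency_levels(), "never")) {
    r <- report_act(new_couples("d"), "d", "partner_to_woman", "kicked", f)
    expect_equal(classify_one(r)$repeated_phy, fm_min_count(f) >= 2,
                 info = f)
  }

  # repeated flag undefined for couples without the type
  expect_true(is.na(classify_one(new_couples("e"))$repeated_phy))
})

test_that("psychological repetition counts only CS victims' acts", {
  rec <- report_psych(new_couples("a"), "a", "partner",
                      c(insulted = "once", grilled = "once"),
                      screener = "stress", attrib = 1L)
  expect_true(classify_one(rec)$repeated_psy)
  rec2 <- report_psych(new_couples("b"), "b", "partner",
                       c(insulted = "once"), screener = "stress", attrib = 1L)
  expect_false(classify_one(rec2)$repeated_psy)
})

test_that("classification is role-symmetric and deterministic", {
  rec <- report_act(new_couples("a"), "a", "woman_to_partner",
                    "pushed_shoved", "twice")
  rec <- report_injury(rec, "a", "woman_to_partner", "pushed_shoved",
                       "graze_or_wound", "victim")
  # swap roles: relabel every row's role and swap nothing else
  swapped <- rec
  swapped$role <- ifelse(rec$role == "partner", "pregnant_woman", "partner")
  swapped <- as_fm_records(swapped)
  a <- classify_one(rec)
  b <- classify_one(swapped)
  expect_equal(as.character(a$category), as.character(b$category))
  expect_equal(as.character(a$direction_phy_cs), "WOMAN_TO_PARTNER")
  expect_equal(as.character(b$direction_phy_cs), "PARTNER_TO_WOMAN")
  expect_equal(a$repeated_phy, b$repeated_phy)

  expect_identical(as.data.frame(classify_couples(rec)),
                   as.data.frame(classify_couples(rec)))
})

test_that("couples with no non-missing report are excluded but tracked", {
  rec <- dplyr::bind_rows(
    report_act(new_couples("a"), "a", "woman_to_partner", "slapped", "once"),
    mark_missing(new_couples("gone"), "gone", fm_roles()))
  cls <- classify_couples(rec)
  expect_equal(nrow(cls), 1L)
  expect_equal(attr(cls, "excluded"), "gone")
})

test_that("classifier matches the brute-force oracle on the closed universe", {
  uni <- enumerate_universe()
  cls <- classify_couples(uni$records)
  got <- as.character(cls$category[match(uni$couple_id, cls$couple_id)])
  expect_equal(got, uni$expected)
})
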