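make_cls <- function(categories) {
  tibble::tibble(couple_id = sprintf("c%d", seq_along(categories)),
                 category = factor(categories,
                                   levels = levels(classify_couples(
                                     new_couples("x"))$category)))
}

study_counts <- c(NO_IPV = 1407, LI_PHY_ONLY = 181, CS_PHY_ONLY = 47,
                  CS_PSY_ONLY = 54, CS_PSY_AND_LI_PHY = 23,
                  CS_PSY_AND_CS_PHY = 14)

test_that("prevalence rollups and percentages follow the combination rules", {
  cls <- make_cls(rep(names(study_counts), study_counts))
  prev <- ipv_prevalence(cls)
  g <- function(m, col = "pct") prev[[col]][prev$measure == m]
  expect_equal(g("any_ipv", "n"), 319L)
  expect_equal(g("any_ipv"), 18.5)
  expect_equal(g("any_phy", "n"), 265L)
  expect_equal(g("cs_phy", "n"), 61L)   # 47 + 14
  expect_equal(g("cs_psy", "n"), 91L)   # 54 + 23 + 14
  expect_equal(g("cs_phy_and_cs_psy", "n"), 14L)

  all_none <- ipv_prevalence(make_cls(rep("NO_IPV", 10)))
  expect_equal(all_none$pct[all_none$measure == "any_ipv"], 0)

  # conservation: category counts sum to the denominator
  expect_equal(sum(prev$n[as.character(prev$measure) %in% names(study_counts)]),
               attr(prev, "denominator"))
})

test_that("a denominator mismatch warns and proceeds with the supplied value", {
  cls <- make_cls(c("NO_IPV", "LI_PHY_ONLY"))
  expect_warning(prev <- ipv_prevalence(cls, denominator = 4), "differs")
  expect_equal(prev$pct[prev$measure == "any_ipv"], 25.0)
  expect_error(ipv_prevalence(cls, denominator = 0), "denominator")
})

test_that("percentage rounding is half away from zero to one decimal", {
  expect_equal(round_half_up(c(18.45, 24.545, 11.76, 0.049), 1),
               c(18.5, 24.5, 11.8, 0.0))
  expect_equal(round_half_up(-18.45, 1), -18.5)
})

test_that("masking suppresses small cells and nothing else", {
  expect_equal(mask_count(c(0, 1, 2, 3, 21)), c("-", "<3", "<3", "3", "21"))
  expect_equal(mask_count(4, threshold = 5), "<5")
  expect_error(mask_count(-1))
})

test_that("rate comparison agrees with a hand-computed Pearson chi-squared", {
  # independent oracle: textbook 2x2 statistic from the four cells
  chisq_oracle <- function(a, b, na, nb) {
    tab <- matrix(c(a, na - a, b, nb - b), nrow = 2, byrow = TRUE)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e)
  }
  cases <- list(c(102, 24, 204, 204), c(22, 18, 61, 61), c(7, 3, 50, 60),
                c(1, 9, 20, 20))
  for (cs in cases) {
    got <- compare_rates(cs[1], cs[2], cs[3], cs[4])
    expect_equal(got$statistic, chisq_oracle(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-9)
    expect_equal(got$p_value, stats::pchisq(got$statistic, 1,
                                            lower.tail = FALSE))
  }
  # identical proportions: p = 1, never significant
  eq <- compare_rates(50, 50, 100, 100)
  expect_equal(eq$p_value, 1)
  expect_false(eq$significant)
  # the study's contrasts: low-impact split significant, CS split not
  expect_true(compare_rates(102, 24, 204, 204)$significant)
  expect_false(compare_rates(22, 18, 61, 61)$significant)
  expect_error(compare_rates(5, 5, 0, 10), "positive")
  expect_error(compare_rates(11, 5, 10, 10), "exceed")
})

test_that("direction counts are conserved against the type denominators", {
  fx <- exact_count_records()
  cls <- classify_couples(fx$records)
  prev <- ipv_prevalence(cls)
  for (tp in c("phy_li", "phy_cs", "psy_cs")) {
    dt <- direction_table(cls, fx$records, tp)
    expect_equal(sum(dt$directions$n), dt$n_type)
  }
  dt_cs <- direction_table(cls, fx$records, "phy_cs")
  expect_equal(dt_cs$n_type, prev$n[prev$measure == "cs_phy"])
  dt_psy <- direction_table(cls, fx$records, "psy_cs")
  expect_equal(dt_psy$n_type, prev$n[prev$measure == "cs_psy"])
})

test_that("concordance counts agreement among dual-report couples only", {
  # 3 couples: agree-yes, agree-no, discord (victim silent)
  rec <- dplyr::bind_rows(
    report_act(new_couples("yes"), "yes", "partner_to_woman", "grabbed",
               "once", by = "both"),
    new_couples("no"),
    report_act(new_couples("dis"), "dis", "partner_to_woman", "grabbed",
               "once", by = "perp"))
  cc <- concordance(rec, "partner_to_woman")
  expect_equal(cc$n_dual, 3L)
  expect_equal(cc$agreement, round(100 * 2 / 3, 1))
  both_yes <- cc$table$n[cc$table$woman_report & cc$table$partner_report]
  expect_equal(both_yes, 1L)

  # single-report couples are excluded
  rec2 <- dplyr::bind_rows(rec, mark_missing(
    report_act(new_couples("single"), "single", "partner_to_woman",
               "grabbed", "once", by = "vict"), "single", "partner"))
  expect_equal(concordance(rec2, "partner_to_woman")$n_dual, 3L)

  # arithmetic by definition: 85 both-no, 10 both-yes, 5 discordant -> 95.0
  expect_equal(round_half_up(100 * (85 + 10) / 100, 1), 95.0)
})

test_that("worst-case missingness bounds recompute from counts", {
  expect_equal(missingness_bound(319, 55, 1781), 21.0)
  expect_equal(missingness_bound(27, 0, 110), 24.5)
  # identity when nothing is assumed positive
  expect_equal(missingness_bound(293, 0, 1616), 18.1)
  expect_error(missingness_bound(100, 50, 120), "exceed")
  expect_error(missingness_bound(1, 0, 0), "positive")
})

test_that("rendered reports apply masking but keep unmasked counts internally", {
  fx <- exact_count_records()
  cls <- classify_couples(fx$records)
  dt <- direction_table(cls, fx$records, "phy_cs")
  lines <- render_report(ipv_prevalence(cls), list(dt))
  expect_true(any(grepl("Any IPV", lines)))
  # no act/impact cell may print a raw small count: every 1 or 2 in the
  # underlying table must render masked
  small <- dt$acts$n[dt$acts$n %in% c(1L, 2L)]
  expect_true(all(mask_count(small) == "<3"))
  act_lines <- lines[grepl("^(pushed|grabbed|slapped|choked)", lines)]
  expect_false(any(grepl("\\s[12]\\s", act_lines)))
  # empty inputs give headers only, deterministically
  expect_identical(render_report(), character(0))
  expect_identical(render_report(ipv_prevalence(cls)),
                   render_report(ipv_prevalence(cls)))
})
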