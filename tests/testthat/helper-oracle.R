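# Closed-universe enumeration of small couples plus an independent
# brute-force evaluator of the six couple-category definitions, written
# directly over abstract per-direction features (occurrence, dangerousness,
# injury, victim fear; per-victim psychological act + impact). The
# classifier path (record columns -> union rule -> severity -> category)
# never touches these features, so agreement is a real cross-check.

oracle_severity <- function(has_act, dangerous, injury, victim_fear) {
  if (!has_act) return("NONE")
  if (dangerous || injury || victim_fear) return("CS") else return("LI")
}

oracle_category <- function(f) {
  sev_w2p <- oracle_severity(f$w2p_act, f$w2p_danger, f$w2p_injury, f$w2p_fear)
  sev_p2w <- oracle_severity(f$p2w_act, f$p2w_danger, f$p2w_injury, f$p2w_fear)
  any_phy <- sev_w2p != "NONE" || sev_p2w != "NONE"
  cs_phy <- sev_w2p == "CS" || sev_p2w == "CS"
  cs_psy <- f$psy_cs_woman || f$psy_cs_partner
  # definitions (1)-(6), verbatim and mutually exclusive
  if (!any_phy && !cs_psy) return("NO_IPV")
  if (any_phy && !cs_phy && !cs_psy) return("LI_PHY_ONLY")
  if (cs_phy && !cs_psy) return("CS_PHY_ONLY")
  if (cs_psy && !any_phy) return("CS_PSY_ONLY")
  if (cs_psy && any_phy && !cs_phy) return("CS_PSY_AND_LI_PHY")
  "CS_PSY_AND_CS_PHY"
}

# Enumerate couples over: w2p act in {none, pushed once, pushed twice,
# choked once} x informant mode {both, perp-only, vict-only} x injury
# {none, victim bruise, victim fear, perpetrator-reported bruise}; p2w act
# in {none, pushed once}; partner-victim psych in {none, act-only,
# act+attribution, act+safety}; woman-victim psych in {none, act+attrib}.
# Combinations where the injury reporter does not carry the act are
# skipped (schema-invalid).
enumerate_universe <- function() {
  grid <- expand.grid(
    w2p = c("none", "pushed_once", "pushed_twice", "choked_once"),
    mode = c("both", "perp", "vict"),
    injury = c("none", "vict_bruise", "vict_fear", "perp_bruise"),
    p2w = c("none", "pushed_once"),
    psy_partner = c("none", "act_only", "act_attrib", "act_safety"),
    psy_woman = c("none", "act_attrib"),
    stringsAsFactors = FALSE)
  keep <- !(grid$w2p == "none" & (grid$injury != "none" | grid$mode != "both"))
  keep <- keep & !(grid$injury %in% c("vict_bruise", "vict_fear") & grid$mode == "perp")
  keep <- keep & !(grid$injury == "perp_bruise" & grid$mode == "vict")
  grid <- grid[keep, , drop = FALSE]

  ids <- sprintf("u%03d", seq_len(nrow(grid)))
  rec <- new_couples(ids)
  expected <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    id <- ids[i]
    act <- NULL
    if (g$w2p != "none") {
      act <- if (g$w2p == "choked_once") "choked" else "pushed_shoved"
      freq <- if (g$w2p == "pushed_twice") "twice" else "once"
      rec <- report_act(rec, id, "woman_to_partner", act, freq, by = g$mode)
      if (g$injury == "vict_bruise") {
        rec <- report_injury(rec, id, "woman_to_partner", act,
                             "bruise_or_welt", "victim")
      } else if (g$injury == "vict_fear") {
        rec <- report_injury(rec, id, "woman_to_partner", act,
                             "feared_for_own_safety", "victim")
      } else if (g$injury == "perp_bruise") {
        rec <- report_injury(rec, id, "woman_to_partner", act,
                             "bruise_or_welt", "perpetrator")
      }
    }
    if (g$p2w == "pushed_once") {
      rec <- report_act(rec, id, "partner_to_woman", "pushed_shoved", "once")
    }
    psy_case <- function(victim, case) {
      switch(case,
             none = rec,
             act_only = report_psych(rec, id, victim,
                                     acts = c(insulted = "once")),
             act_attrib = report_psych(rec, id, victim,
                                       acts = c(insulted = "once"),
                                       screener = "stress", attrib = 1L),
             act_safety = report_psych(rec, id, victim,
                                       acts = c(insulted = "once"),
                                       safety = "fear_own_safety"))
    }
    rec <- psy_case("partner", g$psy_partner)
    rec <- psy_case("pregnant_woman", g$psy_woman)

    expected[i] <- oracle_category(list(
      w2p_act = g$w2p != "none",
      w2p_danger = g$w2p == "choked_once",
      w2p_injury = g$injury %in% c("vict_bruise", "perp_bruise"),
      w2p_fear = g$injury == "vict_fear",
      p2w_act = g$p2w == "pushed_once",
      p2w_danger = FALSE, p2w_injury = FALSE, p2w_fear = FALSE,
      psy_cs_partner = g$psy_partner %in% c("act_attrib", "act_safety"),
      psy_cs_woman = g$psy_woman == "act_attrib"))
  }
  list(records = rec, couple_id = ids, expected = expected, grid = grid)
}
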