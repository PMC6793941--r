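# Small record-construction helpers used across tests. All fixtures are
# built in code; nothing is read from disk.

new_couples <- function(ids = "c1") fm_blank_records(ids)

set_cell <- function(rec, id, role, col, value) {
  rec[[col]][rec$couple_id == id & rec$role == role] <- value
  rec
}

# report an act in a one-way direction; `by` picks which informant(s) carry it
report_act <- function(rec, id, direction, act, freq,
                       by = c("both", "perp", "vict")) {
  by <- match.arg(by)
  perp <- if (direction == "woman_to_partner") "pregnant_woman" else "partner"
  vict <- setdiff(c("pregnant_woman", "partner"), perp)
  if (by %in% c("both", "perp")) {
    rec <- set_cell(rec, id, perp, paste0("phy_", act, "_perp"), freq)
  }
  if (by %in% c("both", "vict")) {
    rec <- set_cell(rec, id, vict, paste0("phy_", act, "_vict"), freq)
  }
  rec
}

# attach an injury follow-up; reporter must already carry the act
report_injury <- function(rec, id, direction, act, impacts,
                          reporter = c("victim", "perpetrator")) {
  reporter <- match.arg(reporter)
  perp <- if (direction == "woman_to_partner") "pregnant_woman" else "partner"
  vict <- setdiff(c("pregnant_woman", "partner"), perp)
  role <- if (reporter == "victim") vict else perp
  side <- if (reporter == "victim") "vict" else "perp"
  set_cell(rec, id, role, paste0("inj_", act, "_", side),
           paste(impacts, collapse = ";"))
}

report_psych <- function(rec, id, victim, acts = c(insulted = "twice"),
                         screener = "", attrib = 0L, safety = "",
                         interfere = "") {
  for (a in names(acts)) {
    rec <- set_cell(rec, id, victim, paste0("psy_act_", a), acts[[a]])
  }
  rec <- set_cell(rec, id, victim, "psy_screen", screener)
  rec <- set_cell(rec, id, victim, "psy_safety", safety)
  rec <- set_cell(rec, id, victim, "psy_interfere", interfere)
  rec$psy_attrib[rec$couple_id == id & rec$role == victim] <- as.integer(attrib)
  rec
}

mark_missing <- function(rec, id, roles) {
  rec$missing[rec$couple_id == id & rec$role %in% roles] <- 1L
  as_fm_records(rec, drop_non_ipv_other = FALSE)
}

classify_one <- function(rec) classify_couples(rec)[1, ]
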