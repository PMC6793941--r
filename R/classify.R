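#' Couple-level act occurrence under the two-informant union rule
#'
#' For each couple and direction (perpetrator side), an act occurs at the
#' couple level if either the perpetrator's self-report or the victim's
#' report endorses it; the couple-level frequency is the maximum of the two
#' ordinal categories, so a concordantly reported act counts as one
#' couple-level incident.
#'
#' @param records an `fm_records` tibble (see [as_fm_records()]).
#' @param physical physical act registry.
#' @return tibble with one row per occurring couple x direction x act:
#'   `couple_id`, `direction` (`woman_to_partner` / `partner_to_woman`),
#'   `act_id`, `frequency` (ordered factor), `min_count`.
#' @export
couple_acts <- function(records, physical = fm_physical_acts()) {
  present <- dplyr::filter(records, .data$missing == 0L)
  if (nrow(present) == 0L) {
    return(tibble::tibble(couple_id = character(), direction = character(),
                          act_id = character(),
                          frequency = fm_freq_factor(character()),
                          min_count = integer()))
  }
  phy_cols <- paste0("phy_", rep(physical$act_id, each = 2), "_", c("perp", "vict"))
  long <- present %>%
    dplyr::select("couple_id", "role", dplyr::all_of(phy_cols)) %>%
    tidyr::pivot_longer(dplyr::all_of(phy_cols), names_to = "item",
                        values_to = "frequency") %>%
    dplyr::filter(.data$frequency != "never")
  long <- long %>%
    dplyr::mutate(
      informant_side = stringr::str_extract(.data$item, "(perp|vict)$"),
      act_id = stringr::str_remove(stringr::str_remove(.data$item, "^phy_"),
                                   "_(perp|vict)$"),
      # direction is named by the perpetrator
      direction = dplyr::if_else(
        (.data$role == "pregnant_woman") == (.data$informant_side == "perp"),
        "woman_to_partner", "partner_to_woman"))
  long %>%
    dplyr::mutate(frequency = fm_freq_factor(.data$frequency)) %>%
    dplyr::group_by(.data$couple_id, .data$direction, .data$act_id) %>%
    dplyr::summarise(
      frequency = fm_freq_factor(
        fm_frequency_levels()[max(c(1L, as.integer(.data$frequency)))]),
      .groups = "drop") %>%
    dplyr::mutate(min_count = fm_min_count(as.character(.data$frequency)))
}

#' Couple-level injury impacts by direction
#'
#' Collects injury follow-ups from both informants, tagged with whether the
#' reporter is the victim of that direction (the fear-for-own-safety clause
#' of the clinical-significance rule only accepts the victim's own report).
#'
#' @inheritParams couple_acts
#' @return tibble: `couple_id`, `direction`, `act_id`, `impact`,
#'   `reporter_role`, `reporter_is_victim`.
#' @export
couple_injuries <- function(records, physical = fm_physical_acts()) {
  present <- dplyr::filter(records, .data$missing == 0L)
  inj_cols <- paste0("inj_", rep(physical$act_id, each = 2), "_", c("perp", "vict"))
  empty <- tibble::tibble(couple_id = character(), direction = character(),
                          act_id = character(), impact = character(),
                          reporter_role = character(),
                          reporter_is_victim = logical())
  if (nrow(present) == 0L) return(empty)
  long <- present %>%
    dplyr::select("couple_id", "role", dplyr::all_of(inj_cols)) %>%
    tidyr::pivot_longer(dplyr::all_of(inj_cols), names_to = "item",
                        values_to = "impacts") %>%
    dplyr::filter(has_tokens(.data$impacts))
  if (nrow(long) == 0L) return(empty)
  long %>%
    dplyr::mutate(
      informant_side = stringr::str_extract(.data$item, "(perp|vict)$"),
      act_id = stringr::str_remove(stringr::str_remove(.data$item, "^inj_"),
                                   "_(perp|vict)$"),
      direction = dplyr::if_else(
        (.data$role == "pregnant_woman") == (.data$informant_side == "perp"),
        "woman_to_partner", "partner_to_woman"),
      reporter_is_victim = .data$informant_side == "vict",
      impact = split_tokens(.data$impacts)) %>%
    tidyr::unnest_longer("impact") %>%
    dplyr::select("couple_id", "direction", "act_id", "impact",
                  reporter_role = "role", "reporter_is_victim")
}

#' Per-direction physical severity
#'
#' Classifies each direction of each couple as `NONE` (no act occurs under
#' the union rule), `CS` (clinically significant: a qualifying injury impact
#' is reported by either informant, an inherently dangerous act occurs, or
#' the victim reports fearing for their own safety), or `LI` (acts without
#' any clinically significant impact).
#'
#' @inheritParams couple_acts
#' @return tibble: `couple_id`, `direction`, `severity` (factor
#'   NONE < LI < CS), `any_act`, `act_total` (sum of minimum counts, the
#'   repeated-IPV statistic), `dangerous_act`, `injury_impact`,
#'   `victim_fear`. Couples with no non-missing report are absent.
#' @export
physical_severity <- function(records, physical = fm_physical_acts()) {
  reported <- count_reports(records) %>% dplyr::filter(.data$n_reports > 0L)
  grid <- tidyr::expand_grid(couple_id = reported$couple_id,
                             direction = c("woman_to_partner", "partner_to_woman"))
  acts <- couple_acts(records, physical)
  act_sum <- acts %>%
    dplyr::left_join(physical[c("act_id", "inherently_dangerous")], by = "act_id") %>%
    dplyr::group_by(.data$couple_id, .data$direction) %>%
    dplyr::summarise(any_act = TRUE,
                     act_total = sum(.data$min_count),
                     dangerous_act = any(.data$inherently_dangerous),
                     .groups = "drop")

  inj <- couple_injuries(records, physical) %>%
    # an impact only qualifies if its act occurs at the couple level
    dplyr::semi_join(acts, by = c("couple_id", "direction", "act_id")) %>%
    dplyr::group_by(.data$couple_id, .data$direction) %>%
    dplyr::summarise(
      injury_impact = any(.data$impact != "feared_for_own_safety"),
      victim_fear = any(.data$impact == "feared_for_own_safety" &
                          .data$reporter_is_victim),
      .groups = "drop")

  grid %>%
    dplyr::left_join(act_sum, by = c("couple_id", "direction")) %>%
    dplyr::left_join(inj, by = c("couple_id", "direction")) %>%
    tidyr::replace_na(list(any_act = FALSE, act_total = 0L,
                           dangerous_act = FALSE, injury_impact = FALSE,
                           victim_fear = FALSE)) %>%
    dplyr::mutate(severity = factor(
      dplyr::case_when(
        !any_act ~ "NONE",
        injury_impact | dangerous_act | victim_fear ~ "CS",
        TRUE ~ "LI"),
      levels = c("NONE", "LI", "CS"), ordered = TRUE)) %>%
    dplyr::select("couple_id", "direction", "severity", "any_act",
                  "act_total", "dangerous_act", "injury_impact", "victim_fear")
}

#' Per-respondent psychological clinical significance
#'
#' A respondent is a victim of clinically significant psychological IPV iff
#' they endorse at least one psychological act and at least one impact
#' clause holds: (a) endorsed acts are attributed to screened significant
#' depression/stress/fear, (b) fear for own or close others' safety, or
#' (c) fear-driven interference with a major life activity. Based solely on
#' the victim's own report; perpetrator self-reports are never used.
#'
#' @inheritParams couple_acts
#' @param psych psychological act registry.
#' @return tibble: `couple_id`, `role` (the victim), `psy_cs` (logical),
#'   `psy_act_total` (sum of minimum counts over endorsed acts).
#' @export
psych_cs <- function(records, psych = fm_psych_acts()) {
  act_cols <- paste0("psy_act_", psych$act_id)
  if (nrow(records) == 0L) {
    return(tibble::tibble(couple_id = character(), role = character(),
                          psy_cs = logical(), psy_act_total = integer()))
  }
  totals <- row_sum_cols(records, act_cols, fm_min_count)
  n_acts <- row_sum_cols(records, act_cols,
                         function(v) as.integer(v != "never"))
  impact <- (records$psy_attrib == 1L & has_tokens(records$psy_screen)) |
    has_tokens(records$psy_safety) | has_tokens(records$psy_interfere)
  tibble::tibble(
    couple_id = records$couple_id,
    role = records$role,
    psy_cs = records$missing == 0L & n_acts > 0 & impact,
    psy_act_total = as.integer(totals) * (records$missing == 0L))
}

.category_levels <- c("NO_IPV", "LI_PHY_ONLY", "CS_PHY_ONLY", "CS_PSY_ONLY",
                      "CS_PSY_AND_LI_PHY", "CS_PSY_AND_CS_PHY")

.direction_label <- function(w2p, p2w) {
  factor(dplyr::case_when(w2p & p2w ~ "BIDIRECTIONAL",
                          w2p ~ "WOMAN_TO_PARTNER",
                          p2w ~ "PARTNER_TO_WOMAN",
                          TRUE ~ NA_character_),
         levels = c("WOMAN_TO_PARTNER", "PARTNER_TO_WOMAN", "BIDIRECTIONAL"))
}

#' Classify couples into the six-category IPV taxonomy
#'
#' Applies the mutually exclusive couple taxonomy: `NO_IPV`, `LI_PHY_ONLY`
#' (physical acts, no clinically significant impact of any type),
#' `CS_PHY_ONLY`, `CS_PSY_ONLY`, `CS_PSY_AND_LI_PHY`, `CS_PSY_AND_CS_PHY` —
#' each couple lands in the single most severe applicable category. Also
#' derives direction labels per IPV type (bidirectional iff both directions
#' are positive at the relevant severity; one-way labels are named by the
#' perpetrator, so `WOMAN_TO_PARTNER` means the partner is the victim) and
#' repeated-IPV flags (more than one act per partner, via minimum counts of
#' the ordinal frequency categories).
#'
#' Couples with no non-missing report cannot be classified and are dropped;
#' their ids are kept in the `"excluded"` attribute and their count feeds
#' the worst-case missingness bound.
#'
#' @inheritParams couple_acts
#' @inheritParams psych_cs
#' @return an `ipv_classification` tibble, one row per couple with >= 1
#'   report: `couple_id`, `n_reports`, `category`, `phy_w2p`, `phy_p2w`
#'   (per-direction physical severity), `psy_cs_woman`, `psy_cs_partner`
#'   (per-victim psychological CS), `direction_phy_li`, `direction_phy_cs`,
#'   `direction_psy`, `repeated_phy`, `repeated_psy`.
#' @examples
#' rec <- fm_blank_records("c1")
#' rec$phy_pushed_shoved_perp[rec$role == "pregnant_woman"] <- "once"
#' classify_couples(rec)
#' @export
classify_couples <- function(records, physical = fm_physical_acts(),
                             psych = fm_psych_acts()) {
  reports <- count_reports(records)
  excluded <- reports$couple_id[reports$n_reports == 0L]
  reports <- dplyr::filter(reports, .data$n_reports > 0L)

  sev <- physical_severity(records, physical)
  sev_wide <- sev %>%
    tidyr::pivot_wider(id_cols = "couple_id", names_from = "direction",
                       values_from = c("severity", "act_total")) %>%
    dplyr::rename(phy_w2p = "severity_woman_to_partner",
                  phy_p2w = "severity_partner_to_woman",
                  act_total_w2p = "act_total_woman_to_partner",
                  act_total_p2w = "act_total_partner_to_woman")

  psy <- psych_cs(dplyr::semi_join(records, reports, by = "couple_id"), psych)
  psy_wide <- psy %>%
    tidyr::pivot_wider(id_cols = "couple_id", names_from = "role",
                       values_from = c("psy_cs", "psy_act_total")) %>%
    dplyr::rename(psy_cs_woman = "psy_cs_pregnant_woman",
                  psy_cs_partner = "psy_cs_partner",
                  psy_total_woman = "psy_act_total_pregnant_woman",
                  psy_total_partner = "psy_act_total_partner")

  out <- reports %>%
    dplyr::left_join(sev_wide, by = "couple_id") %>%
    dplyr::left_join(psy_wide, by = "couple_id") %>%
    dplyr::mutate(
      any_phy = .data$phy_w2p > "NONE" | .data$phy_p2w > "NONE",
      cs_phy = .data$phy_w2p == "CS" | .data$phy_p2w == "CS",
      cs_psy = .data$psy_cs_woman | .data$psy_cs_partner,
      category = factor(dplyr::case_when(
        !any_phy & !cs_psy ~ "NO_IPV",
        cs_psy & cs_phy ~ "CS_PSY_AND_CS_PHY",
        cs_psy & any_phy ~ "CS_PSY_AND_LI_PHY",
        cs_psy ~ "CS_PSY_ONLY",
        cs_phy ~ "CS_PHY_ONLY",
        TRUE ~ "LI_PHY_ONLY"), levels = .category_levels),
      # LI direction among LI-involving categories; CS among CS categories
      direction_phy_li = dplyr::if_else(
        .data$category %in% c("LI_PHY_ONLY", "CS_PSY_AND_LI_PHY"),
        .direction_label(.data$phy_w2p > "NONE", .data$phy_p2w > "NONE"),
        factor(NA, levels = levels(.direction_label(TRUE, TRUE)))),
      direction_phy_cs = dplyr::if_else(
        .data$cs_phy,
        .direction_label(.data$phy_w2p == "CS", .data$phy_p2w == "CS"),
        factor(NA, levels = levels(.direction_label(TRUE, TRUE)))),
      direction_psy = dplyr::if_else(
        .data$cs_psy,
        # victim flags: woman victim  => partner-to-woman direction
        .direction_label(.data$psy_cs_partner, .data$psy_cs_woman),
        factor(NA, levels = levels(.direction_label(TRUE, TRUE)))),
      repeated_phy = dplyr::if_else(
        .data$any_phy,
        pmax(.data$act_total_w2p, .data$act_total_p2w) >= 2L, NA),
      repeated_psy = dplyr::if_else(
        .data$cs_psy,
        (.data$psy_cs_woman & .data$psy_total_woman >= 2L) |
          (.data$psy_cs_partner & .data$psy_total_partner >= 2L), NA)) %>%
    dplyr::select("couple_id", "n_reports", "category", "phy_w2p", "phy_p2w",
                  "psy_cs_woman", "psy_cs_partner", "direction_phy_li",
                  "direction_phy_cs", "direction_psy", "repeated_phy",
                  "repeated_psy")
  attr(out, "excluded") <- excluded
  class(out) <- c("ipv_classification", class(out))
  out
}

#' @export
print.ipv_classification <- function(x, ...) {
  cat("<ipv_classification> ", nrow(x), " couples classified",
      if (length(attr(x, "excluded")))
        paste0(" (", length(attr(x, "excluded")),
               " excluded: no non-missing report)"),
      "\n", sep = "")
  NextMethod()
}

#' Write couple classifications as CSV
#'
#' @param classifications an `ipv_classification` tibble.
#' @param path output file.
#' @export
write_classification_csv <- function(classifications, path) {
  readr::write_csv(tibble::as_tibble(classifications), path, progress = FALSE)
  invisible(classifications)
}
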