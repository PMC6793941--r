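#' Deterministic exact-count synthetic study fixture
#'
#' Builds, with no randomness, a synthetic cohort whose classification
#' marginals equal the study's printed couple counts: 1781 enrolled
#' couples, 55 with both reports missing, 110 with exactly one report (85
#' partner-missing, 25 woman-missing) of which 27 are IPV-positive;
#' category counts 1407 / 181 / 47 / 54 / 23 / 14 over the 1726 reporting
#' couples; direction splits 102/24/78 (low-impact physical), 22/18/21
#' (CS physical, woman-to-partner / partner-to-woman / bidirectional) and
#' 50/36/5 (CS psychological); 185 of 265 physical couples and 70 of 91
#' CS-psychological couples repeated.
#'
#' Act-level composition is deliberately minimal (physical IPV realized as
#' pushing/shoving, CS impacts as bruises, psychological CS as insults
#' attributed to screened stress): the fixture pins couple-level marginals,
#' not the per-act rows, which are mostly suppressed by masking anyway.
#'
#' @return list with `records`, `truth` (as in [generate_couples()]) and
#'   `n_enrolled` (1781).
#' @export
exact_count_records <- function() {
  n_enrolled <- 1781L
  ids <- sprintf("C%04d", seq_len(n_enrolled))

  blocks <- tibble::tibble(
    category = rep(c("LI_PHY_ONLY", "CS_PHY_ONLY", "CS_PSY_ONLY",
                     "CS_PSY_AND_LI_PHY", "CS_PSY_AND_CS_PHY", "NO_IPV"),
                   c(181L, 47L, 54L, 23L, 14L, 1407L)))
  blocks$couple_id <- ids[seq_len(1726L)]

  dir_seq <- function(labels, counts) rep(labels, counts)
  phy_dir <- rep(NA_character_, 1726L)
  phy_dir[blocks$category == "LI_PHY_ONLY"] <-
    dir_seq(c("WOMAN_TO_PARTNER", "PARTNER_TO_WOMAN", "BIDIRECTIONAL"),
            c(102L, 24L, 55L))
  phy_dir[blocks$category == "CS_PHY_ONLY"] <-
    dir_seq(c("WOMAN_TO_PARTNER", "PARTNER_TO_WOMAN", "BIDIRECTIONAL"),
            c(22L, 18L, 7L))
  phy_dir[blocks$category == "CS_PSY_AND_LI_PHY"] <- "BIDIRECTIONAL"
  phy_dir[blocks$category == "CS_PSY_AND_CS_PHY"] <- "BIDIRECTIONAL"
  psy_dir <- rep(NA_character_, 1726L)
  psy_dir[blocks$category == "CS_PSY_ONLY"] <-
    dir_seq(c("WOMAN_TO_PARTNER", "PARTNER_TO_WOMAN", "BIDIRECTIONAL"),
            c(13L, 36L, 5L))
  psy_dir[blocks$category == "CS_PSY_AND_LI_PHY"] <- "WOMAN_TO_PARTNER"
  psy_dir[blocks$category == "CS_PSY_AND_CS_PHY"] <- "WOMAN_TO_PARTNER"
  blocks$phy_dir <- phy_dir
  blocks$psy_dir <- psy_dir

  phy_couples <- blocks$couple_id[!is.na(blocks$phy_dir)]      # 265 couples
  blocks$repeated_phy <- NA
  blocks$repeated_phy[!is.na(blocks$phy_dir)] <-
    blocks$couple_id[!is.na(blocks$phy_dir)] %in% phy_couples[seq_len(185L)]
  psy_couples <- blocks$couple_id[!is.na(blocks$psy_dir)]      # 91 couples
  blocks$repeated_psy <- NA
  blocks$repeated_psy[!is.na(blocks$psy_dir)] <-
    blocks$couple_id[!is.na(blocks$psy_dir)] %in% psy_couples[seq_len(70L)]

  expand_dirs <- function(tab) {
    tab %>%
      dplyr::mutate(direction = purrr::map(.data$label, function(l) {
        switch(l, WOMAN_TO_PARTNER = "woman_to_partner",
               PARTNER_TO_WOMAN = "partner_to_woman",
               BIDIRECTIONAL = c("woman_to_partner", "partner_to_woman"))
      })) %>%
      tidyr::unnest_longer("direction")
  }
  phy_tab <- expand_dirs(
    blocks %>% dplyr::filter(!is.na(.data$phy_dir)) %>%
      dplyr::select("couple_id", "category", label = "phy_dir",
                    "repeated_phy"))
  # repetition realized on the couple's first direction only, so that
  # bidirectional non-repeated couples stay at one act per partner
  phy_events <- phy_tab %>%
    dplyr::group_by(.data$couple_id) %>%
    dplyr::mutate(frequency = dplyr::if_else(
      .data$repeated_phy & dplyr::row_number() == 1L, "twice", "once")) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(act_id = "pushed_shoved") %>%
    dplyr::select("couple_id", "direction", "act_id", "frequency", "category")
  injury_events <- phy_events %>%
    dplyr::filter(.data$category %in% c("CS_PHY_ONLY", "CS_PSY_AND_CS_PHY")) %>%
    dplyr::mutate(impact = "bruise_or_welt") %>%
    dplyr::select("couple_id", "direction", "act_id", "impact")

  psy_tab <- expand_dirs(
    blocks %>% dplyr::filter(!is.na(.data$psy_dir)) %>%
      dplyr::select("couple_id", label = "psy_dir", "repeated_psy")) %>%
    dplyr::mutate(victim_role = unname(.direction_victim[.data$direction]))
  psy_events <- psy_tab %>%
    dplyr::group_by(.data$couple_id) %>%
    dplyr::mutate(frequency = dplyr::if_else(
      .data$repeated_psy & dplyr::row_number() == 1L, "twice", "once")) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(act_id = "insulted", screener = "stress", attrib = 1L,
                  safety = "", interfere = "") %>%
    dplyr::select("couple_id", "victim_role", "act_id", "frequency",
                  "screener", "attrib", "safety", "interfere")

  # missingness pattern: the 27 positive single-report couples are the first
  # 27 low-impact woman-to-partner couples, reported by the pregnant woman
  single_positive <- blocks$couple_id[blocks$category == "LI_PHY_ONLY" &
                                        blocks$phy_dir == "WOMAN_TO_PARTNER"][1:27]
  no_ipv_ids <- blocks$couple_id[blocks$category == "NO_IPV"]
  partner_missing <- c(single_positive, no_ipv_ids[1:58])       # 85 couples
  woman_missing <- no_ipv_ids[59:83]                            # 25 couples
  both_missing <- ids[1727:1781]                                # 55 couples
  missing <- dplyr::bind_rows(
    tibble::tibble(couple_id = partner_missing, role = "partner"),
    tibble::tibble(couple_id = woman_missing, role = "pregnant_woman"),
    tidyr::expand_grid(couple_id = both_missing, role = fm_roles()))

  records <- build_fm_records(
    ids, phy_events[c("couple_id", "direction", "act_id", "frequency")],
    injury_events, psy_events, missing = missing)

  truth <- tibble::tibble(couple_id = ids) %>%
    dplyr::left_join(
      blocks %>%
        dplyr::transmute(
          .data$couple_id,
          category = factor(.data$category, levels = .category_levels),
          direction_phy_li = ifelse(
            .data$category %in% c("LI_PHY_ONLY", "CS_PSY_AND_LI_PHY"),
            .data$phy_dir, NA_character_),
          direction_phy_cs = ifelse(
            .data$category %in% c("CS_PHY_ONLY", "CS_PSY_AND_CS_PHY"),
            .data$phy_dir, NA_character_),
          direction_psy = .data$psy_dir,
          repeated_phy = .data$repeated_phy,
          repeated_psy = .data$repeated_psy),
      by = "couple_id")
  list(records = records, truth = truth, n_enrolled = n_enrolled)
}
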