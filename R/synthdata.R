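# Shared builder: realize event tables as wide respondent records ---------

# phy_events: couple_id, direction, act_id, frequency (label)
# injury_events: couple_id, direction, act_id, impact (recorded on the
#   victim's row: impacts are the victim's experience)
# psy_events: couple_id, victim_role, act_id, frequency, screener, attrib,
#   safety, interfere
# missing: couple_id, role of rows to blank
build_fm_records <- function(couple_ids, phy_events = NULL,
                             injury_events = NULL, psy_events = NULL,
                             missing = NULL, physical = fm_physical_acts(),
                             psych = fm_psych_acts()) {
  rec <- fm_blank_records(couple_ids, physical, psych)
  key <- paste(rec$couple_id, rec$role)
  assign_cells <- function(row_key, col, value) {
    idx <- match(row_key, key)
    stopifnot(!anyNA(idx))
    for (cl in unique(col)) {
      sel <- col == cl
      rec[[cl]][idx[sel]] <<- value[sel]
    }
  }
  if (!is.null(phy_events) && nrow(phy_events)) {
    perp <- .direction_perpetrator[phy_events$direction]
    vict <- .direction_victim[phy_events$direction]
    assign_cells(paste(phy_events$couple_id, perp),
                 paste0("phy_", phy_events$act_id, "_perp"),
                 phy_events$frequency)
    assign_cells(paste(phy_events$couple_id, vict),
                 paste0("phy_", phy_events$act_id, "_vict"),
                 phy_events$frequency)
  }
  if (!is.null(injury_events) && nrow(injury_events)) {
    joined <- injury_events %>%
      dplyr::group_by(.data$couple_id, .data$direction, .data$act_id) %>%
      dplyr::summarise(impacts = paste(unique(.data$impact), collapse = ";"),
                       .groups = "drop")
    assign_cells(paste(joined$couple_id, .direction_victim[joined$direction]),
                 paste0("inj_", joined$act_id, "_vict"), joined$impacts)
  }
  if (!is.null(psy_events) && nrow(psy_events)) {
    assign_cells(paste(psy_events$couple_id, psy_events$victim_role),
                 paste0("psy_act_", psy_events$act_id), psy_events$frequency)
    per_victim <- psy_events %>%
      dplyr::distinct(.data$couple_id, .data$victim_role, .data$screener,
                      .data$attrib, .data$safety, .data$interfere)
    vkey <- paste(per_victim$couple_id, per_victim$victim_role)
    idx <- match(vkey, key)
    rec$psy_screen[idx] <- per_victim$screener
    rec$psy_attrib[idx] <- as.integer(per_victim$attrib)
    rec$psy_safety[idx] <- per_victim$safety
    rec$psy_interfere[idx] <- per_victim$interfere
  }
  if (!is.null(missing) && nrow(missing)) {
    idx <- match(paste(missing$couple_id, missing$role), key)
    rec$missing[idx] <- 1L
    rec <- as_fm_records(rec, physical, psych, drop_non_ipv_other = FALSE)
  }
  rec
}

#' Configuration for the synthetic dyad generator
#'
#' Defaults emulate the study conditions the pipeline targets: 1781
#' enrolled couples; latent six-category mixture at the observed category
#' frequencies over the 1726 reporting couples; direction mixtures per IPV
#' type at the observed splits; one realized act per positive direction
#' with frequency uniform over the non-never categories; injury impact and
#' psychological screener distributions weighted like the observed impact
#' rows; perfect reporters (sensitivity = specificity = 1) unless degraded;
#' missingness rates of 55/1781 (both reports) and 110/1781 (one report,
#' 85:25 partner-missing to woman-missing).
#'
#' @param n_couples number of couples to generate.
#' @param category_probs named 6-vector of latent category probabilities
#'   (names = the taxonomy labels), summing to 1.
#' @param direction_probs list with elements `phy_li`, `phy_cs`, `psy`,
#'   each a named 3-vector over `WOMAN_TO_PARTNER`, `PARTNER_TO_WOMAN`,
#'   `BIDIRECTIONAL`, summing to 1.
#' @param act_probs list with named probability vectors `li` (over
#'   non-dangerous physical acts), `cs` (over physical acts) and `psy`
#'   (over psychological acts).
#' @param freq_probs named probability vector over the non-never frequency
#'   categories.
#' @param impact_probs list: `injury` (named vector over injury impacts)
#'   and `screener` (over depression/stress/fear).
#' @param reporter_sensitivity,reporter_specificity named per-role
#'   probabilities (`pregnant_woman`, `partner`) that a reporter reports a
#'   true item / stays silent on a false one.
#' @param p_one_missing,p_both_missing probabilities that exactly one /
#'   both reports are missing.
#' @param p_partner_missing_given_one given one report is missing, the
#'   probability it is the partner's.
#' @param seed default seed used by [generate_couples()].
#' @return an `ipv_generator_config` list.
#' @export
generator_config <- function(
    n_couples = 1781,
    category_probs = c(NO_IPV = 1407, LI_PHY_ONLY = 181, CS_PHY_ONLY = 47,
                       CS_PSY_ONLY = 54, CS_PSY_AND_LI_PHY = 23,
                       CS_PSY_AND_CS_PHY = 14) / 1726,
    direction_probs = list(
      phy_li = c(WOMAN_TO_PARTNER = 102, PARTNER_TO_WOMAN = 24,
                 BIDIRECTIONAL = 78) / 204,
      phy_cs = c(WOMAN_TO_PARTNER = 22, PARTNER_TO_WOMAN = 18,
                 BIDIRECTIONAL = 21) / 61,
      psy = c(WOMAN_TO_PARTNER = 50, PARTNER_TO_WOMAN = 36,
              BIDIRECTIONAL = 5) / 91),
    act_probs = NULL,
    freq_probs = c(once = 0.25, twice = 0.25, three_to_five = 0.25,
                   six_plus = 0.25),
    impact_probs = list(
      injury = c(bruise_or_welt = 0.40, graze_or_wound = 0.25,
                 pain_at_least_4h = 0.20, feared_for_own_safety = 0.10,
                 sprain_or_fracture = 0.03, fainted = 0.02),
      screener = c(depression = 0.45, stress = 0.40, fear = 0.15)),
    reporter_sensitivity = c(pregnant_woman = 1, partner = 1),
    reporter_specificity = c(pregnant_woman = 1, partner = 1),
    p_one_missing = 110 / 1781, p_both_missing = 55 / 1781,
    p_partner_missing_given_one = 85 / 110,
    seed = 1L) {
  physical <- fm_physical_acts()
  if (is.null(act_probs)) {
    li_acts <- setdiff(physical$act_id[!physical$inherently_dangerous], "other")
    cs_acts <- setdiff(physical$act_id, "other")
    psy_acts <- fm_psych_acts()$act_id
    act_probs <- list(
      li = stats::setNames(rep(1 / length(li_acts), length(li_acts)), li_acts),
      cs = stats::setNames(rep(1 / length(cs_acts), length(cs_acts)), cs_acts),
      psy = stats::setNames(rep(1 / length(psy_acts), length(psy_acts)), psy_acts))
  }
  cfg <- list(n_couples = n_couples, category_probs = category_probs,
              direction_probs = direction_probs, act_probs = act_probs,
              freq_probs = freq_probs, impact_probs = impact_probs,
              reporter_sensitivity = reporter_sensitivity,
              reporter_specificity = reporter_specificity,
              p_one_missing = p_one_missing, p_both_missing = p_both_missing,
              p_partner_missing_given_one = p_partner_missing_given_one,
              seed = seed)
  validate_generator_config(cfg)
  structure(cfg, class = "ipv_generator_config")
}

validate_generator_config <- function(cfg) {
  check_probs <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop(what, " must be a nonnegative vector summing to 1", call. = FALSE)
    }
  }
  if (cfg$n_couples < 1) stop("n_couples must be >= 1", call. = FALSE)
  if (!setequal(names(cfg$category_probs), .category_levels)) {
    stop("category_probs must be named by the six category labels",
         call. = FALSE)
  }
  check_probs(cfg$category_probs, "category_probs")
  for (nm in c("phy_li", "phy_cs", "psy")) {
    check_probs(cfg$direction_probs[[nm]], paste0("direction_probs$", nm))
  }
  for (nm in names(cfg$act_probs)) {
    check_probs(cfg$act_probs[[nm]], paste0("act_probs$", nm))
  }
  check_probs(cfg$freq_probs, "freq_probs")
  if (!all(names(cfg$freq_probs) %in% setdiff(fm_frequency_levels(), "never"))) {
    stop("freq_probs must be over the non-never frequency categories",
         call. = FALSE)
  }
  for (nm in names(cfg$impact_probs)) {
    check_probs(cfg$impact_probs[[nm]], paste0("impact_probs$", nm))
  }
  rates <- c(cfg$reporter_sensitivity, cfg$reporter_specificity,
             cfg$p_one_missing, cfg$p_both_missing,
             cfg$p_partner_missing_given_one)
  if (any(rates < 0 | rates > 1)) {
    stop("sensitivities, specificities and missingness rates must lie in [0, 1]",
         call. = FALSE)
  }
  if (cfg$p_one_missing + cfg$p_both_missing > 1) {
    stop("missingness probabilities exceed 1", call. = FALSE)
  }
  invisible(cfg)
}

sample_from <- function(n, probs) {
  if (n == 0L) return(character(0))
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Generate synthetic couples with known latent truth
#'
#' Draws each couple's latent IPV category, then its direction per positive
#' type, realizes acts, frequencies and clinically significant impacts
#' consistent with the category (so a noiseless run classifies every couple
#' back into its latent category), renders both informants' reports,
#' degrades them through the per-reporter sensitivity/specificity model,
#' and finally applies missingness. Fully reproducible given the seed.
#'
#' @param config an [generator_config()] object.
#' @param seed overrides `config$seed`.
#' @return list with `records` (an `fm_records` tibble) and `truth` (one
#'   row per couple: `couple_id`, `category`, `direction_phy_li`,
#'   `direction_phy_cs`, `direction_psy`, `repeated_phy`, `repeated_psy`).
#' @examples
#' sim <- generate_couples(generator_config(n_couples = 50), seed = 7)
#' classify_couples(sim$records)
#' @export
generate_couples <- function(config = generator_config(), seed = NULL) {
  validate_generator_config(config)
  set.seed(seed %||% config$seed)
  n <- config$n_couples
  ids <- sprintf("C%05d", seq_len(n))
  category <- sample_from(n, config$category_probs)

  li_cat <- category %in% c("LI_PHY_ONLY", "CS_PSY_AND_LI_PHY")
  cs_cat <- category %in% c("CS_PHY_ONLY", "CS_PSY_AND_CS_PHY")
  psy_cat <- category %in% c("CS_PSY_ONLY", "CS_PSY_AND_LI_PHY",
                             "CS_PSY_AND_CS_PHY")
  dir_phy <- rep(NA_character_, n)
  dir_phy[li_cat] <- sample_from(sum(li_cat), config$direction_probs$phy_li)
  dir_phy[cs_cat] <- sample_from(sum(cs_cat), config$direction_probs$phy_cs)
  dir_psy <- rep(NA_character_, n)
  dir_psy[psy_cat] <- sample_from(sum(psy_cat), config$direction_probs$psy)

  one_way_dirs <- function(label) {
    switch(label,
           WOMAN_TO_PARTNER = "woman_to_partner",
           PARTNER_TO_WOMAN = "partner_to_woman",
           BIDIRECTIONAL = c("woman_to_partner", "partner_to_woman"))
  }
  phy_dirs <- tibble::tibble(couple_id = ids, label = dir_phy,
                             severity = dplyr::if_else(cs_cat, "cs", "li")) %>%
    dplyr::filter(!is.na(.data$label)) %>%
    dplyr::mutate(direction = purrr::map(.data$label, one_way_dirs)) %>%
    tidyr::unnest_longer("direction")

  phy_events <- phy_dirs %>%
    dplyr::mutate(
      act_id = dplyr::if_else(
        .data$severity == "cs",
        sample_from(dplyr::n(), config$act_probs$cs),
        sample_from(dplyr::n(), config$act_probs$li)),
      frequency = sample_from(dplyr::n(), config$freq_probs))
  injury_events <- phy_events %>%
    dplyr::filter(.data$severity == "cs") %>%
    dplyr::mutate(impact = sample_from(dplyr::n(), config$impact_probs$injury)) %>%
    dplyr::select("couple_id", "direction", "act_id", "impact")

  psy_victims <- tibble::tibble(couple_id = ids, label = dir_psy) %>%
    dplyr::filter(!is.na(.data$label)) %>%
    dplyr::mutate(direction = purrr::map(.data$label, one_way_dirs)) %>%
    tidyr::unnest_longer("direction") %>%
    dplyr::mutate(victim_role = unname(.direction_victim[.data$direction]))
  psy_events <- psy_victims %>%
    dplyr::mutate(act_id = sample_from(dplyr::n(), config$act_probs$psy),
                  frequency = sample_from(dplyr::n(), config$freq_probs),
                  screener = sample_from(dplyr::n(), config$impact_probs$screener),
                  attrib = 1L, safety = "", interfere = "")

  # missingness
  u <- stats::runif(n)
  both_missing <- u < config$p_both_missing
  one_missing <- !both_missing &
    u < config$p_both_missing + config$p_one_missing
  which_partner <- stats::runif(n) < config$p_partner_missing_given_one
  missing <- dplyr::bind_rows(
    tibble::tibble(couple_id = rep(ids[both_missing], each = 2),
                   role = rep(fm_roles(), sum(both_missing))),
    tibble::tibble(couple_id = ids[one_missing],
                   role = dplyr::if_else(which_partner[one_missing],
                                         "partner", "pregnant_woman")))

  records <- build_fm_records(ids, phy_events, injury_events, psy_events,
                              missing = NULL)
  needs_degrade <- any(config$reporter_sensitivity < 1) ||
    any(config$reporter_specificity < 1)
  if (needs_degrade) {
    records <- degrade_records(records, config$reporter_sensitivity,
                               config$reporter_specificity,
                               freq_probs = config$freq_probs)
  }
  if (nrow(missing)) {
    key <- paste(records$couple_id, records$role)
    records$missing[match(paste(missing$couple_id, missing$role), key)] <- 1L
    records <- as_fm_records(records, drop_non_ipv_other = FALSE)
  }

  phy_rep <- phy_events %>%
    dplyr::group_by(.data$couple_id, .data$direction) %>%
    dplyr::summarise(total = sum(fm_min_count(.data$frequency)),
                     .groups = "drop") %>%
    dplyr::group_by(.data$couple_id) %>%
    dplyr::summarise(repeated_phy = any(.data$total >= 2L), .groups = "drop")
  psy_rep <- psy_events %>%
    dplyr::group_by(.data$couple_id, .data$victim_role) %>%
    dplyr::summarise(total = sum(fm_min_count(.data$frequency)),
                     .groups = "drop") %>%
    dplyr::group_by(.data$couple_id) %>%
    dplyr::summarise(repeated_psy = any(.data$total >= 2L), .groups = "drop")
  truth <- tibble::tibble(
    couple_id = ids, category = factor(category, levels = .category_levels),
    direction_phy_li = ifelse(li_cat, dir_phy, NA_character_),
    direction_phy_cs = ifelse(cs_cat, dir_phy, NA_character_),
    direction_psy = dir_psy) %>%
    dplyr::left_join(phy_rep, by = "couple_id") %>%
    dplyr::left_join(psy_rep, by = "couple_id")
  list(records = records, truth = truth)
}

#' Degrade records through a reporter misclassification model
#'
#' Models per-informant under- and over-reporting: every true act item
#' (frequency above never) is kept with probability `sensitivity` and
#' otherwise silenced; every never item is flipped on with probability
#' `1 - specificity` (frequency then drawn from `freq_probs`). Impact
#' reports — injury follow-ups, screener, safety-fear, interference tokens
#' and the attribution flag — are only ever degraded off, never invented.
#' Silencing an act clears its injury follow-up, and a respondent left with
#' no psychological acts loses the attribution flag, so degraded records
#' stay schema-valid. Rows flagged missing are untouched.
#'
#' @inheritParams couple_acts
#' @param sensitivity,specificity scalar or per-role named vector in [0,1].
#' @param seed optional seed.
#' @param freq_probs frequency distribution for invented acts.
#' @param psych psychological act registry.
#' @return degraded `fm_records` tibble.
#' @export
degrade_records <- function(records, sensitivity, specificity = 1,
                            seed = NULL, freq_probs = c(
                              once = 0.25, twice = 0.25,
                              three_to_five = 0.25, six_plus = 0.25),
                            physical = fm_physical_acts(),
                            psych = fm_psych_acts()) {
  if (!is.null(seed)) set.seed(seed)
  per_role <- function(p) {
    if (length(p) == 1L && is.null(names(p))) {
      stats::setNames(rep(p, 2), fm_roles())
    } else {
      p[fm_roles()]
    }
  }
  sens <- per_role(sensitivity)
  spec <- per_role(specificity)
  stopifnot(all(sens >= 0 & sens <= 1), all(spec >= 0 & spec <= 1))
  n <- nrow(records)
  row_sens <- unname(sens[records$role])
  row_spec <- unname(spec[records$role])

  freq_cols <- c(paste0("phy_", rep(physical$act_id, each = 2), "_",
                        c("perp", "vict")),
                 paste0("psy_act_", psych$act_id))
  for (cl in freq_cols) {
    v <- records[[cl]]
    active <- records$missing == 0L
    is_true <- active & v != "never"
    drop <- is_true & stats::runif(n) > row_sens
    invent <- active & v == "never" & stats::runif(n) > row_spec
    v[drop] <- "never"
    if (any(invent)) v[invent] <- sample_from(sum(invent), freq_probs)
    records[[cl]] <- v
    if (startsWith(cl, "phy_") && any(drop)) {
      records[[sub("^phy_", "inj_", cl)]][drop] <- ""
    }
  }

  degrade_tokens <- function(x, keep_prob) {
    toks <- split_tokens(x)
    keep <- purrr::map2(toks, keep_prob,
                        function(t, p) t[stats::runif(length(t)) <= p])
    join_tokens(keep)
  }
  inj_cols <- paste0("inj_", rep(physical$act_id, each = 2), "_",
                     c("perp", "vict"))
  for (cl in c(inj_cols, "psy_screen", "psy_safety", "psy_interfere")) {
    nonempty <- has_tokens(records[[cl]])
    if (any(nonempty)) {
      records[[cl]][nonempty] <- degrade_tokens(records[[cl]][nonempty],
                                                row_sens[nonempty])
    }
  }
  flip_attrib <- records$psy_attrib == 1L & stats::runif(n) > row_sens
  records$psy_attrib[flip_attrib] <- 0L
  # keep records valid: attribution requires at least one surviving psych act
  psy_cols <- paste0("psy_act_", psych$act_id)
  no_psy <- !row_any_cols(records, psy_cols, function(v) v != "never")
  records$psy_attrib[no_psy] <- 0L
  records
}
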