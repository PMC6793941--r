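.rollup_levels <- c("any_ipv", "any_phy", "cs_phy", "cs_psy", "cs_phy_and_cs_psy")

#' Couple-level IPV prevalence with overlap rollups
#'
#' Counts couples per taxonomy category over the denominator of couples
#' with at least one report, plus the overlap rollups: `any_ipv` (all five
#' positive categories), `any_phy` (every physically positive category),
#' `cs_phy` (CS-physical alone or with CS-psych), `cs_psy` (all
#' CS-psychological categories) and `cs_phy_and_cs_psy`. Percentages are
#' `100 * n / denominator` rounded half away from zero to one decimal.
#'
#' @param classifications an `ipv_classification` tibble (or any tibble
#'   with a `category` column over the six labels).
#' @param denominator denominator for percentages; defaults to
#'   `nrow(classifications)`. A mismatch warns and proceeds with the
#'   supplied value.
#' @return an `ipv_prevalence` tibble: `measure`, `n`, `pct`.
#' @export
ipv_prevalence <- function(classifications, denominator = NULL) {
  n_couples <- nrow(classifications)
  if (is.null(denominator)) denominator <- n_couples
  if (denominator < 1) stop("denominator must be >= 1", call. = FALSE)
  if (denominator != n_couples) {
    warning("denominator (", denominator, ") differs from number of ",
            "classified couples (", n_couples, "); using the supplied value",
            call. = FALSE)
  }
  cat_n <- table(factor(classifications$category, levels = .category_levels))
  cat_n <- stats::setNames(as.integer(cat_n), names(cat_n))
  roll <- c(
    any_ipv = sum(cat_n) - cat_n[["NO_IPV"]],
    any_phy = cat_n[["LI_PHY_ONLY"]] + cat_n[["CS_PHY_ONLY"]] +
      cat_n[["CS_PSY_AND_LI_PHY"]] + cat_n[["CS_PSY_AND_CS_PHY"]],
    cs_phy = cat_n[["CS_PHY_ONLY"]] + cat_n[["CS_PSY_AND_CS_PHY"]],
    cs_psy = cat_n[["CS_PSY_ONLY"]] + cat_n[["CS_PSY_AND_LI_PHY"]] +
      cat_n[["CS_PSY_AND_CS_PHY"]],
    cs_phy_and_cs_psy = cat_n[["CS_PSY_AND_CS_PHY"]])
  out <- tibble::tibble(
    measure = factor(c(names(cat_n), names(roll)),
                     levels = c(.category_levels, .rollup_levels)),
    n = unname(c(cat_n, roll)),
    pct = round_half_up(100 * .data$n / denominator, 1))
  attr(out, "denominator") <- denominator
  class(out) <- c("ipv_prevalence", class(out))
  out
}

#' @export
print.ipv_prevalence <- function(x, ...) {
  cat("<ipv_prevalence> denominator =", attr(x, "denominator"), "couples\n")
  NextMethod()
}

#' Mask small cell counts for disclosure control
#'
#' Renders counts for publication: zero prints as `"-"`, counts below the
#' masking threshold print as `"<threshold>"`, everything else as the
#' decimal string. Masking is a pure rendering layer; unmasked counts are
#' kept internally.
#'
#' @param count integer vector of nonnegative counts.
#' @param threshold counts in `1:(threshold - 1)` are suppressed (default 3).
#' @return character vector of rendered cells.
#' @examples
#' mask_count(c(0, 2, 21))
#' @export
mask_count <- function(count, threshold = 3) {
  stopifnot(all(count >= 0), threshold >= 1)
  dplyr::case_when(count == 0 ~ "-",
                   count < threshold ~ paste0("<", threshold),
                   TRUE ~ as.character(count))
}

#' Compare two proportions with a chi-squared test
#'
#' Pearson chi-squared on the 2x2 table of two independent counts over
#' their denominators, without continuity correction by default (a Yates
#' flag is exposed). Used to compare pregnant-woman and partner
#' victimization rates act-by-act and between direction groups.
#'
#' @param count_a,count_b positive counts.
#' @param n_a,n_b denominators.
#' @param yates apply continuity correction.
#' @param alpha two-sided significance level.
#' @return one-row tibble: `statistic`, `df`, `p_value`, `significant`.
#' @export
compare_rates <- function(count_a, count_b, n_a, n_b, yates = FALSE,
                          alpha = 0.05) {
  if (n_a <= 0 || n_b <= 0) stop("denominators must be positive", call. = FALSE)
  if (count_a > n_a || count_b > n_b) {
    stop("counts must not exceed denominators", call. = FALSE)
  }
  tab <- rbind(c(count_a, n_a - count_a), c(count_b, n_b - count_b))
  if (count_a == count_b && n_a == n_b) {
    # chisq.test warns on some degenerate equal tables; the answer is exact
    return(tibble::tibble(statistic = 0, df = 1L, p_value = 1,
                          significant = FALSE))
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  tibble::tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = unname(ht$p.value),
                 significant = unname(ht$p.value) < alpha)
}

#' Direction, act and impact table for one IPV type
#'
#' Builds the couple-level direction split (one-way by victim side, plus
#' bidirectional) for one IPV type — `"phy_li"` (couples whose category is
#' LI-physical-involving), `"phy_cs"` (CS-physical categories) or `"psy_cs"`
#' (CS-psychological categories) — together with per-act and, for CS types,
#' per-impact couple counts by victim side. One count of an act or impact
#' can include reports from either one or two individuals within the same
#' couple (the union rule). Also computes, per act/impact, the chi-squared
#' comparison of pregnant-woman versus partner victimization counts, and
#' the pairwise comparisons between the direction groups.
#'
#' @param classifications an `ipv_classification` tibble.
#' @param records the `fm_records` the classifications came from.
#' @param ipv_type `"phy_li"`, `"phy_cs"` or `"psy_cs"`.
#' @param physical,psych act registries.
#' @param alpha,yates passed to [compare_rates()].
#' @return an `ipv_direction_table` list with tibbles `directions`
#'   (`direction`, `n`, `pct`), `acts` and `impacts` (`item`,
#'   `couple_direction`, `victim`, `n`), `comparisons` (per-item
#'   pregnant-vic vs partner-vic tests), `group_comparisons`, and fields
#'   `ipv_type`, `n_type` (type denominator).
#' @export
direction_table <- function(classifications, records, ipv_type,
                            physical = fm_physical_acts(),
                            psych = fm_psych_acts(),
                            alpha = 0.05, yates = FALSE) {
  ipv_type <- match.arg(ipv_type, c("phy_li", "phy_cs", "psy_cs"))
  dir_col <- switch(ipv_type, phy_li = "direction_phy_li",
                    phy_cs = "direction_phy_cs", psy_cs = "direction_psy")
  cls <- classifications[!is.na(classifications[[dir_col]]), ]
  n_type <- nrow(cls)
  dir_levels <- c("WOMAN_TO_PARTNER", "PARTNER_TO_WOMAN", "BIDIRECTIONAL")
  dirs <- tibble::tibble(
    direction = factor(dir_levels, levels = dir_levels),
    n = as.integer(table(factor(cls[[dir_col]], levels = dir_levels))))
  dirs$pct <- if (n_type > 0) round_half_up(100 * dirs$n / n_type, 1) else NA_real_

  victim_of <- function(direction) {
    dplyr::if_else(direction == "woman_to_partner", "partner", "pregnant_woman")
  }
  sub_records <- dplyr::semi_join(records, cls, by = "couple_id")

  if (ipv_type %in% c("phy_li", "phy_cs")) {
    occ <- couple_acts(sub_records, physical) %>%
      dplyr::transmute(.data$couple_id, item = .data$act_id,
                       victim = victim_of(.data$direction))
    imp <- if (ipv_type == "phy_cs") {
      couple_injuries(sub_records, physical) %>%
        dplyr::filter(.data$impact != "feared_for_own_safety" |
                        .data$reporter_is_victim) %>%
        dplyr::transmute(.data$couple_id, item = .data$impact,
                         victim = victim_of(.data$direction))
    } else {
      tibble::tibble(couple_id = character(), item = character(),
                     victim = character())
    }
    act_levels <- physical$act_id
    impact_levels <- fm_impact_types()
  } else {
    psy <- psych_cs(sub_records, psych)
    victims <- dplyr::filter(psy, .data$psy_cs)
    vic_rec <- dplyr::semi_join(sub_records, victims,
                                by = c("couple_id", "role"))
    act_cols <- paste0("psy_act_", psych$act_id)
    occ <- vic_rec %>%
      dplyr::select("couple_id", "role", dplyr::all_of(act_cols)) %>%
      tidyr::pivot_longer(dplyr::all_of(act_cols), names_to = "item",
                          values_to = "frequency") %>%
      dplyr::filter(.data$frequency != "never") %>%
      dplyr::transmute(.data$couple_id,
                       item = stringr::str_remove(.data$item, "^psy_act_"),
                       victim = .data$role)
    imp <- vic_rec %>%
      dplyr::select("couple_id", victim = "role", "psy_screen",
                    "psy_safety", "psy_interfere") %>%
      tidyr::pivot_longer(c("psy_screen", "psy_safety", "psy_interfere"),
                          values_to = "tokens") %>%
      dplyr::mutate(item = split_tokens(.data$tokens)) %>%
      tidyr::unnest_longer("item") %>%
      dplyr::select("couple_id", "item", "victim")
    act_levels <- psych$act_id
    impact_levels <- c(fm_screener_types(), fm_safety_types(),
                       fm_interference_types())
  }

  tally <- function(events, item_levels) {
    grid <- tidyr::expand_grid(
      item = factor(item_levels, levels = item_levels),
      couple_direction = factor(dir_levels, levels = dir_levels),
      victim = fm_roles()) %>%
      dplyr::filter(!(.data$couple_direction == "WOMAN_TO_PARTNER" &
                        .data$victim == "pregnant_woman"),
                    !(.data$couple_direction == "PARTNER_TO_WOMAN" &
                        .data$victim == "partner"))
    counted <- events %>%
      dplyr::distinct(.data$couple_id, .data$item, .data$victim) %>%
      dplyr::left_join(tibble::tibble(couple_id = cls$couple_id,
                                      couple_direction = cls[[dir_col]]),
                       by = "couple_id") %>%
      dplyr::count(couple_direction = .data$couple_direction,
                   item = factor(.data$item, levels = item_levels),
                   victim = .data$victim)
    grid %>%
      dplyr::left_join(counted, by = c("item", "couple_direction", "victim")) %>%
      tidyr::replace_na(list(n = 0L)) %>%
      dplyr::arrange(.data$item, .data$couple_direction, .data$victim)
  }
  acts_tab <- tally(occ, act_levels)
  impacts_tab <- tally(imp, impact_levels)

  per_item_tests <- function(tab) {
    if (n_type == 0 || nrow(tab) == 0) {
      return(tibble::tibble(item = character(), n_pregnant_vic = integer(),
                            n_partner_vic = integer(), statistic = double(),
                            p_value = double(), significant = logical()))
    }
    tab %>%
      dplyr::group_by(.data$item) %>%
      dplyr::summarise(
        n_pregnant_vic = sum(.data$n[.data$victim == "pregnant_woman"]),
        n_partner_vic = sum(.data$n[.data$victim == "partner"]),
        .groups = "drop") %>%
      dplyr::mutate(purrr::map2_dfr(
        .data$n_pregnant_vic, .data$n_partner_vic,
        function(a, b) compare_rates(a, b, n_type, n_type,
                                     yates = yates, alpha = alpha)[
                                       c("statistic", "p_value", "significant")]))
  }
  comparisons <- dplyr::bind_rows(per_item_tests(acts_tab),
                                  per_item_tests(impacts_tab))

  group_comparisons <- if (n_type > 0) {
    pairs <- utils::combn(dir_levels, 2, simplify = FALSE)
    purrr::map_dfr(pairs, function(p) {
      na <- dirs$n[dirs$direction == p[1]]
      nb <- dirs$n[dirs$direction == p[2]]
      dplyr::bind_cols(tibble::tibble(group_a = p[1], group_b = p[2],
                                      n_a = na, n_b = nb),
                       compare_rates(na, nb, n_type, n_type,
                                     yates = yates, alpha = alpha))
    })
  } else {
    tibble::tibble()
  }

  structure(list(ipv_type = ipv_type, n_type = n_type, directions = dirs,
                 acts = acts_tab, impacts = impacts_tab,
                 comparisons = comparisons,
                 group_comparisons = group_comparisons),
            class = "ipv_direction_table")
}

#' @export
print.ipv_direction_table <- function(x, ...) {
  cat("<ipv_direction_table> type =", x$ipv_type, "| n =", x$n_type,
      "couples\n")
  print(x$directions)
  invisible(x)
}

#' Intradyadic concordance on physical IPV occurrence
#'
#' Among couples with two non-missing reports, cross-tabulates the pregnant
#' woman's and the partner's any-occurrence indicator of physical IPV in
#' one direction (each informant contributes the item of that direction
#' they were asked: the perpetrator their self-report, the victim their
#' victimization report). Percent agreement is the proportion of couples
#' where the informants agree (both report or both deny), to one decimal.
#'
#' @inheritParams couple_acts
#' @param direction `"woman_to_partner"` or `"partner_to_woman"`.
#' @return an `ipv_concordance` list: `direction`, `n_dual` (dual-report
#'   couples), `table` (2x2 tibble over `woman_report` x `partner_report`),
#'   `agreement` (percent, 1 decimal).
#' @export
concordance <- function(records, direction = c("woman_to_partner",
                                               "partner_to_woman"),
                        physical = fm_physical_acts()) {
  direction <- match.arg(direction)
  dual <- count_reports(records) %>% dplyr::filter(.data$n_reports == 2L)
  sub <- dplyr::semi_join(records, dual, by = "couple_id")
  side <- if (direction == "woman_to_partner") {
    c(pregnant_woman = "perp", partner = "vict")
  } else {
    c(pregnant_woman = "vict", partner = "perp")
  }
  indicator <- function(role) {
    rows <- sub[sub$role == role, ]
    cols <- paste0("phy_", physical$act_id, "_", side[[role]])
    tibble::tibble(couple_id = rows$couple_id,
                   reported = row_any_cols(rows, cols,
                                           function(v) v != "never"))
  }
  wide <- dplyr::inner_join(indicator("pregnant_woman"), indicator("partner"),
                            by = "couple_id",
                            suffix = c("_woman", "_partner"))
  tab <- wide %>%
    dplyr::count(woman_report = .data$reported_woman,
                 partner_report = .data$reported_partner) %>%
    tidyr::complete(woman_report = c(FALSE, TRUE),
                    partner_report = c(FALSE, TRUE), fill = list(n = 0L))
  n_dual <- nrow(wide)
  agreement <- if (n_dual > 0) {
    round_half_up(100 * sum(tab$n[tab$woman_report == tab$partner_report]) /
                    n_dual, 1)
  } else {
    NA_real_
  }
  structure(list(direction = direction, n_dual = n_dual, table = tab,
                 agreement = agreement),
            class = "ipv_concordance")
}

#' @export
print.ipv_concordance <- function(x, ...) {
  cat("<ipv_concordance> direction =", x$direction, "| n_dual =", x$n_dual,
      "| agreement =", x$agreement, "%\n")
  print(x$table)
  invisible(x)
}

#' Worst-case prevalence bound under missing reports
#'
#' The prevalence that would obtain if some number of unobserved couples
#' (e.g. those with both reports missing) were all assumed positive:
#' `100 * (n_detected + n_assumed_positive) / denominator`, rounded half
#' away from zero to one decimal. With `n_assumed_positive = 0` this is the
#' unadjusted prevalence over the chosen denominator.
#'
#' @param n_detected couples observed positive.
#' @param n_assumed_positive unobserved couples assumed positive.
#' @param denominator total couples (e.g. all enrolled).
#' @return percentage (numeric scalar, one decimal).
#' @examples
#' missingness_bound(319, 55, 1781)
#' @export
missingness_bound <- function(n_detected, n_assumed_positive, denominator) {
  stopifnot(n_detected >= 0, n_assumed_positive >= 0)
  if (denominator <= 0) stop("denominator must be positive", call. = FALSE)
  if (n_detected + n_assumed_positive > denominator) {
    stop("detected + assumed positives exceed the denominator", call. = FALSE)
  }
  round_half_up(100 * (n_detected + n_assumed_positive) / denominator, 1)
}
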