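#' Ordinal act-frequency scale
#'
#' Past-year act-frequency items are answered on a five-point ordinal scale.
#' `fm_frequency_levels()` returns the labels in increasing order;
#' `fm_min_count()` maps each label to the minimum number of acts it implies
#' (the lower bound of the printed range), the conservative count floor used
#' by the repeated-IPV rule.
#'
#' @return `fm_frequency_levels()`: a character vector of the five ordered
#'   labels. `fm_min_count()`: an integer vector of minimum counts.
#' @examples
#' fm_frequency_levels()
#' fm_min_count(c("never", "three_to_five", "six_plus"))
#' @export
fm_frequency_levels <- function() {
  c("never", "once", "twice", "three_to_five", "six_plus")
}

.fm_min_counts <- c(never = 0L, once = 1L, twice = 2L,
                    three_to_five = 3L, six_plus = 6L)

#' @param frequency character vector of frequency labels.
#' @rdname fm_frequency_levels
#' @export
fm_min_count <- function(frequency) {
  bad <- !frequency %in% names(.fm_min_counts)
  if (any(bad)) {
    stop("unknown frequency categor",
         if (sum(bad) > 1L) "ies: " else "y: ",
         paste(unique(frequency[bad]), collapse = ", "), call. = FALSE)
  }
  unname(.fm_min_counts[frequency])
}

#' Convert frequency labels to an ordered factor
#'
#' @param x character vector of frequency labels (unknown labels error).
#' @return an ordered factor over [fm_frequency_levels()].
#' @keywords internal
fm_freq_factor <- function(x) {
  fm_min_count(x) # validates
  factor(x, levels = fm_frequency_levels(), ordered = TRUE)
}

#' Instrument registries
#'
#' The default physical-act registry holds the 13 acts of the physical
#' section (12 named acts plus a write-in "other"); `dangerous` marks acts of
#' high inherent dangerousness, which qualify an occurrence as clinically
#' significant on their own. The psychological registry holds the 9 named
#' coercive/denigrating acts of the victimization section. Both registries
#' are extensible through `extra` for instrument dialects carrying additional
#' items.
#'
#' @param extra optional tibble of additional rows with the same columns.
#' @param dangerous character vector of `act_id`s treated as inherently
#'   dangerous (physical registry only).
#' @return a tibble with columns `act_id`, `display_name` and, for physical
#'   acts, `inherently_dangerous`.
#' @examples
#' fm_physical_acts()
#' fm_psych_acts()
#' @export
fm_physical_acts <- function(extra = NULL,
                             dangerous = c("choked", "hit_with_object")) {
  reg <- tibble::tribble(
    ~act_id,                ~display_name,
    "pushed_shoved",        "Pushed or shoved",
    "grabbed",              "Grabbed",
    "scratched",            "Scratched",
    "slapped",              "Slapped",
    "thrown_hard_object",   "Thrown hard object",
    "bitten",               "Bitten",
    "hit_punched",          "Hit or punched",
    "slammed_against_wall", "Slammed against a wall",
    "held_down",            "Held down (e.g. twisted arm, hair)",
    "kicked",               "Kicked",
    "choked",               "Choked",
    "hit_with_object",      "Hit with an object that could hurt",
    "other",                "Other"
  )
  if (!is.null(extra)) reg <- dplyr::bind_rows(reg, extra[c("act_id", "display_name")])
  if (anyDuplicated(reg$act_id)) stop("duplicate act_id in physical registry", call. = FALSE)
  unknown <- setdiff(dangerous, reg$act_id)
  if (length(unknown)) stop("dangerous acts not in registry: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  reg$inherently_dangerous <- reg$act_id %in% dangerous
  reg
}

#' @rdname fm_physical_acts
#' @export
fm_psych_acts <- function(extra = NULL) {
  reg <- tibble::tribble(
    ~act_id,             ~display_name,
    "id_withheld",       "Not allowed to have ID, driver's license or passport",
    "put_down",          "Put down or humiliated",
    "kept_from_services","Kept from seeing service providers",
    "stalked",           "Stalked",
    "kept_from_family",  "Not allowed to see/talk to a family member or friend",
    "made_feel_crazy",   "Tried to make me think that I was crazy",
    "insulted",          "Insulted or sworn at",
    "money_withheld",    "Not allowed access to money",
    "grilled",           "Grilled or interrogated"
  )
  if (!is.null(extra)) reg <- dplyr::bind_rows(reg, extra[c("act_id", "display_name")])
  if (anyDuplicated(reg$act_id)) stop("duplicate act_id in psych registry", call. = FALSE)
  reg
}

#' Fixed token sets of the instrument
#'
#' Injury impact kinds (physical follow-ups), psychological screener items,
#' safety-fear items and life-interference domains, and the two respondent
#' roles / three couple-level direction labels.
#'
#' @return character vectors of valid tokens.
#' @export
fm_impact_types <- function() {
  c("feared_for_own_safety", "pain_at_least_4h", "graze_or_wound",
    "bruise_or_welt", "sprain_or_fracture", "fainted")
}

#' @rdname fm_impact_types
#' @export
fm_screener_types <- function() c("depression", "stress", "fear")

#' @rdname fm_impact_types
#' @export
fm_safety_types <- function() c("fear_own_safety", "fear_harm_close_others")

#' @rdname fm_impact_types
#' @export
fm_interference_types <- function() {
  c("work", "education", "religion", "health_services", "family_friends")
}

#' @rdname fm_impact_types
#' @export
fm_roles <- function() c("pregnant_woman", "partner")

#' @rdname fm_impact_types
#' @export
ipv_directions <- function() {
  c("woman_to_partner", "partner_to_woman", "bidirectional")
}

# perpetrator / victim role for a one-way direction
.direction_perpetrator <- c(woman_to_partner = "pregnant_woman",
                            partner_to_woman = "partner")
.direction_victim <- c(woman_to_partner = "partner",
                       partner_to_woman = "pregnant_woman")

#' Column names of the wide respondent schema
#'
#' One row per respondent: `couple_id`, `role`, `missing`, per physical act
#' and informant direction (`perp` = acts the respondent committed, `vict` =
#' acts committed against them) a frequency column `phy_<act>_<dir>` and an
#' injury column `inj_<act>_<dir>` (semicolon-joined impact list), the
#' psychological victimization block (`psy_screen`, `psy_act_<act>`,
#' `psy_attrib`, `psy_safety`, `psy_interfere`) and the human-coded
#' `other_is_ipv` flag. An empty cell means never/none.
#'
#' @param physical,psych act registries (tibbles as returned by
#'   [fm_physical_acts()] / [fm_psych_acts()]).
#' @return character vector of column names in canonical order.
#' @export
fm_schema_columns <- function(physical = fm_physical_acts(),
                              psych = fm_psych_acts()) {
  phy <- as.vector(t(outer(physical$act_id, c("perp", "vict"),
                           function(a, d) paste0("phy_", a, "_", d))))
  inj <- sub("^phy_", "inj_", phy)
  c("couple_id", "role", "missing", phy, inj,
    "psy_screen", paste0("psy_act_", psych$act_id),
    "psy_attrib", "psy_safety", "psy_interfere", "other_is_ipv")
}
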