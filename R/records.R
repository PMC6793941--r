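#' Build an empty respondent-record tibble
#'
#' Creates the wide one-row-per-respondent table in canonical form: every
#' frequency cell `"never"`, every token-list cell empty, `missing` and flag
#' columns integer 0/1. Two rows per couple (one per role), so a couple with
#' no response from a role still carries a `missing = 1` row.
#'
#' @param couple_id vector of couple identifiers (recycled over both roles).
#' @param physical,psych act registries.
#' @return a `fm_records` tibble in the schema of [fm_schema_columns()].
#' @export
fm_blank_records <- function(couple_id, physical = fm_physical_acts(),
                             psych = fm_psych_acts()) {
  couple_id <- as.character(couple_id)
  n <- length(couple_id) * 2L
  cols <- fm_schema_columns(physical, psych)
  out <- tibble::tibble(
    couple_id = rep(couple_id, each = 2L),
    role = rep(fm_roles(), times = n %/% 2L),
    missing = rep(0L, n)
  )
  freq_cols <- grep("^(phy|psy_act)_", cols, value = TRUE)
  list_cols <- c(grep("^inj_", cols, value = TRUE),
                 "psy_screen", "psy_safety", "psy_interfere")
  for (cl in freq_cols) out[[cl]] <- rep("never", n)
  for (cl in list_cols) out[[cl]] <- rep("", n)
  out$psy_attrib <- 0L
  out$other_is_ipv <- 1L
  out <- out[cols]
  class(out) <- c("fm_records", class(out))
  out
}

#' Normalise a raw data frame into canonical respondent records
#'
#' Accepts the CSV schema (empty cell = never/none), fills absent optional
#' columns, coerces flags to integer, maps empty frequency cells to
#' `"never"`, and blanks all content on `missing = 1` rows. With
#' `drop_non_ipv_other = TRUE` (default), write-in "other" acts human-coded
#' as not-IPV (`other_is_ipv = 0`) are removed at load time.
#'
#' @param x data frame in the wide respondent schema.
#' @inheritParams fm_blank_records
#' @param drop_non_ipv_other drop `other` act content where the write-in was
#'   coded as not IPV.
#' @return a canonical `fm_records` tibble.
#' @export
as_fm_records <- function(x, physical = fm_physical_acts(),
                          psych = fm_psych_acts(), drop_non_ipv_other = TRUE) {
  cols <- fm_schema_columns(physical, psych)
  required <- c("couple_id", "role")
  miss_req <- setdiff(required, names(x))
  if (length(miss_req)) {
    stop("records lack required column(s): ", paste(miss_req, collapse = ", "),
         call. = FALSE)
  }
  x <- tibble::as_tibble(x)
  x$couple_id <- as.character(x$couple_id)
  for (cl in setdiff(cols, names(x))) x[[cl]] <- NA
  x <- x[cols]

  as_flag <- function(v) {
    v <- suppressWarnings(as.integer(ifelse(is.na(v) | v == "", 0L, v)))
    ifelse(is.na(v), 0L, v)
  }
  x$missing <- as_flag(x$missing)
  x$psy_attrib <- as_flag(x$psy_attrib)
  x$other_is_ipv <- ifelse(is.na(x$other_is_ipv) | x$other_is_ipv == "",
                           1L, as_flag(x$other_is_ipv))

  freq_cols <- grep("^(phy|psy_act)_", cols, value = TRUE)
  list_cols <- c(grep("^inj_", cols, value = TRUE),
                 "psy_screen", "psy_safety", "psy_interfere")
  for (cl in freq_cols) {
    v <- as.character(x[[cl]])
    x[[cl]] <- ifelse(is.na(v) | v == "", "never", v)
  }
  for (cl in list_cols) {
    v <- as.character(x[[cl]])
    x[[cl]] <- ifelse(is.na(v), "", v)
  }

  # missing rows carry no content
  m <- x$missing == 1L
  if (any(m)) {
    for (cl in freq_cols) x[[cl]][m] <- "never"
    for (cl in list_cols) x[[cl]][m] <- ""
    x$psy_attrib[m] <- 0L
  }

  if (drop_non_ipv_other && "other" %in% physical$act_id) {
    drop <- x$other_is_ipv == 0L
    for (d in c("perp", "vict")) {
      x[[paste0("phy_other_", d)]][drop] <- "never"
      x[[paste0("inj_other_", d)]][drop] <- ""
    }
  }

  # ensure both roles are present for every couple
  have <- paste(x$couple_id, x$role)
  need <- expand.grid(role = fm_roles(), couple_id = unique(x$couple_id),
                      stringsAsFactors = FALSE)
  absent <- need[!paste(need$couple_id, need$role) %in% have, , drop = FALSE]
  if (nrow(absent)) {
    pad <- fm_blank_records(unique(absent$couple_id), physical, psych)
    pad <- pad[paste(pad$couple_id, pad$role) %in%
                 paste(absent$couple_id, absent$role), ]
    pad$missing <- 1L
    x <- dplyr::bind_rows(x, pad)
  }
  x <- dplyr::arrange(x, .data$couple_id, match(.data$role, fm_roles()))
  class(x) <- c("fm_records", setdiff(class(x), "fm_records"))
  x
}

#' Read and write respondent records as CSV
#'
#' The on-disk form follows the documented schema: UTF-8, header row, one
#' row per respondent, empty cells meaning never/none. `read_fm_csv()`
#' normalises through [as_fm_records()]; `write_fm_csv()` writes never/none
#' back as empty cells so files round-trip field-identically.
#'
#' @param path file path.
#' @inheritParams as_fm_records
#' @return `read_fm_csv()`: an `fm_records` tibble. `write_fm_csv()`: the
#'   input, invisibly.
#' @export
read_fm_csv <- function(path, physical = fm_physical_acts(),
                        psych = fm_psych_acts(), drop_non_ipv_other = TRUE) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0L) stop("empty input: ", path, call. = FALSE)
  as_fm_records(raw, physical, psych, drop_non_ipv_other)
}

#' @param records an `fm_records` tibble.
#' @rdname read_fm_csv
#' @export
write_fm_csv <- function(records, path) {
  out <- records
  freq_cols <- grep("^(phy|psy_act)_", names(out), value = TRUE)
  for (cl in freq_cols) out[[cl]] <- ifelse(out[[cl]] == "never", "", out[[cl]])
  readr::write_csv(out, path, progress = FALSE)
  invisible(records)
}

#' Validate respondent records against the instrument invariants
#'
#' Checks structural and content invariants and returns violations as data
#' rather than raising: duplicated couple-role rows, unknown roles or
#' frequency labels, unknown impact/screener/safety/interference tokens,
#' injuries attached to never-frequency acts, an attribution flag without
#' endorsed psychological acts, and content on rows flagged missing.
#'
#' @inheritParams write_fm_csv
#' @inheritParams fm_blank_records
#' @return tibble of violations with columns `couple_id`, `role`, `field`,
#'   `rule`, `message`; zero rows iff the records are valid.
#' @export
validate_fm <- function(records, physical = fm_physical_acts(),
                        psych = fm_psych_acts()) {
  v <- list()
  add <- function(keep, field, rule, message) {
    if (!any(keep)) return()
    v[[length(v) + 1L]] <<- tibble::tibble(
      couple_id = records$couple_id[keep], role = records$role[keep],
      field = field, rule = rule, message = message)
  }

  add(duplicated(paste(records$couple_id, records$role)),
      "role", "unique_role", "more than one row for this couple and role")
  add(!records$role %in% fm_roles(), "role", "role_domain",
      "role must be pregnant_woman or partner")

  freq_levels <- fm_frequency_levels()
  phy_freq <- paste0("phy_", rep(physical$act_id, each = 2), "_", c("perp", "vict"))
  psy_freq <- paste0("psy_act_", psych$act_id)
  for (cl in c(phy_freq, psy_freq)) {
    add(!records[[cl]] %in% freq_levels, cl, "frequency_domain",
        "unknown frequency label")
  }
  for (cl in sub("^phy_", "inj_", phy_freq)) {
    add(!tokens_valid(records[[cl]], fm_impact_types()), cl, "impact_domain",
        "unknown injury impact token")
    freq_cl <- sub("^inj_", "phy_", cl)
    add(has_tokens(records[[cl]]) & records[[freq_cl]] == "never",
        cl, "injury_without_act",
        "injury follow-up attached to an act with frequency never")
  }
  add(!tokens_valid(records$psy_screen, fm_screener_types()),
      "psy_screen", "screener_domain", "unknown screener token")
  add(!tokens_valid(records$psy_safety, fm_safety_types()),
      "psy_safety", "safety_domain", "unknown safety-fear token")
  add(!tokens_valid(records$psy_interfere, fm_interference_types()),
      "psy_interfere", "interference_domain", "unknown interference token")

  n_psy_acts <- row_sum_cols(records, psy_freq,
                             function(v) as.integer(v != "never"))
  add(records$psy_attrib == 1L & n_psy_acts == 0L,
      "psy_attrib", "attribution_without_acts",
      "attribution endorsed but no psychological acts reported")

  content_cols <- c(phy_freq, psy_freq)
  any_content <- row_any_cols(records, content_cols,
                              function(v) v != "never") |
    has_tokens(records$psy_screen) | has_tokens(records$psy_safety) |
    has_tokens(records$psy_interfere) | records$psy_attrib == 1L
  add(records$missing == 1L & any_content,
      "missing", "missing_with_content",
      "row flagged missing but carries responses")

  if (!length(v)) {
    return(tibble::tibble(couple_id = character(), role = character(),
                          field = character(), rule = character(),
                          message = character()))
  }
  dplyr::bind_rows(v)
}

#' Per-couple report counts
#'
#' @inheritParams write_fm_csv
#' @return tibble with `couple_id` and `n_reports` (0, 1 or 2 non-missing
#'   reports).
#' @export
count_reports <- function(records) {
  records %>%
    dplyr::group_by(.data$couple_id) %>%
    dplyr::summarise(n_reports = sum(.data$missing == 0L), .groups = "drop")
}
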