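.measure_titles <- c(
  NO_IPV = "No IPV", any_ipv = "Any IPV",
  LI_PHY_ONLY = "Low impact physical IPV-only",
  CS_PHY_ONLY = "Clinically significant physical IPV-only",
  CS_PSY_ONLY = "Clinically significant psychological IPV-only",
  CS_PSY_AND_LI_PHY = "Clinically significant psychological IPV & Low impact physical IPV",
  CS_PSY_AND_CS_PHY = "Clinically significant psychological IPV & Clinically significant physical IPV",
  any_phy = "Any physical IPV", cs_phy = "Clinically significant physical IPV",
  cs_psy = "Clinically significant psychological IPV",
  cs_phy_and_cs_psy = "Both physical and psychological CS-IPV")

.type_titles <- c(phy_li = "Low impact physical IPV",
                  phy_cs = "Clinically significant physical IPV",
                  psy_cs = "Clinically significant psychological IPV")

#' Render prevalence, direction and concordance results as plain text
#'
#' Deterministic plain-text rendering of the three table families with
#' small-cell masking applied to act/impact cells and a significance column
#' replacing typographic bolding. Unmasked counts stay available in the
#' underlying objects; the rendering is a pure presentation layer.
#'
#' @param prevalence an [ipv_prevalence()] tibble (or NULL).
#' @param direction_tables list of [direction_table()] objects (or NULL).
#' @param concordance_tables list of [concordance()] objects (or NULL).
#' @param mask_threshold passed to [mask_count()].
#' @return character vector of report lines.
#' @export
render_report <- function(prevalence = NULL, direction_tables = NULL,
                          concordance_tables = NULL, mask_threshold = 3) {
  lines <- character(0)
  pad <- function(x, w) formatC(x, width = w, flag = "-")
  if (!is.null(prevalence)) {
    lines <- c(lines, "== Prevalence of past-year IPV by subtype ==",
               sprintf("Denominator: %d couples with at least one report",
                       attr(prevalence, "denominator")))
    lines <- c(lines, sprintf(
      "%s %6d  %5.1f", pad(.measure_titles[as.character(prevalence$measure)], 72),
      prevalence$n, prevalence$pct))
  }
  for (dt in direction_tables %||% list()) {
    lines <- c(lines, "", sprintf("== %s (n = %d couples) ==",
                                  .type_titles[[dt$ipv_type]], dt$n_type))
    lines <- c(lines, sprintf("%s %6d  %5.1f",
                              pad(as.character(dt$directions$direction), 24),
                              dt$directions$n, dt$directions$pct))
    render_items <- function(tab, header) {
      if (nrow(tab) == 0) return(character(0))
      wide <- tab %>%
        dplyr::mutate(cell = mask_count(.data$n, mask_threshold),
                      col = paste(.data$couple_direction, .data$victim,
                                  sep = ":")) %>%
        tidyr::pivot_wider(id_cols = "item", names_from = "col",
                           values_from = "cell")
      sig <- dt$comparisons$significant[match(wide$item, dt$comparisons$item)]
      body <- apply(wide[-1], 1, function(r) paste(formatC(r, width = 8),
                                                   collapse = ""))
      c(paste0("-- ", header, " --"),
        paste(pad("item", 24), paste(formatC(names(wide)[-1], width = 28),
                                     collapse = ""), "signif"),
        sprintf("%s %s  %s", pad(as.character(wide$item), 24), body,
                ifelse(is.na(sig), "", ifelse(sig, "*", ""))))
    }
    lines <- c(lines, render_items(dt$acts, "acts"),
               render_items(dt$impacts, "impacts"))
  }
  for (ct in concordance_tables %||% list()) {
    lines <- c(lines, "", sprintf(
      "== Concordance, %s physical IPV (n = %d dual-report couples) ==",
      ct$direction, ct$n_dual))
    lines <- c(lines, sprintf(
      "woman=%s partner=%s %6d", ct$table$woman_report,
      ct$table$partner_report, ct$table$n),
      sprintf("percent agreement: %.1f", ct$agreement))
  }
  lines
}

#' Run the full analysis pipeline on a records file
#'
#' Reads respondent records, validates them, classifies couples, and writes
#' the classification CSV, prevalence/direction/concordance tables and a
#' plain-text report plus run log to the output directory. Couples with
#' both reports missing are excluded from the analysis denominator but
#' counted and logged; they feed the worst-case missingness bound. The run
#' is deterministic: identical input and configuration give byte-identical
#' outputs.
#'
#' @param input path to a records CSV, or an `fm_records` tibble.
#' @param output_dir directory for output artifacts (created if needed).
#' @param mask_threshold small-cell masking threshold.
#' @param alpha significance level for rate comparisons.
#' @param yates continuity correction flag.
#' @param dangerous_acts physical act ids treated as inherently dangerous.
#' @param strict stop on validation violations (default) rather than log
#'   and continue.
#' @return invisibly, a list with `classifications`, `prevalence`,
#'   `direction_tables`, `concordance_tables`, `missingness`, `violations`.
#' @export
run_ipv_pipeline <- function(input, output_dir = NULL, mask_threshold = 3,
                             alpha = 0.05, yates = FALSE,
                             dangerous_acts = c("choked", "hit_with_object"),
                             strict = TRUE) {
  physical <- fm_physical_acts(dangerous = dangerous_acts)
  records <- if (is.character(input)) read_fm_csv(input, physical) else
    as_fm_records(input, physical)
  violations <- validate_fm(records, physical)
  if (nrow(violations) > 0 && strict) {
    stop("input failed validation (", nrow(violations), " violation",
         if (nrow(violations) > 1) "s", "); first: couple ",
         violations$couple_id[1], ", field ", violations$field[1], ": ",
         violations$message[1], call. = FALSE)
  }

  cls <- classify_couples(records, physical)
  n_excluded <- length(attr(cls, "excluded"))
  n_enrolled <- nrow(cls) + n_excluded
  prev <- ipv_prevalence(cls)
  dts <- lapply(stats::setNames(nm = c("phy_li", "phy_cs", "psy_cs")),
                function(tp) direction_table(cls, records, tp, physical,
                                             alpha = alpha, yates = yates))
  cts <- lapply(stats::setNames(nm = c("woman_to_partner", "partner_to_woman")),
                function(d) concordance(records, d, physical))
  n_any <- prev$n[prev$measure == "any_ipv"]
  missingness <- tibble::tibble(
    n_enrolled = n_enrolled, n_reporting = nrow(cls),
    n_both_missing = n_excluded,
    n_detected_any_ipv = n_any,
    worst_case_both_missing_pct =
      missingness_bound(n_any, n_excluded, n_enrolled))

  result <- list(classifications = cls, prevalence = prev,
                 direction_tables = dts, concordance_tables = cts,
                 missingness = missingness, violations = violations)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(output_dir, f)
    write_classification_csv(cls, out("classification.csv"))
    readr::write_csv(tibble::as_tibble(prev), out("prevalence.csv"),
                     progress = FALSE)
    for (tp in names(dts)) {
      readr::write_csv(dts[[tp]]$directions,
                       out(paste0("direction_", tp, ".csv")), progress = FALSE)
      readr::write_csv(dts[[tp]]$acts, out(paste0("acts_", tp, ".csv")),
                       progress = FALSE)
    }
    readr::write_csv(missingness, out("missingness.csv"), progress = FALSE)
    writeLines(render_report(prev, dts, cts, mask_threshold), out("report.txt"))
    log_lines <- c(
      sprintf("records read: %d rows, %d couples", nrow(records),
              n_enrolled),
      sprintf("validation violations: %d", nrow(violations)),
      sprintf("couples with >= 1 report: %d; excluded (no report): %d",
              nrow(cls), n_excluded),
      sprintf("any IPV detected: %d couples", n_any))
    writeLines(log_lines, out("run.log"))
  }
  invisible(result)
}
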