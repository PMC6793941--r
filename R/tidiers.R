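#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and glance methods for pipeline result objects
#'
#' `tidy()` returns the object's content as a plain tibble (one row per
#' category/direction/cell); `glance()` returns a one-row summary.
#'
#' @param x a result object.
#' @param ... unused.
#' @return a tibble.
#' @name ipvdyad-tidiers
NULL

#' @rdname ipvdyad-tidiers
#' @export
tidy.ipv_prevalence <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "ipv_prevalence")
  out
}

#' @rdname ipvdyad-tidiers
#' @export
glance.ipv_prevalence <- function(x, ...) {
  g <- function(m, col) x[[col]][x$measure == m]
  tibble::tibble(denominator = attr(x, "denominator"),
                 n_any_ipv = g("any_ipv", "n"), any_ipv_pct = g("any_ipv", "pct"),
                 any_phy_pct = g("any_phy", "pct"),
                 cs_phy_pct = g("cs_phy", "pct"),
                 cs_psy_pct = g("cs_psy", "pct"))
}

#' @rdname ipvdyad-tidiers
#' @export
tidy.ipv_direction_table <- function(x, ...) {
  dplyr::mutate(x$directions, ipv_type = x$ipv_type, .before = 1)
}

#' @rdname ipvdyad-tidiers
#' @export
glance.ipv_direction_table <- function(x, ...) {
  one_way <- x$group_comparisons
  ow <- one_way[one_way$group_a == "WOMAN_TO_PARTNER" &
                  one_way$group_b == "PARTNER_TO_WOMAN", ]
  tibble::tibble(ipv_type = x$ipv_type, n_type = x$n_type,
                 one_way_p_value = if (nrow(ow)) ow$p_value else NA_real_,
                 one_way_significant = if (nrow(ow)) ow$significant else NA)
}

#' @rdname ipvdyad-tidiers
#' @export
tidy.ipv_concordance <- function(x, ...) {
  dplyr::mutate(x$table, direction = x$direction, .before = 1)
}

#' @rdname ipvdyad-tidiers
#' @export
glance.ipv_concordance <- function(x, ...) {
  tibble::tibble(direction = x$direction, n_dual = x$n_dual,
                 agreement_pct = x$agreement)
}

#' @rdname ipvdyad-tidiers
#' @export
tidy.ipv_classification <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "ipv_classification")
  out
}

#' @rdname ipvdyad-tidiers
#' @export
glance.ipv_classification <- function(x, ...) {
  tibble::tibble(n_couples = nrow(x),
                 n_excluded = length(attr(x, "excluded")),
                 n_any_ipv = sum(x$category != "NO_IPV"),
                 n_repeated_phy = sum(x$repeated_phy, na.rm = TRUE),
                 n_repeated_psy = sum(x$repeated_psy, na.rm = TRUE))
}
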