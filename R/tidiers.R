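## broom-style tidiers for result objects.

#' Tidy a mutation spectrum
#'
#' @param x a [mutation_spectrum()] object.
#' @param ... unused.
#' @return tibble `class`, `n`, `fraction`.
#' @export
#' @exportS3Method generics::tidy
tidy.mutation_spectrum <- function(x, ...) {
  x$counts
}

#' One-row summary of a mutation spectrum
#'
#' @param x a [mutation_spectrum()] object.
#' @param ... unused.
#' @return tibble with `total` and `fraction_CG_to_TA`.
#' @export
#' @exportS3Method generics::glance
glance.mutation_spectrum <- function(x, ...) {
  tibble(total = x$total, fraction_CG_to_TA = x$fraction_CG_to_TA)
}

#' Tidy a TE cross-tabulation into long format
#'
#' @param x a [crosstab()] object.
#' @param ... unused.
#' @return long tibble: `te_set`, `expressed`, `num`, `superfamily`,
#'   `pct` (percent of all records, rounded half-up to 2 decimals).
#' @export
#' @exportS3Method generics::tidy
tidy.te_crosstab <- function(x, ...) {
  as_tibble(x) |>
    tidyr::pivot_longer(cols = dplyr::any_of(TE_SUPERFAMILIES),
                        names_to = "superfamily", values_to = "pct") |>
    mutate(pct = round_half_up(.data$pct, 2))
}

#' One-row summary of a TE cross-tabulation
#'
#' @param x a [crosstab()] object.
#' @param ... unused.
#' @return tibble with the record total and the expressed/silenced counts.
#' @export
#' @exportS3Method generics::glance
glance.te_crosstab <- function(x, ...) {
  y <- as_tibble(x)
  tot <- y[y$te_set == "Total", ]
  tibble(
    n_records = attr(x, "n_records"),
    n_expressed = tot$num[tot$expressed == "Yes"],
    n_silent = tot$num[tot$expressed == "No"]
  )
}
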