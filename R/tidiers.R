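#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a grid-search report
#'
#' One row per examined threshold with retention counts and the ARI against
#' the most permissive threshold's clustering.
#'
#' @param x A `grid_search_report`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.grid_search_report <- function(x, ...) x$summary

#' Glance at a grid-search report
#'
#' @param x A `grid_search_report`.
#' @param ... Unused.
#' @return A one-row tibble: `selected`, `stability`, `n_removed`.
#' @export
glance.grid_search_report <- function(x, ...) {
  tibble(selected = x$selected, stability = x$stability,
         n_removed = length(x$removed))
}

#' Tidy an in-silico mixture model
#'
#' One row per mixture profile (cluster pair and mixing fraction).
#'
#' @param x A `mixture_model` from [detect_heterotypic()].
#' @param ... Unused.
#' @return A tibble: `mixture`, `fraction`.
#' @export
tidy.mixture_model <- function(x, ...) {
  nm <- colnames(x$mixtures)
  tibble(
    mixture = nm,
    fraction = as.numeric(sub(".*@", "", nm))
  )
}
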