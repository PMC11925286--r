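#' Tidy a scenario result
#'
#' @param x A `vaxcamp_scenario`.
#' @param per_network If `TRUE`, summarise per network (mean epidemic size
#'   over that network's SIR runs, the anti-vaccine count and cluster
#'   diagnostics); otherwise return the pooled replicate table, one row per
#'   SIR run.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy vaxcamp_scenario
#' @export
tidy.vaxcamp_scenario <- function(x, per_network = FALSE, ...) {
  if (!per_network) {
    return(x$replicates)
  }
  x$replicates |>
    dplyr::group_by(.data$network) |>
    dplyr::summarise(
      mean_size = mean(.data$size),
      n_sir_runs = dplyr::n(),
      n_negative = .data$n_negative[1],
      n_components = .data$n_components[1],
      largest_component = .data$largest_component[1],
      opinion_steps = .data$opinion_steps[1],
      .groups = "drop"
    )
}

#' One-row scenario summary
#'
#' @param x A `vaxcamp_scenario`.
#' @param ... Unused.
#' @return A one-row tibble: `mean_size`, `sd_size`, `ci95_halfwidth`,
#'   `n_replicates`, `n_networks`, `mean_n_negative`.
#' @method glance vaxcamp_scenario
#' @export
glance.vaxcamp_scenario <- function(x, ...) {
  x$summary
}

#' Tidy a sweep result
#'
#' @param x A `vaxcamp_sweep`.
#' @param ... Unused.
#' @return The pooled replicate table with a leading `value` column for the
#'   swept axis.
#' @method tidy vaxcamp_sweep
#' @export
tidy.vaxcamp_sweep <- function(x, ...) {
  dplyr::bind_rows(purrr::map2(
    x$values, x$results,
    function(v, r) dplyr::bind_cols(tibble(value = v), r$replicates)
  ))
}

#' One-row-per-point sweep summary
#'
#' @param x A `vaxcamp_sweep`.
#' @param ... Unused.
#' @return The sweep summary tibble (`value` plus scenario summary columns).
#' @method glance vaxcamp_sweep
#' @export
glance.vaxcamp_sweep <- function(x, ...) {
  x$summary
}
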