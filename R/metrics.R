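#' Anti-vaccine cluster statistics
#'
#' Connected components of the subgraph induced by the anti-vaccine agents.
#' These clusters are the only places an epidemic can spread after
#' vaccination, so their number and size distribution -- not just the total
#' anti-vaccine count -- govern the final epidemic size: a campaign that
#' fragments the negative population into small, mutually unreachable groups
#' protects even the unvaccinated.
#'
#' @param net igraph contact network.
#' @param agents Agent tibble with final opinions.
#' @return A list of class `"cluster_stats"`: `sizes` (component sizes,
#'   decreasing), `n_components`, `largest` (0 when no agent is negative).
#' @export
anti_cluster_stats <- function(net, agents) {
  negatives <- as.integer(agents$id[agents$opinion == "negative"])
  comps <- subset_components(net, negatives)
  sizes <- vapply(comps, length, integer(1))
  structure(
    list(
      sizes = sizes,
      n_components = length(comps),
      largest = if (length(sizes)) max(sizes) else 0L
    ),
    class = "cluster_stats"
  )
}

#' @export
print.cluster_stats <- function(x, ...) {
  cat(sprintf(
    "<cluster_stats> %d anti-vaccine agents in %d component(s), largest %d\n",
    sum(x$sizes), x$n_components, x$largest
  ))
  invisible(x)
}

#' Neighbourhood profile of a target set
#'
#' Bins every currently targeted *neutral* agent by its number of
#' anti-vaccine neighbours (`n_minus`) and neutral neighbours (`n_zero`).
#' The profile visualises where a campaign places its positive influence:
#' local-information strategies with low `zeta` and high `Z` concentrate
#' mass at low `n_minus` / high `n_zero`, and vice versa.
#'
#' @param net igraph contact network.
#' @param agents Agent tibble with current opinions.
#' @param targets Integer vector of currently targeted node ids.
#' @return A tibble with columns `n_minus`, `n_zero` and `n_agents` (one row
#'   per occupied profile). The `n_agents` total equals the number of
#'   targeted agents that are still neutral.
#' @export
target_neighborhood_histogram <- function(net, agents, targets) {
  targets <- as.integer(targets)
  neutral_targets <- intersect(targets, agents$id[agents$opinion == "neutral"])
  if (!length(neutral_targets)) {
    return(tibble(n_minus = integer(0), n_zero = integer(0), n_agents = integer(0)))
  }
  counts <- neighborhood_counts(agents, net, nodes = neutral_targets)
  counts |>
    dplyr::count(.data$n_minus, .data$n_zero, name = "n_agents") |>
    dplyr::arrange(.data$n_minus, .data$n_zero)
}

#' Average target-profile histograms over simulations
#'
#' Averages per-run histograms cellwise over the number of simulations.
#' Profiles never observed in any run are absent from the result
#' (distinguishing "no agent ever has this profile" from an average of
#' zero is left to the caller via the full cross of observed cells).
#'
#' @param histograms List of tibbles from [target_neighborhood_histogram()].
#' @return Tibble `n_minus`, `n_zero`, `mean_agents`, `n_sims`.
#' @export
aggregate_histograms <- function(histograms) {
  n_sims <- length(histograms)
  if (!n_sims) abort("no histograms supplied")
  dplyr::bind_rows(histograms) |>
    dplyr::group_by(.data$n_minus, .data$n_zero) |>
    dplyr::summarise(mean_agents = sum(.data$n_agents) / n_sims, .groups = "drop") |>
    dplyr::mutate(n_sims = n_sims) |>
    dplyr::arrange(.data$n_minus, .data$n_zero)
}
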