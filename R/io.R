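#' Read a contact network from a file
#'
#' Supports two formats: whitespace-delimited edge lists (two columns,
#' `#` comments allowed) and GraphML. Arbitrary node labels are relabelled
#' to contiguous 1-based integer ids; the original labels are persisted in
#' the vertex attribute `label` and as a graph attribute `label_mapping`
#' (a tibble `node`, `label`).
#'
#' Self-loops are rejected with an error naming the offending line;
#' duplicate edges are dropped with a warning.
#'
#' @param path File to read.
#' @param format `"edgelist"` or `"graphml"`.
#' @return An igraph graph on nodes `1..N`.
#' @export
read_network <- function(path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("network file not found: %s", path))
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    g <- igraph::as_undirected(g, mode = "collapse")
    labels <- igraph::vertex_attr(g, "name") %||% as.character(seq_len(igraph::vcount(g)))
    igraph::V(g)$label <- labels
    g$label_mapping <- tibble(node = seq_len(igraph::vcount(g)), label = labels)
    return(g)
  }
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (!length(rows)) abort(sprintf("no edges found in %s", path))
  parts <- strsplit(trimws(lines[rows]), "\\s+")
  bad <- which(vapply(parts, length, 1L) != 2L)
  if (length(bad)) {
    abort(sprintf(
      "malformed edge on line %d of %s: expected two whitespace-separated labels",
      rows[bad[1]], path
    ))
  }
  from <- vapply(parts, `[[`, "", 1L)
  to <- vapply(parts, `[[`, "", 2L)
  loops <- which(from == to)
  if (length(loops)) {
    abort(sprintf("self-loop '%s %s' rejected on line %d of %s", from[loops[1]], to[loops[1]], rows[loops[1]], path))
  }
  labels <- unique(c(from, to))
  labels <- if (all(grepl("^\\d+$", labels))) {
    labels[order(as.numeric(labels))]
  } else {
    sort(labels)
  }
  ek <- paste(pmin(from, to), pmax(from, to))
  dup <- duplicated(ek)
  if (any(dup)) {
    warn(sprintf("%d duplicate edge(s) in %s were dropped", sum(dup), path))
    from <- from[!dup]
    to <- to[!dup]
  }
  g <- igraph::graph_from_edgelist(
    cbind(match(from, labels), match(to, labels)),
    directed = FALSE
  )
  g <- igraph::add_vertices(g, max(0L, length(labels) - igraph::vcount(g)))
  igraph::V(g)$label <- labels
  g$label_mapping <- tibble(node = seq_along(labels), label = labels)
  g
}

#' Write a contact network to a file
#'
#' Edge lists are written with a header comment recording the construction
#' parameters (`N`, `k`, `p`) when the graph carries them (see
#' [ws_network()]).
#'
#' @param net igraph graph.
#' @param path Output file.
#' @param format `"edgelist"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    ## graph/vertex attributes that are not GraphML scalars must not leak in
    g <- drop_graph_attrs(net)
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  header <- sprintf(
    "# undirected edge list%s",
    if (!is.null(net$n)) sprintf(" | N=%d k=%d p=%g", net$n, net$k, net$p) else ""
  )
  el <- igraph::as_edgelist(net, names = FALSE)
  writeLines(
    c(header, sprintf("%d %d", el[, 1], el[, 2])),
    path
  )
  invisible(path)
}

drop_graph_attrs <- function(g) {
  for (at in igraph::graph_attr_names(g)) g <- igraph::delete_graph_attr(g, at)
  g
}

#' Export an opinion trajectory as CSV
#'
#' One row per step with columns `step`, `n_negative`, `n_neutral`,
#' `n_positive`.
#'
#' @param run An `opinion_run` from [run_opinion_stage()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_trajectory <- function(run, path) {
  if (is.null(run$trajectory)) {
    abort("this run was executed without trajectory recording")
  }
  utils::write.csv(run$trajectory, path, row.names = FALSE)
  invisible(path)
}

fmt_num <- function(x) {
  ifelse(x == round(x), format(x, scientific = FALSE, trim = TRUE),
    signif(x, 6)
  )
}

#' Write scenario or sweep results to a directory
#'
#' Produces a deterministic set of files: `scenario.csv` (one row per
#' scenario point: the swept value where applicable, mean epidemic size,
#' 95% CI half-width, replication counts), `replicates.csv` (one row per
#' SIR run) and `metadata.json` (the full configuration including seeds).
#' Floating-point columns are written with 6 significant digits; counts and
#' seeds as integers.
#'
#' @param x A `vaxcamp_scenario` or `vaxcamp_sweep`.
#' @param out_dir Output directory, created if needed.
#' @return Character vector of files written (the manifest), invisibly.
#' @export
write_results <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(x, "vaxcamp_scenario")) {
    scen <- dplyr::mutate(x$summary, dplyr::across(dplyr::where(is.double), fmt_num))
    reps <- tidy(x)
    meta <- config_metadata(x$config)
  } else if (inherits(x, "vaxcamp_sweep")) {
    scen <- dplyr::mutate(x$summary, dplyr::across(dplyr::where(is.double), fmt_num))
    reps <- tidy(x)
    meta <- list(
      axis = x$axis, values = x$values,
      base_config = config_metadata(x$results[[1]]$config)
    )
  } else {
    abort("`x` must be a vaxcamp_scenario or vaxcamp_sweep")
  }
  paths <- file.path(out_dir, c("scenario.csv", "replicates.csv", "metadata.json"))
  utils::write.csv(scen, paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(reps, paths[2], row.names = FALSE, quote = FALSE)
  jsonlite::write_json(meta, paths[3], auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(paths)
}

config_metadata <- function(config) {
  diff_meta <- unclass(config$diffusion)
  if (!is.finite(diff_meta$tau)) diff_meta$tau <- "Inf"
  list(
    network = list(N = config$n, k = config$k, p = config$p),
    diffusion = diff_meta,
    campaign = if (is.null(config$campaign)) NULL else unclass(config$campaign),
    sir = unclass(config$sir),
    replication = list(
      n_networks = config$n_networks, n_sir_runs = config$n_sir_runs,
      master_seed = config$master_seed
    ),
    package_version = as.character(utils::packageVersion("vaxcampsim"))
  )
}
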