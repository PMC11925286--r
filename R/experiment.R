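#' Full simulation configuration for one scenario
#'
#' Bundles network, diffusion, campaign and disease parameters with the
#' replication plan: `n_networks` independently generated contact networks,
#' each carrying one opinion-stage realisation whose vaccination outcome is
#' shared by `n_sir_runs` independent SIR runs.
#'
#' @param n,k,p Watts-Strogatz network parameters (see [ws_network()]).
#' @param diffusion A [diffusion_params()] object.
#' @param campaign A [campaign()] or `NULL` for the anti-vaccine-only
#'   benchmark.
#' @param sir A [sir_params()] object.
#' @param n_networks Number of replicate networks per scenario.
#' @param n_sir_runs Number of SIR runs per network.
#' @param master_seed Integer master seed; every random draw of the scenario
#'   derives deterministically from it.
#' @param reps_scale Convenience multiplier applied to both `n_networks` and
#'   `n_sir_runs` (rounded up), for scaling a reference replication plan up
#'   or down.
#' @param require_connected Passed to [ws_network()].
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n = 5000, k = 10, p = 0.01,
                       diffusion = diffusion_params(mu_minus = 0.001, omega_minus = 0.006),
                       campaign = NULL,
                       sir = sir_params(beta = 0.1, gamma = 0.1, i0 = 1),
                       n_networks = 1L, n_sir_runs = 1L, master_seed = 1L,
                       reps_scale = 1, require_connected = FALSE) {
  stopifnot(inherits(diffusion, "diffusion_params"), inherits(sir, "sir_params"))
  if (!is.null(campaign)) {
    stopifnot(inherits(campaign, "vaxcamp_campaign"))
    if (!is.na(campaign$T) && campaign$T > n) {
      abort("campaign target-set size exceeds the population")
    }
  }
  if (n_networks < 1 || n_sir_runs < 1) {
    abort("`n_networks` and `n_sir_runs` must be >= 1")
  }
  if (!is.numeric(master_seed) || length(master_seed) != 1L) {
    abort("`master_seed` must be a single integer")
  }
  structure(
    list(
      n = as.integer(n), k = as.integer(k), p = p,
      diffusion = diffusion, campaign = campaign, sir = sir,
      n_networks = as.integer(ceiling(n_networks * reps_scale)),
      n_sir_runs = as.integer(ceiling(n_sir_runs * reps_scale)),
      master_seed = as.integer(master_seed),
      require_connected = isTRUE(require_connected)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> N=%d WS(k=%d, p=%g); mu-=%g omega-=%g omega+=%g theta=%d tau=%s; %s; beta=%g gamma=%g I0=%d; %d networks x %d SIR runs (seed %d)\n",
    x$n, x$k, x$p, x$diffusion$mu_minus, x$diffusion$omega_minus,
    x$diffusion$omega_plus, x$diffusion$theta,
    if (is.finite(x$diffusion$tau)) format(x$diffusion$tau) else "Inf",
    if (is.null(x$campaign)) "no positive campaign" else x$campaign$strategy,
    x$sir$beta, x$sir$gamma, x$sir$i0, x$n_networks, x$n_sir_runs, x$master_seed
  ))
  invisible(x)
}

## deterministic seed streams: the master seed is consumed once to draw one
## sub-seed per (network) and per (network, SIR run); replicates are then
## mutually independent and reproducible in any evaluation order.
derive_seeds <- function(master_seed, n_networks, n_sir_runs) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(master_seed)
  list(
    network = sample.int(.Machine$integer.max, n_networks),
    sir = matrix(
      sample.int(.Machine$integer.max, n_networks * n_sir_runs),
      nrow = n_networks
    )
  )
}

#' Run a single replicate: one network, one opinion stage, one SIR run
#'
#' Generates a contact network, runs the opinion stage and vaccination, then
#' a single SIR run, returning the full per-replicate diagnostics (opinion
#' trajectory, anti-vaccine cluster statistics, SIR time series).
#'
#' @param config A [sim_config()].
#' @param network_seed Seed for network generation and the opinion stage.
#' @param sir_seed Seed for the SIR run.
#' @return A list of class `"sim_replicate"`: `size`, `opinion` (an
#'   `opinion_run`), `sir` (a `sir_run`), `susceptible`, `clusters` (see
#'   [anti_cluster_stats()]) and `net`.
#' @export
run_replicate <- function(config, network_seed, sir_seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(network_seed)
  net <- ws_network(config$n, config$k, config$p, config$require_connected)
  orun <- run_opinion_stage(net, config$diffusion, config$campaign)
  sus <- vaccinate(orun$agents)
  set.seed(sir_seed)
  srun <- run_sir(net, sus, config$sir)
  structure(
    list(
      size = srun$size, opinion = orun, sir = srun,
      susceptible = sus, clusters = anti_cluster_stats(net, orun$agents),
      net = net
    ),
    class = "sim_replicate"
  )
}

#' Run a full scenario: replicated networks and SIR runs
#'
#' Executes `n_networks` independent network + opinion-stage realisations;
#' on each, the vaccination outcome is fixed and `n_sir_runs` independent
#' SIR runs measure the epidemic size. The mean epidemic size is reported
#' with a 95% confidence interval over all pooled replicates
#' (`1.96 * sd / sqrt(n)`).
#'
#' @param config A [sim_config()].
#' @param .progress Print a dot per completed network.
#' @return An object of class `"vaxcamp_scenario"`: list with `replicates`
#'   (tibble `network`, `sir_run`, `size`, `n_negative`, `n_components`,
#'   `largest_component`, `opinion_steps`), `summary` (one-row tibble, see
#'   [glance.vaxcamp_scenario()]) and `config`.
#' @export
run_scenario <- function(config, .progress = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- derive_seeds(config$master_seed, config$n_networks, config$n_sir_runs)
  reps <- vector("list", config$n_networks)
  for (i in seq_len(config$n_networks)) {
    set.seed(seeds$network[i])
    net <- ws_network(config$n, config$k, config$p, config$require_connected)
    orun <- run_opinion_stage(net, config$diffusion, config$campaign,
      record_trajectory = FALSE
    )
    sus <- vaccinate(orun$agents)
    cl <- anti_cluster_stats(net, orun$agents)
    sizes <- integer(config$n_sir_runs)
    for (j in seq_len(config$n_sir_runs)) {
      set.seed(seeds$sir[i, j])
      sizes[j] <- run_sir(net, sus, config$sir, trajectory = FALSE)$size
    }
    reps[[i]] <- tibble(
      network = i, sir_run = seq_len(config$n_sir_runs), size = sizes,
      n_negative = length(sus), n_components = cl$n_components,
      largest_component = cl$largest, opinion_steps = orun$n_steps
    )
    if (.progress) cat(".")
  }
  if (.progress) cat("\n")
  replicates <- dplyr::bind_rows(reps)
  structure(
    list(
      replicates = replicates,
      summary = summarize_replicates(replicates),
      config = config
    ),
    class = "vaxcamp_scenario"
  )
}

summarize_replicates <- function(replicates) {
  n <- nrow(replicates)
  s <- if (n > 1) sd(replicates$size) else 0
  tibble(
    mean_size = mean(replicates$size),
    sd_size = s,
    ci95_halfwidth = 1.96 * s / sqrt(n),
    n_replicates = n,
    n_networks = dplyr::n_distinct(replicates$network),
    mean_n_negative = mean(replicates$n_negative)
  )
}

#' @export
print.vaxcamp_scenario <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<vaxcamp_scenario> mean epidemic size %.2f +/- %.2f (95%% CI, %d replicates = %d networks x %d SIR runs)\n",
    s$mean_size, s$ci95_halfwidth, s$n_replicates, x$config$n_networks,
    x$config$n_sir_runs
  ))
  invisible(x)
}

SWEEP_AXES <- c("omega", "mu_plus", "mu_minus", "t_r", "zeta", "Z", "T")

## return a modified copy of `config` with the axis set to `value`
set_axis <- function(config, axis, value) {
  if (axis == "omega") {
    config$diffusion$omega_minus <- value
    config$diffusion$omega_plus <- value
  } else if (axis == "mu_minus") {
    config$diffusion$mu_minus <- value
  } else {
    if (is.null(config$campaign)) {
      abort(sprintf("axis '%s' requires a campaign in the configuration", axis))
    }
    config$campaign[[if (axis == "mu_plus") "mu_plus" else axis]] <-
      if (axis %in% c("T", "t_r")) as.integer(value) else value
  }
  config
}

#' Sweep one parameter across a set of values
#'
#' Runs [run_scenario()] once per value of the swept axis. All points share
#' the same master seed, hence identical network seeds: sweeps are paired
#' (common random numbers), which sharpens comparisons along the axis.
#'
#' @param config Base [sim_config()].
#' @param axis One of `"omega"` (sets both social rates), `"mu_plus"`,
#'   `"mu_minus"`, `"t_r"`, `"zeta"`, `"Z"`, `"T"`.
#' @param values Numeric vector of axis values, reported in input order.
#' @param .progress Print progress per scenario.
#' @return An object of class `"vaxcamp_sweep"`: list with `summary`
#'   (tibble: `value` plus the scenario summary columns), `results` (list of
#'   `vaxcamp_scenario`), `axis`, `values`.
#' @export
run_sweep <- function(config, axis, values, .progress = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (!axis %in% SWEEP_AXES) {
    abort(sprintf("unknown sweep axis '%s' (use one of: %s)", axis, paste(SWEEP_AXES, collapse = ", ")))
  }
  results <- purrr::map(values, function(v) {
    if (.progress) cat(sprintf("%s = %g ", axis, v))
    run_scenario(set_axis(config, axis, v), .progress = .progress)
  })
  summary <- dplyr::bind_rows(purrr::map2(
    values, results,
    function(v, r) dplyr::bind_cols(tibble(value = v), r$summary)
  ))
  structure(
    list(summary = summary, results = results, axis = axis, values = values),
    class = "vaxcamp_sweep"
  )
}

#' @export
print.vaxcamp_sweep <- function(x, ...) {
  cat(sprintf("<vaxcamp_sweep> axis '%s', %d points\n", x$axis, length(x$values)))
  print(x$summary)
  invisible(x)
}
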