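#' Diffusion-stage parameters
#'
#' Bundles the rates of the opinion-diffusion stage. Influence reaches an
#' agent through two channels, each with a negative and a positive side:
#' *general* (campaign/media) exposure, hitting each neutral agent with a
#' per-step probability (`mu_minus` for the negative campaign; the positive
#' side is the per-agent allocation set by the [campaign()]), and *social*
#' exposure, in which every committed neighbour independently exposes a
#' neutral agent with per-link probability `omega_minus` or `omega_plus`.
#' Every successful exposure increments the agent's corresponding counter by
#' one; a neutral agent commits once the counter difference crosses the
#' opinion threshold `theta` (see [update_opinion()]).
#'
#' @param mu_minus Negative general exposure probability per neutral agent
#'   per step, in `[0, 1]`.
#' @param omega_minus,omega_plus Social exposure probability per
#'   adopter-neighbour link per step, in `[0, 1]`.
#' @param theta Opinion formation threshold, a positive integer. `theta = 1`
#'   is simple contagion (a single exposure converts); `theta >= 2` requires
#'   multiple reinforcing exposures (complex contagion). Default 2.
#' @param tau Length of the opinion stage in steps, or `Inf` to run until no
#'   neutral agent remains (the long-run regime).
#' @return A list of class `"diffusion_params"`.
#' @export
diffusion_params <- function(mu_minus, omega_minus, omega_plus = omega_minus,
                             theta = 2L, tau = Inf) {
  for (nm in c("mu_minus", "omega_minus", "omega_plus")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      abort(sprintf("`%s` must be a probability in [0, 1]", nm))
    }
  }
  if (!is.numeric(theta) || length(theta) != 1L || theta < 1 || theta != round(theta)) {
    abort("`theta` must be a positive integer")
  }
  if (!(identical(tau, Inf) || (is.numeric(tau) && length(tau) == 1L &&
    tau >= 1 && tau == round(tau)))) {
    abort("`tau` must be a positive integer number of steps or Inf")
  }
  structure(
    list(
      mu_minus = mu_minus, omega_minus = omega_minus,
      omega_plus = omega_plus, theta = as.integer(theta), tau = tau
    ),
    class = "diffusion_params"
  )
}

#' Initialise a fully neutral agent population
#'
#' At the start of the opinion stage every agent is neutral with both
#' exposure counters at zero.
#'
#' @param n Population size, at least 1.
#' @return A tibble with one row per agent: `id`, `opinion`
#'   (`"negative"`/`"neutral"`/`"positive"`), and the exposure counters
#'   `phi_minus`, `phi_plus`.
#' @export
init_agents <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    abort("`n` must be a single integer >= 1")
  }
  tibble(
    id = seq_len(n),
    opinion = rep("neutral", n),
    phi_minus = integer(n),
    phi_plus = integer(n)
  )
}

#' Threshold rule for opinion commitment
#'
#' A neutral agent commits to the negative opinion once its net negative
#' exposure `phi_minus - phi_plus` reaches the threshold `theta`, to the
#' positive opinion once it reaches `-theta`, and stays neutral otherwise.
#' The two conditions are mutually exclusive for `theta >= 1`. Commitment is
#' absorbing: the stage runner applies this rule to neutral agents only.
#'
#' @param phi_minus,phi_plus Non-negative exposure counters (vectorised).
#' @param theta Positive integer threshold.
#' @return Character vector of opinion states.
#' @examples
#' update_opinion(2, 0, theta = 2) # "negative"
#' update_opinion(0, 0, theta = 2) # "neutral"
#' update_opinion(2, 12, theta = 2) # "positive"
#' @export
update_opinion <- function(phi_minus, phi_plus, theta) {
  if (any(phi_minus < 0) || any(phi_plus < 0)) {
    abort("exposure counters must be non-negative")
  }
  if (theta < 1) abort("`theta` must be >= 1")
  d <- phi_minus - phi_plus
  out <- rep("neutral", length(d))
  out[d >= theta] <- "negative"
  out[d <= -theta] <- "positive"
  out
}

## ---- vector kernels -------------------------------------------------------
## The stage runner keeps the agent state as three plain vectors (opinion
## codes and the two counters) and calls these kernels once per step; the
## exported tibble interfaces below wrap the same code paths.  Random draw
## order within a step is fixed and documented: negative general, positive
## general, negative social, positive social -- each one vectorised draw over
## the neutral agents in increasing id order.

kernel_general <- function(op, phm, php, alloc, mu_minus) {
  neu <- which(op == 0L)
  if (length(neu)) {
    phm[neu] <- phm[neu] + (runif(length(neu)) < mu_minus)
    php[neu] <- php[neu] + (runif(length(neu)) < alloc[neu])
  }
  list(phm = phm, php = php)
}

kernel_social <- function(op, phm, php, a, omega_minus, omega_plus) {
  if (!any(op != 0L) || (omega_minus == 0 && omega_plus == 0)) {
    return(list(phm = phm, php = php)) # no influence sources this step
  }
  neu <- which(op == 0L)
  if (length(neu)) {
    m_neg <- as.integer(a %*% (op == -1L))[neu]
    m_pos <- as.integer(a %*% (op == 1L))[neu]
    phm[neu] <- phm[neu] + rbinom(length(neu), m_neg, omega_minus)
    php[neu] <- php[neu] + rbinom(length(neu), m_pos, omega_plus)
  }
  list(phm = phm, php = php)
}

kernel_update <- function(op, phm, php, theta) {
  neu <- which(op == 0L)
  if (length(neu)) {
    d <- phm[neu] - php[neu]
    op[neu[d >= theta]] <- -1L
    op[neu[d <= -theta]] <- 1L
  }
  op
}

#' Apply one step of general (campaign) exposures
#'
#' Each *neutral* agent receives one Bernoulli trial per general channel:
#' probability `mu_minus` of one negative exposure, and probability
#' `allocation[i]` of one positive exposure. Committed agents are untouched;
#' exposures aimed at them are dropped.
#'
#' @param agents Agent tibble (see [init_agents()]).
#' @param allocation Per-agent positive exposure probability, as produced by
#'   [allocate_positive()]; values must lie in `[0, 1]`.
#' @param mu_minus Negative general exposure probability.
#' @return The updated agent tibble.
#' @export
apply_general_exposures <- function(agents, allocation, mu_minus) {
  n <- nrow(agents)
  if (length(allocation) == 1L) allocation <- rep(allocation, n)
  if (length(allocation) != n) {
    abort("`allocation` must have one entry per agent")
  }
  if (anyNA(allocation) || any(allocation < 0) || any(allocation > 1)) {
    abort("invalid allocation: per-agent positive exposure probabilities must lie in [0, 1]")
  }
  op <- opinion_to_int(agents$opinion)
  k <- kernel_general(op, agents$phi_minus, agents$phi_plus, allocation, mu_minus)
  agents$phi_minus <- as.integer(k$phm)
  agents$phi_plus <- as.integer(k$php)
  agents
}

#' Apply one step of social exposures
#'
#' Every committed agent exposes each of its currently neutral neighbours
#' independently with probability `omega_minus` (negative adopters) or
#' `omega_plus` (positive adopters), so a neutral agent with `m` negative
#' neighbours receives a `Binomial(m, omega_minus)` increment this step.
#' Influence sources are the adopters as of the start of the step
#' (synchronous semantics).
#'
#' @inheritParams apply_general_exposures
#' @param net igraph contact network over the agent ids.
#' @param omega_minus,omega_plus Per-link social exposure probabilities.
#' @return The updated agent tibble.
#' @export
apply_social_exposures <- function(agents, net, omega_minus, omega_plus) {
  op <- opinion_to_int(agents$opinion)
  a <- adjacency_of(net)
  k <- kernel_social(op, agents$phi_minus, agents$phi_plus, a, omega_minus, omega_plus)
  agents$phi_minus <- as.integer(k$phm)
  agents$phi_plus <- as.integer(k$php)
  agents
}

#' Run the opinion-diffusion stage
#'
#' Starting from an all-neutral population, repeats per step: (1) campaign
#' retargeting when due, (2) general exposures, (3) social exposures from
#' start-of-step adopters, (4) synchronous threshold update of all neutral
#' agents. The stage ends after `params$tau` steps, or -- in the long-run
#' regime `tau = Inf` -- as soon as no neutral agent remains.
#'
#' An agent that commits at step `t` exerts social influence from step
#' `t + 1` onwards, and its counters are frozen from the moment of
#' commitment.
#'
#' @param net igraph contact network.
#' @param params [diffusion_params()].
#' @param campaign A [campaign()] describing the positive-information
#'   strategy, or `NULL` for the anti-vaccine-only benchmark (no positive
#'   general exposure).
#' @param centrality Optional tibble from [betweenness_scores()]; computed on
#'   demand when the strategy needs it.
#' @param record_trajectory Record per-step opinion counts (default `TRUE`;
#'   turn off in tight replication loops).
#' @param record_targets Record the target set chosen at each retargeting
#'   step (for diagnostics such as [target_neighborhood_histogram()]).
#' @param snapshot_step If non-`NULL`, capture the neighbourhood profile
#'   (`n_minus`, `n_zero`) of every targeted neutral agent at the start of
#'   this step.
#' @param max_steps Hard safety cap for `tau = Inf`; exceeding it is an
#'   error, never a silent truncation.
#'
#' @return An object of class `"opinion_run"`: a list with elements
#'   `agents` (final agent tibble), `trajectory` (tibble `step`,
#'   `n_negative`, `n_neutral`, `n_positive`), `termination`
#'   (`"tau_reached"` or `"all_adopted"`), `n_steps`, and optionally
#'   `targets` (tibble `step`, `node`) and `snapshot` (tibble `node`,
#'   `n_minus`, `n_zero`).
#' @export
run_opinion_stage <- function(net, params, campaign = NULL, centrality = NULL,
                              record_trajectory = TRUE, record_targets = FALSE,
                              snapshot_step = NULL, max_steps = 1e6) {
  stopifnot(inherits(params, "diffusion_params"))
  n <- igraph::vcount(net)
  a <- adjacency_of(net)
  mu_plus <- if (is.null(campaign)) 0 else campaign$mu_plus
  if (identical(params$tau, Inf) && params$mu_minus == 0 && mu_plus == 0) {
    abort(paste(
      "tau = Inf cannot terminate: with mu_minus = 0 and no positive budget",
      "an all-neutral population never gains a first adopter"
    ))
  }

  op <- integer(n)
  phm <- numeric(n)
  php <- numeric(n)
  alloc <- numeric(n)
  scores <- NULL
  if (!is.null(campaign) && campaign$strategy == "StatCentT" && campaign$mu_plus > 0) {
    scores <- if (is.null(centrality)) betweenness_scores(net)$betweenness else centrality$betweenness
  }

  traj_steps <- if (record_trajectory) list(c(0L, 0L, n, 0L)) else NULL
  targets_log <- if (record_targets) list() else NULL
  snapshot <- NULL

  step <- 0L
  termination <- "tau_reached"
  repeat {
    neu <- which(op == 0L)
    if (!length(neu)) {
      termination <- "all_adopted"
      break
    }
    if (is.finite(params$tau) && step >= params$tau) break
    if (step >= max_steps) {
      abort(sprintf("opinion stage exceeded max_steps = %g without absorbing", max_steps))
    }

    ## (1) retargeting hook (steps are 0-based for the schedule)
    if (!is.null(campaign) && retarget_due(campaign, step)) {
      tgt <- select_targets(campaign, net, op, a, scores)
      alloc <- numeric(n)
      if (length(tgt) && campaign$mu_plus > 0) {
        ind <- integer(n)
        ind[tgt] <- 1L
        if (!is.na(campaign$T) && length(tgt) < campaign$T) {
          ## endgame shortfall: fewer neutral agents remain than the
          ## configured target-set size, so the concentrated budget may
          ## exceed certainty; exposure probabilities cap at 1
          alloc <- pmin(1, as.numeric(ind) * campaign$mu_plus * n / length(tgt))
        } else {
          alloc <- allocate_positive(ind, campaign$mu_plus, n)
        }
      }
      if (record_targets && length(tgt)) {
        targets_log[[length(targets_log) + 1L]] <- tibble(step = step, node = sort(tgt))
      }
      if (!is.null(snapshot_step) && step == snapshot_step) {
        cnt <- neighbor_state_counts(a, op)
        keep <- tgt[op[tgt] == 0L]
        snapshot <- tibble(
          node = keep, n_minus = cnt$n_minus[keep], n_zero = cnt$n_zero[keep]
        )
      }
    }

    ## (2) general, (3) social, (4) synchronous threshold update
    k <- kernel_general(op, phm, php, alloc, params$mu_minus)
    k <- kernel_social(op, k$phm, k$php, a, params$omega_minus, params$omega_plus)
    phm <- k$phm
    php <- k$php
    op <- kernel_update(op, phm, php, params$theta)
    step <- step + 1L

    if (record_trajectory) {
      traj_steps[[step + 1L]] <- c(step, sum(op == -1L), sum(op == 0L), sum(op == 1L))
    }
  }

  agents <- tibble(
    id = seq_len(n),
    opinion = opinion_to_chr(op),
    phi_minus = as.integer(phm),
    phi_plus = as.integer(php)
  )
  trajectory <- NULL
  if (record_trajectory) {
    m <- do.call(rbind, traj_steps)
    trajectory <- tibble(
      step = m[, 1], n_negative = m[, 2], n_neutral = m[, 3], n_positive = m[, 4]
    )
  }
  structure(
    list(
      agents = agents,
      trajectory = trajectory,
      termination = termination,
      n_steps = step,
      targets = if (record_targets) dplyr::bind_rows(targets_log) else NULL,
      snapshot = snapshot
    ),
    class = "opinion_run"
  )
}

#' @export
print.opinion_run <- function(x, ...) {
  counts <- table(factor(x$agents$opinion, levels = .OPINION_LEVELS))
  cat(sprintf(
    "<opinion_run> %d agents after %d steps (%s): %d negative, %d neutral, %d positive\n",
    nrow(x$agents), x$n_steps, x$termination,
    counts[["negative"]], counts[["neutral"]], counts[["positive"]]
  ))
  invisible(x)
}
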