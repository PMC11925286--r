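#' Disease-stage parameters
#'
#' @param beta Transmission probability per infectious contact per step.
#' @param gamma Recovery probability per infected agent per step.
#' @param i0 Initial number of infected agents (seeded uniformly at random
#'   among the susceptible).
#' @return A list of class `"sir_params"`.
#' @export
sir_params <- function(beta, gamma, i0 = 1L) {
  for (nm in c("beta", "gamma")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      abort(sprintf("`%s` must be a probability in [0, 1]", nm))
    }
  }
  if (!is.numeric(i0) || length(i0) != 1L || i0 < 1 || i0 != round(i0)) {
    abort("`i0` must be a positive integer")
  }
  structure(list(beta = beta, gamma = gamma, i0 = as.integer(i0)),
    class = "sir_params"
  )
}

#' Vaccination: map final opinions to the susceptible set
#'
#' After the opinion stage, every agent holding a non-negative opinion
#' (neutral or positive) accepts the vaccine and acquires full immunity;
#' agents with the negative opinion refuse it and remain susceptible.
#' Vaccinated agents keep their network position, so they block transmission
#' paths between susceptible clusters without ever entering the disease
#' dynamics.
#'
#' @param agents Final agent tibble from [run_opinion_stage()].
#' @return Integer vector of susceptible (anti-vaccine) node ids.
#' @export
vaccinate <- function(agents) {
  as.integer(agents$id[agents$opinion == "negative"])
}

#' Seed the initial infections
#'
#' @param susceptible Integer vector of susceptible node ids.
#' @param i0 Number of seeds.
#' @return Integer vector of `i0` distinct seed ids; empty when no agent is
#'   susceptible (no outbreak is possible).
#' @export
seed_infection <- function(susceptible, i0 = 1L) {
  if (!length(susceptible)) {
    return(integer(0))
  }
  if (length(susceptible) < i0) {
    abort(sprintf(
      "cannot seed %d infections among %d susceptible agents", i0, length(susceptible)
    ))
  }
  sample_ids(susceptible, i0)
}

#' Run the discrete-time SIR stage among unvaccinated agents
#'
#' Seeds `i0` uniformly chosen susceptible agents, then iterates
#' synchronously: every agent infected at the start of a step transmits
#' independently to each currently susceptible neighbour with probability
#' `beta`, after which it recovers with probability `gamma`. A newly
#' infected agent neither transmits nor recovers within its infection step.
#' The process stops when no infected agent remains; the epidemic size is
#' the number of agents that ever experienced infection (the recovered count
#' at absorption).
#'
#' @param net igraph contact network.
#' @param susceptible Integer vector of susceptible node ids (from
#'   [vaccinate()]); all other nodes are immune and take no part.
#' @param params [sir_params()].
#' @param trajectory Record the per-step `(S, I, R)` counts (default
#'   `TRUE`; turn off in tight replication loops).
#' @return An object of class `"sir_run"`: list with `size` (final epidemic
#'   size), `seed` (seed node ids), `n_steps`, and `trajectory` (tibble
#'   `step`, `S`, `I`, `R`, or `NULL`).
#' @examples
#' net <- fixture_graph("complete", 3)
#' run_sir(net, 1:3, sir_params(beta = 1, gamma = 1))$size # always 3
#' @export
run_sir <- function(net, susceptible, params, trajectory = TRUE) {
  stopifnot(inherits(params, "sir_params"))
  susceptible <- as.integer(susceptible)
  n <- igraph::vcount(net)
  if (length(susceptible) && (anyNA(susceptible) ||
    any(susceptible < 1L | susceptible > n))) {
    abort("`susceptible` contains node ids outside the network")
  }
  if (!length(susceptible)) {
    return(structure(
      list(
        size = 0L, seed = integer(0), n_steps = 0L,
        trajectory = if (trajectory) tibble(step = 0L, S = 0L, I = 0L, R = 0L) else NULL
      ),
      class = "sir_run"
    ))
  }
  seeds <- seed_infection(susceptible, params$i0)
  m <- length(susceptible)
  ## adjacency restricted to the susceptible subpopulation; small sets get a
  ## dense base matrix, which avoids S4 dispatch in the replication loops
  el <- igraph::as_edgelist(net, names = FALSE)
  keep <- el[, 1] %in% susceptible & el[, 2] %in% susceptible
  ii <- match(el[keep, 1], susceptible)
  jj <- match(el[keep, 2], susceptible)
  a_sub <- if (m <= 512) {
    d <- matrix(0, m, m)
    d[cbind(c(ii, jj), c(jj, ii))] <- 1
    d
  } else {
    Matrix::sparseMatrix(
      i = c(ii, jj), j = c(jj, ii), x = 1, dims = c(m, m)
    )
  }
  status <- integer(m) # 0 = S, 1 = I, 2 = R
  status[match(seeds, susceptible)] <- 1L

  traj <- if (trajectory) list(c(0L, m - params$i0, params$i0, 0L)) else NULL
  step <- 0L
  while (any(status == 1L)) {
    infected <- status == 1L
    pressure <- as.numeric(a_sub %*% infected)
    at_risk <- which(status == 0L & pressure > 0)
    if (length(at_risk)) {
      p_inf <- 1 - (1 - params$beta)^pressure[at_risk]
      status[at_risk[runif(length(at_risk)) < p_inf]] <- 1L
    }
    recovering <- which(infected)
    status[recovering[runif(length(recovering)) < params$gamma]] <- 2L
    step <- step + 1L
    if (trajectory) {
      traj[[step + 1L]] <- c(step, sum(status == 0L), sum(status == 1L), sum(status == 2L))
    }
  }
  out_traj <- NULL
  if (trajectory) {
    tm <- do.call(rbind, traj)
    out_traj <- tibble(step = tm[, 1], S = tm[, 2], I = tm[, 3], R = tm[, 4])
  }
  structure(
    list(size = sum(status == 2L), seed = seeds, n_steps = step, trajectory = out_traj),
    class = "sir_run"
  )
}

#' @export
print.sir_run <- function(x, ...) {
  cat(sprintf(
    "<sir_run> epidemic size %d after %d steps (seed%s: %s)\n",
    x$size, x$n_steps, if (length(x$seed) > 1) "s" else "",
    if (length(x$seed)) paste(x$seed, collapse = ", ") else "none"
  ))
  invisible(x)
}
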