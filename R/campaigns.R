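CAMPAIGN_STRATEGIES <- c(
  "StatRandAll", "StatRandT", "StatCentT",
  "DynRandT", "DynAntiT", "DynLocT", "DynAdvLocT"
)

DYNAMIC_STRATEGIES <- c("DynRandT", "DynAntiT", "DynLocT", "DynAdvLocT")

#' Specify a positive-information campaign
#'
#' The positive campaign concentrates a population-wide budget `mu_plus` of
#' positive general exposure on a target set. Under targeting, each target
#' receives per-step exposure probability `mu_plus * n / |T|`
#' ([allocate_positive()]), so the population average always equals
#' `mu_plus`. Seven strategies are available:
#'
#' * `StatRandAll` -- untargeted baseline: every agent receives `mu_plus`.
#' * `StatRandT` -- a fixed uniform-random subset of size `T`.
#' * `StatCentT` -- the `T` highest-betweenness nodes, fixed for the run.
#' * `DynRandT` -- every `t_r` steps, a fresh uniform sample of `T` currently
#'   neutral agents.
#' * `DynAntiT` -- every `t_r` steps, `T` neutral agents having at least one
#'   anti-vaccine neighbour (random top-up from other neutrals on shortfall).
#' * `DynLocT` -- every `t_r` steps, the `T` neutral agents whose
#'   anti-vaccine neighbour count is closest to `zeta`
#'   (score `|n_minus - zeta|`, ascending; ties random).
#' * `DynAdvLocT` -- as `DynLocT` but trading off proximity to negative
#'   clusters against room for positive growth:
#'   score `|n_minus - zeta| + |n_zero - Z|`.
#'
#' @param strategy One of the seven strategy names above.
#' @param T Target-set size (ignored by `StatRandAll`).
#' @param t_r Retargeting interval in steps (dynamic strategies only).
#' @param zeta Target number of anti-vaccine neighbours (`DynLocT`,
#'   `DynAdvLocT`).
#' @param Z Target number of neutral neighbours (`DynAdvLocT`).
#' @param mu_plus Population-averaged positive general exposure rate.
#' @return A list of class `"vaxcamp_campaign"`.
#' @examples
#' campaign("StatCentT", T = 500, mu_plus = 0.001)
#' campaign("DynAdvLocT", T = 50, t_r = 1, zeta = 10, Z = 10, mu_plus = 0.001)
#' @export
campaign <- function(strategy, T = NULL, t_r = 1L, zeta = NULL, Z = NULL,
                     mu_plus = 0) {
  if (!is.character(strategy) || length(strategy) != 1L ||
    !strategy %in% CAMPAIGN_STRATEGIES) {
    abort(sprintf(
      "`strategy` must be one of: %s", paste(CAMPAIGN_STRATEGIES, collapse = ", ")
    ))
  }
  if (!is.numeric(mu_plus) || length(mu_plus) != 1L || is.na(mu_plus) || mu_plus < 0) {
    abort("`mu_plus` must be a non-negative rate")
  }
  if (strategy != "StatRandAll") {
    if (is.null(T) || !is.numeric(T) || length(T) != 1L || T < 1 || T != round(T)) {
      abort("targeted strategies need a target-set size `T` >= 1")
    }
    T <- as.integer(T)
  } else {
    T <- NA_integer_
  }
  if (strategy %in% DYNAMIC_STRATEGIES) {
    if (!is.numeric(t_r) || length(t_r) != 1L || t_r < 1 || t_r != round(t_r)) {
      abort("`t_r` must be a positive integer retargeting interval")
    }
    t_r <- as.integer(t_r)
  } else {
    t_r <- NA_integer_
  }
  if (strategy %in% c("DynLocT", "DynAdvLocT")) {
    if (is.null(zeta) || !is.numeric(zeta) || zeta < 0) {
      abort(sprintf("`zeta` (target anti-vaccine neighbour count) is required for %s", strategy))
    }
  }
  if (strategy == "DynAdvLocT" && (is.null(Z) || !is.numeric(Z) || Z < 0)) {
    abort("`Z` (target neutral neighbour count) is required for DynAdvLocT")
  }
  structure(
    list(
      strategy = strategy, T = T, t_r = t_r,
      zeta = if (is.null(zeta)) NA_real_ else as.numeric(zeta),
      Z = if (is.null(Z)) NA_real_ else as.numeric(Z),
      mu_plus = mu_plus
    ),
    class = "vaxcamp_campaign"
  )
}

#' @export
print.vaxcamp_campaign <- function(x, ...) {
  extras <- c(
    if (!is.na(x$T)) sprintf("T=%d", x$T),
    if (!is.na(x$t_r)) sprintf("t_r=%d", x$t_r),
    if (!is.na(x$zeta)) sprintf("zeta=%g", x$zeta),
    if (!is.na(x$Z)) sprintf("Z=%g", x$Z),
    sprintf("mu_plus=%g", x$mu_plus)
  )
  cat(sprintf("<campaign> %s (%s)\n", x$strategy, paste(extras, collapse = ", ")))
  invisible(x)
}

#' Is a retargeting due at this step?
#'
#' Dynamic strategies reselect their target set at steps `0, t_r, 2*t_r,
#' ...`; static strategies select once at step 0 and never again.
#'
#' @param campaign A [campaign()].
#' @param step Step index, 0-based.
#' @return `TRUE` or `FALSE`.
#' @export
retarget_due <- function(campaign, step) {
  if (step < 0) abort("`step` must be >= 0")
  if (campaign$strategy %in% DYNAMIC_STRATEGIES) {
    step %% campaign$t_r == 0
  } else {
    step == 0
  }
}

#' Concentrate the positive budget on a target set
#'
#' The population-wide positive rate `mu_plus` is redistributed over the
#' targets: `mu_i = T_i * mu_plus * n / sum(T_i)`, so that the per-agent
#' allocations always sum to `mu_plus * n` (budget conservation). An
#' allocation exceeding 1 is not a valid per-step probability and raises an
#' error naming the offending configuration rather than clamping silently.
#'
#' @param indicator 0/1 vector, `indicator[i] = 1` when agent `i` is
#'   targeted.
#' @param mu_plus Population-averaged positive exposure rate.
#' @param n Population size.
#' @return Numeric vector of per-agent exposure probabilities.
#' @examples
#' alloc <- allocate_positive(rep(c(1, 0), c(500, 4500)), 0.001, 5000)
#' alloc[1] # 0.01
#' sum(alloc) # 5 = 0.001 * 5000
#' @export
allocate_positive <- function(indicator, mu_plus, n) {
  if (length(indicator) != n) abort("`indicator` must have length `n`")
  if (!all(indicator %in% c(0, 1))) abort("`indicator` must be a 0/1 vector")
  n_targets <- sum(indicator)
  if (mu_plus == 0) {
    return(numeric(n))
  }
  if (n_targets == 0) {
    abort("empty target set with a positive budget: no agent can receive mu_plus > 0")
  }
  per_target <- mu_plus * n / n_targets
  if (per_target > 1) {
    abort(sprintf(
      "per-target allocation mu_plus * n / |T| = %g * %d / %d = %g exceeds 1 and is not a valid probability",
      mu_plus, n, n_targets, per_target
    ))
  }
  as.numeric(indicator) * per_target
}

#' Local-information target scores
#'
#' `score_local()` ranks neutral agents by how close their anti-vaccine
#' neighbour count is to the target `zeta`; `score_advanced()` adds the
#' distance of the neutral neighbour count from `Z`, trading off blocking
#' negative clusters against room for positive clusters to grow. Lower is
#' better; the campaigns select the `T` lowest-scoring agents.
#'
#' @param n_minus Anti-vaccine neighbour count(s).
#' @param n_zero Neutral neighbour count(s).
#' @param zeta,Z Target neighbour counts.
#' @return Non-negative numeric score(s).
#' @examples
#' score_local(1, zeta = 1) # 0
#' score_advanced(1, 8, zeta = 8, Z = 1) # 14
#' @export
score_local <- function(n_minus, zeta) {
  if (any(n_minus < 0) || any(zeta < 0)) abort("counts must be non-negative")
  abs(n_minus - zeta)
}

#' @rdname score_local
#' @export
score_advanced <- function(n_minus, n_zero, zeta, Z) {
  if (any(c(n_minus, n_zero, zeta, Z) < 0)) abort("counts must be non-negative")
  abs(n_minus - zeta) + abs(n_zero - Z)
}

#' Ascending-score selection with random tie-breaking
#'
#' Selects the `size` lowest-scoring candidates; ties (in particular at the
#' cut boundary) are resolved uniformly at random. With fewer candidates
#' than `size`, all are selected.
#'
#' @param ids Candidate node ids.
#' @param scores Score per candidate (lower is better).
#' @param size Number to select.
#' @return Integer vector of selected ids.
#' @export
select_by_score <- function(ids, scores, size) {
  if (length(ids) != length(scores)) abort("`ids` and `scores` must have equal length")
  if (length(ids) <= size) {
    return(as.integer(ids))
  }
  ord <- order(scores, sample.int(length(ids)))
  as.integer(ids[ord[seq_len(size)]])
}

## uniform sample that never hits the sample(x, ...) scalar gotcha
sample_ids <- function(ids, size) {
  if (length(ids) <= size) {
    return(as.integer(ids))
  }
  as.integer(ids[sample.int(length(ids), size)])
}

#' Select a static uniform-random target set
#'
#' @param net igraph network (only its node count is used).
#' @param size Target-set size `T`.
#' @return Integer vector of `size` distinct node ids.
#' @export
select_static_random <- function(net, size) {
  n <- igraph::vcount(net)
  if (size > n) abort("target-set size exceeds the population")
  sample_ids(seq_len(n), size)
}

#' Select the most central nodes as static targets
#'
#' Takes the `size` highest-betweenness nodes; ties among agents with the
#' same score at the cut boundary are resolved uniformly at random.
#'
#' @param centrality Tibble from [betweenness_scores()].
#' @param size Target-set size `T`.
#' @return Integer vector of node ids.
#' @export
select_static_central <- function(centrality, size) {
  n <- nrow(centrality)
  if (size > n) abort("target-set size exceeds the population")
  sc <- centrality$betweenness
  cutoff <- sort(sc, decreasing = TRUE)[size]
  sure <- centrality$node[sc > cutoff]
  tied <- centrality$node[sc == cutoff]
  as.integer(c(sure, sample_ids(tied, size - length(sure))))
}

#' Dynamic selection rules over the currently neutral population
#'
#' `select_dynamic_random()` draws a fresh uniform sample from the neutral
#' agents. `select_dyn_anti()` draws from neutral agents with at least one
#' anti-vaccine neighbour, topping up uniformly from the remaining neutrals
#' when fewer than `size` are eligible. Both take the whole neutral set when
#' it is smaller than `size`.
#'
#' @param neutral_ids Ids of currently neutral agents.
#' @param size Target-set size `T`.
#' @return Integer vector of selected ids (possibly shorter than `size`).
#' @export
select_dynamic_random <- function(neutral_ids, size) {
  sample_ids(neutral_ids, size)
}

#' @rdname select_dynamic_random
#' @param n_minus Anti-vaccine neighbour count for each agent in
#'   `neutral_ids` (same order).
#' @export
select_dyn_anti <- function(neutral_ids, n_minus, size) {
  if (length(neutral_ids) != length(n_minus)) {
    abort("`n_minus` must have one count per neutral agent")
  }
  eligible <- neutral_ids[n_minus >= 1]
  if (length(eligible) >= size) {
    return(sample_ids(eligible, size))
  }
  rest <- neutral_ids[n_minus < 1]
  as.integer(c(eligible, sample_ids(rest, size - length(eligible))))
}

## strategy dispatcher used by the stage runner at each retargeting step;
## `op` is the internal opinion code vector, `a` the sparse adjacency.
select_targets <- function(campaign, net, op, a = NULL, scores = NULL) {
  n <- length(op)
  switch(campaign$strategy,
    StatRandAll = seq_len(n),
    StatRandT = select_static_random(net, campaign$T),
    StatCentT = {
      if (is.null(scores)) scores <- betweenness_scores(net)$betweenness
      select_static_central(tibble(node = seq_len(n), betweenness = scores), campaign$T)
    },
    {
      neu <- which(op == 0L)
      if (!length(neu)) {
        return(integer(0))
      }
      if (is.null(a)) a <- adjacency_of(net)
      if (campaign$strategy == "DynRandT") {
        select_dynamic_random(neu, campaign$T)
      } else {
        n_min <- as.integer(a %*% (op == -1L))[neu]
        if (campaign$strategy == "DynAntiT") {
          select_dyn_anti(neu, n_min, campaign$T)
        } else {
          sc <- if (campaign$strategy == "DynLocT") {
            score_local(n_min, campaign$zeta)
          } else {
            n_zero <- as.integer(a %*% (op == 0L))[neu]
            score_advanced(n_min, n_zero, campaign$zeta, campaign$Z)
          }
          select_by_score(neu, sc, campaign$T)
        }
      }
    }
  )
}
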