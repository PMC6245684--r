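#' Partial truth assignments observed in perturbation experiments
#'
#' An observation set records, for a subset of regulator states, the target
#' output measured there. It is the object behind the "common set of
#' transitions": the ambiguity of an experiment is the number of
#' search-space functions agreeing with the observation set at every
#' observed state.
#'
#' @param k number of regulator inputs.
#' @param states integer vector of observed state numbers.
#' @param outputs integer vector of observed target outputs (same length).
#' @return An object of class `observation_set` (fields `k`, `observed`:
#'   named integer vector, names are state numbers).
#' @export
observation_set <- function(k, states = integer(0), outputs = integer(0)) {
  k <- check_k(k, max_warn = .Machine$integer.max)
  states <- as.integer(states); outputs <- as.integer(outputs)
  if (length(states) != length(outputs))
    stop("`states` and `outputs` must have the same length", call. = FALSE)
  if (length(states) && (any(states < 0L) || any(states >= 2^k)))
    stop("state numbers must lie in [0, ", 2^k - 1, "]", call. = FALSE)
  if (!all(outputs %in% c(0L, 1L)))
    stop("outputs must be 0/1", call. = FALSE)
  if (anyDuplicated(states)) {
    first <- !duplicated(states)
    for (s in unique(states[duplicated(states)])) {
      if (length(unique(outputs[states == s])) > 1L)
        stop("conflicting outputs observed for state ", s, call. = FALSE)
    }
    states <- states[first]; outputs <- outputs[first]
  }
  o <- order(states)
  observed <- outputs[o]
  names(observed) <- states[o]
  structure(list(k = k, observed = observed), class = "observation_set")
}

#' @rdname observation_set
#' @param a,b observation sets with equal `k`.
#' @export
merge_observations <- function(a, b) {
  stopifnot(inherits(a, "observation_set"), inherits(b, "observation_set"))
  if (a$k != b$k) stop("cannot merge observation sets with different k", call. = FALSE)
  observation_set(a$k,
                  c(as.integer(names(a$observed)), as.integer(names(b$observed))),
                  c(unname(a$observed), unname(b$observed)))
}

#' @export
print.observation_set <- function(x, ...) {
  cat(sprintf("<observation set, k = %d: %d of %d states observed>\n",
              x$k, length(x$observed), 2^x$k))
  if (length(x$observed))
    cat("  ", paste(sprintf("%s:%d", names(x$observed), x$observed),
                    collapse = " "), "\n")
  invisible(x)
}

#' Observations produced by one perturbation step
#'
#' One step of the protocol, starting from state `s`: the unperturbed
#' output at `s` is recorded, then every available single perturbation is
#' performed (all k under `"DO"`, the popcount(s) knock-downs under `"D"`)
#' and the output at each destination is recorded. On the first step the
#' full-visibility status of `s` under the requested integration is also
#' reported -- it is the Eq-4 gate deciding whether the experiment
#' identifies all k regulators; visibility plays no role in later steps.
#'
#' @param f a [boolean_function()].
#' @param s initial state of the step.
#' @param regime `"DO"` or `"D"`.
#' @param first_step logical; compute the visibility gate?
#' @param integration integration mode used for the gate.
#' @return List with `observations` ([observation_set()]), `destinations`
#'   (integer vector), and when `first_step` `fully_visible` (logical) and
#'   `n_visible` (visible out-degree of `s`).
#' @examples
#' st <- observations_from_step(decode_index(22, 3), 3, "DO")
#' st$observations$observed # states 1,2,3,7 -> 0,0,1,0
#' @export
observations_from_step <- function(f, s, regime = c("DO", "D"),
                                   first_step = TRUE, integration = "TX") {
  stopifnot(inherits(f, "boolean_function"))
  regime <- match_arg_regime(regime[1])
  k <- f$k
  if (s < 0 || s >= 2^k) stop("invalid state number ", s, call. = FALSE)
  dests <- perturbation_destinations(s, k, regime)
  states <- unique(c(s, dests))
  obs <- observation_set(k, states, f$outputs[states + 1])
  out <- list(observations = obs, destinations = dests)
  if (first_step) {
    d <- build_spsd(f, regime, integration)
    out$fully_visible <- d$fully_visible[s + 1]
    out$n_visible <- d$visible_out_degree[s + 1]
  }
  out
}

#' Count search-space functions consistent with observations
#'
#' The ambiguity count N^cmn: how many non-degenerate k-input functions
#' agree with an observation set at every observed state. Two independent
#' routes are provided: `"filter"` scans the enumerated search space,
#' `"completion"` counts truth-table completions by inclusion-exclusion
#' over forced-silent input subsets (degenerate consistent completions are
#' subtracted without enumerating anything). Both must agree; the test
#' suite verifies this.
#'
#' @param obs an [observation_set()] (may be empty: the whole space counts).
#' @param space optional [enumerate_search_space()] result (defaults to the
#'   full space for `obs$k`).
#' @param method `"filter"` or `"completion"`.
#' @param indices logical; also return the sorted consistent index list
#'   (only with `method = "filter"`).
#' @return Integer count, or when `indices = TRUE` a list
#'   `list(count, indices)`.
#' @examples
#' st <- observations_from_step(decode_index(22, 3), 3, "DO")
#' consistent_count(st$observations) # 16
#' @export
consistent_count <- function(obs, space = NULL,
                             method = c("filter", "completion"),
                             indices = FALSE) {
  stopifnot(inherits(obs, "observation_set"))
  method <- match.arg(method)
  k <- obs$k
  if (method == "completion") {
    if (indices) stop("indices are only available with method = 'filter'",
                      call. = FALSE)
    if (!is.null(space))
      stop("method = 'completion' counts over the full search space only",
           call. = FALSE)
    return(completion_count(obs))
  }
  if (is.null(space)) space <- enumerate_search_space(k)
  stopifnot(inherits(space, "search_space"), space$k == k)
  O <- if (space$size == search_space_size(k)) space_outputs(k)
       else outputs_matrix(k, space$indices)
  if (length(obs$observed) == 0L) {
    return(if (indices) list(count = space$size, indices = space$indices)
           else space$size)
  }
  st <- as.integer(names(obs$observed))
  ok <- rowSums(O[, st + 1, drop = FALSE] ==
                  matrix(obs$observed, nrow(O), length(st), byrow = TRUE)) ==
        length(st)
  if (indices) list(count = sum(ok), indices = space$indices[ok]) else sum(ok)
}

# inclusion-exclusion completion counting: for each subset J of inputs
# forced to be ineffective, consistent functions factor through the orbit
# classes of states under flipping bits in J; a class is admissible when
# its observed outputs agree, and free classes each contribute a factor 2.
completion_count <- function(obs) {
  k <- obs$k
  n <- 2^k
  st <- as.integer(names(obs$observed))
  val <- unname(obs$observed)
  total <- 0
  for (Jmask in 0:(2^k - 1)) {
    jsize <- popcount(Jmask)
    # orbit representative: clear all bits in J
    reps <- vapply(0:(n - 1), function(s) bitwAnd(s, bitwNot(Jmask)), integer(1))
    classes <- match(reps, sort(unique(reps)))
    nclass <- max(classes)
    fixed <- rep(NA_integer_, nclass)
    okJ <- TRUE
    for (idx in seq_along(st)) {
      cl <- classes[st[idx] + 1]
      if (is.na(fixed[cl])) fixed[cl] <- val[idx]
      else if (fixed[cl] != val[idx]) { okJ <- FALSE; break }
    }
    cnt <- if (okJ) 2^sum(is.na(fixed)) else 0
    total <- total + (-1)^jsize * cnt
  }
  total
}

# ---- multi-step machinery -------------------------------------------------

# all distinct observed-state sets reachable by paths of `np` initial
# states from s1; a path that dead-ends (state 0 under regime D) keeps its
# accumulated observations and stops.
path_state_sets <- function(s1, k, regime, np) {
  sets <- list()
  seen <- new.env(parent = emptyenv())
  rec <- function(s, t, acc) {
    dests <- perturbation_destinations(s, k, regime)
    acc <- sort(unique(c(acc, s, dests)))
    if (t == np || length(dests) == 0L) {
      key <- paste(acc, collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        sets[[length(sets) + 1L]] <<- acc
      }
      return(invisible(NULL))
    }
    for (s2 in dests) rec(s2, t + 1L, acc)
  }
  rec(s1, 1L, integer(0))
  sets
}

# N^cmn over the whole search space for a fixed observed-state set:
# functions sharing the same restriction pattern are mutually consistent,
# so one pattern tabulation gives every function's count at once. Cached.
space_pattern_counts <- function(k, states) {
  key <- paste0("pat_", k, "_", paste(states, collapse = "."))
  cache_get(key, function() {
    O <- space_outputs(k)
    w <- 2^(seq_along(states) - 1)
    p <- as.integer(O[, states + 1, drop = FALSE] %*% w)
    tabulate(p + 1L, nbins = 2^length(states))[p + 1L]
  })
}

# matrix [N_B, 2^k]: minimal N^cmn over all np-step paths from each state
space_min_common <- function(k, regime, np) {
  key <- paste("minN", k, regime, np, sep = "_")
  cache_get(key, function() {
    nb <- enumerate_search_space(k)$size
    n <- 2^k
    m <- matrix(NA_real_, nb, n)
    for (s1 in 0:(n - 1)) {
      minN <- rep(Inf, nb)
      for (S in path_state_sets(s1, k, regime, np))
        minN <- pmin(minN, space_pattern_counts(k, S))
      m[, s1 + 1] <- minN
    }
    m
  })
}

#' Probability of unambiguity for (multi-)step perturbation experiments
#'
#' Implements the unambiguity average and its multi-step generalization.
#' For every search-space function and every initial state that is fully
#' visible under the chosen integration, the experiment contributes
#' `1 / min N^cmn`, where the minimum is taken over all perturbation paths
#' of `n_p` initial states chained through the SPSD (each step performs
#' all available perturbations and records every destination output; path
#' choice only selects the next initial state). The average over all
#' functions and all 2^k initial states is
#' \deqn{P_{ua} = \frac{1}{2^k N_B(k)} \sum_b \sum_s
#'       \frac{I(\textrm{s fully visible})}{\min N^{cmn}_{k,b,s}}.}
#' With `n_p = 1` this is the single-step formula exactly. Under regime
#' `"D"` paths can only descend and exhaust at state 0, so `n_p` beyond `k`
#' adds nothing and is rejected (see `Details`).
#'
#' @inheritParams visibility_probability
#' @param n_p number of perturbation steps (initial states) per experiment.
#' @return An object of class `ambiguity_result`: list with `k`, `regime`,
#'   `integration`, `n_p`, `P_ua`, `n_functions`, and `min_common`
#'   (matrix of per-function, per-state minimal ambiguity counts).
#' @examples
#' unambiguity_probability(2, "DO", "TX_CIS_PPI", 1)$P_ua # 0.8
#' @export
unambiguity_probability <- function(k, regime = "DO", integration = "TX",
                                    n_p = 1) {
  k <- check_k(k)
  regime <- match_arg_regime(regime)
  integration <- match_arg_integration(integration)
  if (n_p < 1 || n_p != floor(n_p))
    stop("`n_p` must be a positive integer", call. = FALSE)
  if (regime == "D" && n_p > k)
    stop("under regime D a path of knock-downs from the top state reaches ",
         "state 0 after k = ", k, " steps and no further perturbation is ",
         "possible; n_p = ", n_p, " is undefined", call. = FALSE)
  v <- space_visibility(k, regime, integration)
  minN <- space_min_common(k, regime, n_p)
  nb <- nrow(minN)
  P <- sum((1 / minN)[v$gate]) / (2^k * nb)
  structure(list(k = k, regime = regime, integration = integration,
                 n_p = n_p, P_ua = P, n_functions = nb, min_common = minN),
            class = "ambiguity_result")
}

#' @export
print.ambiguity_result <- function(x, ...) {
  cat(sprintf("<P_ua = %.6g | k = %d, %s, %s, n_p = %d, %d functions>\n",
              x$P_ua, x$k, x$regime, x$integration, x$n_p, x$n_functions))
  invisible(x)
}

#' Mean ambiguity count of single-step experiments
#'
#' Average of N^cmn (the number of search-space functions sharing the
#' observed transitions of a single-step experiment) over the averaging
#' set: for regime `"D"` only the top state `2^k - 1` is considered; for
#' `"DO"` all states. By default the average is restricted to fully
#' visible (function, state) pairs, matching the gate of the unambiguity
#' average; set `fully_visible_only = FALSE` for the unrestricted mean.
#'
#' @inheritParams visibility_probability
#' @param fully_visible_only restrict to fully visible initial states?
#' @return The mean count (>= 1; the generating function always matches).
#' @export
mean_common_count <- function(k, regime = "DO", integration = "TX",
                              fully_visible_only = TRUE) {
  k <- check_k(k)
  regime <- match_arg_regime(regime)
  integration <- match_arg_integration(integration)
  v <- space_visibility(k, regime, integration)
  N <- space_min_common(k, regime, 1)
  states <- if (regime == "D") 2^k else 1:2^k
  sel <- if (fully_visible_only) v$gate[, states, drop = FALSE]
         else matrix(TRUE, nrow(N), length(states))
  mean(N[, states, drop = FALSE][sel])
}

#' Unambiguity ratio tables across integration modes and regimes
#'
#' Reproduces the two headline comparisons of the exhaustive analysis:
#' \describe{
#'   \item{`integration_gain`}{per (k, regime, integration): the mean over
#'     step counts of `P_ua(regime+X, n_p) / P_ua(regime+TX, n_p)` -- how
#'     much ambiguity multi-omics evidence removes.}
#'   \item{`regime_ratio`}{per (k, n_p, integration):
#'     `P_ua(DO+X, n_p) / P_ua(D+X, n_p)` -- how much richer DO
#'     experiments are than knock-down-only ones.}
#' }
#' A knock-down-only experiment with more than k steps is operationally
#' the k-step experiment (paths exhaust at state 0), so under the default
#' `np_policy = "saturate"` regime-D entries with `n_p > k` reuse the
#' `n_p = k` value (flagged by the `saturated` column); with
#' `np_policy = "feasible"` they are `NA` and the `integration_gain`
#' average runs over `n_p <= k` only.
#'
#' @param k_list numbers of inputs (any of 2..4; 4 is the slow one).
#' @param n_p_max largest step count (default 4).
#' @param np_policy `"saturate"` or `"feasible"` (see above).
#' @return List of two data frames, `integration_gain` and `regime_ratio`.
#' @export
ratio_tables <- function(k_list = 2:3, n_p_max = 4,
                         np_policy = c("saturate", "feasible")) {
  np_policy <- match.arg(np_policy)
  pua <- function(k, regime, X, np) {
    if (regime == "D" && np > k) {
      if (np_policy == "feasible") return(NA_real_)
      np <- k
    }
    unambiguity_probability(k, regime, X, np)$P_ua
  }
  ints <- c("TX", "TX_PPI", "TX_CIS_PPI")
  rr <- expand.grid(k = k_list, n_p = seq_len(n_p_max), integration = ints,
                    stringsAsFactors = FALSE)
  rr$ratio <- NA_real_
  rr$saturated <- rr$n_p > rr$k
  for (r in seq_len(nrow(rr))) {
    num <- pua(rr$k[r], "DO", rr$integration[r], rr$n_p[r])
    den <- pua(rr$k[r], "D", rr$integration[r], rr$n_p[r])
    rr$ratio[r] <- num / den
  }
  ig <- expand.grid(k = k_list, regime = c("D", "DO"),
                    integration = ints[-1], stringsAsFactors = FALSE)
  ig$mean_ratio <- NA_real_
  for (r in seq_len(nrow(ig))) {
    nps <- seq_len(n_p_max)
    if (np_policy == "feasible" && ig$regime[r] == "D")
      nps <- seq_len(min(ig$k[r], n_p_max))
    vals <- vapply(nps, function(np)
      pua(ig$k[r], ig$regime[r], ig$integration[r], np) /
        pua(ig$k[r], ig$regime[r], "TX", np), numeric(1))
    ig$mean_ratio[r] <- mean(vals)
  }
  list(integration_gain = ig, regime_ratio = rr)
}
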