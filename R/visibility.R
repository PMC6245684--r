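# Vectorized visibility engine over a whole search space.
#
# For every function in the k-input search space and every state s it
# computes N[b, s]: the number of visible out-edges of s in the SPSD of
# F_b under (regime, integration), and gate[b, s]: whether s is fully
# visible (the effect of all k regulators evidenced from s). The single-
# diagram rules in build_spsd() are the specification; this engine is the
# array form used by the exhaustive analyses, and the test suite checks
# the two against each other.
space_visibility <- function(k, regime, integration) {
  regime <- match_arg_regime(regime)
  integration <- match_arg_integration(integration)
  key <- paste("vis", k, regime, integration, sep = "_")
  cache_get(key, function() {
    O <- space_outputs(k)
    nb <- nrow(O)
    n <- 2^k
    # R1 visibility per (state, rf): list of logical vectors over functions
    r1 <- vector("list", n * k)
    has_edge <- matrix(FALSE, n, k)
    for (s in 0:(n - 1)) {
      for (i in seq_len(k)) {
        has <- regime == "DO" || state_bit(s, i, k) == 1L
        has_edge[s + 1, i] <- has
        r1[[s * k + i]] <- if (has) O[, s + 1] != O[, flip_state(s, i, k) + 1]
                           else rep(FALSE, nb)
      }
    }
    vis <- r1
    if (integration == "TX_PPI") {
      for (s in 0:(n - 1)) {
        for (i in seq_len(k)) {
          if (!has_edge[s + 1, i] || state_bit(s, i, k) != 1L) next
          up <- rep(FALSE, nb)
          for (j in setdiff(seq_len(k), i)) {
            if (state_bit(s, j, k) == 1L && has_edge[s + 1, j])
              up <- up | r1[[s * k + j]]
          }
          vis[[s * k + i]] <- r1[[s * k + i]] | up
        }
      }
    } else if (integration == "TX_CIS_PPI") {
      for (s in 0:(n - 1)) for (i in seq_len(k)) {
        if (has_edge[s + 1, i]) vis[[s * k + i]] <- rep(TRUE, nb)
      }
    }
    N <- matrix(0L, nb, n)
    for (s in 0:(n - 1)) {
      acc <- integer(nb)
      for (i in seq_len(k)) acc <- acc + vis[[s * k + i]]
      N[, s + 1] <- acc
    }
    gate <- if (integration == "TX_CIS_PPI") matrix(TRUE, nb, n) else N == k
    list(N = N, gate = gate)
  })
}

edge_total <- function(k, regime) {
  kprime <- if (regime == "D") k / 2 else k
  kprime * 2^k
}

#' Probability of visibility over the whole search space
#'
#' Average fraction of visible transition edges in the SPSD, over all
#' non-degenerate k-input functions and all states:
#' \deqn{P_v = \frac{1}{N_B(k)} \sum_{b \in S_B(k)}
#'       \frac{1}{k' 2^k} \sum_{s} N_{k,b,s},}
#' with k' = k/2 for regime `"D"` and k for `"DO"` (the total edge count of
#' the diagram is k' 2^k). Sums are exact integers; the single final
#' division is the only floating-point step.
#'
#' @param k number of inputs (2..4 analyzed).
#' @param regime `"DO"` or `"D"`.
#' @param integration `"TX"`, `"TX_PPI"` or `"TX_CIS_PPI"`.
#' @return `P_v` in [0, 1]; exactly 1 under `TX_CIS_PPI`.
#' @export
visibility_probability <- function(k, regime = "DO", integration = "TX") {
  k <- check_k(k)
  regime <- match_arg_regime(regime)
  v <- space_visibility(k, regime, integration)
  sum(v$N) / (nrow(v$N) * edge_total(k, regime))
}

#' Per-state probability of full visibility
#'
#' Fraction of search-space functions for which state `s` is fully visible
#' (the effects of all k regulators are evidenced from `s`). Under regime
#' `"D"` with `TX` or `TX_PPI` integration only the top state `2^k - 1` can
#' be fully visible; under `TX_CIS_PPI` every state of every function is.
#'
#' @inheritParams visibility_probability
#' @return Named numeric vector over states `0..2^k-1`.
#' @export
full_visibility_by_state <- function(k, regime = "DO", integration = "TX") {
  k <- check_k(k)
  v <- space_visibility(k, regime, integration)
  out <- colMeans(v$gate)
  names(out) <- 0:(2^k - 1)
  out
}

#' Overall probability of full visibility
#'
#' Mean of the per-state full-visibility probabilities over all 2^k states.
#'
#' @inheritParams visibility_probability
#' @return `P_fv` in [0, 1].
#' @export
full_visibility_probability <- function(k, regime = "DO", integration = "TX") {
  mean(full_visibility_by_state(k, regime, integration))
}

#' Tabulate visibility results across settings
#'
#' @param k_list numbers of inputs to analyze.
#' @param regimes perturbation regimes.
#' @param integrations integration modes.
#' @return Data frame with one row per (k, regime, integration):
#'   `P_v`, `P_fv`, and `P_fv_top` (the top state's full visibility).
#' @export
visibility_summary <- function(k_list = 2:4, regimes = c("D", "DO"),
                               integrations = c("TX", "TX_PPI", "TX_CIS_PPI")) {
  grid <- expand.grid(k = k_list, regime = regimes, integration = integrations,
                      stringsAsFactors = FALSE)
  grid$P_v <- NA_real_; grid$P_fv <- NA_real_; grid$P_fv_top <- NA_real_
  for (r in seq_len(nrow(grid))) {
    fv <- full_visibility_by_state(grid$k[r], grid$regime[r], grid$integration[r])
    grid$P_v[r] <- visibility_probability(grid$k[r], grid$regime[r], grid$integration[r])
    grid$P_fv[r] <- mean(fv)
    grid$P_fv_top[r] <- fv[length(fv)]
  }
  grid
}
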