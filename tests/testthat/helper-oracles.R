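# Independent oracles: deliberately slow, loop-based implementations that
# share no code path with the package's vectorized engines.

oracle_bit <- function(s, i, k) (s %/% 2^(k - i)) %% 2

oracle_decode <- function(b, k) {
  n <- 2^k
  vapply(0:(n - 1), function(s) (b %/% 2^(n - 1 - s)) %% 2, numeric(1))
}

oracle_effective <- function(b, k) {
  out <- oracle_decode(b, k)
  eff <- integer(0)
  for (i in 1:k) {
    for (s in 0:(2^k - 1)) {
      d <- bitwXor(s, 2^(k - i))
      if (out[s + 1] != out[d + 1]) { eff <- c(eff, i); break }
    }
  }
  eff
}

# brute-force consistency count by decoding every candidate
oracle_consistent <- function(obs_states, obs_outputs, k) {
  count <- 0
  for (b in 0:(2^(2^k) - 1)) {
    out <- oracle_decode(b, k)
    if (length(oracle_effective(b, k)) != k) next
    if (all(out[obs_states + 1] == obs_outputs)) count <- count + 1
  }
  count
}

# closed-form oracle for the top state under knock-down + PPI integration:
# all k knock-down edges of the top state become visible iff at least one
# is R1-visible, i.e. iff the outputs are not constant over the states with
# popcount >= k - 1.
oracle_top_state_d_ppi <- function(k) {
  sp <- enumerate_search_space(k)
  near_top <- which(vapply(0:(2^k - 1), function(s)
    sum(oracle_bit(s, 1:k, k)) >= k - 1, logical(1))) - 1L
  hits <- vapply(sp$indices, function(b) {
    out <- oracle_decode(b, k)
    length(unique(out[near_top + 1])) > 1
  }, logical(1))
  mean(hits)
}

gal_records <- function() {
  read_perturbation_records(
    system.file("extdata", "gal_records.tsv", package = "spsdinfer")
  )
}
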