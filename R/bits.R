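# Bit conventions used throughout the package:
#   * a state number s in 0..2^k-1 encodes the regulator tuple
#     RF_1 RF_2 ... RF_k with RF_1 as the most significant bit
#     (state 2 at k = 2 is the tuple 10);
#   * a function index b in 0..2^(2^k)-1 encodes the truth-table output
#     column with state 0 as the most significant bit.
# Everything else in the package inherits these two conventions.

state_bit <- function(s, i, k) bitwAnd(bitwShiftR(as.integer(s), k - i), 1L)

flip_state <- function(s, i, k) bitwXor(as.integer(s), bitwShiftL(1L, k - i))

popcount <- function(s) {
  s <- as.integer(s)
  vapply(s, function(x) sum(bitwAnd(bitwShiftR(x, 0:30), 1L)), integer(1))
}

state_bits <- function(s, k) {
  vapply(seq_len(k), function(i) state_bit(s, i, k), integer(1))
}

# destinations of all single perturbations available from s under a regime
perturbation_destinations <- function(s, k, regime) {
  keep <- if (regime == "D") state_bits(s, k) == 1L else rep(TRUE, k)
  which_rf <- which(keep)
  vapply(which_rf, function(i) flip_state(s, i, k), integer(1))
}

match_arg_regime <- function(regime) {
  match.arg(toupper(regime), c("DO", "D"))
}

match_arg_integration <- function(integration) {
  x <- toupper(gsub("[+-]", "_", integration))
  x <- switch(x,
    "TX" = "TX", "TRANSCRIPTOME" = "TX",
    "PPI" = "TX_PPI", "TX_PPI" = "TX_PPI",
    "CIS" = "TX_CIS_PPI", "CIS_PPI" = "TX_CIS_PPI", "TX_CIS_PPI" = "TX_CIS_PPI",
    stop("unknown integration mode '", integration,
         "'; use one of 'TX', 'TX_PPI', 'TX_CIS_PPI'", call. = FALSE)
  )
  x
}

check_k <- function(k, max_warn = 4L) {
  if (!is.numeric(k) || length(k) != 1L || k != as.integer(k) || k < 1L)
    stop("`k` must be a single integer >= 1", call. = FALSE)
  k <- as.integer(k)
  if (k > max_warn)
    warning("k = ", k, " implies enumerating 2^", 2^k,
            " truth tables; expect this to be very expensive", call. = FALSE)
  k
}
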