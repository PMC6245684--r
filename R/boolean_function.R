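#' k-input Boolean functions indexed by their truth-table column
#'
#' A Boolean regulatory function with `k` regulator inputs is represented by
#' its truth table: `outputs[s + 1]` is the target-gene state produced by the
#' regulator tuple with state number `s` (RF_1 is the most significant bit of
#' `s`). The decimal index `b` of the function is the output column read with
#' state 0 as the most significant bit, so at `k = 2` the index 8 is the
#' table 1,0,0,0 over the states 00, 01, 10, 11 (the NOR gate
#' `!RF1 & !RF2`).
#'
#' @param outputs integer vector of 2^k values in \{0, 1\}, the truth-table
#'   output column ordered by state number.
#' @param k number of regulator inputs; inferred from `outputs` if missing.
#' @return An object of class `boolean_function` with fields `k`, `b` and
#'   `outputs`.
#' @seealso [decode_index()], [effective_inputs()], [reduce_to_essential()]
#' @examples
#' boolean_function(c(0, 0, 0, 1)) # the AND gate, b = 1
#' @export
boolean_function <- function(outputs, k = NULL) {
  outputs <- as.integer(outputs)
  if (is.null(k)) k <- as.integer(round(log2(length(outputs))))
  if (k < 0L || length(outputs) != 2^k || !all(outputs %in% c(0L, 1L)))
    stop("`outputs` must be 2^k values in {0, 1}", call. = FALSE)
  b <- sum(outputs * 2^((2^k - 1):0))
  structure(list(k = k, b = b, outputs = outputs), class = "boolean_function")
}

#' Decode a function index into its truth table
#'
#' Inverse of the indexing convention: the output at state `s` is binary
#' digit `2^k - 1 - s` of `b` (state 0 is the most significant digit).
#' `decode_index(encode_index(f), k)` is the identity.
#'
#' @param b function index, `0 <= b <= 2^(2^k) - 1`.
#' @param k number of inputs (1..4 analyzed; larger values warn).
#' @return A [boolean_function()].
#' @examples
#' decode_index(8, 2)$outputs  # 1 0 0 0
#' decode_index(22, 3)$outputs # 1 exactly at states 3, 5, 6
#' @export
decode_index <- function(b, k) {
  k <- check_k(k)
  if (!is.numeric(b) || length(b) != 1L || b != floor(b) || b < 0 || b > 2^(2^k) - 1)
    stop("function index `b` must be an integer in [0, ", 2^(2^k) - 1,
         "] for k = ", k, call. = FALSE)
  n <- 2^k
  outputs <- as.integer(floor(b / 2^((n - 1):0)) %% 2)
  structure(list(k = k, b = b, outputs = outputs), class = "boolean_function")
}

#' @rdname decode_index
#' @param f a `boolean_function`.
#' @export
encode_index <- function(f) {
  stopifnot(inherits(f, "boolean_function"))
  f$b
}

#' Inputs that actually influence a Boolean function
#'
#' Input `i` is effective when there is at least one regulator state whose
#' output changes if bit `i` is flipped. Functions in which some input is
#' ineffective are degenerate: they belong to a smaller-`k` function family
#' (the 3-input function with index 60 is the 2-input XOR with a silent third
#' input) and are excluded from every search space.
#'
#' @param f a [boolean_function()].
#' @return Increasing integer vector of effective input positions (1-based).
#' @examples
#' effective_inputs(decode_index(60, 3)) # 1 2
#' effective_inputs(decode_index(0, 2))  # integer(0): constant
#' @export
effective_inputs <- function(f) {
  stopifnot(inherits(f, "boolean_function"))
  k <- f$k
  if (k == 0L) return(integer(0))
  eff <- logical(k)
  for (i in seq_len(k)) {
    for (s in 0:(2^k - 1)) {
      if (state_bit(s, i, k) == 0L &&
          f$outputs[s + 1] != f$outputs[flip_state(s, i, k) + 1]) {
        eff[i] <- TRUE
        break
      }
    }
  }
  which(eff)
}

#' @rdname effective_inputs
#' @export
is_degenerate <- function(f) length(effective_inputs(f)) < f$k

#' Project a Boolean function onto its effective inputs
#'
#' Drops ineffective inputs while preserving the order of the remaining
#' ones, so the reduced function agrees with `f` on every state. Constants
#' reduce to a designated 0-input form (`k = 0`, a single output bit) and
#' are flagged by the `constant` attribute.
#'
#' @param f a [boolean_function()].
#' @return A `boolean_function` over `length(effective_inputs(f))` inputs.
#'   The attribute `inputs` records which original inputs were kept.
#' @examples
#' reduce_to_essential(decode_index(60, 3))$b # 6: XOR of inputs 1 and 2
#' @export
reduce_to_essential <- function(f) {
  stopifnot(inherits(f, "boolean_function"))
  eff <- effective_inputs(f)
  kk <- length(eff)
  if (kk == f$k) {
    attr(f, "inputs") <- eff
    return(f)
  }
  if (kk == 0L) {
    out <- structure(list(k = 0L, b = f$outputs[1], outputs = f$outputs[1]),
                     class = "boolean_function")
    attr(out, "inputs") <- integer(0)
    attr(out, "constant") <- TRUE
    return(out)
  }
  outputs <- integer(2^kk)
  for (sr in 0:(2^kk - 1)) {
    s <- 0L # embed the reduced state with ineffective inputs held at 0
    for (j in seq_len(kk)) {
      if (state_bit(sr, j, kk) == 1L) s <- flip_state(s, eff[j], f$k)
    }
    outputs[sr + 1] <- f$outputs[s + 1]
  }
  out <- boolean_function(outputs, kk)
  attr(out, "inputs") <- eff
  out
}

#' Canonical sum-of-products display of a Boolean function
#'
#' Emits the minterm expansion over inputs named `RF1..RFk` (no logic
#' minimization is attempted). Constants print as `0` or `1`.
#'
#' @param f a [boolean_function()].
#' @return A single character string.
#' @examples
#' as_minterm_string(decode_index(2, 2)) # "RF1*~RF2"
#' @export
as_minterm_string <- function(f) {
  stopifnot(inherits(f, "boolean_function"))
  if (f$k == 0L) return(as.character(f$outputs[1]))
  ones <- which(f$outputs == 1L) - 1L
  if (length(ones) == 0L) return("0")
  if (length(ones) == 2^f$k) return("1")
  terms <- vapply(ones, function(s) {
    lits <- vapply(seq_len(f$k), function(i) {
      if (state_bit(s, i, f$k) == 1L) paste0("RF", i) else paste0("~RF", i)
    }, character(1))
    paste(lits, collapse = "*")
  }, character(1))
  paste(terms, collapse = " + ")
}

#' JSON record for a Boolean function
#'
#' @param f a [boolean_function()].
#' @return JSON text with fields `k`, `b`, `outputs`, `effective_inputs`.
#' @export
boolean_function_to_json <- function(f) {
  stopifnot(inherits(f, "boolean_function"))
  jsonlite::toJSON(
    list(k = f$k, b = f$b, outputs = f$outputs,
         effective_inputs = effective_inputs(f)),
    auto_unbox = TRUE
  )
}

#' @rdname boolean_function_to_json
#' @param json JSON text produced by `boolean_function_to_json()`.
#' @export
boolean_function_from_json <- function(json) {
  rec <- jsonlite::fromJSON(json)
  boolean_function(rec$outputs, rec$k)
}

#' @export
format.boolean_function <- function(x, ...) {
  if (x$k == 0L) return(sprintf("<constant Boolean function: %d>", x$outputs[1]))
  sprintf("<Boolean function F_%d^%d: %s>", x$b, x$k, as_minterm_string(x))
}

#' @export
print.boolean_function <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
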