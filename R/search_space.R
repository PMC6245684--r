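# package-level cache for enumeration products (search spaces, output
# matrices, visibility gates); keyed by character ids, lives for the session
.spsd_cache <- new.env(parent = emptyenv())

cache_get <- function(key, compute) {
  v <- .spsd_cache[[key]]
  if (is.null(v)) {
    v <- compute()
    .spsd_cache[[key]] <- v
  }
  v
}

# truth-table output matrix: one row per index in `bs`, one column per state
outputs_matrix <- function(k, bs) {
  n <- 2^k
  m <- matrix(0L, length(bs), n)
  for (s in 0:(n - 1)) m[, s + 1] <- as.integer(floor(bs / 2^(n - 1 - s)) %% 2)
  m
}

# logical matrix [length(bs), k]: is input i effective for each function
effective_matrix <- function(O, k) {
  n <- 2^k
  eff <- matrix(FALSE, nrow(O), k)
  for (i in seq_len(k)) {
    for (s in 0:(n - 1)) {
      if (state_bit(s, i, k) == 0L) {
        d <- flip_state(s, i, k)
        eff[, i] <- eff[, i] | (O[, s + 1] != O[, d + 1])
      }
    }
  }
  eff
}

#' Closed-form size of the non-degenerate function space
#'
#' Number of k-input Boolean functions in which every input is effective,
#' by inclusion-exclusion over the inputs forced to be silent:
#' \deqn{N_B(k) = \sum_{j=0}^{k} (-1)^j \binom{k}{j} 2^{2^{k-j}}.}
#' Serves as an independent cross-check of [enumerate_search_space()].
#'
#' @param k number of inputs.
#' @return Integer count (10, 218, 64594 for k = 2, 3, 4).
#' @export
search_space_size <- function(k) {
  k <- check_k(k, max_warn = .Machine$integer.max)
  j <- 0:k
  sum((-1)^j * choose(k, j) * 2^(2^(k - j)))
}

#' Enumerate the search space of non-degenerate Boolean functions
#'
#' Lists, in increasing index order, every k-input Boolean function whose
#' inputs are all effective. Degenerate functions (constants, functions
#' ignoring at least one regulator) are excluded; they are counted in the
#' space of a smaller k. The enumerated size is checked against the
#' inclusion-exclusion closed form.
#'
#' @param k number of inputs (1..4 analyzed; larger values warn about cost).
#' @param filter optional predicate `function(b) logical` restricting the
#'   space further, e.g. to a biologically motivated subset.
#' @return An object of class `search_space` with fields `k`, `indices`
#'   and `size`.
#' @examples
#' enumerate_search_space(2)$size # 10
#' @export
enumerate_search_space <- function(k, filter = NULL) {
  k <- check_k(k)
  key <- paste0("space_", k)
  sp <- cache_get(key, function() {
    bs <- 0:(2^(2^k) - 1)
    O <- outputs_matrix(k, bs)
    keep <- rowSums(effective_matrix(O, k)) == k
    indices <- bs[keep]
    stopifnot(length(indices) == search_space_size(k))
    structure(list(k = k, indices = indices, size = length(indices)),
              class = "search_space")
  })
  if (!is.null(filter)) {
    keep <- vapply(sp$indices, filter, logical(1))
    sp$indices <- sp$indices[keep]
    sp$size <- length(sp$indices)
  }
  sp
}

# cached output matrix restricted to the (unfiltered) search space
space_outputs <- function(k) {
  cache_get(paste0("space_outputs_", k), function() {
    outputs_matrix(k, enumerate_search_space(k)$indices)
  })
}

#' @export
print.search_space <- function(x, ...) {
  cat(sprintf("<search space: %d non-degenerate Boolean functions with k = %d inputs>\n",
              x$size, x$k))
  invisible(x)
}
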