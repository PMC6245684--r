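#' Read a perturbation-experiment record table
#'
#' The table is TSV with one row per observed condition of the regulators:
#' the first k columns are the regulator states (0/1, column order fixes
#' the regulator order and column names the regulator names), followed by
#' `target` (observed target state), `label` (free-text description of the
#' perturbation) and `condition` (free-text experimental condition, e.g.
#' carbon source).
#'
#' @param path TSV file path.
#' @return Data frame of records with attribute `regulators` (the
#'   regulator column names, in order).
#' @export
read_perturbation_records <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("target", "label", "condition")
  if (!all(required %in% names(df)))
    stop("record table must contain columns ", paste(required, collapse = ", "),
         call. = FALSE)
  regs <- setdiff(names(df), required)
  if (length(regs) == 0L) stop("no regulator columns found", call. = FALSE)
  for (cn in c(regs, "target")) {
    if (!all(df[[cn]] %in% 0:1))
      stop("column '", cn, "' must be 0/1", call. = FALSE)
  }
  attr(df, "regulators") <- regs
  df
}

#' @rdname read_perturbation_records
#' @param records a record data frame.
#' @param condition keep only rows with this condition (`NULL`: all).
#' @return `records_to_observations()`: an [observation_set()] over the
#'   regulator states, with conflicting duplicate rows rejected.
#' @export
records_to_observations <- function(records, condition = NULL) {
  regs <- attr(records, "regulators")
  if (is.null(regs)) regs <- setdiff(names(records), c("target", "label", "condition"))
  if (!is.null(condition)) records <- records[records$condition == condition, , drop = FALSE]
  if (nrow(records) == 0L)
    stop("no records", if (!is.null(condition)) paste0(" for condition '", condition, "'"),
         call. = FALSE)
  k <- length(regs)
  states <- as.integer(as.matrix(records[regs]) %*% 2^((k - 1):0))
  for (s in unique(states[duplicated(states)])) {
    tv <- unique(records$target[states == s])
    if (length(tv) > 1L)
      stop("conflicting target states for regulator state ", s,
           " (rows ", paste(which(states == s), collapse = ", "), ")",
           call. = FALSE)
  }
  observation_set(k, states, records$target)
}

#' Propose candidate regulators from cis-element and PPI evidence
#'
#' Rule R2 seeds the candidate list with every gene that has a binding
#' site at the target (direct evidence). Rule R3 then expands it to a
#' fixpoint over the protein-interaction graph: any protein interacting
#' with an already-accepted regulator is added as an indirect, putative
#' regulator (optimistic: a PPI alone never proves regulation, so with no
#' cis anchor the list stays empty).
#'
#' @param cis_regulators character vector of directly bound regulators.
#' @param ppi_edges two-column data frame (or matrix) of unordered protein
#'   pairs.
#' @return Data frame with columns `regulator` and `evidence`
#'   (`"cis"`/`"ppi"`), cis entries first, PPI additions in discovery order.
#' @examples
#' candidate_regulators("GAL4", data.frame(a = "GAL4", b = "GAL80"))
#' @export
candidate_regulators <- function(cis_regulators, ppi_edges = NULL) {
  cis_regulators <- unique(as.character(cis_regulators))
  out <- data.frame(regulator = cis_regulators,
                    evidence = rep("cis", length(cis_regulators)),
                    stringsAsFactors = FALSE)
  if (is.null(ppi_edges) || NROW(ppi_edges) == 0L) return(out)
  ppi <- as.matrix(ppi_edges)[, 1:2, drop = FALSE]
  mode(ppi) <- "character"
  repeat {
    known <- out$regulator
    touch <- ppi[, 1] %in% known | ppi[, 2] %in% known
    partners <- unique(c(ppi[touch, 1], ppi[touch, 2]))
    new <- setdiff(partners, known)
    if (length(new) == 0L) break
    out <- rbind(out, data.frame(regulator = new,
                                 evidence = rep("ppi", length(new)),
                                 stringsAsFactors = FALSE))
  }
  out
}

#' @rdname candidate_regulators
#' @param path two-column TSV (`regulator`, `target`) or SIF-like pair list.
#' @export
read_evidence_pairs <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Identify the Boolean function behind perturbation records
#'
#' Builds an observation set from the records and counts the consistent
#' functions among ALL 2^(2^k) truth tables -- degenerate ones included,
#' because a candidate regulator pool assembled from cis/PPI evidence may
#' be over-complete, in which case the true function simply ignores the
#' spurious input (reported via its essential-input reduction). When the
#' records cover all 2^k states the function is unique.
#'
#' @param records a record data frame ([read_perturbation_records()]).
#' @param condition optional condition filter.
#' @return List with `k`, `count`, `indices` (consistent function
#'   indices), and when the function is unique: `fn`
#'   ([boolean_function()]), `effective_inputs`, `reduced`
#'   (its essential reduction) and `regulators` (names, when available).
#' @examples
#' path <- system.file("extdata", "gal_records.tsv", package = "spsdinfer")
#' identify_function(read_perturbation_records(path), "glucose")$fn
#' @export
identify_function <- function(records, condition = NULL) {
  regs <- attr(records, "regulators")
  obs <- records_to_observations(records, condition)
  k <- obs$k
  if (k > 4L) stop("identification over all truth tables supports k <= 4",
                   call. = FALSE)
  bs <- 0:(2^(2^k) - 1)
  O <- outputs_matrix(k, bs)
  st <- as.integer(names(obs$observed))
  ok <- rowSums(O[, st + 1, drop = FALSE] ==
                  matrix(obs$observed, nrow(O), length(st), byrow = TRUE)) ==
        length(st)
  res <- list(k = k, count = sum(ok), indices = bs[ok], regulators = regs)
  if (res$count == 1L) {
    fn <- decode_index(res$indices, k)
    res$fn <- fn
    res$effective_inputs <- effective_inputs(fn)
    res$reduced <- reduce_to_essential(fn)
  }
  res
}

#' Simulate a multi-step perturbation experiment
#'
#' Fixture generator: runs the multi-step protocol on a hidden function.
#' Each step records the (unperturbed) initial state and then all
#' available single perturbations; the next initial state is drawn
#' uniformly from the current step's destinations. With `dropout > 0`
#' every non-wild-type record is independently omitted with that
#' probability (the wild-type row always survives). Deterministic for a
#' fixed `seed`.
#'
#' @param hidden_f the generating [boolean_function()].
#' @param wild_type initial (wild-type) regulator state number.
#' @param regime `"DO"` or `"D"`; regime `"D"` with `wild_type = 0` is an
#'   error (nothing can be knocked down).
#' @param n_p number of steps.
#' @param seed integer seed.
#' @param dropout per-record omission probability in [0, 1).
#' @return A record data frame in the [read_perturbation_records()] layout
#'   (regulators named `RF1..RFk`, condition `"simulated"`).
#' @export
simulate_experiment <- function(hidden_f, wild_type, regime = c("DO", "D"),
                                n_p = 1, seed = 1, dropout = 0) {
  stopifnot(inherits(hidden_f, "boolean_function"))
  regime <- match_arg_regime(regime[1])
  k <- hidden_f$k
  if (wild_type < 0 || wild_type >= 2^k)
    stop("invalid wild-type state ", wild_type, call. = FALSE)
  if (regime == "D" && wild_type == 0)
    stop("regime D with wild-type state 0: no regulator can be knocked down",
         call. = FALSE)
  if (dropout < 0 || dropout >= 1)
    stop("`dropout` must lie in [0, 1)", call. = FALSE)
  set.seed(as.integer(seed))
  rows <- list()
  add <- function(s, label, droppable) {
    if (droppable && dropout > 0 && stats::runif(1) < dropout) return(invisible(NULL))
    bits <- state_bits(s, k)
    row <- as.list(bits)
    names(row) <- paste0("RF", seq_len(k))
    row$target <- hidden_f$outputs[s + 1]
    row$label <- label
    row$condition <- "simulated"
    rows[[length(rows) + 1L]] <<- as.data.frame(row, stringsAsFactors = FALSE)
  }
  s <- as.integer(wild_type)
  for (t in seq_len(n_p)) {
    add(s, sprintf("step%d:initial", t), droppable = t > 1)
    dests <- perturbation_destinations(s, k, regime)
    rfs <- if (regime == "D") which(state_bits(s, k) == 1L) else seq_len(k)
    kinds <- ifelse(state_bits(s, k)[rfs] == 1L, "D", "O")
    for (j in seq_along(dests))
      add(dests[j], sprintf("step%d:%s%d", t, kinds[j], rfs[j]), droppable = TRUE)
    if (length(dests) == 0L) break
    s <- if (length(dests) == 1L) dests else sample(dests, 1)
  }
  df <- do.call(rbind, rows)
  attr(df, "regulators") <- paste0("RF", seq_len(k))
  df
}
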