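#' Single-perturbation state diagram (SPSD) of a Boolean function
#'
#' The SPSD of a k-input function has one node per regulator state
#' (2^k nodes) and one directed edge per available single perturbation:
#' a knock-down `D_i` leaves a state whose bit i is 1 (so the destination
#' has a smaller state number), an over-expression `O_i` leaves a state
#' whose bit i is 0. Under regime `"D"` only knock-down edges exist
#' (popcount(s) edges out of state s); under `"DO"` every state has k
#' out-edges. An edge is R1-visible when the perturbation changes the
#' target output, i.e. the outputs of its endpoints differ.
#'
#' Evidence integration upgrades visibility:
#' \describe{
#'   \item{`TX`}{transcriptome only; visibility is R1 alone.}
#'   \item{`TX_PPI`}{an invisible knock-down edge `D_i` out of `s` becomes
#'     `PPI_VISIBLE` when another regulator j is also 1 in `s` and its own
#'     perturbation edge out of `s` is R1-visible: both partner proteins are
#'     present in the unperturbed state, so a protein-protein interaction
#'     between RF_i and the proven regulator RF_j can be observed (rule R3).
#'     Upgrades are a single pass from R1 visibility; over-expression edges
#'     are never upgraded because RF_i is absent before the perturbation.}
#'   \item{`TX_CIS_PPI`}{with complete cis-element and PPI knowledge every
#'     regulator is evidenced a priori (rules R2+R3): all edges are
#'     `CIS_VISIBLE` and every state is fully visible, in both regimes.}
#' }
#'
#' A state is *fully visible* when the effect of all k regulators is
#' evidenced from it: under `TX`/`TX_PPI` this requires k visible out-edges
#' (under regime `"D"` only the top state 2^k-1 can achieve it); under
#' `TX_CIS_PPI` every state is fully visible.
#'
#' @param f a [boolean_function()].
#' @param regime `"DO"` (knock-down and over-expression) or `"D"`
#'   (knock-down only).
#' @param integration `"TX"`, `"TX_PPI"` or `"TX_CIS_PPI"` (aliases
#'   `"tx"`, `"ppi"`, `"cis-ppi"` are accepted).
#' @return An object of class `spsd`: list with `fn`, `regime`,
#'   `integration`, `nodes` (data frame: `s`, `bits`, `output`), `edges`
#'   (data frame: `source`, `dest`, `kind`, `rf`, `visibility`),
#'   `visible_out_degree` (N_s, indexed by state + 1) and `fully_visible`
#'   (logical per state).
#' @examples
#' spsd <- build_spsd(decode_index(4, 2), "DO", "TX")
#' sum(spsd$edges$visibility == "INVISIBLE") # 4 of the 8 edges
#' @export
build_spsd <- function(f, regime = c("DO", "D"),
                       integration = c("TX", "TX_PPI", "TX_CIS_PPI")) {
  stopifnot(inherits(f, "boolean_function"))
  regime <- match_arg_regime(regime[1])
  integration <- match_arg_integration(integration[1])
  k <- f$k
  n <- 2^k
  src <- integer(0); rf <- integer(0)
  for (s in 0:(n - 1)) {
    bits <- state_bits(s, k)
    keep <- if (regime == "D") which(bits == 1L) else seq_len(k)
    src <- c(src, rep.int(s, length(keep)))
    rf <- c(rf, keep)
  }
  dest <- mapply(flip_state, src, rf, MoreArgs = list(k = k))
  kind <- ifelse(mapply(state_bit, src, rf, MoreArgs = list(k = k)) == 1L, "D", "O")
  r1 <- f$outputs[src + 1] != f$outputs[dest + 1]
  visibility <- ifelse(r1, "R1_VISIBLE", "INVISIBLE")
  edges <- data.frame(source = src, dest = dest, kind = kind, rf = rf,
                      visibility = visibility, stringsAsFactors = FALSE)
  nodes <- data.frame(
    s = 0:(n - 1),
    bits = vapply(0:(n - 1), function(s) paste(state_bits(s, k), collapse = ""),
                  character(1)),
    output = f$outputs,
    stringsAsFactors = FALSE
  )
  out <- structure(
    list(fn = f, regime = regime, integration = integration,
         nodes = nodes, edges = edges,
         visible_out_degree = integer(n), fully_visible = logical(n)),
    class = "spsd"
  )
  if (integration == "TX_PPI") out <- apply_ppi_rule(out)
  if (integration == "TX_CIS_PPI") {
    out$edges$visibility[out$edges$visibility == "INVISIBLE"] <- "CIS_VISIBLE"
  }
  vis <- out$edges$visibility != "INVISIBLE"
  out$visible_out_degree <- vapply(0:(n - 1), function(s)
    sum(vis[out$edges$source == s]), integer(1))
  out$fully_visible <- if (integration == "TX_CIS_PPI") rep(TRUE, n) else
    out$visible_out_degree == k
  out
}

#' Upgrade invisible knock-down edges with protein-interaction evidence
#'
#' Applies rule R3 to an SPSD whose R1 visibility is already assigned: an
#' `INVISIBLE` knock-down edge `D_i` out of state `s` becomes `PPI_VISIBLE`
#' when some other regulator j has bit 1 in `s` (both partner proteins
#' present in the unperturbed state) and j's own perturbation edge out of
#' `s` is `R1_VISIBLE` (j is a proven regulator there). The pass never
#' chains off upgraded edges and never downgrades visibility.
#'
#' @param spsd an `spsd` built with R1 visibility (integration `TX` or
#'   `TX_PPI`).
#' @return The `spsd` with upgraded edge visibilities and recomputed
#'   `visible_out_degree` / `fully_visible`.
#' @export
apply_ppi_rule <- function(spsd) {
  stopifnot(inherits(spsd, "spsd"))
  k <- spsd$fn$k
  e <- spsd$edges
  upgraded <- logical(nrow(e))
  for (idx in which(e$visibility == "INVISIBLE" & e$kind == "D")) {
    s <- e$source[idx]
    i <- e$rf[idx]
    anchors <- which(e$source == s & e$rf != i & e$visibility == "R1_VISIBLE")
    if (any(state_bit(s, e$rf[anchors], k) == 1L)) upgraded[idx] <- TRUE
  }
  e$visibility[upgraded] <- "PPI_VISIBLE"
  spsd$edges <- e
  vis <- e$visibility != "INVISIBLE"
  n <- 2^k
  spsd$visible_out_degree <- vapply(0:(n - 1), function(s)
    sum(vis[e$source == s]), integer(1))
  spsd$fully_visible <- spsd$visible_out_degree == k
  spsd
}

#' @export
print.spsd <- function(x, ...) {
  cat(sprintf("<SPSD of F_%d^%d, regime %s, integration %s>\n",
              x$fn$b, x$fn$k, x$regime, x$integration))
  cat(sprintf("  %d states, %d edges (%d visible)\n",
              nrow(x$nodes), nrow(x$edges),
              sum(x$edges$visibility != "INVISIBLE")))
  invisible(x)
}

#' Serialize an SPSD
#'
#' Writes the diagram as Graphviz DOT (dashed style marks invisible edges,
#' mirroring the usual dashed-arrow drawing), GraphML (via igraph) or JSON
#' (round-trippable with [spsd_from_json()]). Output is byte-stable for a
#' fixed diagram.
#'
#' @param spsd an `spsd`.
#' @param format `"dot"`, `"graphml"` or `"json"`.
#' @param file optional path; when `NULL` the serialization is returned as
#'   a character string.
#' @return The serialized text (invisibly when `file` is given).
#' @export
export_spsd <- function(spsd, format = c("dot", "graphml", "json"), file = NULL) {
  stopifnot(inherits(spsd, "spsd"))
  format <- tolower(format[1])
  if (!format %in% c("dot", "graphml", "json"))
    stop("unknown export format '", format, "'; use dot, graphml or json",
         call. = FALSE)
  txt <- switch(format,
    dot = spsd_to_dot(spsd),
    graphml = spsd_to_graphml(spsd),
    json = spsd_to_json(spsd)
  )
  if (is.null(file)) return(txt)
  writeLines(txt, file, sep = "")
  invisible(txt)
}

spsd_to_dot <- function(spsd) {
  e <- spsd$edges
  lines <- c(
    sprintf("digraph \"F_%d^%d_%s_%s\" {", spsd$fn$b, spsd$fn$k,
            spsd$regime, spsd$integration),
    "  node [shape=Mrecord];",
    sprintf("  s%d [label=\"{%s (%d)|%d}\"];",
            spsd$nodes$s, spsd$nodes$bits, spsd$nodes$s, spsd$nodes$output),
    sprintf("  s%d -> s%d [label=\"%s%d\", style=%s];",
            e$source, e$dest, e$kind, e$rf,
            ifelse(e$visibility == "INVISIBLE", "dashed", "solid")),
    "}"
  )
  paste0(paste(lines, collapse = "\n"), "\n")
}

spsd_to_graphml <- function(spsd) {
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = paste0("s", spsd$edges$source),
                   to = paste0("s", spsd$edges$dest),
                   kind = spsd$edges$kind, rf = spsd$edges$rf,
                   visibility = spsd$edges$visibility),
    directed = TRUE,
    vertices = data.frame(name = paste0("s", spsd$nodes$s),
                          s = spsd$nodes$s, bits = spsd$nodes$bits,
                          output = spsd$nodes$output)
  )
  tf <- tempfile(fileext = ".graphml")
  on.exit(unlink(tf))
  igraph::write_graph(g, tf, format = "graphml")
  paste0(paste(readLines(tf), collapse = "\n"), "\n")
}

spsd_to_json <- function(spsd) {
  obj <- list(
    fn = list(k = spsd$fn$k, b = spsd$fn$b, outputs = spsd$fn$outputs),
    regime = spsd$regime,
    integration = spsd$integration,
    nodes = spsd$nodes,
    edges = spsd$edges
  )
  paste0(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), "\n")
}

#' @rdname export_spsd
#' @param json JSON produced by `export_spsd(..., format = "json")`.
#' @export
spsd_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  f <- boolean_function(obj$fn$outputs, obj$fn$k)
  stopifnot(f$b == obj$fn$b)
  build_spsd(f, obj$regime, obj$integration)
}
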