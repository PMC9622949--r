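#' Cortical network specification
#'
#' A `network_spec` describes the directed source network a Jansen-Rit model
#' is simulated (and inverted) on: the ordered source set, forward and
#' backward edge lists (exact reciprocals of one another), lateral
#' connections between homologous pairs, and the source receiving the
#' exogenous stimulus.
#'
#' @param sources character vector of unique source names.
#' @param forward data.frame with columns `from`, `to`: forward edges.
#' @param lateral_pairs data.frame with columns `a`, `b`: homologous pairs,
#'   connected reciprocally. May have zero rows.
#' @param input_site name of the source that receives the stimulus.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(sources, forward, lateral_pairs = NULL, input_site = sources[[1]]) {
  sources <- as.character(sources)
  if (anyDuplicated(sources)) stop("duplicate source names")
  forward <- as.data.frame(forward, stringsAsFactors = FALSE)
  if (!all(c("from", "to") %in% names(forward))) stop("forward needs columns from, to")
  bad <- setdiff(c(forward$from, forward$to), sources)
  if (length(bad)) stop("unknown source in edges: ", paste(bad, collapse = ", "))
  if (!input_site %in% sources) stop("input_site not a source")
  backward <- data.frame(from = forward$to, to = forward$from, stringsAsFactors = FALSE)
  if (is.null(lateral_pairs)) {
    lateral_pairs <- data.frame(a = character(), b = character(), stringsAsFactors = FALSE)
  }
  if (nrow(lateral_pairs) && length(setdiff(c(lateral_pairs$a, lateral_pairs$b), sources)))
    stop("unknown source in lateral pairs")
  structure(
    list(sources = sources, forward = forward, backward = backward,
         lateral_pairs = lateral_pairs, input_site = input_site,
         n_sources = length(sources)),
    class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat("network_spec:", x$n_sources, "sources,", nrow(x$forward),
      "forward/backward edge pairs,", nrow(x$lateral_pairs),
      "lateral pairs; input at", x$input_site, "\n")
  invisible(x)
}

edge_keys <- function(edges) paste(edges$from, edges$to, sep = "->")

#' The 10-source MSIT task network
#'
#' V1 and dACC plus bilateral ITG, SPL, vlPFC and dlPFC. Forward edges per
#' hemisphere: V1->ITG, ITG->SPL, SPL->vlPFC, SPL->dlPFC, vlPFC->dlPFC,
#' vlPFC->dACC (12 in total); backward edges are their reciprocals; the four
#' homologous pairs (ITG, SPL, vlPFC, dlPFC) are laterally connected. The
#' stimulus enters at V1.
#'
#' @return A [network_spec()] with 10 sources and 12 forward edges.
#' @export
msit_network <- function() {
  hemi <- function(h) {
    p <- function(x) paste0(h, x)
    data.frame(
      from = c("V1", p("ITG"), p("SPL"), p("SPL"), p("vlPFC"), p("vlPFC")),
      to   = c(p("ITG"), p("SPL"), p("vlPFC"), p("dlPFC"), p("dlPFC"), "dACC"),
      stringsAsFactors = FALSE)
  }
  network_spec(
    sources = c("V1", "dACC", "lITG", "rITG", "lSPL", "rSPL",
                "lvlPFC", "rvlPFC", "ldlPFC", "rdlPFC"),
    forward = rbind(hemi("l"), hemi("r")),
    lateral_pairs = data.frame(a = c("lITG", "lSPL", "lvlPFC", "ldlPFC"),
                               b = c("rITG", "rSPL", "rvlPFC", "rdlPFC"),
                               stringsAsFactors = FALSE),
    input_site = "V1")
}

#' Reduced four-source chain network for desk-scale benchmarks
#'
#' A single-hemisphere feedforward chain V1 -> ITG -> SPL -> vlPFC with
#' reciprocal backward edges and no lateral connections. Used by the
#' parameter-recovery, model-recovery and classification benchmarks where a
#' 10-source inversion would be needlessly slow.
#'
#' @return A [network_spec()] with 4 sources and 3 forward edges.
#' @export
chain_network <- function() {
  network_spec(
    sources = c("V1", "ITG", "SPL", "vlPFC"),
    forward = data.frame(from = c("V1", "ITG", "SPL"),
                         to   = c("ITG", "SPL", "vlPFC"),
                         stringsAsFactors = FALSE),
    input_site = "V1")
}
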