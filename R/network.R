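# Directed interspecific communication network: who responds to whose alarm
# calls. Edges run caller -> receiver, weighted by response probability, and
# are retained when the probability reaches a cut-off (0.72 by default).

#' Empirical caller x receiver response-probability matrix
#'
#' The proportion of playback trials in which the receiver responded, per
#' (caller, receiver) pair. Control trials are ignored; conspecific pairs
#' are included only on request. Pairs with no trials are `NA` and listed in
#' the `"missing_pairs"` attribute.
#'
#' @param playbacks playback trial table with `caller`, `receiver`,
#'   `call_kind` and logical `responded`.
#' @param include_conspecific include the diagonal (default `FALSE`).
#' @return matrix P with callers in rows, receivers in columns, entries in
#'   \[0, 1\] or `NA`.
#' @export
response_probability_matrix <- function(playbacks,
                                        include_conspecific = FALSE) {
  d <- playbacks[playbacks$call_kind != "control", , drop = FALSE]
  if (!include_conspecific)
    d <- d[d$call_kind != "conspecific", , drop = FALSE]
  callers <- sort(unique(d$caller))
  receivers <- sort(unique(d$receiver))
  n <- table(factor(d$caller, callers), factor(d$receiver, receivers))
  r <- stats::xtabs(responded ~ factor(caller, callers) +
                      factor(receiver, receivers), data = d)
  P <- matrix(ifelse(n > 0, as.numeric(r) / as.numeric(n), NA_real_),
              length(callers), length(receivers),
              dimnames = list(caller = callers, receiver = receivers))
  miss <- which(is.na(P) & !(outer(callers, receivers, "==") &
                               !include_conspecific), arr.ind = TRUE)
  attr(P, "missing_pairs") <-
    data.frame(caller = callers[miss[, 1]], receiver = receivers[miss[, 2]])
  P
}

#' Build the thresholded directed communication network
#'
#' Creates a directed graph with one node per species and an edge
#' caller -> receiver for every pair whose response probability reaches the
#' cut-off (comparison is `>=`). Edge weight is the response probability;
#' each node carries `in_degree_callers`, the number of species whose alarm
#' calls it responds to above the cut-off (the node-size variable in the
#' usual network figure). Self-loops are excluded unless the probability
#' matrix explicitly contains conspecific entries.
#'
#' @param P caller x receiver probability matrix (entries in \[0, 1\] or
#'   `NA`).
#' @param threshold probability cut-off in \[0, 1\] (default 0.72).
#' @return `igraph` directed graph.
#' @export
build_network <- function(P, threshold = 0.72) {
  if (any(P < 0 | P > 1, na.rm = TRUE)) stop("P entries must lie in [0, 1]")
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  species <- union(rownames(P), colnames(P))
  idx <- which(!is.na(P) & P >= threshold, arr.ind = TRUE)
  edges <- data.frame(from = rownames(P)[idx[, 1]],
                      to = colnames(P)[idx[, 2]],
                      weight = P[idx])
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = species))
  indeg <- igraph::degree(g, mode = "in")
  g <- igraph::set_vertex_attr(g, "in_degree_callers",
                               value = as.numeric(indeg))
  g <- igraph::set_graph_attr(g, "threshold", threshold)
  g
}

#' Pairwise asymmetry of response probabilities
#'
#' For every unordered species pair with both directions defined, the
#' absolute difference |P(a -> b) - P(b -> a)|; 0 for perfectly symmetric
#' communication, 1 for completely one-sided dependence.
#'
#' @param P caller x receiver probability matrix; pairs are evaluated over
#'   the species present in both dimensions (a species that never calls has
#'   no outgoing direction and contributes no pairs).
#' @return data frame `species_a`, `species_b`, `asymmetry` (pairs with a
#'   missing direction omitted).
#' @export
asymmetry_index <- function(P) {
  sp <- intersect(rownames(P), colnames(P))
  if (length(sp) < 2)
    stop("P must share at least two species between callers and receivers")
  P <- P[sp, sp, drop = FALSE]
  out <- list()
  for (a in seq_along(sp)) for (b in seq_len(a - 1L)) {
    pab <- P[a, b]; pba <- P[b, a]
    if (is.na(pab) || is.na(pba)) next
    out[[length(out) + 1L]] <- data.frame(
      species_a = sp[b], species_b = sp[a], asymmetry = abs(pab - pba))
  }
  if (!length(out))
    return(data.frame(species_a = character(0), species_b = character(0),
                      asymmetry = numeric(0)))
  do.call(rbind, out)
}

#' Write / read the communication network as GraphML
#'
#' GraphML round-trips the node set, edge set and edge weights exactly (to
#' numeric print precision); an edge-list CSV is written alongside when
#' `edgelist` is given.
#'
#' @param g `igraph` network from [build_network()].
#' @param path GraphML output path.
#' @param edgelist optional CSV path for a `caller,receiver,weight` table.
#' @return `path`, invisibly.
#' @export
write_network <- function(g, path, edgelist = NULL) {
  igraph::write_graph(g, path, format = "graphml")
  if (!is.null(edgelist)) {
    el <- igraph::as_data_frame(g, what = "edges")
    names(el)[1:2] <- c("caller", "receiver")
    utils::write.csv(el, edgelist, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
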