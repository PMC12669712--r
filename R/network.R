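# Signed protein-interaction networks: parsing, route enumeration from a
# source scaffold to a target effector, alignment scoring against a ranked
# protein list, and hub identification.
#
# Scoring criteria (sets made disjoint, each ranked protein counted once,
# in the lowest applicable criterion):
#   c1 - ranked proteins that are route nodes;
#   c2 - ranked proteins directly linked (one edge, either direction) to a
#        route node;
#   c3 - ranked proteins reachable from a route node via exactly one
#        mediator node (two edges, either direction).
# Route edges follow direction; c2/c3 adjacency ignores it. Edge signs are
# parsed and retained but do not weight the score.

#' Read a SIGNOR-dialect signed edge list
#'
#' Expects a TSV with header columns `entity_a`, `entity_b`, `effect`
#' (extra columns ignored). Effects containing "up-regulates"/"activat"
#' map to activation, "down-regulates"/"inhib" to inhibition, anything
#' else to unknown. Gene symbols are upper-cased, duplicate edges
#' deduplicated and self-loops dropped (count reported via message).
#'
#' @param edge_file path to the TSV.
#' @return directed `igraph` with edge attribute `sign`.
#' @export
read_signor <- function(edge_file) {
  df <- read_tsv(edge_file)
  if (nrow(df) == 0) stop("empty edge file: ", edge_file, call. = FALSE)
  need <- c("entity_a", "entity_b", "effect")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("edge file missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  a <- toupper(trimws(df$entity_a)); b <- toupper(trimws(df$entity_b))
  sign <- map_effect(df$effect)
  self <- a == b
  if (any(self)) {
    message("dropped ", sum(self), " self-loop(s)")
    a <- a[!self]; b <- b[!self]; sign <- sign[!self]
  }
  key <- paste(a, b, sign)
  dup <- duplicated(key)
  edges <- data.frame(from = a[!dup], to = b[!dup], sign = sign[!dup])
  # collapse parallel edges with different signs to one edge carrying the
  # union of signs
  ekey <- paste(edges$from, edges$to)
  if (anyDuplicated(ekey)) {
    agg <- lapply(split(edges$sign, ekey), function(s)
      paste(sort(unique(s)), collapse = "|"))
    first <- !duplicated(ekey)
    edges <- edges[first, ]
    edges$sign <- unlist(agg[paste(edges$from, edges$to)])
  }
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  g
}

map_effect <- function(effect) {
  e <- tolower(as.character(effect))
  out <- rep("unknown", length(e))
  out[grepl("up-regulates|activat", e)] <- "activation"
  out[grepl("down-regulates|inhib", e)] <- "inhibition"
  out
}

#' Enumerate simple directed routes between two proteins
#'
#' All simple directed paths with at most `max_len` edges, in
#' deterministic order (by length, then lexicographic node sequence).
#'
#' @param graph directed `igraph` (e.g. from [read_signor()]).
#' @param source,target node ids (case-insensitive; must differ).
#' @param max_len maximum route length in edges (default 4).
#' @param max_routes cap on the number of returned routes; when hit, the
#'   result carries attribute `truncated = TRUE`.
#' @param require_signs if `"activation"`, restrict route edges to pure
#'   activation edges.
#' @return list of character vectors (node sequences source..target).
#' @export
enumerate_routes <- function(graph, source, target, max_len = 4,
                             max_routes = 10000, require_signs = NULL) {
  source <- toupper(source); target <- toupper(target)
  vs <- igraph::V(graph)$name
  for (v in c(source, target)) {
    if (!v %in% vs) stop("node '", v, "' absent from graph", call. = FALSE)
  }
  if (source == target) stop("source and target must differ", call. = FALSE)
  assert_that(max_len >= 1, "max_len must be >= 1")
  g <- graph
  if (!is.null(require_signs)) {
    keep <- igraph::E(g)[igraph::E(g)$sign == require_signs]
    g <- igraph::subgraph.edges(g, keep, delete.vertices = FALSE)
  }
  paths <- igraph::all_simple_paths(g, from = source, to = target,
                                    mode = "out", cutoff = max_len)
  routes <- lapply(paths, function(p) igraph::V(g)$name[as.integer(p)])
  ord <- order(lengths(routes),
               vapply(routes, paste, "", collapse = "\r"))
  routes <- routes[ord]
  truncated <- length(routes) > max_routes
  if (truncated) routes <- routes[seq_len(max_routes)]
  attr(routes, "truncated") <- truncated
  routes
}

#' Score a route against a ranked protein list
#'
#' @param route character vector of node ids (a valid directed path).
#' @param graph the `igraph` the route lives in.
#' @param ranked ranked protein universe: character vector of ids, or a
#'   ranked data frame with a `protein` column (e.g. from
#'   [rppa_filter_rank()]).
#' @return list `c1`, `c2`, `c3`, `total`, and `members` (the disjoint
#'   protein sets behind each count).
#' @export
score_route <- function(route, graph, ranked) {
  if (is.data.frame(ranked)) ranked <- ranked$protein
  ranked <- unique(toupper(ranked))
  route <- toupper(route)
  vs <- igraph::V(graph)$name
  c1_set <- intersect(ranked, route)
  rest <- setdiff(setdiff(ranked, c1_set), setdiff(ranked, vs))
  c2_set <- character(0); c3_set <- character(0)
  if (length(rest)) {
    d <- igraph::distances(graph, v = rest, to = route, mode = "all")
    dmin <- apply(d, 1, min)
    c2_set <- rest[dmin == 1]
    c3_set <- rest[dmin == 2]
  }
  list(c1 = length(c1_set), c2 = length(c2_set), c3 = length(c3_set),
       total = length(c1_set) + length(c2_set) + length(c3_set),
       members = list(c1 = sort(c1_set), c2 = sort(c2_set),
                      c3 = sort(c3_set)))
}

#' Order routes by score and identify hub node(s)
#'
#' Routes are ordered by total score (desc), then length (asc), then
#' lexicographic node sequence. The hub is the non-terminal node (or
#' tied nodes) occurring most often among the interior nodes of the
#' `top_k` best routes.
#'
#' @param routes list of routes (character vectors).
#' @param scores list of scores aligned with `routes`
#'   (from [score_route()]).
#' @param top_k number of top routes considered for the hub (default 5).
#' @return list `ranked` (data frame: route string, length, c1, c2, c3,
#'   total, in route order) and `hubs` (character vector, ties together).
#' @export
rank_routes_identify_hub <- function(routes, scores, top_k = 5) {
  assert_that(length(routes) > 0, "empty route list")
  assert_that(length(routes) == length(scores), "routes and scores not aligned")
  df <- data.frame(
    route = vapply(routes, paste, "", collapse = ","),
    length = lengths(routes) - 1L,
    c1 = vapply(scores, `[[`, 0, "c1"),
    c2 = vapply(scores, `[[`, 0, "c2"),
    c3 = vapply(scores, `[[`, 0, "c3"),
    total = vapply(scores, `[[`, 0, "total")
  )
  ord <- order(-df$total, df$length, df$route)
  df <- df[ord, ]; rownames(df) <- NULL
  top <- head(ord, top_k)
  interior <- unlist(lapply(routes[top], function(r) {
    if (length(r) > 2) r[-c(1, length(r))] else character(0)
  }))
  hubs <- character(0)
  if (length(interior)) {
    tab <- table(interior)
    hubs <- sort(names(tab)[tab == max(tab)])
  }
  list(ranked = df, hubs = hubs)
}
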