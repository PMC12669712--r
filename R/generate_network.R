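# Random signed digraphs with a planted source->target route and a ranked
# list with planted overlap counts at graph distances 0/1/2 from the route.
# With edge_prob = 0 the construction makes the route score exact, which is
# what turns these graphs into oracles for the scoring code.

#' Construct a network design
#'
#' @param n_nodes total nodes in the graph (specials included).
#' @param edge_prob probability of each random directed edge.
#' @param sign_probs named probabilities over
#'   `activation`/`inhibition`/`unknown` for random and planted edges.
#' @param source,target endpoint node ids.
#' @param planted_route ordered node ids, a simple path source..target.
#' @param ranked_list_size length of the generated ranked list.
#' @param ranked_overlap_plan counts `c(c1=, c2=, c3=)` of ranked proteins
#'   planted at route distance 0, 1, 2.
#' @export
network_design <- function(n_nodes = 30, edge_prob = 0.05,
                           sign_probs = c(activation = 0.5,
                                          inhibition = 0.3, unknown = 0.2),
                           source = "KSR1", target = "YAP1",
                           planted_route = c("KSR1", "STK4", "LATS1", "YAP1"),
                           ranked_list_size = 10,
                           ranked_overlap_plan = c(c1 = 2, c2 = 3, c3 = 1)) {
  d <- list(n_nodes = as.integer(n_nodes), edge_prob = edge_prob,
            sign_probs = sign_probs, source = toupper(source),
            target = toupper(target),
            planted_route = toupper(planted_route),
            ranked_list_size = as.integer(ranked_list_size),
            ranked_overlap_plan = ranked_overlap_plan)
  assert_that(d$planted_route[1] == d$source &&
              d$planted_route[length(d$planted_route)] == d$target,
              "planted_route must start at source and end at target")
  assert_that(!anyDuplicated(d$planted_route), "planted_route must be a simple path")
  assert_that(all(c("c1", "c2", "c3") %in% names(d$ranked_overlap_plan)),
              "ranked_overlap_plan needs named counts c1, c2, c3")
  assert_that(d$ranked_list_size >= sum(d$ranked_overlap_plan),
              "ranked_list_size smaller than the overlap plan")
  assert_that(d$ranked_overlap_plan[["c1"]] <= length(d$planted_route),
              "cannot plant more c1 proteins than route nodes")
  class(d) <- "hq_network_design"
  d
}

#' Generate a signed digraph with a planted route and ranked list
#'
#' Erdos-Renyi-style random directed edges at `edge_prob`, with the planted
#' route's edges forced present. The ranked list contains, per the overlap
#' plan, route nodes (c1), fresh nodes one undirected edge from a route
#' node (c2), fresh nodes exactly two undirected edges away via a dedicated
#' mediator (c3), and isolated fillers. With `edge_prob = 0`, scoring the
#' planted route returns the plan exactly.
#'
#' @param design a [network_design()].
#' @param seed integer seed.
#' @return list `graph` (igraph with `sign` edge attribute), `ranked`
#'   (character vector), `route` (the planted route).
#' @export
generate_ppi_network <- function(design, seed = 1) {
  stopifnot(inherits(design, "hq_network_design"))
  withr::with_seed(seed, {
    plan <- design$ranked_overlap_plan
    route <- design$planted_route
    n_special <- length(route) + plan[["c2"]] + 2 * plan[["c3"]] +
      (design$ranked_list_size - sum(plan))
    if (design$n_nodes < n_special) {
      stop("overlap plan infeasible: needs at least ", n_special,
           " nodes, n_nodes = ", design$n_nodes, call. = FALSE)
    }
    c2_nodes <- sprintf("ADJ%02d", seq_len(plan[["c2"]]))
    med_nodes <- sprintf("MED%02d", seq_len(plan[["c3"]]))
    c3_nodes <- sprintf("DIST%02d", seq_len(plan[["c3"]]))
    fillers <- sprintf("FAR%02d",
                       seq_len(design$ranked_list_size - sum(plan)))
    n_generic <- design$n_nodes - length(route) - length(c2_nodes) -
      length(med_nodes) - length(c3_nodes) - length(fillers)
    generic <- if (n_generic > 0) sprintf("N%03d", seq_len(n_generic)) else character(0)
    nodes <- c(route, c2_nodes, med_nodes, c3_nodes, fillers, generic)

    ef <- character(0); et <- character(0)
    add_edge <- function(a, b) { ef <<- c(ef, a); et <<- c(et, b) }
    # planted route edges
    for (i in seq_len(length(route) - 1)) add_edge(route[i], route[i + 1])
    # c2: one edge (random direction) between a route node and the adjunct
    for (x in c2_nodes) {
      rn <- sample(route, 1)
      if (runif(1) < 0.5) add_edge(rn, x) else add_edge(x, rn)
    }
    # c3: route node - mediator - distant node (random directions)
    for (i in seq_along(c3_nodes)) {
      rn <- sample(route, 1)
      m <- med_nodes[i]; y <- c3_nodes[i]
      if (runif(1) < 0.5) add_edge(rn, m) else add_edge(m, rn)
      if (runif(1) < 0.5) add_edge(m, y) else add_edge(y, m)
    }
    # random background edges
    if (design$edge_prob > 0) {
      pairs <- expand.grid(a = nodes, b = nodes, stringsAsFactors = FALSE)
      pairs <- pairs[pairs$a != pairs$b, ]
      on <- runif(nrow(pairs)) < design$edge_prob
      ef <- c(ef, pairs$a[on]); et <- c(et, pairs$b[on])
    }
    dup <- duplicated(paste(ef, et))
    ef <- ef[!dup]; et <- et[!dup]
    signs <- sample(names(design$sign_probs), length(ef), replace = TRUE,
                    prob = design$sign_probs)
    g <- igraph::graph_from_data_frame(
      data.frame(from = ef, to = et, sign = signs),
      directed = TRUE, vertices = nodes)

    c1_pick <- sample(route, plan[["c1"]])
    ranked <- c(c1_pick, c2_nodes, c3_nodes, fillers)
    ranked <- sample(ranked)  # order carries no information here
    list(graph = g, ranked = ranked, route = route)
  })
}
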