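# Signed-network parsing, route enumeration and scoring, hub identification.
# Enumeration and scoring are checked against hand-rolled brute-force
# oracles that do not use igraph.

write_edges <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("entity_a\tentity_b\teffect", lines), f)
  f
}

test_that("SIGNOR parsing dedupes, case-folds, drops self-loops, checks columns", {
  f <- write_edges(c("A\tB\tup-regulates activity",
                     "A\tB\tup-regulates activity",
                     "B\tC\tdown-regulates"))
  g <- read_signor(f)
  expect_equal(igraph::ecount(g), 2)
  expect_setequal(igraph::E(g)$sign, c("activation", "inhibition"))

  f2 <- write_edges(c("A\tA\tbinding", "A\tB\tbinding"))
  expect_message(g2 <- read_signor(f2), "1 self-loop")
  expect_equal(igraph::ecount(g2), 1)
  expect_equal(igraph::E(g2)$sign, "unknown")

  f3 <- write_edges(c("Yap1\tCcn1\tup-regulates", "YAP1\tTEAD1\tbinding"))
  g3 <- read_signor(f3)
  expect_equal(sum(igraph::V(g3)$name == "YAP1"), 1)

  f4 <- tempfile(); writeLines(c("a\tb", "A\tB"), f4)
  expect_error(read_signor(f4), "mandatory column")
  f5 <- tempfile(); writeLines("entity_a\tentity_b\teffect", f5)
  expect_error(read_signor(f5), "empty")
})

test_that("route enumeration matches hand enumeration on a toy graph", {
  f <- write_edges(c("S\tM\tbinding", "M\tT\tbinding", "S\tT\tbinding"))
  g <- read_signor(f)
  r <- enumerate_routes(g, "S", "T", max_len = 2)
  expect_equal(lapply(r, identity)[1:2],
               list(c("S", "T"), c("S", "M", "T")))
  expect_length(enumerate_routes(g, "S", "T", max_len = 1), 1)
  # no direct edge and max_len 1 -> empty
  f2 <- write_edges("S\tM\tbinding")
  g2 <- read_signor(f2)
  expect_error(enumerate_routes(g2, "S", "T"), "absent")
  expect_error(enumerate_routes(g, "S", "S"), "must differ")
})

test_that("enumeration matches brute force on random graphs (100 seeds)", {
  for (s in 1:100) {
    n <- sample(4:8, 1)
    edges <- random_edge_df(n, runif(1, 0.15, 0.5), seed = s)
    if (nrow(edges) == 0) next
    g <- igraph::graph_from_data_frame(
      edges, directed = TRUE,
      vertices = LETTERS[seq_len(n)])
    ml <- sample(2:4, 1)
    mine <- enumerate_routes(g, "A", LETTERS[n], max_len = ml)
    oracle <- brute_force_paths(edges, "A", LETTERS[n], max_len = ml)
    key <- function(p) paste(p, collapse = ">")
    expect_setequal(vapply(mine, key, ""), vapply(oracle, key, ""))
  }
})

test_that("route scoring matches the distance-based oracle on random graphs", {
  set.seed(99)
  for (s in 1:100) {
    n <- sample(5:8, 1)
    edges <- random_edge_df(n, runif(1, 0.2, 0.5), seed = 1000 + s)
    if (nrow(edges) == 0) next
    nodes <- LETTERS[seq_len(n)]
    g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = nodes)
    routes <- enumerate_routes(g, "A", nodes[n], max_len = 4)
    if (!length(routes)) next
    ranked <- sample(c(nodes, paste0("X", 1:3)), 5)
    for (r in routes[seq_len(min(3, length(routes)))]) {
      mine <- score_route(r, g, ranked)
      oracle <- brute_force_score(r, edges, nodes, toupper(ranked))
      expect_equal(c(mine$c1, mine$c2, mine$c3), unname(oracle))
      expect_lte(mine$total, length(unique(ranked)))  # boundedness
    }
  }
})

test_that("criteria are disjoint: a route protein is counted only in c1", {
  f <- write_edges(c("S\tM\tbinding", "M\tT\tbinding", "M\tM2\tbinding"))
  g <- read_signor(f)
  # M is on the route AND adjacent to route nodes; counted once, in c1
  sc <- score_route(c("S", "M", "T"), g, c("M", "M2"))
  expect_equal(c(sc$c1, sc$c2, sc$c3), c(1, 1, 0))
})

test_that("adding an edge never decreases c2 + c3 at fixed c1", {
  set.seed(7)
  for (i in 1:25) {
    n <- 7
    edges <- random_edge_df(n, 0.25, seed = 2000 + i)
    nodes <- LETTERS[seq_len(n)]
    route <- c("A", "B")  # fixed node pair as pseudo-route
    ranked <- sample(nodes, 4)
    base_edges <- rbind(edges, data.frame(from = "A", to = "B"))
    g1 <- igraph::graph_from_data_frame(base_edges, directed = TRUE,
                                        vertices = nodes)
    s1 <- score_route(route, g1, setdiff(ranked, route))
    # add one random absent edge
    cand <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
    cand <- cand[cand$from != cand$to, ]
    have <- paste(base_edges$from, base_edges$to)
    cand <- cand[!paste(cand$from, cand$to) %in% have, ]
    extra <- cand[sample(nrow(cand), 1), ]
    g2 <- igraph::graph_from_data_frame(rbind(base_edges, extra),
                                        directed = TRUE, vertices = nodes)
    s2 <- score_route(route, g2, setdiff(ranked, route))
    expect_gte(s2$c2 + s2$c3, s1$c2 + s1$c3)
  }
})

test_that("route ranking and hub identification follow the counting rule", {
  routes <- list(c("S", "M", "T"), c("S", "M", "X", "T"), c("S", "Y", "T"),
                 c("S", "M", "Z", "T"), c("S", "M", "W", "T"))
  scores <- lapply(c(5, 4, 3, 3, 2), function(t)
    list(c1 = t, c2 = 0, c3 = 0, total = t))
  rk <- rank_routes_identify_hub(routes, scores, top_k = 5)
  expect_equal(rk$hubs, "M")  # M interior in 4 of top 5
  expect_equal(rk$ranked$total, c(5, 4, 3, 3, 2))
  # equal totals: order falls back to length then lexicographic
  scores_eq <- lapply(1:5, function(i) list(c1 = 1, c2 = 0, c3 = 0, total = 1))
  rk2 <- rank_routes_identify_hub(routes, scores_eq, top_k = 5)
  expect_equal(rk2$ranked$route[1], "S,M,T")  # shortest, then alphabetical
  expect_equal(rk2$ranked$route[2], "S,Y,T")
  # single route: all interior nodes tie as hub
  rk3 <- rank_routes_identify_hub(list(c("S", "A", "B", "T")),
                                  list(list(c1 = 0, c2 = 0, c3 = 0, total = 0)))
  expect_setequal(rk3$hubs, c("A", "B"))
  expect_error(rank_routes_identify_hub(list(), list()), "empty")
})

test_that("the packaged toy network identifies the MST1 kinase as hub", {
  g <- read_signor(hq_fixture("network", "toy_signor.tsv"))
  routes <- enumerate_routes(g, "KSR1", "YAP1", max_len = 4)
  ranked <- c("STK4", "LATS1", "LATS2", "MAPK1", "RHOA", "AMOT", "CCN1", "PXN")
  scores <- lapply(routes, score_route, graph = g, ranked = ranked)
  rk <- rank_routes_identify_hub(routes, scores, top_k = 5)
  expect_equal(rk$hubs, "STK4")
})
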